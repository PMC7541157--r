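# Shared fixtures and independent oracles for the test suite.

# A desk-scale cohort configuration: same statistical shape as the default
# (two epigenotypes, four planted categories, bad calibration probes) at a
# fraction of the gene count so unit tests run in milliseconds.
tiny_config <- function(seed = 1L, beta_noise_sd = 0.05, ...) {
  cohort_config(seed = seed,
                n_tumors = 20L, n_high = 6L,
                n_genes_by_category = c(unmethylated = 40L,
                                        high_meth_marker = 12L,
                                        commonly_methylated = 5L,
                                        normally_methylated = 10L,
                                        filler_low_cpg = 12L),
                beta_noise_sd = beta_noise_sd,
                max_probes_per_gene = 5L,
                promoter_length = 1000L, ...)
}

tiny_fit <- function(bundle, ...) {
  epitype(bundle$betas, bundle$manifest, bundle$sequences,
          bundle$sample_roles, calibration = bundle$calibration,
          clinical = bundle$clinical,
          prc_genes = bundle$prc$PRC_TARGETS_ES, ...)
}

# Brute-force CpG observed/expected counter: explicit base-by-base loop,
# independent of the Biostrings-backed implementation.
bf_cpg_score <- function(s) {
  v <- strsplit(s, "")[[1]]
  nC <- sum(v == "C"); nG <- sum(v == "G")
  if (nC == 0 || nG == 0) return(0)
  L <- sum(v != "N")
  nCG <- 0L
  for (i in seq_len(length(v) - 1L))
    if (v[i] == "C" && v[i + 1L] == "G") nCG <- nCG + 1L
  nCG * L / (nC * nG)
}

# Naive O(n^3) Ward agglomeration on squared Euclidean distances
# (Lance-Williams recurrence), returning merge heights on the distance
# scale used by hclust's ward.D2.
naive_ward_heights <- function(D) {
  D2 <- as.matrix(D)^2
  n <- ncol(D2)
  sizes <- rep(1L, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(active)) for (b in seq_len(a - 1L)) {
      i <- active[a]; j <- active[b]
      h <- sqrt(D2[i, j])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bh)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, best)) {
      nk <- sizes[k]
      D2[i, k] <- D2[k, i] <-
        ((ni + nk) * D2[i, k] + (nj + nk) * D2[j, k] - nk * D2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Exhaustive two-sided Fisher oracle: enumerates every table with the
# observed margins and sums the hypergeometric probabilities (computed from
# choose(), not dhyper) of tables no more probable than the observed one.
enum_fisher_p <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  m <- a + c_; k <- a + b
  x <- max(0L, k - (N - m)):min(k, m)
  pr <- choose(m, x) * choose(N - m, k - x) / choose(N, k)
  p_obs <- choose(m, a) * choose(N - m, k - a) / choose(N, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Agreement of two 2-class labelings up to label swap.
label_agreement <- function(a, b) {
  b <- b[names(a)]
  max(mean(a == b), mean(a != b))
}
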