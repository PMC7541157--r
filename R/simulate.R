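# Synthetic cohort generator: seeded fixture bundles with planted truth.
# Promoter sequences are synthesized at byte level (raw vectors) so that a
# full-size bundle builds in seconds.

CATEGORIES <- c("unmethylated", "high_meth_marker", "commonly_methylated",
                "normally_methylated", "filler_low_cpg")

# Planted marker gene names; the first entries are the genes reported as
# frequently hypermethylated in melanoma, the remainder synthetic symbols.
marker_gene_names <- function(n) {
  known <- c("TFPI2", "P4HTM", "ACADL", "DDIT4L")
  if (n <= length(known)) return(known[seq_len(n)])
  c(known, sprintf("MARK%03d", seq.int(length(known) + 1L, n)))
}

plant_gene_table <- function(cfg) {
  counts <- cfg$n_genes_by_category[CATEGORIES]
  genes <- c(sprintf("UNM%05d", seq_len(counts[["unmethylated"]])),
             marker_gene_names(counts[["high_meth_marker"]]),
             sprintf("COM%03d", seq_len(counts[["commonly_methylated"]])),
             sprintf("NRM%04d", seq_len(counts[["normally_methylated"]])),
             sprintf("LCG%05d", seq_len(counts[["filler_low_cpg"]])))
  data.frame(gene = genes,
             category = rep(CATEGORIES, counts),
             stringsAsFactors = FALSE)
}

# Raw-byte sequence synthesis. Three promoter archetypes:
#   hcp: CpG forced every 8 bp on an iid background  -> score ~ 1.5
#   icp: CpG-depleted background, CpG every 28 bp    -> score ~ 0.55-0.78
#   lcp: CpG-depleted iid background                 -> score 0
.BASES <- charToRaw("ACGT")
.C <- charToRaw("C"); .G <- charToRaw("G"); .T <- charToRaw("T")

synth_promoter_block <- function(n_genes, len, archetype) {
  if (n_genes == 0L) return(character(0))
  total <- n_genes * len
  b <- sample(.BASES, total, replace = TRUE)
  within_gene <- function(i) i %% len != 0L  # CG pair must not span genes
  suppress <- function(b, keep_starts = integer(0)) {
    i <- which(b[-length(b)] == .C & b[-1L] == .G)
    i <- i[within_gene(i)]
    if (length(keep_starts)) i <- setdiff(i, keep_starts)
    if (length(i)) b[i + 1L] <- .T
    b
  }
  force_cg <- function(b, by) {
    st <- seq.int(1L, len - 1L, by = by)
    gst <- rep((seq_len(n_genes) - 1L) * len, each = length(st)) + st
    b[gst] <- .C; b[gst + 1L] <- .G
    list(b = b, starts = gst)
  }
  if (archetype == "hcp") {
    b <- force_cg(b, 8L)$b
  } else if (archetype == "icp") {
    b <- suppress(b)
    f <- force_cg(b, 28L)
    b <- suppress(f$b, keep_starts = f$starts)
  } else {
    b <- suppress(b)
  }
  big <- rawToChar(b)
  substring(big, seq.int(1L, total, by = len), seq.int(len, total, by = len))
}

#' Generate the synthetic probe manifest and promoter sequences
#'
#' Lays out 1 to `max_probes_per_gene` promoter probes per gene at signed TSS
#' distances in \[-1500, +500\] bp and synthesizes a promoter sequence
#' (`promoter_length` bp centered on the TSS, transcription orientation)
#' whose CpG score lands in the promoter class implied by the gene's planted
#' category: genes that take part in the promoter analysis get high- or
#' intermediate-CpG sequence, filler genes low-CpG sequence. The exemplar
#' gene TFPI2 always carries the maximum probe count with its nearest probe
#' 15 bp upstream of the TSS.
#'
#' @param config A [cohort_config()] object.
#' @return A list with `manifest` (data.frame: probe_id, gene, chrom,
#'   position, strand, tss), `sequences` (a named
#'   [Biostrings::DNAStringSet], names `gene|chrom|tss|strand`) and
#'   `gene_table` (gene, category, n_probes).
#' @export
generate_manifest <- function(config) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)
  gt <- plant_gene_table(cfg)
  n_genes <- nrow(gt)
  len <- cfg$promoter_length

  # probe counts cycle 1..max deterministically so bundle shapes do not
  # depend on the seed; the TFPI2 exemplar always gets the maximum
  gt$n_probes <- rep_len(seq_len(cfg$max_probes_per_gene), n_genes)
  is_tfpi2 <- gt$gene == "TFPI2"
  gt$n_probes[is_tfpi2] <- cfg$max_probes_per_gene

  idx <- seq_len(n_genes)
  chrom <- paste0("chr", ((idx - 1L) %% 22L) + 1L)
  tss <- 1e6 + 1e4 * (((idx - 1L) %/% 22L) + 1L)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  dist_pool <- seq.int(-1500L, 500L)
  distances <- lapply(idx, function(i) {
    k <- gt$n_probes[i]
    if (is_tfpi2[i] && k >= 2L)
      c(-15L, sample(dist_pool[abs(dist_pool) > 15L], k - 1L))
    else if (is_tfpi2[i]) -15L
    else sample(dist_pool, k)
  })
  per_gene <- gt$n_probes
  gi <- rep(idx, per_gene)
  d <- unlist(distances)
  position <- ifelse(strand[gi] == "+", tss[gi] + d, tss[gi] - d)
  manifest <- data.frame(probe_id = sprintf("cg%08d", seq_along(gi)),
                         gene = gt$gene[gi], chrom = chrom[gi],
                         position = position, strand = strand[gi],
                         tss = tss[gi], stringsAsFactors = FALSE)

  arch <- c(unmethylated = "hcp", high_meth_marker = "hcp",
            commonly_methylated = "hcp", normally_methylated = "icp",
            filler_low_cpg = "lcp")[gt$category]
  seqs <- character(n_genes)
  for (a in c("hcp", "icp", "lcp"))
    seqs[arch == a] <- synth_promoter_block(sum(arch == a), len, a)
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- paste(gt$gene, chrom, tss, strand, sep = "|")

  list(manifest = manifest, sequences = dss, gene_table = gt)
}

# Choose the corrupted-calibration probes. One randomly chosen probe per
# gene is protected so that no gene can lose its entire promoter to QC.
plant_bad_probes <- function(config, manifest) {
  cfg <- validate_cohort_config(config)
  n_bad <- round(cfg$frac_bad_probes * nrow(manifest))
  if (n_bad == 0L)
    return(data.frame(probe_id = character(0), mode = character(0)))
  prot <- vapply(split(manifest$probe_id, manifest$gene),
                 function(p) p[sample.int(length(p), 1L)], character(1))
  pool <- setdiff(manifest$probe_id, prot)
  n_bad <- min(n_bad, length(pool))
  bad <- sample(pool, n_bad)
  data.frame(probe_id = bad,
             mode = rep_len(c("flat", "inverted"), n_bad),
             stringsAsFactors = FALSE)
}

#' Generate the cohort beta matrix with planted epigenotype structure
#'
#' Every beta cell is `clamp[0,1](base + Normal(0, beta_noise_sd))`, with the
#' base level set by the gene's planted category and the sample's latent
#' epigenotype: unmethylated genes sit at the unmethylated level everywhere;
#' each high-methylation marker gene is methylated in a per-gene fraction
#' (drawn from `marker_freq_range`) of all tumors, the methylated samples
#' drawn from the high-epigenotype subgroup only; commonly methylated genes
#' are methylated in all tumors of both subgroups but not in normals;
#' normally methylated genes are methylated in every sample; filler low-CpG
#' genes get an intermediate per-gene base so they carry no subgroup signal.
#' Probes planted with a corrupted calibration response report a flat 0.5
#' (or inverted) signal in the cohort as well.
#'
#' @param config A [cohort_config()] object.
#' @param manifest,gene_table From [generate_manifest()].
#' @param truth Optional list with pre-drawn `epigenotype` (named vector over
#'   tumor samples, values `"high"`/`"low"`) and `bad_probes` (data.frame
#'   probe_id, mode); drawn here when `NULL`.
#' @return A list: `betas` (probes x samples matrix), `sample_roles` (named
#'   `"tumor"`/`"normal"`), and `truth` (epigenotype, bad_probes,
#'   marker_freq, gene_category).
#' @export
generate_cohort_betas <- function(config, manifest, gene_table, truth = NULL) {
  cfg <- validate_cohort_config(config)
  if (!all(manifest$gene %in% gene_table$gene))
    stop("manifest and gene_table disagree on gene identities")
  set.seed(cfg$seed + 1L)

  tumors <- sprintf("MM%02d", seq_len(cfg$n_tumors))
  normals <- paste0("N_", cfg$normal_roles)
  samples <- c(tumors, normals)
  roles <- setNames(rep(c("tumor", "normal"), c(length(tumors), length(normals))),
                    samples)

  if (is.null(truth$epigenotype)) {
    epi <- setNames(rep("low", cfg$n_tumors), tumors)
    epi[sample.int(cfg$n_tumors, cfg$n_high)] <- "high"
  } else epi <- truth$epigenotype
  if (is.null(truth$bad_probes)) bad <- plant_bad_probes(cfg, manifest)
  else bad <- truth$bad_probes
  high_idx <- which(epi == "high")

  n_genes <- nrow(gene_table)
  state <- matrix(FALSE, n_genes, length(samples),
                  dimnames = list(gene_table$gene, samples))
  marker_freq <- numeric(0)
  is_tumor <- roles == "tumor"

  mk <- which(gene_table$category == "high_meth_marker")
  if (length(mk)) {
    # per-gene methylated-tumor counts drawn uniformly over the counts whose
    # cohort frequency k/n_tumors lies inside marker_freq_range
    k_lo <- ceiling(cfg$marker_freq_range[1] * cfg$n_tumors)
    k_hi <- floor(cfg$marker_freq_range[2] * cfg$n_tumors)
    if (k_lo > k_hi) k_lo <- k_hi <- round(mean(cfg$marker_freq_range) *
                                             cfg$n_tumors)
    k <- sample(seq.int(k_lo, k_hi), length(mk), replace = TRUE)
    # TFPI2 is planted as the most frequently methylated marker
    tf <- match("TFPI2", gene_table$gene[mk])
    if (!is.na(tf)) k[tf] <- k_hi
    k <- pmin(pmax(k, 1L), length(high_idx))
    marker_freq <- setNames(k / cfg$n_tumors, gene_table$gene[mk])
    for (j in seq_along(mk))
      state[mk[j], high_idx[sample.int(length(high_idx), k[j])]] <- TRUE
  }
  state[gene_table$category == "commonly_methylated", is_tumor] <- TRUE
  state[gene_table$category == "normally_methylated", ] <- TRUE

  base_gene <- matrix(ifelse(state, cfg$beta_meth, cfg$beta_unmeth),
                      n_genes, length(samples))
  fill <- gene_table$category == "filler_low_cpg"
  base_gene[fill, ] <- runif(sum(fill), 0.3, 0.7)  # constant across samples

  gi <- match(manifest$gene, gene_table$gene)
  base <- base_gene[gi, , drop = FALSE]
  bi <- match(bad$probe_id, manifest$probe_id)
  if (length(bi)) {
    flat <- bi[bad$mode == "flat"]
    inv <- bi[bad$mode == "inverted"]
    base[flat, ] <- 0.5
    base[inv, ] <- 1 - base[inv, , drop = FALSE]
  }
  betas <- base
  if (cfg$beta_noise_sd > 0)
    betas <- betas + rnorm(length(betas), 0, cfg$beta_noise_sd)
  betas <- pmin(pmax(betas, 0), 1)
  dimnames(betas) <- list(manifest$probe_id, samples)

  list(betas = betas, sample_roles = roles,
       truth = list(epigenotype = epi, bad_probes = bad,
                    marker_freq = marker_freq,
                    gene_category = setNames(gene_table$category,
                                             gene_table$gene)))
}

#' Generate the calibration dilution series
#'
#' Emulates control samples of 0, 25, 50, 75 and 100% methylation assayed on
#' every probe. Well-behaved probes report the expected fraction plus small
#' Gaussian noise (`calib_noise_sd`); probes planted as bad report a flat
#' 0.5 or an inverted response, so that quantitative-accuracy QC must
#' exclude them.
#'
#' @param config A [cohort_config()] object.
#' @param manifest From [generate_manifest()].
#' @param bad_probes Optional data.frame (probe_id, mode); drawn via
#'   [plant_bad_probes] under the config seed when `NULL`.
#' @return Long-format data.frame: probe_id, expected_fraction,
#'   measured_beta (5 rows per probe).
#' @export
generate_calibration_betas <- function(config, manifest, bad_probes = NULL) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + 2L)
  if (is.null(bad_probes)) bad_probes <- plant_bad_probes(cfg, manifest)
  expected <- c(0, 0.25, 0.5, 0.75, 1)
  n <- nrow(manifest)
  mode <- rep("good", n)
  mode[match(bad_probes$probe_id, manifest$probe_id)] <- bad_probes$mode
  truthv <- matrix(expected, n, 5L, byrow = TRUE)
  truthv[mode == "flat", ] <- 0.5
  if (any(mode == "inverted"))
    truthv[mode == "inverted", ] <- matrix(1 - expected,
                                           sum(mode == "inverted"), 5L,
                                           byrow = TRUE)
  meas <- truthv
  if (cfg$calib_noise_sd > 0)
    meas <- meas + rnorm(length(meas), 0, cfg$calib_noise_sd)
  meas <- pmin(pmax(meas, 0), 1)
  data.frame(probe_id = rep(manifest$probe_id, each = 5L),
             expected_fraction = rep(expected, n),
             measured_beta = as.vector(t(meas)),
             stringsAsFactors = FALSE)
}

#' Generate the synthetic clinical table
#'
#' Breslow thickness is drawn per latent subgroup from the configured
#' normals (clamped below at `floor`); overall survival is exponential with
#' subgroup-specific hazard (high-methylation worse) and independent
#' exponential censoring calibrated to the configured censor rate; clinical
#' stage is enriched for 3-4 in the high subgroup; BRAF/NRAS hotspot status
#' (mutually exclusive), acral site, ulceration and age are drawn
#' independently of epigenotype.
#'
#' @param config A [cohort_config()] object.
#' @param epigenotype Named vector over tumor samples, values
#'   `"high"`/`"low"`.
#' @return data.frame: sample, age, stage, thickness_mm, os_days, event,
#'   braf, nras, acral, ulcer.
#' @export
generate_clinical_table <- function(config, epigenotype) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + 3L)
  n <- length(epigenotype)
  hi <- epigenotype == "high"
  tp <- cfg$thickness_params
  mu <- ifelse(hi, tp$high[["mean"]], tp$low[["mean"]])
  sdv <- ifelse(hi, tp$high[["sd"]], tp$low[["sd"]])
  thickness <- pmax(rnorm(n, mu, sdv), tp$floor)

  sp <- cfg$survival_params
  haz <- ifelse(hi, sp$hazard_high, sp$hazard_low)
  tt <- rexp(n, haz)
  cr <- sp$censor_rate
  cens <- if (cr > 0) rexp(n, haz * cr / (1 - cr)) else rep(Inf, n)
  os <- pmin(tt, cens)
  event <- as.integer(tt <= cens)

  p34 <- ifelse(hi, cfg$stage34_prob[["high"]], cfg$stage34_prob[["low"]])
  adv <- runif(n) < p34
  stage <- ifelse(adv, sample(3:4, n, replace = TRUE),
                  sample(1:2, n, replace = TRUE))

  mf <- cfg$mutation_freqs
  u <- runif(n)
  braf <- as.integer(u < mf[["braf"]])
  nras <- as.integer(u >= mf[["braf"]] & u < mf[["braf"]] + mf[["nras"]])
  acral <- as.integer(runif(n) < mf[["acral"]])
  ulcer <- as.integer(runif(n) < cfg$ulcer_prob)
  age <- as.integer(round(pmin(pmax(rnorm(n, 65, 14), 20), 95)))

  data.frame(sample = names(epigenotype), age = age, stage = stage,
             thickness_mm = round(thickness, 2),
             os_days = round(os, 1), event = event,
             braf = braf, nras = nras, acral = acral, ulcer = ulcer,
             stringsAsFactors = FALSE)
}

generate_prc_set <- function(config, gene_table) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + 4L)
  members <- character(0)
  for (cat in names(cfg$prc_frac)) {
    g <- gene_table$gene[gene_table$category == cat]
    k <- round(cfg$prc_frac[[cat]] * length(g))
    if (k > 0) members <- c(members, sample(g, k))
  }
  list(PRC_TARGETS_ES = sort(members))
}

#' Simulate a complete synthetic methylation cohort
#'
#' Runs every generator stage under the configuration seed and returns the
#' full fixture bundle: manifest and promoter sequences, cohort beta matrix,
#' calibration dilution series, clinical table, synthetic Polycomb target
#' gene set, and the planted ground truth. Identical configurations produce
#' identical bundles.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `cohort_bundle`: a list with elements
#'   `config`, `manifest`, `sequences`, `gene_table`, `betas`,
#'   `sample_roles`, `calibration`, `clinical`, `prc` and `truth`.
#' @examples
#' cfg <- cohort_config(seed = 1, n_tumors = 12, n_high = 4,
#'   n_genes_by_category = c(unmethylated = 30, high_meth_marker = 5,
#'     commonly_methylated = 4, normally_methylated = 6, filler_low_cpg = 8))
#' bundle <- simulate_cohort(cfg)
#' dim(bundle$betas)
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  man <- generate_manifest(cfg)
  set.seed(cfg$seed + 5L)
  bad <- plant_bad_probes(cfg, man$manifest)
  bet <- generate_cohort_betas(cfg, man$manifest, man$gene_table,
                               truth = list(bad_probes = bad))
  calib <- generate_calibration_betas(cfg, man$manifest, bad_probes = bad)
  clin <- generate_clinical_table(cfg, bet$truth$epigenotype)
  prc <- generate_prc_set(cfg, man$gene_table)
  structure(list(config = cfg, manifest = man$manifest,
                 sequences = man$sequences, gene_table = man$gene_table,
                 betas = bet$betas, sample_roles = bet$sample_roles,
                 calibration = calib, clinical = clin, prc = prc,
                 truth = bet$truth),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic methylation cohort bundle (seed", x$config$seed, ")\n")
  cat(" ", nrow(x$manifest), "probes /", nrow(x$gene_table), "genes;",
      sum(x$sample_roles == "tumor"), "tumors +",
      sum(x$sample_roles == "normal"), "normals\n")
  cat("  planted high-epigenotype tumors:",
      sum(x$truth$epigenotype == "high"), "\n")
  cat("  planted bad probes:", nrow(x$truth$bad_probes), "\n")
  invisible(x)
}
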