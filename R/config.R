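#' Configuration for the synthetic methylation cohort generator
#'
#' Builds and validates the parameter set that [simulate_cohort()] uses to
#' generate a seeded fixture bundle (manifest, promoter sequences, beta
#' matrix, calibration dilution series, clinical table, Polycomb target gene
#' set, and planted ground truth). Defaults mirror the structure of a
#' 51-tumor melanoma cohort: two latent methylation epigenotypes, three
#' normal reference samples, planted marker-gene categories with counts
#' 4444/27/25/405, marker methylation frequencies of 22-33% of tumors,
#' Breslow thickness of 8.3 +/- 5.3 mm (high subgroup) vs 4.5 +/- 2.9 mm
#' (low), and BRAF/NRAS/acral prevalences of 18/77, 20/77 and 35/77.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_tumors Number of tumor samples.
#' @param n_normals Number of normal reference samples.
#' @param normal_roles Labels for the normal samples.
#' @param n_high Number of tumors in the latent high-methylation epigenotype.
#' @param n_genes_by_category Named integer vector of planted gene counts for
#'   the categories `unmethylated`, `high_meth_marker`, `commonly_methylated`,
#'   `normally_methylated` and `filler_low_cpg` (low-CpG promoter genes that
#'   never enter the promoter analysis).
#' @param marker_freq_range Interval from which each marker gene's
#'   methylation frequency among all tumors is drawn; the methylated samples
#'   are drawn from the high subgroup only.
#' @param beta_noise_sd Standard deviation of the Gaussian beta-scale noise
#'   added to every cohort beta cell (clamped to `[0,1]`).
#' @param calib_noise_sd Noise SD for the calibration dilution series; the
#'   control series is cleaner than FFPE tumor material.
#' @param frac_bad_probes Fraction of probes planted with a corrupted (flat
#'   or inverted) calibration response.
#' @param beta_unmeth,beta_meth Base beta levels of the unmethylated and
#'   methylated promoter states.
#' @param thickness_params List with per-subgroup `high = c(mean, sd)` and
#'   `low = c(mean, sd)` Breslow thickness (mm) and a lower clamp `floor`.
#' @param survival_params List with `hazard_high`, `hazard_low` (per-day
#'   exponential hazards of melanoma-related death) and `censor_rate`
#'   (target fraction of censored observations).
#' @param mutation_freqs Named vector of `braf`, `nras` and `acral`
#'   prevalences (drawn independently of epigenotype).
#' @param stage34_prob Probability of clinical stage 3-4 per subgroup
#'   (`high`, `low`); stages are enriched in the high epigenotype.
#' @param ulcer_prob Ulceration prevalence.
#' @param prc_frac Named vector: fraction of each gene category planted as
#'   Polycomb (PRC) targets in the generated gene set.
#' @param max_probes_per_gene Maximum promoter probes per gene (drawn
#'   uniformly from 1..max; the TFPI2 exemplar always gets the maximum).
#' @param promoter_length Length (bp) of each synthesized promoter sequence,
#'   centered on the TSS.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [simulate_cohort()], [write_cohort()]
#' @examples
#' cfg <- cohort_config(seed = 1, n_tumors = 12, n_high = 4,
#'   n_genes_by_category = c(unmethylated = 30, high_meth_marker = 5,
#'     commonly_methylated = 4, normally_methylated = 6, filler_low_cpg = 8))
#' @export
cohort_config <- function(seed = 1L,
                          n_tumors = 51L,
                          n_normals = 3L,
                          normal_roles = c("melanocyte", "PBMC", "fibroblast"),
                          n_high = 17L,
                          n_genes_by_category = c(unmethylated = 4444L,
                                                  high_meth_marker = 27L,
                                                  commonly_methylated = 25L,
                                                  normally_methylated = 405L,
                                                  filler_low_cpg = 2000L),
                          marker_freq_range = c(0.22, 0.33),
                          beta_noise_sd = 0.05,
                          calib_noise_sd = 0.02,
                          frac_bad_probes = 0.03,
                          beta_unmeth = 0.1,
                          beta_meth = 0.8,
                          thickness_params = list(high = c(mean = 8.3, sd = 5.3),
                                                  low = c(mean = 4.5, sd = 2.9),
                                                  floor = 0.1),
                          survival_params = list(hazard_high = log(2) / 730,
                                                 hazard_low = log(2) / 1825,
                                                 censor_rate = 0.4),
                          mutation_freqs = c(braf = 18 / 77, nras = 20 / 77,
                                             acral = 35 / 77),
                          stage34_prob = c(high = 0.8, low = 0.3),
                          ulcer_prob = 0.4,
                          prc_frac = c(unmethylated = 0.1,
                                       high_meth_marker = 0.6,
                                       commonly_methylated = 0.1,
                                       normally_methylated = 0.1),
                          max_probes_per_gene = 21L,
                          promoter_length = 2000L) {
  cfg <- list(seed = as.integer(seed), n_tumors = as.integer(n_tumors),
              n_normals = as.integer(n_normals), normal_roles = normal_roles,
              n_high = as.integer(n_high),
              n_genes_by_category = n_genes_by_category,
              marker_freq_range = marker_freq_range,
              beta_noise_sd = beta_noise_sd, calib_noise_sd = calib_noise_sd,
              frac_bad_probes = frac_bad_probes,
              beta_unmeth = beta_unmeth, beta_meth = beta_meth,
              thickness_params = thickness_params,
              survival_params = survival_params,
              mutation_freqs = mutation_freqs,
              stage34_prob = stage34_prob, ulcer_prob = ulcer_prob,
              prc_frac = prc_frac,
              max_probes_per_gene = as.integer(max_probes_per_gene),
              promoter_length = as.integer(promoter_length))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  req <- c("unmethylated", "high_meth_marker", "commonly_methylated",
           "normally_methylated", "filler_low_cpg")
  if (!all(req %in% names(cfg$n_genes_by_category)))
    stop("n_genes_by_category must name all of: ", paste(req, collapse = ", "))
  counts <- cfg$n_genes_by_category[req]
  if (any(counts < 0) || counts[["high_meth_marker"]] < 1)
    stop("gene category counts must be non-negative (>=1 marker gene)")
  if (cfg$n_tumors < 2L || cfg$n_normals < 1L)
    stop("need at least 2 tumors and 1 normal sample")
  if (cfg$n_high < 1L || cfg$n_high >= cfg$n_tumors)
    stop("n_high must satisfy 1 <= n_high < n_tumors")
  if (length(cfg$normal_roles) != cfg$n_normals)
    stop("normal_roles must have length n_normals")
  fr <- cfg$marker_freq_range
  if (length(fr) != 2L || fr[1] > fr[2] || fr[1] <= 0 || fr[2] > 1)
    stop("marker_freq_range must be an interval within (0, 1]")
  for (p in c("beta_noise_sd", "calib_noise_sd"))
    if (cfg[[p]] < 0) stop(p, " must be >= 0")
  if (cfg$frac_bad_probes < 0 || cfg$frac_bad_probes >= 1)
    stop("frac_bad_probes must be in [0, 1)")
  if (!(cfg$beta_unmeth >= 0 && cfg$beta_unmeth < cfg$beta_meth &&
        cfg$beta_meth <= 1))
    stop("need 0 <= beta_unmeth < beta_meth <= 1")
  if (any(cfg$mutation_freqs < 0 | cfg$mutation_freqs > 1))
    stop("mutation_freqs must be fractions in [0, 1]")
  if (cfg$mutation_freqs[["braf"]] + cfg$mutation_freqs[["nras"]] > 1)
    stop("braf + nras prevalence must not exceed 1 (calls are exclusive)")
  if (cfg$max_probes_per_gene < 1L) stop("max_probes_per_gene must be >= 1")
  if (cfg$promoter_length < 200L) stop("promoter_length must be >= 200 bp")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic methylation cohort configuration\n")
  cat("  seed:", x$seed, "\n")
  cat("  samples:", x$n_tumors, "tumors (", x$n_high, "high-epigenotype ) +",
      x$n_normals, "normals\n")
  cat("  genes: ", paste(sprintf("%s=%d", names(x$n_genes_by_category),
                                 x$n_genes_by_category), collapse = ", "), "\n")
  cat(sprintf("  beta levels %.2f/%.2f, noise SD %.3f, bad probes %.1f%%\n",
              x$beta_unmeth, x$beta_meth, x$beta_noise_sd,
              100 * x$frac_bad_probes))
  invisible(x)
}

#' Binary methylation-call thresholds
#'
#' Thresholds used to dichotomize beta values and to classify genes into the
#' four marker categories. A beta at or below `beta_unmeth_max` is called
#' unmethylated, at or above `beta_meth_min` methylated, and anything in
#' between indeterminate. Category rules (applied to per-subgroup methylation
#' frequencies, as fractions): a gene whose normal samples are methylated and
#' whose frequency reaches `common_freq_min` in both tumor subgroups is
#' *normally methylated*; with unmethylated normals, frequencies at or below
#' `absent_freq_max` in both subgroups give *unmethylated*, frequency at
#' least `marker_freq_min` in the high subgroup with at most
#' `absent_freq_max` in the low gives *high_meth_marker*, and at least
#' `marker_freq_min` in both gives *commonly_methylated*; everything else is
#' unclassified.
#'
#' `beta_unmeth_max` defaults to 0.25, three noise SDs above the nominal
#' unmethylated level of the synthetic cohort, so that state calls on clean
#' unmethylated promoters are essentially never indeterminate.
#'
#' @param beta_unmeth_max Upper beta bound for an unmethylated call.
#' @param beta_meth_min Lower beta bound for a methylated call.
#' @param marker_freq_min Minimum subgroup methylation fraction for marker /
#'   commonly-methylated calls.
#' @param absent_freq_max Maximum subgroup methylation fraction treated as
#'   absence of methylation.
#' @param common_freq_min Minimum subgroup fraction (both subgroups) for the
#'   normally-methylated category.
#' @return An object of class `call_thresholds`.
#' @export
call_thresholds <- function(beta_unmeth_max = 0.25, beta_meth_min = 0.4,
                            marker_freq_min = 0.20, absent_freq_max = 0.05,
                            common_freq_min = 0.95) {
  if (beta_unmeth_max >= beta_meth_min)
    stop("beta_unmeth_max must be < beta_meth_min")
  if (absent_freq_max >= marker_freq_min)
    stop("absent_freq_max must be < marker_freq_min")
  for (v in c(beta_unmeth_max, beta_meth_min, marker_freq_min,
              absent_freq_max, common_freq_min))
    if (v < 0 || v > 1) stop("all thresholds must lie in [0, 1]")
  structure(list(beta_unmeth_max = beta_unmeth_max,
                 beta_meth_min = beta_meth_min,
                 marker_freq_min = marker_freq_min,
                 absent_freq_max = absent_freq_max,
                 common_freq_min = common_freq_min),
            class = "call_thresholds")
}

#' Analysis parameters for the epigenotyping pipeline
#'
#' Collects every tunable parameter of the analysis stages behind
#' [epitype()] and [run_pipeline()].
#'
#' @param qc_epsilon Maximum absolute calibration error (beta units) a probe
#'   may show across the five dilution points and still pass QC.
#' @param qc_rho Minimum Pearson correlation between measured and expected
#'   dilution betas.
#' @param window Promoter window, in bp relative to the TSS, over which the
#'   CpG score is computed (default -500..+500).
#' @param hcp_min,icp_min CpG-score thresholds: scores above `hcp_min` are
#'   high-CpG promoters, above `icp_min` intermediate, the rest low-CpG.
#' @param sd_threshold Minimum per-gene standard deviation across tumors for
#'   a gene to enter the clustering set.
#' @param top_n Cap on the number of variable genes retained (highest SD
#'   first).
#' @param metric Distance between samples/genes: `"euclidean"` or
#'   `"pearson"` (1 - correlation).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param thresholds A [call_thresholds()] object.
#' @param freq_floor Cohort methylation frequency (percent) above which a
#'   marker gene is reported as frequently methylated.
#' @param thickness_cut Breslow thickness cutpoint (mm) for the categorical
#'   clinical display.
#' @param alpha Significance level for flagging tests.
#' @return An object of class `epitype_control`.
#' @export
epitype_control <- function(qc_epsilon = 0.15, qc_rho = 0.95,
                            window = c(-500L, 500L),
                            hcp_min = 0.72, icp_min = 0.48,
                            sd_threshold = 0.15, top_n = 2000L,
                            metric = c("euclidean", "pearson"),
                            linkage = "ward.D2",
                            thresholds = call_thresholds(),
                            freq_floor = 25, thickness_cut = 4,
                            alpha = 0.05) {
  metric <- match.arg(metric)
  stopifnot(qc_epsilon >= 0, qc_rho >= -1, qc_rho <= 1,
            length(window) == 2L, window[1] < window[2],
            hcp_min > icp_min, icp_min >= 0,
            sd_threshold >= 0, top_n >= 1,
            inherits(thresholds, "call_thresholds"),
            freq_floor >= 0, freq_floor <= 100, alpha > 0, alpha < 1)
  structure(list(qc_epsilon = qc_epsilon, qc_rho = qc_rho,
                 window = as.integer(window),
                 hcp_min = hcp_min, icp_min = icp_min,
                 sd_threshold = sd_threshold, top_n = as.integer(top_n),
                 metric = metric, linkage = linkage,
                 thresholds = thresholds, freq_floor = freq_floor,
                 thickness_cut = thickness_cut, alpha = alpha),
            class = "epitype_control")
}
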