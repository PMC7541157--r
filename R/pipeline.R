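# File-based pipeline orchestration: each stage consumes and produces the
# bundle's TSV interfaces so stages are independently runnable, and
# run_pipeline() chains them with validation and a machine-readable report.

pipeline_stop <- function(stage, ...) {
  cond <- structure(class = c("pipeline_error", "error", "condition"),
                    list(message = paste0("[", stage, "] ", ...),
                         call = sys.call(-1), stage = stage))
  stop(cond)
}

#' Run the probe QC stage on a bundle directory
#'
#' Reads `calibration.tsv`, writes `probe_qc.tsv`.
#'
#' @param indir Bundle directory.
#' @param outdir Output directory.
#' @param control An [epitype_control()] object.
#' @return The QC data.frame, invisibly.
#' @export
stage_qc <- function(indir, outdir, control = epitype_control()) {
  f <- file.path(indir, "calibration.tsv")
  if (!file.exists(f)) pipeline_stop("qc", "missing input ", f)
  qc <- qc_probes(read_tsv(f), epsilon = control$qc_epsilon,
                  rho = control$qc_rho)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(qc, file.path(outdir, "probe_qc.tsv"))
  invisible(qc)
}

#' Run the promoter annotation stage on a bundle directory
#'
#' Reads `manifest.tsv` and `promoters.fasta` (and `probe_qc.tsv` from
#' `outdir` when present), writes `gene_promoters.tsv`.
#'
#' @inheritParams stage_qc
#' @return The gene-promoter annotation data.frame, invisibly.
#' @export
stage_annotate <- function(indir, outdir, control = epitype_control()) {
  fm <- file.path(indir, "manifest.tsv")
  ff <- file.path(indir, "promoters.fasta")
  for (f in c(fm, ff))
    if (!file.exists(f)) pipeline_stop("annotate", "missing input ", f)
  qc_pass <- NULL
  fq <- file.path(outdir, "probe_qc.tsv")
  if (file.exists(fq)) {
    qc <- read_tsv(fq)
    qc_pass <- qc$probe_id[qc$pass]
  }
  ann <- annotate_promoters(read_tsv(fm),
                            Biostrings::readDNAStringSet(ff),
                            qc_pass = qc_pass, control = control)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(ann, file.path(outdir, "gene_promoters.tsv"))
  invisible(ann)
}

#' Run a complete pipeline over a fixture bundle directory
#'
#' Executes annotate -> QC -> epigenotype -> markers -> statistics on the
#' files of a bundle directory, writing every stage output plus a
#' machine-readable `run_report.json` to `outdir`. Any stage failure aborts
#' with a stage-named error; a missing input is detected before any
#' computation.
#'
#' @param config Either a YAML file path or a list with elements `indir`,
#'   `outdir`, and optionally `control` (a list of [epitype_control()]
#'   arguments, with `thresholds` a list of [call_thresholds()] arguments).
#' @return The run report (list), invisibly; the fitted `epityper` object is
#'   attached as attribute `"fit"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$indir) || is.null(config$outdir))
    pipeline_stop("config", "config must name 'indir' and 'outdir'")
  ctl_args <- config$control
  if (!is.null(ctl_args$thresholds))
    ctl_args$thresholds <- do.call(call_thresholds, ctl_args$thresholds)
  if (!is.null(ctl_args$window)) ctl_args$window <- unlist(ctl_args$window)
  control <- do.call(epitype_control, ctl_args %||% list())

  indir <- config$indir; outdir <- config$outdir
  required <- c("manifest.tsv", "promoters.fasta", "betas.tsv",
                "calibration.tsv")
  for (fn in required)
    if (!file.exists(file.path(indir, fn)))
      pipeline_stop("config", "missing input file ", file.path(indir, fn))

  bundle <- read_cohort(indir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  fit <- tryCatch(
    epitype(bundle$betas, bundle$manifest, bundle$sequences,
            bundle$sample_roles, calibration = bundle$calibration,
            clinical = bundle$clinical,
            prc_genes = if (!is.null(bundle$prc)) bundle$prc[[1L]],
            control = control),
    error = function(e) pipeline_stop("fit", conditionMessage(e)))

  write_tsv(fit$qc, file.path(outdir, "probe_qc.tsv"))
  write_tsv(fit$promoters, file.path(outdir, "gene_promoters.tsv"))
  write_tsv(fit$selected_genes, file.path(outdir, "selected_genes.tsv"))
  write_tsv(data.frame(sample = names(fit$labels), label = fit$labels,
                       mean_beta = colMeans(
                         fit$gene_betas[fit$selected_genes$gene,
                                        names(fit$labels), drop = FALSE]),
                       row.names = NULL),
            file.path(outdir, "epigenotypes.tsv"))
  write_tsv(fit$marker_table, file.path(outdir, "marker_table.tsv"))
  write_tsv(fit$frequent_markers, file.path(outdir, "frequent_markers.tsv"))
  if (!is.null(fit$association))
    write_tsv(fit$association, file.path(outdir, "association_report.tsv"))
  if (!is.null(fit$enrichment))
    write_tsv(fit$enrichment, file.path(outdir, "enrichment.tsv"))
  if (!is.null(bundle$clinical)) {
    curves <- do.call(rbind, lapply(c("high", "low"), function(g) {
      sm <- names(fit$labels)[fit$labels == g]
      cl <- bundle$clinical[match(sm, bundle$clinical$sample), ]
      km <- km_estimate(cl$os_days, cl$event)
      cbind(group = g, km$curve)
    }))
    write_tsv(curves, file.path(outdir, "survival_curves.tsv"))
  }

  report <- list(
    inputs = as.list(tools::md5sum(file.path(indir, required))),
    parameters = unclass(control)[c("qc_epsilon", "qc_rho", "hcp_min",
                                    "icp_min", "sd_threshold", "top_n",
                                    "metric", "linkage", "freq_floor")],
    thresholds = unclass(control$thresholds),
    counts = list(
      probes_total = nrow(fit$qc),
      probes_passing_qc = sum(fit$qc$pass),
      genes_analyzed = length(fit$analyzed_genes),
      genes_selected = nrow(fit$selected_genes),
      cluster_sizes = list(high = sum(fit$labels == "high"),
                           low = sum(fit$labels == "low")),
      categories = as.list(fit$category_counts)),
    frequent_markers = fit$frequent_markers$gene,
    tests = if (!is.null(fit$association))
      setNames(as.list(fit$association$p_value), fit$association$factor),
    enrichment = if (!is.null(fit$enrichment))
      setNames(as.list(fit$enrichment$p_value), fit$enrichment$comparison),
    stage_order = c("annotate", "qc", "epitype", "markers", "stats"))
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(report, "fit") <- fit
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort and write its bundle to disk
#'
#' Convenience wrapper combining [simulate_cohort()] and [write_cohort()].
#'
#' @param config A [cohort_config()] object (or a list of its arguments).
#' @param outdir Output directory.
#' @return The bundle, invisibly.
#' @export
simulate_to_dir <- function(config, outdir) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  bundle <- simulate_cohort(config)
  write_cohort(bundle, outdir)
  invisible(bundle)
}
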