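# Readers and writers for the bundle's plain-text interchange formats.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   member genes).
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled over sets).
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Write a synthetic cohort bundle to a directory
#'
#' Writes `manifest.tsv`, `promoters.fasta`, `betas.tsv` (probes x samples,
#' first column `probe_id`), `calibration.tsv`, `clinical.tsv`,
#' `prc_targets.gmt` and `truth.json`.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(bundle$manifest, file.path(dir, "manifest.tsv"))
  Biostrings::writeXStringSet(bundle$sequences,
                              file.path(dir, "promoters.fasta"))
  bdf <- data.frame(probe_id = rownames(bundle$betas), bundle$betas,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(bdf, file.path(dir, "betas.tsv"))
  write_tsv(bundle$calibration, file.path(dir, "calibration.tsv"))
  write_tsv(bundle$clinical, file.path(dir, "clinical.tsv"))
  write_gmt(bundle$prc, file.path(dir, "prc_targets.gmt"),
            description = "synthetic PRC target set")
  truth <- bundle$truth
  truth$sample_roles <- as.list(bundle$sample_roles)
  truth$epigenotype <- as.list(truth$epigenotype)
  truth$gene_category <- as.list(truth$gene_category)
  truth$marker_freq <- as.list(truth$marker_freq)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' Inverse of [write_cohort()]; `truth.json` is loaded when present.
#'
#' @param dir Bundle directory.
#' @return A list with elements manifest, sequences, betas, sample_roles,
#'   calibration, clinical, prc and (if present) truth.
#' @export
read_cohort <- function(dir) {
  f <- function(x) file.path(dir, x)
  for (fn in c("manifest.tsv", "betas.tsv"))
    if (!file.exists(f(fn))) stop("bundle is missing ", fn)
  manifest <- read_tsv(f("manifest.tsv"))
  bdf <- read_tsv(f("betas.tsv"))
  betas <- as.matrix(bdf[, -1, drop = FALSE])
  rownames(betas) <- bdf$probe_id
  out <- list(manifest = manifest, betas = betas)
  if (file.exists(f("promoters.fasta")))
    out$sequences <- Biostrings::readDNAStringSet(f("promoters.fasta"))
  if (file.exists(f("calibration.tsv")))
    out$calibration <- read_tsv(f("calibration.tsv"))
  if (file.exists(f("clinical.tsv")))
    out$clinical <- read_tsv(f("clinical.tsv"))
  if (file.exists(f("prc_targets.gmt")))
    out$prc <- read_gmt(f("prc_targets.gmt"))
  if (file.exists(f("truth.json"))) {
    tr <- jsonlite::read_json(f("truth.json"), simplifyVector = TRUE)
    for (nm in c("epigenotype", "gene_category", "marker_freq",
                 "sample_roles"))
      tr[[nm]] <- unlist(tr[[nm]])
    out$truth <- tr
    out$sample_roles <- tr$sample_roles
  }
  if (is.null(out$sample_roles)) {
    # fall back: normal columns are prefixed N_
    cn <- colnames(betas)
    out$sample_roles <- setNames(ifelse(grepl("^N_", cn), "normal", "tumor"),
                                 cn)
  }
  out
}
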