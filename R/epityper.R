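#' Fit the promoter-methylation epigenotyping model to a cohort
#'
#' Runs the full analysis on a methylation-array cohort: (1) probe QC
#' against the 0-100% methylation dilution series (when a calibration table
#' is given); (2) promoter annotation — CpG score over the TSS window,
#' HCP/ICP/LCP class, representative (nearest-to-TSS, QC-passing) probe per
#' gene; (3) epigenotyping — selection of high/intermediate-CpG genes with
#' beta SD above threshold across tumors, two-way Ward/Euclidean
#' hierarchical clustering of tumors, two-cluster cut, and high/low labeling
#' by mean beta; (4) marker extraction — binary methylation calls and
#' classification of every analyzed gene into unmethylated,
#' high-methylation-marker, commonly-methylated, normally-methylated or
#' unclassified; (5) cohort statistics — clinical associations (Fisher,
#' Welch t, log-rank) and Polycomb-target enrichment, when clinical /
#' gene-set inputs are given.
#'
#' @param betas Probe x sample beta matrix in `[0, 1]` (rownames = probe
#'   ids).
#' @param manifest Probe manifest data.frame (probe_id, gene, chrom,
#'   position, strand, tss).
#' @param sequences Named [Biostrings::DNAStringSet] of promoter sequences
#'   centered on the TSS.
#' @param sample_roles Named vector over the beta columns,
#'   `"tumor"`/`"normal"`; normals are displayed alongside but never enter
#'   the clustering.
#' @param calibration Optional long-format calibration table (probe_id,
#'   expected_fraction, measured_beta).
#' @param clinical Optional clinical table (see [association_report()]).
#' @param prc_genes Optional character vector of Polycomb target genes.
#' @param control An [epitype_control()] parameter object.
#' @return An object of class `epityper`; see Details.
#' @details The returned object contains `qc` (per-probe QC table or NULL),
#'   `promoters` (per-gene annotation), `analyzed_genes` (HCP/ICP genes in
#'   the marker analysis), `selected_genes` (clustering set with SDs),
#'   `sample_tree` / `gene_tree` (dendrograms), `labels` (epigenotype per
#'   tumor), `cluster_means`, `marker_table`, `category_counts`,
#'   `frequent_markers`, `association`, `enrichment`, `control` and `call`.
#' @examples
#' cfg <- cohort_config(seed = 1, n_tumors = 14, n_high = 5,
#'   n_genes_by_category = c(unmethylated = 40, high_meth_marker = 6,
#'     commonly_methylated = 5, normally_methylated = 8, filler_low_cpg = 10))
#' b <- simulate_cohort(cfg)
#' fit <- epitype(b$betas, b$manifest, b$sequences, b$sample_roles,
#'                calibration = b$calibration, clinical = b$clinical,
#'                prc_genes = b$prc$PRC_TARGETS_ES)
#' fit$category_counts
#' @export
epitype <- function(betas, manifest, sequences, sample_roles,
                    calibration = NULL, clinical = NULL, prc_genes = NULL,
                    control = epitype_control()) {
  stopifnot(inherits(control, "epitype_control"))
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop("betas must carry probe rownames and sample colnames")
  if (!all(colnames(betas) %in% names(sample_roles)))
    stop("sample_roles must cover every beta column")
  if (any(betas < 0 | betas > 1, na.rm = TRUE))
    stop("betas must lie in [0, 1]")
  if (anyNA(betas)) stop("betas must have no missing values")
  roles <- sample_roles[colnames(betas)]

  qc <- NULL
  qc_pass <- NULL
  if (!is.null(calibration)) {
    qc <- qc_probes(calibration, epsilon = control$qc_epsilon,
                    rho = control$qc_rho)
    qc_pass <- qc$probe_id[qc$pass]
    betas <- betas[rownames(betas) %in% qc_pass, , drop = FALSE]
  }

  promoters <- annotate_promoters(manifest, sequences, qc_pass = qc_pass,
                                  control = control)
  gb <- gene_beta_matrix(betas, promoters)
  tumors <- names(roles)[roles == "tumor"]
  if (length(tumors) < 2L) stop("need at least 2 tumor samples")

  sel <- select_variable_genes(gb[, tumors, drop = FALSE],
                               sd_threshold = control$sd_threshold,
                               top_n = control$top_n)
  sub <- gb[sel$gene, tumors, drop = FALSE]
  trees <- hierarchical_cluster(sub, metric = control$metric,
                                linkage = control$linkage)
  epi <- assign_epigenotype(trees$sample_tree, sub, k = 2L)

  marker_table <- build_marker_table(gb, epi$labels, roles,
                                     thresholds = control$thresholds)
  category_counts <- table(factor(marker_table$category,
                                  levels = c("unmethylated",
                                             "high_meth_marker",
                                             "commonly_methylated",
                                             "normally_methylated",
                                             "unclassified")))
  frequent <- rank_frequent_markers(marker_table,
                                    freq_floor = control$freq_floor)

  association <- NULL
  if (!is.null(clinical))
    association <- association_report(epi$labels, clinical,
                                      thickness_cut = control$thickness_cut,
                                      alpha = control$alpha)
  enrichment <- NULL
  if (!is.null(prc_genes) && category_counts[["high_meth_marker"]] > 0 &&
      category_counts[["unmethylated"]] > 0 &&
      category_counts[["normally_methylated"]] > 0)
    enrichment <- prc_enrichment(marker_table, prc_genes,
                                 alpha = control$alpha)

  structure(list(call = match.call(), control = control, qc = qc,
                 promoters = promoters, analyzed_genes = rownames(gb),
                 selected_genes = sel, sample_tree = trees$sample_tree,
                 gene_tree = trees$gene_tree, labels = epi$labels,
                 cluster_means = epi$cluster_means,
                 marker_table = marker_table,
                 category_counts = category_counts,
                 frequent_markers = frequent,
                 association = association, enrichment = enrichment,
                 gene_betas = gb, sample_roles = roles,
                 clinical = clinical),
            class = "epityper")
}

#' @export
print.epityper <- function(x, ...) {
  cat("Promoter-methylation epigenotyping fit\n")
  cat(sprintf("  %d analyzed HCP/ICP genes, %d in clustering set\n",
              length(x$analyzed_genes), nrow(x$selected_genes)))
  cat(sprintf("  epigenotypes: high n=%d (mean beta %.3f), low n=%d (%.3f)\n",
              sum(x$labels == "high"), x$cluster_means[["high"]],
              sum(x$labels == "low"), x$cluster_means[["low"]]))
  cc <- x$category_counts
  cat("  categories:",
      paste(sprintf("%s=%d", names(cc), as.integer(cc)), collapse = ", "),
      "\n")
  if (nrow(x$frequent_markers))
    cat("  frequently methylated markers (>",
        x$control$freq_floor, "%): ",
        paste(x$frequent_markers$gene, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.epityper <- function(object, ...) {
  print(object)
  if (!is.null(object$qc))
    cat(sprintf("  QC: %d/%d probes pass\n", sum(object$qc$pass),
                nrow(object$qc)))
  if (!is.null(object$association)) {
    cat("\nClinical associations:\n")
    print(object$association[, c("factor", "test", "p_value", "significant")],
          row.names = FALSE)
  }
  if (!is.null(object$enrichment)) {
    cat("\nPRC-target enrichment:\n")
    print(object$enrichment[, c("comparison", "odds_ratio", "p_value")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Heatmap and dendrogram of an epigenotyping fit
#'
#' Draws the selected-gene beta matrix (tumors ordered by the sample
#' dendrogram, genes by the gene dendrogram; normal reference columns
#' appended on the right) with the sample dendrogram on top.
#'
#' @param x An `epityper` object.
#' @param ... Ignored.
#' @export
plot.epityper <- function(x, ...) {
  ord_s <- x$sample_tree$labels[x$sample_tree$order]
  ord_g <- x$gene_tree$labels[x$gene_tree$order]
  normals <- names(x$sample_roles)[x$sample_roles == "normal"]
  m <- x$gene_betas[ord_g, c(ord_s, normals), drop = FALSE]
  op <- par(no.readonly = TRUE)
  on.exit(par(op))
  layout(matrix(1:2, 2L), heights = c(1, 3))
  par(mar = c(0, 4, 2, 1))
  plot(as.dendrogram(x$sample_tree), leaflab = "none",
       main = "methylation epigenotypes")
  par(mar = c(5, 4, 0.5, 1))
  image(seq_len(ncol(m)), seq_len(nrow(m)), t(m), zlim = c(0, 1),
        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "samples (tumors by dendrogram order, then normals)",
        ylab = "selected genes", axes = FALSE)
  axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
       cex.axis = 0.5)
  box()
  invisible(x)
}

#' Assign new samples to the fitted epigenotypes
#'
#' Classifies new samples by the nearest cluster centroid (Euclidean
#' distance over the fit's selected genes).
#'
#' @param object An `epityper` object.
#' @param newdata Probe x sample beta matrix covering the representative
#'   probes of the selected genes, or a gene x sample matrix with gene
#'   rownames.
#' @param ... Ignored.
#' @return Named character vector of `"high"`/`"low"` labels.
#' @export
predict.epityper <- function(object, newdata, ...) {
  genes <- object$selected_genes$gene
  if (all(genes %in% rownames(newdata))) {
    m <- newdata[genes, , drop = FALSE]
  } else {
    rep_probe <- object$promoters$representative_probe[
      match(genes, object$promoters$gene)]
    if (!all(rep_probe %in% rownames(newdata)))
      stop("newdata lacks the selected genes' representative probes")
    m <- newdata[rep_probe, , drop = FALSE]
    rownames(m) <- genes
  }
  tumors <- names(object$labels)
  cen <- sapply(c("high", "low"), function(g)
    rowMeans(object$gene_betas[genes, tumors[object$labels == g],
                               drop = FALSE]))
  d2 <- sapply(c("high", "low"), function(g)
    colSums((m - cen[, g])^2))
  d2 <- matrix(d2, ncol = 2L, dimnames = list(colnames(m), c("high", "low")))
  setNames(c("high", "low")[max.col(-d2, ties.method = "first")],
           colnames(m))
}
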