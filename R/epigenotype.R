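# Epigenotyping: variable-gene selection, two-way hierarchical clustering,
# and high/low methylation labeling of the two major clusters.

#' Build the gene-level beta matrix from representative probes
#'
#' Restricts the probe-level beta matrix to the representative probe of each
#' analyzed (HCP or ICP) gene.
#'
#' @param betas Probe x sample beta matrix (rownames = probe ids).
#' @param promoters Output of [annotate_promoters()].
#' @param classes Promoter classes to keep (default HCP and ICP).
#' @return Gene x sample matrix of representative-probe betas.
#' @export
gene_beta_matrix <- function(betas, promoters, classes = c("HCP", "ICP")) {
  keep <- promoters$promoter_class %in% classes &
    promoters$representative_probe %in% rownames(betas)
  p <- promoters[keep, , drop = FALSE]
  m <- betas[p$representative_probe, , drop = FALSE]
  rownames(m) <- p$gene
  m
}

#' Select variable genes for clustering
#'
#' Computes the per-gene sample standard deviation (n-1 denominator) across
#' tumor columns, keeps genes with SD strictly above `sd_threshold`, and
#' caps the list at the `top_n` genes of highest SD.
#'
#' @param gene_betas Gene x tumor beta matrix.
#' @param sd_threshold Minimum SD (strict).
#' @param top_n Cap on the number of genes returned.
#' @return data.frame (gene, sd), sorted by decreasing SD. Errors when no
#'   gene passes.
#' @export
select_variable_genes <- function(gene_betas, sd_threshold = 0.15,
                                  top_n = 2000L) {
  if (ncol(gene_betas) < 2L) stop("need at least 2 samples to compute SDs")
  mu <- rowMeans(gene_betas)
  sds <- sqrt(rowSums((gene_betas - mu)^2) / (ncol(gene_betas) - 1L))
  keep <- which(sds > sd_threshold)
  if (length(keep) == 0L)
    stop("no gene exceeds the SD threshold of ", sd_threshold)
  ord <- keep[order(sds[keep], rownames(gene_betas)[keep],
                    decreasing = c(TRUE, FALSE), method = "radix")]
  ord <- head(ord, top_n)
  data.frame(gene = rownames(gene_betas)[ord], sd = unname(sds[ord]),
             stringsAsFactors = FALSE)
}

cluster_dist <- function(m, metric) {
  if (metric == "euclidean") dist(m)
  else as.dist(1 - cor(t(m)))
}

#' Two-way hierarchical clustering of a beta submatrix
#'
#' Agglomerative clustering of samples (columns) and genes (rows), by
#' default Ward linkage on Euclidean distances. Deterministic given the
#' input ordering.
#'
#' @param m Gene x sample beta matrix (at least 2 x 2).
#' @param metric `"euclidean"` or `"pearson"` (1 - correlation).
#' @param linkage Method passed to [stats::hclust()].
#' @return List with `sample_tree` and `gene_tree` ([stats::hclust]
#'   objects).
#' @export
hierarchical_cluster <- function(m, metric = c("euclidean", "pearson"),
                                 linkage = "ward.D2") {
  metric <- match.arg(metric)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("clustering needs at least 2 genes and 2 samples")
  list(sample_tree = hclust(cluster_dist(t(m), metric), method = linkage),
       gene_tree = hclust(cluster_dist(m, metric), method = linkage))
}

#' Cut the sample dendrogram into the two methylation epigenotypes
#'
#' Cuts the sample tree into exactly two clusters and labels the cluster
#' with the greater mean beta over the selected genes `"high"`, the other
#' `"low"`. Cluster membership is invariant under relabeling; the label is
#' a deterministic function of the cluster means.
#'
#' @param sample_tree [stats::hclust] object over tumor samples.
#' @param m Gene x sample beta matrix over the selected genes (columns must
#'   cover the tree's labels).
#' @param k Number of clusters; only `k = 2` is supported.
#' @return List: `labels` (named character, `"high"`/`"low"`),
#'   `cluster_means` (named numeric). Errors when the dendrogram is
#'   degenerate (all merge heights ~0, i.e. indistinguishable samples).
#' @export
assign_epigenotype <- function(sample_tree, m, k = 2L) {
  if (k != 2L) stop("only k = 2 epigenotypes are supported")
  if (max(sample_tree$height) < sqrt(.Machine$double.eps))
    stop("samples are indistinguishable: all merge heights are zero")
  cl <- cutree(sample_tree, k = 2L)
  m <- m[, names(cl), drop = FALSE]
  means <- vapply(1:2, function(g) mean(m[, cl == g, drop = FALSE]),
                  numeric(1))
  hi <- which.max(means)
  labels <- ifelse(cl == hi, "high", "low")
  list(labels = labels,
       cluster_means = c(high = max(means), low = min(means)))
}
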