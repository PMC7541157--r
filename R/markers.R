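# Marker extraction: binary methylation calls, per-subgroup frequencies,
# and the four-category gene classification.

#' Dichotomize beta values into methylation states
#'
#' @param beta Numeric vector of betas in `[0, 1]`.
#' @param thresholds A [call_thresholds()] object.
#' @return Character vector: `"unmethylated"`, `"methylated"` or
#'   `"indeterminate"`.
#' @examples
#' call_state(c(0.10, 0.80, 0.30))
#' @export
call_state <- function(beta, thresholds = call_thresholds()) {
  if (any(is.na(beta)) || any(beta < 0 | beta > 1))
    stop("betas must lie in [0, 1]")
  ifelse(beta <= thresholds$beta_unmeth_max, "unmethylated",
         ifelse(beta >= thresholds$beta_meth_min, "methylated",
                "indeterminate"))
}

#' Methylation frequency of a gene in a sample subset
#'
#' Percentage of samples called methylated; indeterminate calls count in the
#' denominator only.
#'
#' @param beta Betas of one gene over a non-empty sample subset.
#' @param thresholds A [call_thresholds()] object.
#' @return Frequency in percent.
#' @export
methylation_frequency <- function(beta, thresholds = call_thresholds()) {
  if (length(beta) == 0L) stop("sample subset is empty")
  100 * mean(call_state(beta, thresholds) == "methylated")
}

#' Classify one gene into a marker category
#'
#' Applies, in order: *normally_methylated* (normals methylated, both tumor
#' subgroup frequencies at least `common_freq_min`); *unmethylated* (normals
#' unmethylated, both frequencies at most `absent_freq_max`);
#' *high_meth_marker* (normals unmethylated, high-subgroup frequency at
#' least `marker_freq_min`, low at most `absent_freq_max`);
#' *commonly_methylated* (normals unmethylated, both frequencies at least
#' `marker_freq_min`); otherwise *unclassified*.
#'
#' @param normal_state `"methylated"`, `"unmethylated"` or
#'   `"indeterminate"` (consensus state of the normal samples).
#' @param freq_high,freq_low Methylation frequencies (fractions in `[0,1]`)
#'   among high- and low-subgroup tumors.
#' @param thresholds A [call_thresholds()] object.
#' @return Category string.
#' @examples
#' classify_gene("unmethylated", 0.30, 0.00)  # high_meth_marker
#' @export
classify_gene <- function(normal_state, freq_high, freq_low,
                          thresholds = call_thresholds()) {
  stopifnot(length(normal_state) == 1L, freq_high >= 0, freq_high <= 1,
            freq_low >= 0, freq_low <= 1)
  th <- thresholds
  if (normal_state == "methylated" &&
      freq_high >= th$common_freq_min && freq_low >= th$common_freq_min)
    return("normally_methylated")
  if (normal_state == "unmethylated") {
    if (freq_high <= th$absent_freq_max && freq_low <= th$absent_freq_max)
      return("unmethylated")
    if (freq_high >= th$marker_freq_min && freq_low <= th$absent_freq_max)
      return("high_meth_marker")
    if (freq_high >= th$marker_freq_min && freq_low >= th$marker_freq_min)
      return("commonly_methylated")
  }
  "unclassified"
}

#' Build the marker table for all analyzed genes
#'
#' Computes, per gene (representative probe), the pooled normal-sample state
#' (the state call on the mean beta across normal columns), the methylation
#' frequencies in the high and low tumor subgroups and overall, and the
#' marker category.
#'
#' @param gene_betas Gene x sample matrix of representative-probe betas
#'   (tumors and normals).
#' @param labels Named vector over tumor samples, `"high"`/`"low"`.
#' @param sample_roles Named vector over all columns, `"tumor"`/`"normal"`.
#' @param thresholds A [call_thresholds()] object.
#' @return data.frame: gene, category, freq_high, freq_low, freq_all
#'   (percent), normal_state.
#' @export
build_marker_table <- function(gene_betas, labels, sample_roles,
                               thresholds = call_thresholds()) {
  tum <- names(sample_roles)[sample_roles == "tumor"]
  nor <- names(sample_roles)[sample_roles == "normal"]
  if (!all(tum %in% names(labels)))
    stop("missing epigenotype labels for: ",
         paste(head(setdiff(tum, names(labels)), 3L), collapse = ", "))
  hi <- tum[labels[tum] == "high"]
  lo <- tum[labels[tum] == "low"]
  if (length(hi) == 0L || length(lo) == 0L)
    stop("both epigenotypes must be non-empty")

  meth <- gene_betas >= thresholds$beta_meth_min
  f_hi <- rowMeans(meth[, hi, drop = FALSE])
  f_lo <- rowMeans(meth[, lo, drop = FALSE])
  f_all <- rowMeans(meth[, tum, drop = FALSE])
  nstate <- call_state(rowMeans(gene_betas[, nor, drop = FALSE]), thresholds)

  th <- thresholds
  category <- rep("unclassified", nrow(gene_betas))
  n_meth <- nstate == "methylated"
  n_unm <- nstate == "unmethylated"
  category[n_meth & f_hi >= th$common_freq_min &
             f_lo >= th$common_freq_min] <- "normally_methylated"
  category[n_unm & f_hi <= th$absent_freq_max &
             f_lo <= th$absent_freq_max] <- "unmethylated"
  category[n_unm & f_hi >= th$marker_freq_min &
             f_lo <= th$absent_freq_max] <- "high_meth_marker"
  category[n_unm & f_hi >= th$marker_freq_min &
             f_lo >= th$marker_freq_min] <- "commonly_methylated"

  data.frame(gene = rownames(gene_betas), category = category,
             freq_high = 100 * f_hi, freq_low = 100 * f_lo,
             freq_all = 100 * f_all, normal_state = nstate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank frequently methylated marker genes
#'
#' Among high-methylation marker genes, keeps those with cohort methylation
#' frequency strictly above `freq_floor` percent, sorted by decreasing
#' frequency. When a second cohort's marker table is supplied, only genes
#' exceeding the floor in both cohorts are kept (frequencies from both are
#' reported).
#'
#' @param marker_table Output of [build_marker_table()].
#' @param freq_floor Frequency floor in percent (default 25).
#' @param second_table Optional marker table of a second cohort.
#' @return data.frame: gene, freq_all (and freq_all_2 when two cohorts);
#'   possibly empty.
#' @export
rank_frequent_markers <- function(marker_table, freq_floor = 25,
                                  second_table = NULL) {
  mk <- marker_table[marker_table$category == "high_meth_marker" &
                       marker_table$freq_all > freq_floor, c("gene", "freq_all")]
  if (!is.null(second_table)) {
    mk2 <- second_table[second_table$category == "high_meth_marker" &
                          second_table$freq_all > freq_floor,
                        c("gene", "freq_all")]
    mk <- merge(mk, mk2, by = "gene", suffixes = c("", "_2"))
  }
  mk <- mk[order(-mk$freq_all, mk$gene), , drop = FALSE]
  rownames(mk) <- NULL
  mk
}
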