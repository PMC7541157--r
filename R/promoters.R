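# Promoter annotation: CpG scores, HCP/ICP/LCP classes, signed TSS
# distances and representative-probe selection.

#' CpG score (observed/expected CpG ratio) of a sequence window
#'
#' The CpG score of a window is the observed count of CG dinucleotides
#' divided by the count expected from base composition:
#' `n_CG * L / (n_C * n_G)`, with `L` the number of informative (non-N)
#' bases. Windows without any C or any G score 0. N bases are excluded from
#' all counts and no CG is counted across an N.
#'
#' @param sequence A single uppercase ACGTN string (or a
#'   [Biostrings::DNAString]).
#' @param start,end 1-based window within the sequence (defaults: whole
#'   sequence).
#' @return Non-negative numeric CpG score.
#' @examples
#' cpg_score("CGCGCG")   # 2
#' cpg_score("ATATATAT") # 0
#' @export
cpg_score <- function(sequence, start = 1L, end = NA_integer_) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  n <- nchar(sequence)
  if (is.na(end)) end <- n
  if (start < 1L || end > n || start > end)
    stop("window [", start, ", ", end, "] outside sequence of length ", n)
  win <- substr(sequence, start, end)
  if (grepl("[^ACGTN]", win))
    stop("sequence contains characters outside ACGTN")
  v <- Biostrings::DNAString(win)
  fr <- Biostrings::letterFrequency(v, c("C", "G"))
  nC <- fr[["C"]]; nG <- fr[["G"]]
  if (nC == 0 || nG == 0) return(0)
  L <- nchar(win) - Biostrings::letterFrequency(v, "N")[[1]]
  nCG <- Biostrings::countPattern("CG", v)
  nCG * L / (nC * nG)
}

#' Classify a promoter by its CpG score
#'
#' Scores above `hcp_min` are high-CpG promoters (HCP), scores above
#' `icp_min` (and at most `hcp_min`) intermediate (ICP), everything else
#' low-CpG (LCP). Both comparisons are strict, so a score exactly at a
#' threshold falls in the lower class.
#'
#' @param score Numeric vector of CpG scores (all `>= 0`).
#' @param hcp_min,icp_min Class thresholds (defaults 0.72 and 0.48).
#' @return Character vector: `"HCP"`, `"ICP"` or `"LCP"`.
#' @examples
#' classify_promoter(c(0.80, 0.50, 0.48))  # HCP ICP LCP
#' @export
classify_promoter <- function(score, hcp_min = 0.72, icp_min = 0.48) {
  if (any(is.na(score)) || any(score < 0)) stop("CpG scores must be >= 0")
  ifelse(score > hcp_min, "HCP", ifelse(score > icp_min, "ICP", "LCP"))
}

#' Signed probe-to-TSS distance in transcription orientation
#'
#' Negative distances are upstream of the TSS in the direction of
#' transcription: on the + strand the distance is `position - tss`, on the
#' - strand `tss - position`.
#'
#' @param position,tss 1-based genomic coordinates.
#' @param strand `"+"` or `"-"` (vectorized).
#' @return Integer vector of signed distances (bp).
#' @examples
#' signed_tss_distance(985, 1000, "+")  # -15, i.e. 15 bp upstream
#' @export
signed_tss_distance <- function(position, tss, strand) {
  if (any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  as.integer(ifelse(strand == "+", position - tss, tss - position))
}

#' Select one representative probe per gene
#'
#' The representative probe of a gene is the probe nearest to the TSS
#' (minimum absolute signed distance). Exact ties are broken in favor of the
#' upstream (negative-distance) probe, then by lexicographic probe id, so
#' the choice is deterministic.
#'
#' @param probe_id Character vector of probe ids.
#' @param tss_distance Integer vector of signed TSS distances.
#' @return Index (into the input vectors) of the representative probe.
#' @export
select_representative_probe <- function(probe_id, tss_distance) {
  if (length(probe_id) == 0L) stop("no probes supplied")
  ord <- order(abs(tss_distance), tss_distance, probe_id)
  ord[1L]
}

#' Annotate genes with CpG scores, promoter classes and representative probes
#'
#' Computes, for every gene in the manifest with an available promoter
#' sequence, the CpG score over the promoter window, the HCP/ICP/LCP class,
#' and the representative (nearest-to-TSS) probe. When a QC pass set is
#' supplied, only passing probes are eligible as representatives, so a gene
#' whose nearest probe fails QC falls back to its next-nearest passing
#' probe; genes with no passing probe are dropped (recorded in the
#' `"dropped"` attribute).
#'
#' @param manifest data.frame with columns probe_id, gene, chrom, position,
#'   strand, tss.
#' @param sequences Named [Biostrings::DNAStringSet] of promoter sequences
#'   (first `|`-field of the name is the gene symbol), each centered on the
#'   TSS.
#' @param qc_pass Optional character vector of QC-passing probe ids.
#' @param control An [epitype_control()] object (uses `window`, `hcp_min`,
#'   `icp_min`).
#' @return data.frame: gene, cpg_score, promoter_class, representative_probe,
#'   tss_distance; attribute `"dropped"` lists genes lost to QC or missing
#'   sequence.
#' @export
annotate_promoters <- function(manifest, sequences, qc_pass = NULL,
                               control = epitype_control()) {
  need <- c("probe_id", "gene", "position", "strand", "tss")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  seq_gene <- vapply(strsplit(names(sequences), "|", fixed = TRUE),
                     `[[`, character(1), 1L)

  man <- manifest
  man$tss_distance <- signed_tss_distance(man$position, man$tss, man$strand)
  if (!is.null(qc_pass)) man <- man[man$probe_id %in% qc_pass, , drop = FALSE]

  genes_all <- unique(manifest$gene)
  keep <- intersect(genes_all, intersect(unique(man$gene), seq_gene))
  dropped <- setdiff(genes_all, keep)
  if (length(keep) == 0L) stop("no gene has both a sequence and a usable probe")

  # representative probe per gene
  o <- order(man$gene, abs(man$tss_distance), man$tss_distance, man$probe_id)
  man_o <- man[o, , drop = FALSE]
  first <- !duplicated(man_o$gene)
  rep_tab <- man_o[first, c("gene", "probe_id", "tss_distance")]
  rep_tab <- rep_tab[rep_tab$gene %in% keep, , drop = FALSE]

  # vectorized CpG score over the promoter window around the TSS midpoint
  si <- match(rep_tab$gene, seq_gene)
  dss <- sequences[si]
  w <- control$window
  mid <- floor(Biostrings::width(dss) / 2L) + 1L
  from <- pmax(mid + w[1], 1L)
  to <- pmin(mid + w[2], Biostrings::width(dss))
  win <- Biostrings::subseq(dss, start = from, end = to)
  fr <- Biostrings::letterFrequency(win, c("C", "G", "N"))
  nCG <- Biostrings::vcountPattern("CG", win)
  L <- Biostrings::width(win) - fr[, "N"]
  denom <- fr[, "C"] * fr[, "G"]
  score <- ifelse(denom > 0, nCG * L / denom, 0)

  out <- data.frame(gene = rep_tab$gene,
                    cpg_score = as.numeric(score),
                    promoter_class = classify_promoter(score, control$hcp_min,
                                                       control$icp_min),
                    representative_probe = rep_tab$probe_id,
                    tss_distance = rep_tab$tss_distance,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
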