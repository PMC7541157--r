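# Cohort statistics built from first principles: Fisher's exact test by
# hypergeometric summation, Welch's t with Satterthwaite df, the
# product-limit survival estimator, and the log-rank test with the
# hypergeometric tie correction. Distribution functions come from stats.

test_result <- function(statistic, p_value, method, alpha = 0.05, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  p_value <- min(p_value, 1)
  structure(c(list(statistic = statistic, p_value = p_value, method = method,
                   significant = p_value < alpha), list(...)),
            class = "epityper_test")
}

#' @export
print.epityper_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4),
      if (x$significant) "  (significant at 0.05)" else "", "\n", sep = "")
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood method: with the margins
#' fixed, the hypergeometric probabilities of all tables at most as probable
#' as the observed one are summed. The sample odds ratio `ad/(bc)` is
#' reported.
#'
#' @param table 2x2 matrix of non-negative counts (rows = group, columns =
#'   outcome), or the four counts `a, b, c, d` given via `...`.
#' @param ... Alternative scalar counts a, b, c, d (row-wise).
#' @param alpha Significance level.
#' @return An `epityper_test` list: statistic (odds ratio), p_value, method,
#'   significant, odds_ratio.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table = NULL, ..., alpha = 0.05) {
  if (is.null(table)) table <- matrix(c(...), 2L, 2L, byrow = TRUE)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  N <- a + b + c_ + d
  if (N == 0) stop("empty table")
  m <- a + c_          # first-column margin
  k <- a + b           # first-row margin
  lo <- max(0L, k - (N - m)); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, N - m, k)
  p_obs <- dhyper(a, m, N - m, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (a * d) / (b * c_)
  test_result(statistic = or, p_value = p, method = "Fisher's exact test",
              alpha = alpha, odds_ratio = or, table = table)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value; per-group means and sample SDs are reported in
#' mean +/- SD form.
#'
#' @param x,y Numeric vectors (each of length at least 2, with nonzero
#'   variance).
#' @param alpha Significance level.
#' @return An `epityper_test` list with statistic (t), df, p_value, and
#'   per-group `mean_x`, `sd_x`, `mean_y`, `sd_y`.
#' @export
welch_t <- function(x, y, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  vx <- var(x); vy <- var(y)
  if (vx == 0 || vy == 0) stop("degenerate group with zero variance")
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t_stat), df)
  test_result(statistic = t_stat, p_value = p, method = "Welch's t test",
              alpha = alpha, df = df,
              mean_x = mean(x), sd_x = sqrt(vx),
              mean_y = mean(y), sd_y = sqrt(vy))
}

#' Kaplan-Meier product-limit estimate for one group
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = event (melanoma-related death), 0 = censored.
#' @return List with `curve` (data.frame: time, n_risk, n_event, n_censor,
#'   surv at each distinct observed time) and `median` (smallest time with
#'   survival at or below 0.5, `NA` if never reached). `S(0) = 1` and
#'   censored times do not decrease the curve.
#' @examples
#' km_estimate(c(5, 10, 15, 20), c(1, 1, 0, 1))$curve
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time)
  n <- length(time)
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  s <- 1; at_risk <- n
  for (i in seq_along(ut)) {
    here <- time == ut[i]
    d <- sum(event[here]); cns <- sum(here) - d
    n_risk[i] <- at_risk; n_event[i] <- d; n_censor[i] <- cns
    if (d > 0) s <- s * (1 - d / at_risk)
    surv[i] <- s
    at_risk <- at_risk - sum(here)
  }
  med_i <- which(surv <= 0.5 + 1e-12)
  list(curve = data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                          n_censor = n_censor, surv = surv),
       median = if (length(med_i)) ut[min(med_i)] else NA_real_)
}

#' Log-rank test comparing survival of two groups
#'
#' Sums observed-minus-expected events in the first group over the distinct
#' event times, with the hypergeometric variance (standard multi-tie
#' formula), and refers the squared standardized sum to chi-squared with
#' 1 df.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level grouping vector.
#' @param alpha Significance level.
#' @return An `epityper_test` list: statistic (chi-squared, 1 df), p_value,
#'   observed/expected event counts per group.
#' @export
logrank_test <- function(time, event, group, alpha = 0.05) {
  if (any(time < 0)) stop("times must be non-negative")
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("need exactly two groups")
  if (sum(event) == 0) {
    return(test_result(0, 1, "log-rank test", alpha = alpha,
                       observed = c(0, 0), expected = c(0, 0)))
  }
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  g1 <- g == levels(g)[1]
  for (t0 in ev_times) {
    at <- time >= t0
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(event == 1 & time == t0)
    d1 <- sum(event == 1 & time == t0 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0)
    return(test_result(0, 1, "log-rank test", alpha = alpha,
                       observed = c(O1, sum(event) - O1),
                       expected = c(E1, sum(event) - E1)))
  stat <- (O1 - E1)^2 / V
  test_result(stat, pchisq(stat, df = 1, lower.tail = FALSE),
              "log-rank test", alpha = alpha,
              observed = c(O1, sum(event) - O1),
              expected = c(E1, sum(event) - E1))
}

#' Quartile-based expression grouping
#'
#' Labels the samples with the top quartile of expression `"high"`, the
#' bottom quartile `"low"`, and the middle half `"excluded"`. Each quartile
#' holds `floor(n/4)` samples; ties at a quartile boundary are resolved by
#' rank with first-occurrence order (so group sizes are always exactly
#' `floor(n/4)`).
#'
#' @param values Numeric expression values (n >= 4, not all equal).
#' @return Character vector of labels, same order as `values`.
#' @export
quartile_groups <- function(values) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 samples for quartile grouping")
  if (max(values) == min(values))
    stop("quartiles undefined: all values are equal")
  nq <- n %/% 4L
  rk <- rank(values, ties.method = "first")
  labels <- rep("excluded", n)
  labels[rk > n - nq] <- "high"
  labels[rk <= nq] <- "low"
  labels
}

#' Polycomb-target enrichment in marker categories
#'
#' Tests whether PRC target genes are enriched among high-methylation
#' marker genes, against unmethylated genes and against normally methylated
#' genes, by Fisher's exact test on the 2x2 table category membership x
#' PRC-target membership.
#'
#' @param marker_table Output of [build_marker_table()].
#' @param prc_genes Character vector of PRC target gene symbols (e.g. one
#'   set from [read_gmt()]).
#' @param alpha Significance level.
#' @return data.frame with one row per comparison: comparison, n_marker,
#'   prc_marker, n_ref, prc_ref, odds_ratio, p_value, significant.
#' @export
prc_enrichment <- function(marker_table, prc_genes, alpha = 0.05) {
  cats <- split(marker_table$gene, marker_table$category)
  mk <- cats[["high_meth_marker"]]
  if (is.null(mk) || length(mk) == 0L)
    stop("no high-methylation marker genes to test")
  one <- function(ref_name) {
    ref <- cats[[ref_name]]
    if (is.null(ref) || length(ref) == 0L)
      stop("empty reference category: ", ref_name)
    tab <- matrix(c(sum(mk %in% prc_genes), sum(!mk %in% prc_genes),
                    sum(ref %in% prc_genes), sum(!ref %in% prc_genes)),
                  2L, 2L, byrow = TRUE)
    ft <- fisher_exact(tab, alpha = alpha)
    data.frame(comparison = paste0("high_meth_marker_vs_", ref_name),
               n_marker = length(mk), prc_marker = tab[1, 1],
               n_ref = length(ref), prc_ref = tab[2, 1],
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               significant = ft$significant, stringsAsFactors = FALSE)
  }
  out <- rbind(one("unmethylated"), one("normally_methylated"))
  rownames(out) <- NULL
  out
}

#' Associations between epigenotype and clinicopathological factors
#'
#' Dichotomizes each clinical factor (stage 1-2 vs 3-4, thickness at
#' `thickness_cut` mm, age at the cohort median; BRAF/NRAS/acral/ulcer are
#' already binary) and tests its association with the methylation
#' epigenotype by Fisher's exact test; quantitative Breslow thickness is
#' additionally tested by Welch's t-test (the headline comparison, reported
#' with per-subgroup mean +/- SD), and overall survival by the log-rank
#' test. A Benjamini-Hochberg adjusted column is appended as a labeled
#' extension; the per-test significance flag uses the unadjusted p.
#'
#' @param labels Named epigenotype vector over tumor samples
#'   (`"high"`/`"low"`).
#' @param clinical Clinical data.frame with columns sample, age, stage,
#'   thickness_mm, os_days, event, braf, nras, acral, ulcer.
#' @param thickness_cut Cutpoint in mm for the categorical thickness test.
#' @param alpha Significance level.
#' @return data.frame: factor, test, statistic, p_value, significant,
#'   p_adj_BH, detail (mean +/- SD per subgroup where applicable).
#' @export
association_report <- function(labels, clinical, thickness_cut = 4,
                               alpha = 0.05) {
  need <- c("sample", "age", "stage", "thickness_mm", "os_days", "event",
            "braf", "nras", "acral", "ulcer")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  cl <- clinical[match(names(labels), clinical$sample), , drop = FALSE]
  if (any(is.na(cl$sample))) stop("clinical table lacks some labeled samples")
  hi <- labels == "high"

  fisher_row <- function(name, flag) {
    tab <- matrix(c(sum(hi & flag), sum(hi & !flag),
                    sum(!hi & flag), sum(!hi & !flag)), 2L, 2L, byrow = TRUE)
    ft <- fisher_exact(tab, alpha = alpha)
    data.frame(factor = name, test = "fisher_exact",
               statistic = ft$odds_ratio, p_value = ft$p_value,
               detail = sprintf("high %d/%d vs low %d/%d",
                                tab[1, 1], sum(hi), tab[2, 1], sum(!hi)),
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    fisher_row("stage_3_4", cl$stage >= 3),
    fisher_row(sprintf("thickness_gt_%gmm", thickness_cut),
               cl$thickness_mm > thickness_cut),
    fisher_row("age_above_median", cl$age > median(cl$age)),
    fisher_row("braf_mutant", cl$braf == 1),
    fisher_row("nras_mutant", cl$nras == 1),
    fisher_row("acral_site", cl$acral == 1),
    fisher_row("ulceration", cl$ulcer == 1))

  wt <- welch_t(cl$thickness_mm[hi], cl$thickness_mm[!hi], alpha = alpha)
  rows <- rbind(rows, data.frame(
    factor = "thickness_mm", test = "welch_t", statistic = wt$statistic,
    p_value = wt$p_value,
    detail = sprintf("high %.1f +/- %.1f mm vs low %.1f +/- %.1f mm",
                     wt$mean_x, wt$sd_x, wt$mean_y, wt$sd_y),
    stringsAsFactors = FALSE))

  lr <- logrank_test(cl$os_days, cl$event, ifelse(hi, "high", "low"),
                     alpha = alpha)
  rows <- rbind(rows, data.frame(
    factor = "overall_survival", test = "logrank", statistic = lr$statistic,
    p_value = lr$p_value,
    detail = sprintf("events high %d low %d", sum(cl$event[hi]),
                     sum(cl$event[!hi])),
    stringsAsFactors = FALSE))

  rows$significant <- rows$p_value < alpha
  rows$p_adj_BH <- p.adjust(rows$p_value, method = "BH")
  rows[, c("factor", "test", "statistic", "p_value", "significant",
           "p_adj_BH", "detail")]
}
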