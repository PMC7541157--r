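# Probe QC against the 0/25/50/75/100% methylation dilution series.

#' Evaluate one probe against the methylation dilution series
#'
#' A probe passes quantitative-accuracy QC when its maximum absolute error
#' over the five dilution points is at most `epsilon` and the Pearson
#' correlation between measured and expected betas is at least `rho`. A
#' constant measured response has undefined correlation and always fails
#' (reported as `NA`).
#'
#' @param expected Numeric vector of expected methylation fractions
#'   (the five values 0, 0.25, 0.5, 0.75, 1).
#' @param measured Numeric vector of measured betas, same length.
#' @param epsilon Beta-unit error tolerance.
#' @param rho Correlation floor.
#' @return List: `max_abs_error`, `pearson_r`, `pass`.
#' @examples
#' evaluate_probe(c(0, .25, .5, .75, 1), c(.05, .30, .45, .80, .95))
#' @export
evaluate_probe <- function(expected, measured, epsilon = 0.15, rho = 0.95) {
  if (length(expected) != 5L || length(measured) != 5L)
    stop("a calibration series has exactly 5 points")
  if (any(measured < 0 | measured > 1))
    stop("measured betas must lie in [0, 1]")
  err <- max(abs(measured - expected))
  r <- if (sd(measured) == 0) NA_real_ else cor(measured, expected)
  list(max_abs_error = err, pearson_r = r,
       pass = err <= epsilon && !is.na(r) && r >= rho)
}

#' Filter probes by calibration accuracy
#'
#' Evaluates every probe of a calibration table against the dilution series
#' and returns the per-probe QC report. Computation is vectorized over
#' probes.
#'
#' @param calibration Long-format data.frame with columns probe_id,
#'   expected_fraction, measured_beta (5 rows per probe).
#' @param epsilon,rho As in [evaluate_probe()].
#' @return data.frame: probe_id, max_abs_error, pearson_r, pass. Errors if
#'   no probe passes.
#' @export
qc_probes <- function(calibration, epsilon = 0.15, rho = 0.95) {
  need <- c("probe_id", "expected_fraction", "measured_beta")
  if (!all(need %in% names(calibration)))
    stop("calibration must have columns: ", paste(need, collapse = ", "))
  o <- order(calibration$probe_id, calibration$expected_fraction)
  cal <- calibration[o, , drop = FALSE]
  cnt <- table(cal$probe_id)
  if (any(cnt != 5L))
    stop("every probe needs exactly 5 calibration points; offending: ",
         paste(head(names(cnt)[cnt != 5L], 3L), collapse = ", "))
  probes <- unique(cal$probe_id)
  M <- matrix(cal$measured_beta, ncol = 5L, byrow = TRUE)
  E <- matrix(sort(unique(cal$expected_fraction)), nrow(M), 5L, byrow = TRUE)
  if (any(M < 0 | M > 1)) stop("measured betas must lie in [0, 1]")
  A <- abs(M - E)
  err <- do.call(pmax, lapply(seq_len(5L), function(j) A[, j]))
  mm <- rowMeans(M)
  sm <- sqrt(rowSums((M - mm)^2))
  ev <- E[1L, ]
  se <- sqrt(sum((ev - mean(ev))^2))
  r <- as.vector((M - mm) %*% (ev - mean(ev))) / (sm * se)
  r[sm == 0] <- NA_real_
  pass <- err <= epsilon & !is.na(r) & r >= rho
  res <- data.frame(probe_id = probes, max_abs_error = err, pearson_r = r,
                    pass = pass, stringsAsFactors = FALSE)
  if (!any(res$pass))
    stop("no probe passes QC at epsilon = ", epsilon, ", rho = ", rho)
  res
}
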