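# Method-comparison statistics: Bland-Altman agreement with stratified
# acceptance bounds, observer-consensus maps, paired t-test, Pearson
# correlation.

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `automated - manual` (a positive bias means
#' the automated counts run higher). Limits of agreement (LOAs) are
#' `bias +/- 1.96 x SD` of the differences; the bias CI uses
#' `t(n-1) x sd/sqrt(n)` and each LOA CI the classical approximation
#' `t(n-1) x sd x sqrt(3/n)`.
#'
#' @param manual,automated numeric vectors of paired %PIT measurements
#'   (equal length >= 2, no missing values). Alternatively pass a data
#'   frame from [read_pairs()] as `manual` and leave `automated` absent.
#' @param conf_level confidence level for the CIs.
#' @return A `bland_altman` object: `n`, `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, their CIs, the per-pair `differences` and `means`, and
#'   `n_outside` (pairs outside the LOAs). Has `print` and `plot`
#'   methods.
#' @export
bland_altman <- function(manual, automated = NULL, conf_level = 0.95) {
  if (is.null(automated)) {
    stopifnot(is.data.frame(manual))
    automated <- manual$automated_percent_pit
    manual <- manual$manual_percent_pit
  }
  if (length(manual) != length(automated)) stop("paired vectors differ in length")
  if (anyNA(manual) || anyNA(automated)) stop("paired measurements contain NA")
  n <- length(manual)
  if (n < 2) stop("at least 2 pairs are required")
  d <- automated - manual
  bias <- mean(d)
  s <- sd(d)
  loa_upper <- bias + 1.96 * s
  loa_lower <- bias - 1.96 * s
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  structure(list(n = n, bias = bias, sd_diff = s,
                 loa_lower = loa_lower, loa_upper = loa_upper,
                 bias_ci = bias + c(-1, 1) * tq * se_bias,
                 loa_lower_ci = loa_lower + c(-1, 1) * tq * se_loa,
                 loa_upper_ci = loa_upper + c(-1, 1) * tq * se_loa,
                 conf_level = conf_level,
                 differences = d, means = (manual + automated) / 2,
                 n_outside = sum(d < loa_lower | d > loa_upper)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  ci <- function(v) sprintf("(%.2f to %.2f)", v[1], v[2])
  cat(sprintf("Bland-Altman agreement, n = %d pairs (automated - manual)\n", x$n))
  cat(sprintf("  bias: %.2f%% %s\n", x$bias, ci(x$bias_ci)))
  cat(sprintf("  upper LOA: %.2f%% %s\n", x$loa_upper, ci(x$loa_upper_ci)))
  cat(sprintf("  lower LOA: %.2f%% %s\n", x$loa_lower, ci(x$loa_lower_ci)))
  cat(sprintf("  %d pair(s) outside the LOAs\n", x$n_outside))
  invisible(x)
}

#' Bland-Altman plot (mean vs difference with bias and LOA bands)
#'
#' @param x a `bland_altman` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  yl <- range(c(x$differences, x$loa_lower_ci, x$loa_upper_ci))
  plot(x$means, x$differences, xlab = "mean of methods (%PIT)",
       ylab = "automated - manual (%PIT)", ylim = yl, pch = 19, ...)
  band <- function(ci, col) rect(par("usr")[1], ci[1], par("usr")[2], ci[2],
                                 col = col, border = NA)
  band(x$bias_ci, grDevices::adjustcolor("blue", 0.15))
  band(x$loa_upper_ci, grDevices::adjustcolor("darkgreen", 0.15))
  band(x$loa_lower_ci, grDevices::adjustcolor("red", 0.15))
  abline(h = x$bias, col = "blue")
  abline(h = c(x$loa_lower, x$loa_upper), lty = 2, col = c("red", "darkgreen"))
  points(x$means, x$differences, pch = 19)
  invisible(x)
}

#' Write a Bland-Altman result to CSV or JSON
#'
#' One-row summary (n, bias, SD, LOAs, CI bounds, pairs outside); the
#' format follows the file extension (`.csv` or `.json`).
#'
#' @param ba a [bland_altman()] result.
#' @param path output path ending in `.csv` or `.json`.
#' @export
write_bland_altman <- function(ba, path) {
  stopifnot(inherits(ba, "bland_altman"))
  row <- data.frame(n = ba$n, bias = ba$bias, sd_diff = ba$sd_diff,
                    loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
                    bias_ci_low = ba$bias_ci[1], bias_ci_high = ba$bias_ci[2],
                    loa_lower_ci_low = ba$loa_lower_ci[1],
                    loa_lower_ci_high = ba$loa_lower_ci[2],
                    loa_upper_ci_low = ba$loa_upper_ci[1],
                    loa_upper_ci_high = ba$loa_upper_ci[2],
                    n_outside = ba$n_outside)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") write.csv(row, path, row.names = FALSE)
  else if (ext == "json") jsonlite::write_json(as.list(row), path,
                                               auto_unbox = TRUE, digits = NA)
  else stop("unsupported extension: .", ext)
  invisible(path)
}

#' Check limits of agreement against stratified acceptance bounds
#'
#' The acceptance policy: overall, LOAs must lie within +/- `overall`
#' percentage points; for the low stratum (samples with manual %PIT
#' below 5%), within +/- `low`. The caller subsets the pairs to the
#' stratum before computing the Bland-Altman fit.
#'
#' @param ba a [bland_altman()] result computed on the stratum's pairs.
#' @param stratum `"overall"` or `"low"`.
#' @param overall,low acceptance bounds in percentage points.
#' @return List: `pass`, `bound`, `stratum`, and `margin_upper` /
#'   `margin_lower` (bound minus |LOA|; negative = exceeded).
#' @export
check_loa_acceptance <- function(ba, stratum = c("overall", "low"),
                                 overall = 5, low = 1.5) {
  stratum <- match.arg(stratum)
  stopifnot(overall > 0, low > 0)
  bound <- if (stratum == "overall") overall else low
  list(pass = max(abs(ba$loa_upper), abs(ba$loa_lower)) <= bound,
       bound = bound, stratum = stratum,
       margin_upper = bound - abs(ba$loa_upper),
       margin_lower = bound - abs(ba$loa_lower))
}

#' Observer consensus map
#'
#' Sums binary annotation masks pixel-wise: the value at each pixel is
#' the number of observers who annotated it.
#'
#' @param masks list of >= 2 binary matrices of identical geometry.
#' @return List with `counts` (integer matrix, 0..k) and `summary`
#'   (pixel tally per consensus level).
#' @export
consensus_map <- function(masks) {
  if (!is.list(masks) || length(masks) < 2)
    stop("at least 2 annotation masks are required")
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("annotation masks differ in geometry")
  counts <- Reduce(`+`, lapply(masks, function(m) (m != 0) * 1L))
  storage.mode(counts) <- "integer"
  k <- length(masks)
  tally <- base::table(factor(counts, levels = 0:k))
  list(counts = counts, n_observers = k, summary = tally)
}

#' Paired t-test on manual vs automated measurements
#'
#' Two-sided paired t-test of the differences `automated - manual`
#' (delegated to [stats::t.test()]).
#'
#' @param manual,automated paired numeric vectors, length >= 2.
#' @return List: `t`, `df`, `p`, `mean_difference`.
#' @export
paired_t_test <- function(manual, automated) {
  if (length(manual) != length(automated)) stop("paired vectors differ in length")
  if (length(manual) < 2) stop("at least 2 pairs are required")
  d <- automated - manual
  if (sd(d) == 0)
    stop("degenerate input: differences have zero variance")
  tt <- stats::t.test(automated, manual, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Pearson correlation with two-sided p-value
#'
#' Delegated to [stats::cor.test()]; requires n >= 3 and non-constant
#' inputs.
#'
#' @param x,y numeric vectors of equal length.
#' @return List: `r`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3) stop("at least 3 observations are required")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}
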