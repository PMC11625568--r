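#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of a value vector against a normal law. The default
#' `"lilliefors"` variant estimates mean and SD from the data and uses the
#' Lilliefors correction (the appropriate choice for empirical gait data with
#' unknown parameters); `"classic"` plugs the sample estimates into a plain
#' KS test, whose p-values are anti-conservative and retained only for
#' comparison with software that does the same.
#'
#' @param values Numeric vector, `n >= 5`, non-constant.
#' @param variant `"lilliefors"` (default) or `"classic"`.
#' @return The p-value.
#' @export
ks_normality <- function(values, variant = c("lilliefors", "classic")) {
  variant <- match.arg(variant)
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("need at least 5 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant vector: normality test undefined", call. = FALSE)
  if (variant == "lilliefors")
    nortest::lillie.test(values)$p.value
  else
    suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value)
}

#' Paired t test between two measurement systems
#'
#' Two-sided paired t test on the per-observation differences
#' `measured - actual`. Identical vectors return `t = 0, p = 1` (rather than
#' the degenerate-data error a textbook routine raises); nonzero differences
#' with zero variance signal a degenerate infinite-t condition.
#'
#' @param measured,actual Equal-length numeric vectors (`n >= 2`).
#' @return List with `t`, `p` and `df`.
#' @export
paired_t <- function(measured, actual) {
  if (length(measured) != length(actual))
    stop("paired vectors differ in length", call. = FALSE)
  n <- length(measured)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- measured - actual
  # float-tolerant zero-variance guard (x + c - x leaves ~1e-16 residue)
  eps <- 1e-10 * max(1, max(abs(d)))
  if (stats::sd(d) <= eps) {
    if (abs(mean(d)) <= eps) return(list(t = 0, p = 1, df = n - 1L))
    stop("degenerate: differences constant and nonzero (infinite t)",
         call. = FALSE)
  }
  tt <- stats::t.test(measured, actual, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Accuracy as 100% minus the mean absolute percentage error
#'
#' `accuracy = 100 - mean(|measured - actual| / |actual|) * 100`, with the
#' camera-side value as `measured` and the reference system as `actual`.
#'
#' @param measured,actual Equal-length numeric vectors; all `actual` nonzero.
#' @return Accuracy in percent (can be negative when MAPE exceeds 100%).
#' @export
accuracy_mape <- function(measured, actual) {
  if (length(measured) != length(actual))
    stop("paired vectors differ in length", call. = FALSE)
  zero <- which(actual == 0)
  if (length(zero))
    stop("actual value is zero at pair ", zero[1L],
         ": percentage error undefined", call. = FALSE)
  100 - mean(abs(measured - actual) / abs(actual)) * 100
}

#' Pearson correlation between two measurement systems
#'
#' @param measured,actual Equal-length numeric vectors, `n >= 3`, both with
#'   nonzero variance.
#' @return List with `r` and two-sided `p`.
#' @export
pearson_r <- function(measured, actual) {
  if (length(measured) != length(actual))
    stop("paired vectors differ in length", call. = FALSE)
  if (length(measured) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(measured) == 0 || stats::sd(actual) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(measured, actual, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Root mean square error between two measurement systems
#'
#' `sqrt(mean((actual - measured)^2))` over the paired observations.
#'
#' @param measured,actual Equal-length numeric vectors, `n >= 1`.
#' @return The RMSE, in the units of the inputs.
#' @export
rmse <- function(measured, actual) {
  if (length(measured) != length(actual))
    stop("paired vectors differ in length", call. = FALSE)
  if (!length(measured)) stop("empty input", call. = FALSE)
  sqrt(mean((actual - measured)^2))
}

#' Bland-Altman analysis
#'
#' Differences `measured - actual` against pair means, with the mean
#' difference and the limits of agreement at mean +- 1.96 times the sample
#' standard deviation of the differences.
#'
#' @param measured,actual Equal-length numeric vectors, `n >= 2`.
#' @return An object of class `bland_altman`: list with `mean_diff`,
#'   `loa_low`, `loa_high`, `sd_diff`, `inside_fraction` (share of points
#'   within the LoA) and `points` (data frame `mean`, `diff`).
#' @export
bland_altman <- function(measured, actual) {
  if (length(measured) != length(actual))
    stop("paired vectors differ in length", call. = FALSE)
  n <- length(measured)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- measured - actual
  m <- (measured + actual) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  lo <- md - 1.96 * sdd
  hi <- md + 1.96 * sdd
  structure(list(mean_diff = md, sd_diff = sdd, loa_low = lo, loa_high = hi,
                 inside_fraction = mean(d >= lo & d <= hi),
                 points = data.frame(mean = m, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4g, LoA [%.4g, %.4g], %.1f%% inside\n",
              x$mean_diff, x$loa_low, x$loa_high, 100 * x$inside_fraction))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, main = "Bland-Altman", xlab = "Mean of pair",
                              ylab = "Difference (measured - actual)", ...) {
  graphics::plot(x$points$mean, x$points$diff, main = main, xlab = xlab,
                 ylab = ylab, pch = 19, col = "#00000080", ...)
  graphics::abline(h = c(x$loa_low, x$mean_diff, x$loa_high),
                   lty = c(2, 1, 2), col = c("red", "blue", "red"))
  invisible(x)
}

#' Per-parameter, per-group agreement table
#'
#' Runs the full method-comparison battery for every parameter, pooled over
#' all groups and separately per group: per-system mean and SD, paired-t
#' p-value, accuracy (100 - MAPE), Pearson r with its p-value (flagged
#' significant at p < 0.05), RMSE, and Bland-Altman mean difference and
#' limits of agreement. No multiple-testing correction is applied; p-values
#' are raw.
#'
#' @param pairs Tidy data frame with columns `parameter`, `measured`,
#'   `actual` and optionally `group` (e.g. stroke/healthy).
#' @param min_pairs Cells with fewer pairs are omitted with a warning
#'   (default 3).
#' @return Data frame with one row per (parameter, group) cell, group
#'   `"all"` first.
#' @export
agreement_table <- function(pairs, min_pairs = 3L) {
  stopifnot(all(c("parameter", "measured", "actual") %in% names(pairs)))
  groups <- if ("group" %in% names(pairs))
    c("all", sort(unique(as.character(pairs$group)))) else "all"
  rows <- list()
  for (g in groups) {
    sub <- if (g == "all") pairs else pairs[pairs$group == g, , drop = FALSE]
    for (p in unique(as.character(pairs$parameter))) {
      cell <- sub[sub$parameter == p, , drop = FALSE]
      if (nrow(cell) < min_pairs) {
        warning("cell (", p, ", ", g, ") has ", nrow(cell),
                " pairs: omitted")
        next
      }
      tt <- paired_t(cell$measured, cell$actual)
      pr <- pearson_r(cell$measured, cell$actual)
      ba <- bland_altman(cell$measured, cell$actual)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p, n = nrow(cell),
        mean_actual = mean(cell$actual), sd_actual = stats::sd(cell$actual),
        mean_measured = mean(cell$measured), sd_measured = stats::sd(cell$measured),
        t_p = tt$p,
        accuracy_pct = accuracy_mape(cell$measured, cell$actual),
        pearson_r = pr$r, r_p = pr$p, r_significant = pr$p < 0.05,
        rmse = rmse(cell$measured, cell$actual),
        ba_mean_diff = ba$mean_diff, ba_loa_low = ba$loa_low,
        ba_loa_high = ba$loa_high, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
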