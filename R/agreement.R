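#' Paired measured/reference readings for method comparison
#'
#' Holds K pairs of device readings (\code{measured}) against a reference
#' instrument (\code{reference}) for one vital parameter. Reference values
#' must be strictly positive because the mean relative error divides by them.
#'
#' @param measured,reference numeric vectors of equal length K >= 2.
#' @param parameter which vital the pairs measure: \code{"heart_rate"},
#'   \code{"spo2"} or \code{"temperature"} (free text accepted).
#' @return An object of class \code{paired_readings}; \code{$pairs} is a
#'   data.frame, \code{$K} the pair count.
#' @export
paired_readings <- function(measured, reference, parameter = "unspecified") {
  stopifnot(is.numeric(measured), is.numeric(reference))
  if (length(measured) != length(reference))
    stop("measured and reference must have equal length", call. = FALSE)
  if (length(measured) < 2L)
    stop("insufficient data: need at least 2 pairs", call. = FALSE)
  if (!all(is.finite(measured)) || !all(is.finite(reference)))
    stop("all readings must be finite", call. = FALSE)
  if (any(reference <= 0))
    stop("all reference values must be > 0 (relative error denominator)",
         call. = FALSE)
  structure(list(parameter = as.character(parameter),
                 pairs = data.frame(measured = as.numeric(measured),
                                    reference = as.numeric(reference)),
                 K = length(measured)),
            class = "paired_readings")
}

#' @export
print.paired_readings <- function(x, ...) {
  cat(sprintf("<paired_readings '%s'> K = %d pairs\n", x$parameter, x$K))
  invisible(x)
}

#' Root mean squared error between reference and measured readings
#'
#' \eqn{RMSE = \sqrt{\sum_i (ref_i - mes_i)^2 / K}}.
#'
#' @param p a \code{\link{paired_readings}}.
#' @return RMSE in the parameter's units.
#' @export
rmse <- function(p) {
  stopifnot(inherits(p, "paired_readings"))
  sqrt(sum((p$pairs$reference - p$pairs$measured)^2) / p$K)
}

#' Mean absolute error between reference and measured readings
#'
#' \eqn{MAE = \sum_i |ref_i - mes_i| / K}.
#'
#' @inheritParams rmse
#' @return MAE in the parameter's units.
#' @export
mae <- function(p) {
  stopifnot(inherits(p, "paired_readings"))
  mean(abs(p$pairs$reference - p$pairs$measured))
}

#' Mean relative error between reference and measured readings
#'
#' \eqn{MRE = (1/K) \sum_i |ref_i - mes_i| / ref_i}, a dimensionless
#' fraction; multiply by 100 (or set \code{percent = TRUE}) for the percent
#' scale in which comparison tables often quote it.
#'
#' @inheritParams rmse
#' @param percent if TRUE, return MRE x 100.
#' @return MRE as a fraction (default) or percent.
#' @export
mre <- function(p, percent = FALSE) {
  stopifnot(inherits(p, "paired_readings"))
  v <- mean(abs(p$pairs$reference - p$pairs$measured) / p$pairs$reference)
  if (percent) 100 * v else v
}

#' Per-reading percentage error
#'
#' \eqn{100 |measured - reference| / reference}, rounded to 2 decimals for
#' display (set \code{digits = NULL} for full precision). Vectorized.
#'
#' @param measured,reference numeric vectors; reference > 0.
#' @param digits decimals for display rounding, or NULL.
#' @return Percentage error(s).
#' @examples
#' per_reading_error(107, 104)  # 2.88
#' @export
per_reading_error <- function(measured, reference, digits = 2) {
  stopifnot(is.numeric(measured), is.numeric(reference))
  if (any(reference <= 0))
    stop("reference must be > 0", call. = FALSE)
  v <- 100 * abs(measured - reference) / reference
  if (is.null(digits)) v else round(v, digits)
}

#' Ordinary least-squares fit of reference on measured readings
#'
#' Fits \eqn{reference = a \cdot measured + b} by OLS and reports the squared
#' Pearson correlation of the two sequences as \eqn{R^2}. A perfect-match
#' device lies on the identity line a = 1, b = 0.
#'
#' @inheritParams rmse
#' @return List with \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
linear_fit <- function(p) {
  stopifnot(inherits(p, "paired_readings"))
  if (p$K < 3L) stop("insufficient data: need K >= 3 for a fit", call. = FALSE)
  if (stats::var(p$pairs$measured) == 0)
    stop("degenerate fit: measured values have zero variance", call. = FALSE)
  fit <- stats::lm(reference ~ measured, data = p$pairs)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(p$pairs$measured, p$pairs$reference)^2)
}

#' Bland-Altman limits of agreement
#'
#' Differences are \code{measured - reference}; averages are the per-pair
#' means. The 95\% limits of agreement are mean(d) +/- 1.96 SD(d), with SD
#' the sample standard deviation (divisor K - 1) by default.
#' \code{n_outside_loa} counts differences strictly beyond either limit.
#'
#' @inheritParams rmse
#' @param sd_divisor \code{"sample"} (K - 1, default) or
#'   \code{"population"} (K).
#' @return List with \code{mean_diff}, \code{sd_diff}, \code{loa_lower},
#'   \code{loa_upper}, \code{n_outside_loa}, \code{sd_divisor}, and
#'   \code{points} (data.frame of per-pair average and difference).
#' @export
bland_altman <- function(p, sd_divisor = c("sample", "population")) {
  stopifnot(inherits(p, "paired_readings"))
  sd_divisor <- match.arg(sd_divisor)
  if (p$K < 3L)
    stop("insufficient data: need K >= 3 for limits of agreement", call. = FALSE)
  d <- p$pairs$measured - p$pairs$reference
  avg <- (p$pairs$measured + p$pairs$reference) / 2
  m <- mean(d)
  s <- stats::sd(d)
  if (sd_divisor == "population") s <- s * sqrt((p$K - 1) / p$K)
  upper <- m + 1.96 * s
  lower <- m - 1.96 * s
  list(mean_diff = m, sd_diff = s, loa_lower = lower, loa_upper = upper,
       n_outside_loa = sum(d > upper | d < lower),
       sd_divisor = sd_divisor,
       points = data.frame(average = avg, difference = d))
}

#' Full device-agreement report for one paired table
#'
#' Composes RMSE, MAE, MRE (fraction and percent), the OLS fit with
#' \eqn{R^2}, and the Bland-Altman limits into one report object. All values
#' are kept at full precision; the print method rounds for display (RMSE/MAE
#' to 2 decimals, MRE and \eqn{R^2} to 3).
#'
#' @inheritParams bland_altman
#' @return An object of class \code{agreement_report}.
#' @examples
#' p <- load_fixture("hr")
#' agreement_report(p)
#' @export
agreement_report <- function(p, sd_divisor = "sample") {
  stopifnot(inherits(p, "paired_readings"))
  fit <- linear_fit(p)
  ba <- bland_altman(p, sd_divisor)
  structure(list(parameter = p$parameter, K = p$K,
                 rmse = rmse(p), mae = mae(p),
                 mre = mre(p), mre_percent = mre(p, percent = TRUE),
                 slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared,
                 mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                 loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
                 n_outside_loa = ba$n_outside_loa,
                 sd_divisor = ba$sd_divisor),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report: %s (K = %d)\n", x$parameter, x$K))
  cat(sprintf("  RMSE %6.2f   MAE %6.2f   MRE %.3f (%.2f%%)   R^2 %.3f\n",
              x$rmse, x$mae, x$mre, x$mre_percent, x$r_squared))
  cat(sprintf("  fit: reference = %.3f * measured %+.3f\n", x$slope, x$intercept))
  cat(sprintf("  Bland-Altman: mean diff %.4f, SD %.4f (%s), LoA [%.4f, %.4f], %d outside\n",
              x$mean_diff, x$sd_diff, x$sd_divisor, x$loa_lower, x$loa_upper,
              x$n_outside_loa))
  invisible(x)
}

#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(parameter = x$parameter, K = x$K, rmse = x$rmse, mae = x$mae,
             mre = x$mre, mre_percent = x$mre_percent, slope = x$slope,
             intercept = x$intercept, r_squared = x$r_squared,
             mean_diff = x$mean_diff, sd_diff = x$sd_diff,
             loa_lower = x$loa_lower, loa_upper = x$loa_upper,
             n_outside_loa = x$n_outside_loa)
}
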