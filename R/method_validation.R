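#' Fit a linear calibration curve
#'
#' Ordinary least-squares line of instrument response on standard
#' concentration, as used for external-standard quantification.
#'
#' @param levels Standard concentrations, mg/L (>= 3 distinct values).
#' @param responses Instrument responses, one per level.
#' @param compound,medium Identifiers stored on the result; `medium` is
#'   `"solvent"` or `"matrix"`.
#' @return An object of class `"calibration_curve"`: a list with `slope`,
#'   `intercept`, `correlation` (Pearson r), `levels`, `compound`, `medium`.
#' @examples
#' fit_calibration(c(0.1, 0.5, 1, 5), 75.023 * c(0.1, 0.5, 1, 5) - 0.1507)
#' @export
fit_calibration <- function(levels, responses,
                            compound = "compound",
                            medium = c("solvent", "matrix")) {
  medium <- match.arg(medium)
  if (!is.numeric(levels) || !is.numeric(responses) ||
      length(levels) != length(responses))
    stop_field("levels/responses", "must be numeric vectors of equal length")
  if (length(unique(levels)) < 3L)
    stop_field("levels", "need at least 3 distinct calibration levels")
  if (stats::sd(responses) == 0)
    stop_field("responses", "constant responses give a degenerate curve")
  fit <- stats::lm(responses ~ levels)
  structure(
    list(compound = as.character(compound), medium = medium,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         correlation = stats::cor(levels, responses),
         levels = as.numeric(levels)),
    class = "calibration_curve"
  )
}

#' Matrix effect from matrix and solvent calibration slopes
#'
#' ME% = (K1/K2 - 1) x 100, where K1 is the slope of the matrix-matched
#' curve and K2 the slope of the solvent curve. |ME| >= 20% is conventionally
#' taken as a significant matrix effect (signal enhancement or suppression
#' large enough to require matrix-matched calibration).
#'
#' @param matrix_slope K1, slope of the matrix-matched calibration curve.
#'   May also be a `"calibration_curve"`.
#' @param solvent_slope K2, slope of the solvent calibration curve (nonzero).
#'   May also be a `"calibration_curve"`.
#' @param threshold Significance threshold on |ME|, percent (default 20).
#' @return A list with `me_percent` (signed), `abs_me_percent`, and
#'   `significant` (logical flag at `threshold`).
#' @examples
#' matrix_effect(79.557, 75.023)$abs_me_percent  # ~6%
#' @export
matrix_effect <- function(matrix_slope, solvent_slope, threshold = 20) {
  if (inherits(matrix_slope, "calibration_curve"))
    matrix_slope <- matrix_slope$slope
  if (inherits(solvent_slope, "calibration_curve"))
    solvent_slope <- solvent_slope$slope
  check_scalar_num(matrix_slope, "matrix_slope")
  check_scalar_num(solvent_slope, "solvent_slope")
  if (solvent_slope == 0)
    stop_field("solvent_slope", "must be nonzero")
  me <- (matrix_slope / solvent_slope - 1) * 100
  list(me_percent = me, abs_me_percent = abs(me),
       significant = abs(me) >= threshold)
}

#' Recovery and precision of a fortification experiment
#'
#' Mean recovery is 100 x mean(measured)/spike level; precision is the
#' relative standard deviation, 100 x SD/mean with the sample (n - 1)
#' standard deviation.
#'
#' @param measured Measured concentrations, mg/kg (>= 2 replicates).
#' @param spike_level Fortified concentration, mg/kg (> 0).
#' @param compound Identifier stored on the result.
#' @return An object of class `"recovery_result"`: `compound`, `spike_level`,
#'   `mean_recovery` (percent), `rsd` (percent), `n`.
#' @export
compute_recovery <- function(measured, spike_level, compound = "compound") {
  check_scalar_num(spike_level, "spike_level", positive = TRUE)
  if (!is.numeric(measured) || length(measured) < 2L)
    stop_field("measured", "need at least 2 replicate measurements")
  if (any(!is.finite(measured)))
    stop_field("measured", "must be finite")
  m <- mean(measured)
  structure(
    list(compound = as.character(compound), spike_level = spike_level,
         mean_recovery = 100 * m / spike_level,
         rsd = 100 * stats::sd(measured) / m,
         n = length(measured)),
    class = "recovery_result"
  )
}

#' Screen spike levels for the method limit of quantification
#'
#' The LOQ is taken as the lowest fortification level whose mean recovery
#' falls inside `recovery_band` and whose RSD does not exceed `rsd_max`
#' (defaults follow the 70-120% / 20% residue-guideline convention).
#'
#' @param recoveries A list of `"recovery_result"` objects.
#' @param recovery_band Acceptable mean-recovery interval, percent.
#' @param rsd_max Maximum acceptable RSD, percent.
#' @return A list with `loq` (mg/kg, or `NA` when no level passes),
#'   `established` (logical), and `table` (per-level pass/fail data frame).
#'   A failure to establish an LOQ is a result, not an error.
#' @export
screen_loq <- function(recoveries, recovery_band = c(70, 120), rsd_max = 20) {
  if (inherits(recoveries, "recovery_result")) recoveries <- list(recoveries)
  if (length(recoveries) == 0L)
    stop_field("recoveries", "need at least one spike level")
  if (!all(vapply(recoveries, inherits, logical(1), "recovery_result")))
    stop_field("recoveries", "must be recovery_result objects")
  tab <- data.frame(
    spike_level = vapply(recoveries, `[[`, numeric(1), "spike_level"),
    mean_recovery = vapply(recoveries, `[[`, numeric(1), "mean_recovery"),
    rsd = vapply(recoveries, `[[`, numeric(1), "rsd")
  )
  tab$pass <- tab$mean_recovery >= recovery_band[1] &
    tab$mean_recovery <= recovery_band[2] & tab$rsd <= rsd_max
  passing <- tab$spike_level[tab$pass]
  list(loq = if (length(passing)) min(passing) else NA_real_,
       established = length(passing) > 0,
       table = tab[order(tab$spike_level), ])
}
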