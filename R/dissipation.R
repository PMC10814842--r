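#' A residue dissipation time series
#'
#' Container for residue-versus-time observations from one site, with
#' per-observation LOQ-censoring flags.
#'
#' @param compound,site Identifiers.
#' @param days Sampling days (>= 0, strictly increasing).
#' @param residues Residue concentrations, mg/kg (>= 0).
#' @param censored Logical flags, `TRUE` where the observation is below the
#'   LOQ. Defaults to `residues < loq`.
#' @param loq Limit of quantification, mg/kg.
#' @return An object of class `"dissipation_series"`.
#' @export
dissipation_series <- function(compound, site, days, residues,
                               censored = residues < loq, loq = 0) {
  if (!is.numeric(days) || is.unsorted(days, strictly = TRUE))
    stop_field("days", "must be strictly increasing")
  if (any(days < 0)) stop_field("days", "must be >= 0")
  if (length(residues) != length(days))
    stop_field("residues", "must have one value per day")
  if (any(!is.finite(residues)) || any(residues < 0))
    stop_field("residues", "must be finite and >= 0")
  if (length(censored) != length(days) || !is.logical(censored))
    stop_field("censored", "must be a logical vector matching `days`")
  check_scalar_num(loq, "loq", nonneg = TRUE)
  structure(
    list(compound = as.character(compound), site = as.character(site),
         days = as.numeric(days), residues = as.numeric(residues),
         censored = censored, loq = loq),
    class = "dissipation_series"
  )
}

# Apply a censoring policy, returning the usable (day, value) pairs.
apply_censor_policy <- function(series, policy) {
  values <- series$residues
  keep <- rep(TRUE, length(values))
  if (any(series$censored)) {
    switch(policy,
      drop = keep[series$censored] <- FALSE,
      half_loq = values[series$censored] <- series$loq / 2,
      loq = values[series$censored] <- series$loq
    )
  }
  list(days = series$days[keep], values = values[keep])
}

#' Fit first-order dissipation kinetics
#'
#' Fits \eqn{C_t = C_0 e^{-kt}} by least squares on the log scale
#' (`ln(Ct) ~ t`), the standard convention in residue dissipation studies;
#' `method = "nls"` refines the log-linear estimates by nonlinear least
#' squares on the original scale. Censored (<LOQ) observations are handled
#' by `censor_policy`: substituted at LOQ/2 (default), dropped, or
#' substituted at the LOQ.
#'
#' @param series A [dissipation_series()].
#' @param censor_policy One of `"half_loq"`, `"drop"`, `"loq"`.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return An object of class `"dissipation_fit"`: `c0_hat` (mg/kg), `k_hat`
#'   (per day), `half_life` (days; `NA` with `half_life_defined = FALSE` when
#'   the fitted slope is non-negative), `r_squared` (of the log-linear fit),
#'   `n_used`, plus the compound/site labels and the policy used.
#' @examples
#' s <- generate_decay_series(trial_config(1, 0.0693, c(0, 3, 7, 14, 21, 28)))
#' fit_first_order(s)$half_life  # 10.0 days
#' @export
fit_first_order <- function(series,
                            censor_policy = c("half_loq", "drop", "loq"),
                            method = c("loglinear", "nls")) {
  censor_policy <- match.arg(censor_policy)
  method <- match.arg(method)
  if (!inherits(series, "dissipation_series"))
    stop_field("series", "must be a `dissipation_series`")
  usable <- apply_censor_policy(series, censor_policy)
  if (any(usable$values <= 0))
    stop_field("series", "non-positive residue cannot be log-transformed; use a substitution policy")
  if (length(usable$values) < 3L || length(unique(usable$days)) < 2L)
    stop("fewer than 3 usable points (or < 2 distinct days); cannot fit",
         call. = FALSE)
  fit <- stats::lm(log(usable$values) ~ usable$days)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # r^2 of a simple linear regression is the squared Pearson correlation;
  # computing it directly avoids summary.lm()'s perfect-fit warning on
  # noiseless data
  r2 <- if (stats::sd(log(usable$values)) == 0) NA_real_
        else stats::cor(usable$days, log(usable$values))^2
  c0 <- exp(intercept)
  k <- -slope
  if (method == "nls" && k > 0) {
    nl <- try(stats::nls(values ~ c0 * exp(-k * days), data = usable,
                         start = list(c0 = c0, k = k)), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      c0 <- unname(stats::coef(nl)["c0"])
      k <- unname(stats::coef(nl)["k"])
    }
  }
  defined <- k > 0
  structure(
    list(compound = series$compound, site = series$site,
         c0_hat = c0, k_hat = k,
         half_life = if (defined) log(2) / k else NA_real_,
         half_life_defined = defined,
         r_squared = r2, n_used = length(usable$values),
         censor_policy = censor_policy, method = method),
    class = "dissipation_fit"
  )
}

#' Half-life from a first-order rate constant
#'
#' @param k First-order rate constant, per day (> 0).
#' @return Half-life in days, `ln(2)/k`.
#' @export
half_life <- function(k) {
  check_scalar_num(k, "k", positive = TRUE)
  log(2) / k
}

#' Dissipation percentage between the initial deposit and a later residue
#'
#' @param c0 Initial deposit, mg/kg (> 0).
#' @param ct Residue at the later time, mg/kg (>= 0).
#' @return Percent dissipated, `100 * (c0 - ct) / c0`.
#' @export
dissipation_rate <- function(c0, ct) {
  check_scalar_num(c0, "c0", positive = TRUE)
  check_scalar_num(ct, "ct", nonneg = TRUE)
  100 * (c0 - ct) / c0
}

#' @export
print.dissipation_fit <- function(x, ...) {
  cat(sprintf("First-order dissipation fit: %s @ %s\n", x$compound, x$site))
  cat(sprintf("  C0 = %.4g mg/kg, k = %.4g /day, T1/2 = %s days\n",
              x$c0_hat, x$k_hat,
              if (x$half_life_defined) sprintf("%.3g", x$half_life)
              else "undefined"))
  cat(sprintf("  r^2 = %.4f (log-linear), n = %d, censoring = %s\n",
              x$r_squared, x$n_used, x$censor_policy))
  invisible(x)
}
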