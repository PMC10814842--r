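#' Fit a lognormal distribution by log-moment maximum likelihood
#'
#' mu and sigma are the mean and standard deviation of the log-transformed
#' observations (the MLE uses the n-denominator SD). Censored observations
#' are substituted before the transform according to `censor_policy`, using
#' `loq`.
#'
#' @param observations Positive observations (consumption kg/day or residue
#'   mg/kg).
#' @param censored Logical flags marking <LOQ observations (default none).
#' @param censor_policy One of `"half_loq"`, `"drop"`, `"loq"`.
#' @param loq Limit of quantification used for substitution.
#' @return An object of class `"lognormal_params"`: `mu`, `sigma`, `n_fit`.
#' @export
fit_lognormal <- function(observations, censored = NULL,
                          censor_policy = c("half_loq", "drop", "loq"),
                          loq = 0) {
  censor_policy <- match.arg(censor_policy)
  if (!is.numeric(observations) || length(observations) == 0L)
    stop_field("observations", "must be a non-empty numeric vector")
  if (is.null(censored)) censored <- rep(FALSE, length(observations))
  if (length(censored) != length(observations))
    stop_field("censored", "must match `observations` in length")
  x <- observations
  if (any(censored)) {
    switch(censor_policy,
      drop = x <- x[!censored],
      half_loq = x[censored] <- loq / 2,
      loq = x[censored] <- loq
    )
  }
  if (length(x) < 2L)
    stop("fewer than 2 usable observations; cannot fit", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop_field("observations",
               "must be positive after censoring substitution")
  lx <- log(x)
  n <- length(lx)
  structure(
    list(mu = mean(lx),
         sigma = sqrt(sum((lx - mean(lx))^2) / n),  # MLE, n denominator
         n_fit = n),
    class = "lognormal_params"
  )
}

#' Construct lognormal parameters directly
#'
#' @param mu Log-scale location.
#' @param sigma Log-scale scale (>= 0).
#' @param n_fit Number of observations behind the parameters (0 when set by
#'   hand).
#' @return An object of class `"lognormal_params"`.
#' @export
lognormal_params <- function(mu, sigma, n_fit = 0L) {
  check_scalar_num(mu, "mu")
  check_scalar_num(sigma, "sigma", nonneg = TRUE)
  structure(list(mu = mu, sigma = sigma, n_fit = as.integer(n_fit)),
            class = "lognormal_params")
}

#' Specify a Monte-Carlo exposure simulation
#'
#' One consumption/residue lognormal pair per food; exposure per iteration is
#' \eqn{y_i = \sum_k x_{ik} c_{ik} / bw_i} with consumption \eqn{x_{ik}} and
#' residue \eqn{c_{ik}} drawn independently and \eqn{bw_i} the subgroup point
#' bodyweight (a bodyweight CV may be supplied to sample it instead).
#'
#' @param subgroup A [population_subgroup()].
#' @param consumption_dist A [lognormal_params()] (or list of, one per food).
#' @param residue_dist A [lognormal_params()] (or list of, one per food).
#' @param n_iter Number of Monte-Carlo iterations (default 1000).
#' @param seed Integer seed.
#' @param bw_cv Bodyweight coefficient of variation; 0 keeps the point
#'   bodyweight.
#' @return An object of class `"exposure_simulation"` (unrun; `samples` is
#'   `NULL` until [simulate_exposure()] is called).
#' @export
exposure_simulation <- function(subgroup, consumption_dist, residue_dist,
                                n_iter = 1000L, seed = NULL, bw_cv = 0) {
  if (!inherits(subgroup, "population_subgroup"))
    stop_field("subgroup", "must be a `population_subgroup`")
  if (inherits(consumption_dist, "lognormal_params"))
    consumption_dist <- list(consumption_dist)
  if (inherits(residue_dist, "lognormal_params"))
    residue_dist <- list(residue_dist)
  ok <- function(l) all(vapply(l, inherits, logical(1), "lognormal_params"))
  if (!ok(consumption_dist))
    stop_field("consumption_dist", "must be fitted `lognormal_params`")
  if (!ok(residue_dist))
    stop_field("residue_dist", "must be fitted `lognormal_params`")
  if (length(consumption_dist) != length(residue_dist))
    stop_field("residue_dist", "need one residue distribution per food")
  n_iter <- check_count(n_iter, "n_iter", min = 1L)
  check_scalar_num(bw_cv, "bw_cv", nonneg = TRUE)
  structure(
    list(subgroup = subgroup, consumption_dist = consumption_dist,
         residue_dist = residue_dist, n_iter = n_iter, seed = seed,
         bw_cv = bw_cv, samples = NULL),
    class = "exposure_simulation"
  )
}

#' Run a Monte-Carlo exposure simulation
#'
#' Draws `n_iter` exposures reproducibly under the stored seed.
#'
#' @param sim An [exposure_simulation()].
#' @return The simulation with `samples` filled (mg/kg bw/day).
#' @export
simulate_exposure <- function(sim) {
  if (!inherits(sim, "exposure_simulation"))
    stop_field("sim", "must be an `exposure_simulation`")
  n <- sim$n_iter
  sim$samples <- with_seed(sim$seed, {
    total <- numeric(n)
    for (k in seq_along(sim$consumption_dist)) {
      cd <- sim$consumption_dist[[k]]
      rd <- sim$residue_dist[[k]]
      x <- stats::rlnorm(n, cd$mu, cd$sigma)
      cc <- stats::rlnorm(n, rd$mu, rd$sigma)
      total <- total + x * cc
    }
    bw <- if (sim$bw_cv > 0) {
      b <- stats::rnorm(n, sim$subgroup$bw, sim$subgroup$bw * sim$bw_cv)
      while (any(bad <- b <= 0))
        b[bad] <- stats::rnorm(sum(bad), sim$subgroup$bw,
                               sim$subgroup$bw * sim$bw_cv)
      b
    } else sim$subgroup$bw
    total / bw
  })
  sim
}

#' Percentile report of exposure against a reference dose
#'
#' Empirical quantiles (linear interpolation between order statistics,
#' `stats::quantile` type 7) of the exposure sample, each expressed as a
#' percentage of the toxicological reference dose.
#'
#' @param samples Exposure samples, mg/kg bw/day (non-empty), or a run
#'   [exposure_simulation()].
#' @param reference ADI (chronic) or ARfD (acute), mg/kg bw (> 0).
#' @param levels Percentile levels in (0, 100].
#' @param subgroup,compound Labels carried into the report.
#' @return An object of class `"percentile_report"`: a data frame with
#'   columns `subgroup`, `compound`, `percentile` (labels "P50", ...,
#'   "P99.9") and `percent_of_reference`, non-decreasing in level.
#' @export
percentile_report <- function(samples, reference,
                              levels = c(50, 75, 90, 95, 97.5, 99, 99.9),
                              subgroup = "", compound = "") {
  if (inherits(samples, "exposure_simulation")) {
    if (is.null(samples$samples))
      stop_field("samples", "simulation has not been run")
    if (identical(subgroup, "")) subgroup <- samples$subgroup$name
    samples <- samples$samples
  }
  if (!is.numeric(samples) || length(samples) == 0L)
    stop_field("samples", "must be a non-empty numeric vector")
  check_scalar_num(reference, "reference", positive = TRUE)
  if (any(levels <= 0 | levels > 100))
    stop_field("levels", "percentiles must be in (0, 100]")
  levels <- sort(levels)
  q <- stats::quantile(samples, probs = levels / 100, names = FALSE, type = 7)
  out <- data.frame(
    subgroup = subgroup, compound = compound,
    percentile = paste0("P", formatC(levels, format = "g")),
    percent_of_reference = 100 * q / reference
  )
  class(out) <- c("percentile_report", "data.frame")
  out
}

#' Stratified probabilistic risk across subgroups and compounds
#'
#' Fits lognormal distributions per subgroup (consumption) and per compound
#' (residues), runs one Monte-Carlo exposure simulation per subgroup x
#' compound, and reports percentile risk against the ARfD (`mode = "acute"`)
#' or ADI (`mode = "chronic"`). A subgroup with missing data is recorded as
#' an error entry and the run continues.
#'
#' @param subgroups List of [population_subgroup()] objects.
#' @param residue_data Data frame: `compound`, `residue_mg_per_kg`,
#'   `censored` (0/1), one row per field observation.
#' @param consumption_data Data frame: `subgroup`, `intake_kg_per_day`,
#'   `bw_kg`, one row per surveyed individual.
#' @param toxicology List of [toxicology_reference()] objects or an
#'   equivalent data frame.
#' @param mode `"acute"` or `"chronic"`.
#' @param n_iter Monte-Carlo iterations per simulation (default 1000; note
#'   that extreme percentiles such as P99.9 are noisy at this size).
#' @param seed Base seed; each subgroup x compound gets a distinct stream.
#' @param levels Percentile levels.
#' @param censor_policy Policy for <LOQ residues passed to [fit_lognormal()].
#' @param loq LOQ used by the censoring policy.
#' @return A list with `reports` (one `"percentile_report"` per successful
#'   combination) and `errors` (named character vector of failures).
#' @export
stratified_run <- function(subgroups, residue_data, consumption_data,
                           toxicology, mode = c("chronic", "acute"),
                           n_iter = 1000L, seed = NULL,
                           levels = c(50, 75, 90, 95, 97.5, 99, 99.9),
                           censor_policy = "half_loq", loq = 0.05) {
  mode <- match.arg(mode)
  if (is.data.frame(toxicology))
    toxicology <- lapply(seq_len(nrow(toxicology)), function(i)
      toxicology_reference(toxicology$compound[i], toxicology$adi[i],
                           toxicology$arfd[i]))
  tox_by <- stats::setNames(toxicology,
                            vapply(toxicology, `[[`, character(1), "compound"))
  reports <- list()
  errors <- character(0)
  combo <- 0L
  for (sg in subgroups) {
    for (cmp in unique(residue_data$compound)) {
      combo <- combo + 1L
      key <- paste(sg$name, cmp, sep = " x ")
      res <- try({
        cons <- consumption_data[consumption_data$subgroup == sg$name, ]
        if (nrow(cons) == 0L)
          stop(sprintf("no consumption data for subgroup '%s'", sg$name))
        resid <- residue_data[residue_data$compound == cmp, ]
        tox <- tox_by[[cmp]]
        if (is.null(tox))
          stop(sprintf("no toxicology reference for '%s'", cmp))
        cd <- fit_lognormal(cons$intake_kg_per_day)
        rd <- fit_lognormal(resid$residue_mg_per_kg,
                            censored = as.logical(resid$censored),
                            censor_policy = censor_policy, loq = loq)
        sim_seed <- if (is.null(seed)) NULL else (seed + combo) %% 2147483647
        sim <- simulate_exposure(exposure_simulation(
          sg, cd, rd, n_iter = n_iter, seed = sim_seed))
        ref <- if (mode == "acute") tox$arfd else tox$adi
        percentile_report(sim, ref, levels = levels, compound = cmp)
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        errors[key] <- conditionMessage(attr(res, "condition"))
      else reports[[key]] <- res
    }
  }
  list(reports = reports, errors = errors, mode = mode)
}
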