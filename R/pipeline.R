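#' Load a pipeline run configuration
#'
#' Reads a flat YAML file describing one end-to-end run: input table paths
#' (resolved relative to the config file), the censoring policy, the residue
#' variability factor, Monte-Carlo settings and the output directory. All
#' referenced input files must exist at load time.
#'
#' @param path Path to a YAML config file with keys `calibration`,
#'   `recovery`, `decay`, `residue`, `residue_summary`, `consumption`,
#'   `subgroups`, `toxicology` (CSV paths), `censor_policy`,
#'   `variability_factor`, `n_iter`, `seed`, `percentile_levels`,
#'   `output_dir`, `loq`.
#' @param output_dir Optional override of the config's `output_dir`, useful
#'   when the config ships inside an installed package.
#' @param seed Optional override of the config's seed.
#' @return An object of class `"run_config"`.
#' @export
load_run_config <- function(path, output_dir = NULL, seed = NULL) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }
  cfg <- list(
    calibration = resolve(raw$calibration),
    recovery = resolve(raw$recovery),
    decay = resolve(raw$decay),
    residue = resolve(raw$residue),
    residue_summary = resolve(raw$residue_summary),
    consumption = resolve(raw$consumption),
    subgroups = resolve(raw$subgroups),
    toxicology = resolve(raw$toxicology),
    censor_policy = if (is.null(raw$censor_policy)) "half_loq"
                    else raw$censor_policy,
    variability_factor = if (is.null(raw$variability_factor)) 3
                         else raw$variability_factor,
    n_iter = if (is.null(raw$n_iter)) 1000L else as.integer(raw$n_iter),
    seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
    percentile_levels = if (is.null(raw$percentile_levels))
      c(50, 75, 90, 95, 97.5, 99, 99.9) else as.numeric(raw$percentile_levels),
    loq = if (is.null(raw$loq)) 0.05 else as.numeric(raw$loq),
    output_dir = if (is.null(raw$output_dir)) "." else resolve(raw$output_dir),
    config_hash = fnv1a32(readLines(path, warn = FALSE))
  )
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  needed <- c("calibration", "recovery", "decay", "residue",
              "residue_summary", "consumption", "subgroups", "toxicology")
  for (key in needed) {
    if (is.null(cfg[[key]]))
      stop(sprintf("config key '%s' is required", key), call. = FALSE)
    if (!file.exists(cfg[[key]]))
      stop(sprintf("config key '%s': input file not found: %s",
                   key, cfg[[key]]), call. = FALSE)
  }
  if (!cfg$censor_policy %in% c("half_loq", "drop", "loq"))
    stop_field("censor_policy", "must be half_loq, drop or loq")
  structure(cfg, class = "run_config")
}

#' Run the full residue-to-risk pipeline
#'
#' Executes the four analysis stages in order — method validation,
#' dissipation kinetics, deterministic risk, probabilistic risk — writing one
#' provenance-stamped CSV per stage plus a combined summary into
#' `config$output_dir`. The run is deterministic for a fixed seed: repeating
#' it produces byte-identical outputs. If a stage fails, the outputs of
#' earlier stages are retained on disk and the error is re-raised with the
#' stage named.
#'
#' @param config A `"run_config"` from [load_run_config()].
#' @return Invisibly, a named list of the output file paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_field("config", "must be a `run_config`")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- list()
  emit <- function(df, name) {
    p <- file.path(config$output_dir, paste0(name, ".csv"))
    write_table(df, p, seed = if (is.null(config$seed)) NA else config$seed,
                config_hash = config$config_hash)
    outs[[name]] <<- p
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## 1. method validation: calibration fits, matrix effect, recovery, LOQ
  validation <- stage("validation", {
    cal <- load_table(config$calibration, "calibration")
    rec <- load_table(config$recovery, "recovery")
    rows <- list()
    for (cmp in unique(cal$compound)) {
      curves <- lapply(c("solvent", "matrix"), function(med) {
        sub <- cal[cal$compound == cmp & cal$medium == med, ]
        if (nrow(sub) == 0L) return(NULL)
        fit_calibration(sub$level_mg_per_L, sub$response, cmp, med)
      })
      names(curves) <- c("solvent", "matrix")
      me <- if (!is.null(curves$solvent) && !is.null(curves$matrix))
        matrix_effect(curves$matrix, curves$solvent) else NULL
      recs <- lapply(sort(unique(rec$spike_mg_per_kg[rec$compound == cmp])),
        function(lvl) {
          sub <- rec[rec$compound == cmp & rec$spike_mg_per_kg == lvl, ]
          compute_recovery(sub$measured_mg_per_kg, lvl, cmp)
        })
      loq_res <- if (length(recs)) screen_loq(recs) else
        list(loq = NA_real_, established = FALSE)
      for (r in recs)
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cmp, metric = "recovery",
          spike_mg_per_kg = r$spike_level,
          value = r$mean_recovery, rsd = r$rsd, n = r$n)
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp, metric = "matrix_effect_percent",
        spike_mg_per_kg = NA_real_,
        value = if (is.null(me)) NA_real_ else me$me_percent,
        rsd = NA_real_, n = NA_integer_)
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp, metric = "loq_mg_per_kg",
        spike_mg_per_kg = NA_real_, value = loq_res$loq,
        rsd = NA_real_, n = NA_integer_)
    }
    do.call(rbind, rows)
  })
  emit(validation, "validation")

  ## 2. dissipation kinetics per compound x site
  dissipation <- stage("dissipation", {
    decay <- load_table(config$decay, "decay")
    rows <- list()
    for (cmp in unique(decay$compound)) {
      for (site in unique(decay$site[decay$compound == cmp])) {
        sub <- decay[decay$compound == cmp & decay$site == site, ]
        sub <- sub[order(sub$day), ]
        ser <- dissipation_series(cmp, site, sub$day, sub$residue_mg_per_kg,
                                  as.logical(sub$censored), config$loq)
        fit <- fit_first_order(ser, censor_policy = config$censor_policy)
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cmp, site = site, c0_hat = fit$c0_hat,
          k_hat_per_day = fit$k_hat, half_life_days = fit$half_life,
          r_squared = fit$r_squared, n_used = fit$n_used)
      }
    }
    do.call(rbind, rows)
  })
  emit(dissipation, "dissipation")

  ## 3. deterministic acute + chronic risk
  deterministic <- stage("deterministic_risk", {
    sg_tab <- load_table(config$subgroups, "subgroups")
    subgroups <- lapply(seq_len(nrow(sg_tab)), function(i)
      population_subgroup(sg_tab$name[i], sg_tab$bw_kg[i],
                          sg_tab$lp_kg_per_day[i], sg_tab$fi_kg_per_day[i],
                          sg_tab$v[i]))
    residues <- load_table(config$residue_summary, "residue_summary")
    tox <- load_table(config$toxicology, "toxicology")
    deterministic_risk_table(subgroups, residues, tox)
  })
  emit(deterministic, "deterministic_risk")

  ## 4. probabilistic (Monte-Carlo) risk, chronic and acute
  probabilistic <- stage("probabilistic_risk", {
    sg_tab <- load_table(config$subgroups, "subgroups")
    subgroups <- lapply(seq_len(nrow(sg_tab)), function(i)
      population_subgroup(sg_tab$name[i], sg_tab$bw_kg[i],
                          sg_tab$lp_kg_per_day[i], sg_tab$fi_kg_per_day[i],
                          sg_tab$v[i]))
    residue <- load_table(config$residue, "residue")
    consumption <- load_table(config$consumption, "consumption")
    tox <- load_table(config$toxicology, "toxicology")
    rows <- list()
    for (mode in c("chronic", "acute")) {
      run <- stratified_run(subgroups, residue, consumption, tox, mode,
                            n_iter = config$n_iter, seed = config$seed,
                            levels = config$percentile_levels,
                            censor_policy = config$censor_policy,
                            loq = config$loq)
      if (length(run$errors))
        warning(sprintf("probabilistic %s: %d combination(s) failed: %s",
                        mode, length(run$errors),
                        paste(names(run$errors), collapse = "; ")),
                call. = FALSE)
      for (report in run$reports) {
        report$mode <- mode
        rows[[length(rows) + 1L]] <- as.data.frame(report)
      }
    }
    df <- do.call(rbind, rows)
    df[, c("subgroup", "compound", "mode", "percentile",
           "percent_of_reference")]
  })
  emit(probabilistic, "probabilistic_risk")

  ## 5. combined summary: one row per compound x subgroup
  summary_tab <- stage("summary", {
    p50 <- probabilistic[probabilistic$percentile == "P50" &
                           probabilistic$mode == "chronic", ]
    merged <- merge(deterministic,
                    p50[, c("subgroup", "compound", "percent_of_reference")],
                    by = c("subgroup", "compound"), all.x = TRUE)
    names(merged)[names(merged) == "percent_of_reference"] <-
      "probabilistic_chronic_p50"
    merged[order(merged$compound, merged$subgroup), ]
  })
  emit(summary_tab, "summary")

  invisible(outs)
}
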