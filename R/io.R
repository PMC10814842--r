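# CSV readers/writers for the pipeline's table schemas. Units are encoded in
# the column names so mismatched units fail loudly at load time.

table_schemas <- list(
  calibration = list(
    cols = c("compound", "medium", "level_mg_per_L", "response"),
    numeric = c("level_mg_per_L", "response"),
    nonneg = "level_mg_per_L"),
  recovery = list(
    cols = c("compound", "spike_mg_per_kg", "replicate", "measured_mg_per_kg"),
    numeric = c("spike_mg_per_kg", "replicate", "measured_mg_per_kg"),
    nonneg = c("spike_mg_per_kg", "measured_mg_per_kg")),
  decay = list(
    cols = c("compound", "site", "day", "residue_mg_per_kg", "censored"),
    numeric = c("day", "residue_mg_per_kg", "censored"),
    nonneg = c("day", "residue_mg_per_kg")),
  consumption = list(
    cols = c("subgroup", "intake_kg_per_day", "bw_kg"),
    numeric = c("intake_kg_per_day", "bw_kg"),
    nonneg = c("intake_kg_per_day", "bw_kg")),
  residue = list(
    cols = c("compound", "residue_mg_per_kg", "censored"),
    numeric = c("residue_mg_per_kg", "censored"),
    nonneg = "residue_mg_per_kg"),
  residue_summary = list(
    cols = c("compound", "hr_mg_per_kg", "stmr_mg_per_kg"),
    numeric = c("hr_mg_per_kg", "stmr_mg_per_kg"),
    nonneg = c("hr_mg_per_kg", "stmr_mg_per_kg")),
  subgroups = list(
    cols = c("name", "bw_kg", "lp_kg_per_day", "fi_kg_per_day", "v"),
    numeric = c("bw_kg", "lp_kg_per_day", "fi_kg_per_day", "v"),
    nonneg = c("bw_kg", "lp_kg_per_day", "fi_kg_per_day")),
  toxicology = list(
    cols = c("compound", "adi", "arfd"),
    numeric = c("adi", "arfd"),
    nonneg = c("adi", "arfd"))
)

#' Load and validate a pipeline CSV table
#'
#' Reads a CSV (lines starting with `#` are provenance comments and are
#' skipped) and checks it against the named schema: required columns must be
#' present, numeric columns numeric, and concentration-like columns
#' non-negative. Violations raise an error naming the row and column.
#'
#' @param path Path to the CSV file.
#' @param schema_name One of `"calibration"`, `"recovery"`, `"decay"`,
#'   `"consumption"`, `"residue"`, `"residue_summary"`, `"subgroups"`,
#'   `"toxicology"`.
#' @return A validated data frame.
#' @export
load_table <- function(path, schema_name) {
  schema <- table_schemas[[schema_name]]
  if (is.null(schema))
    stop_field("schema_name",
               paste("must be one of:",
                     paste(names(table_schemas), collapse = ", ")))
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot read %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L)
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  missing <- setdiff(schema$cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in schema$numeric) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("%s: column '%s' row %d: non-numeric value '%s'",
                   path, col, bad, v[bad]), call. = FALSE)
    }
    if (anyNA(v))
      stop(sprintf("%s: column '%s' row %d: missing value",
                   path, col, which(is.na(v))[1]), call. = FALSE)
  }
  for (col in schema$nonneg) {
    bad <- which(df[[col]] < 0)
    if (length(bad))
      stop(sprintf("%s: column '%s' row %d: negative value %g",
                   path, col, bad[1], df[[col]][bad[1]]), call. = FALSE)
  }
  df
}

#' Write a pipeline CSV table with provenance header
#'
#' Writes `#`-prefixed provenance lines (tool version, seed, config hash)
#' followed by the CSV body. Numeric columns are written with 17 significant
#' digits so a [load_table()] round trip preserves doubles exactly.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header (may be `NA`).
#' @param config_hash Config fingerprint recorded in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, seed = NA, config_hash = "") {
  header <- c(
    sprintf("# resrisk %s",
            as.character(utils::packageVersion("resrisk"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", config_hash))
  out <- df
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
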