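#' A consumer population subgroup
#'
#' @param name Subgroup label (e.g. "children").
#' @param bw Mean bodyweight, kg (> 0).
#' @param lp Large portion, kg/day: the 97.5th-percentile single-day
#'   consumption of the commodity.
#' @param fi Mean daily intake of the commodity, kg/day.
#' @param variability_factor Unit-to-unit residue variability multiplier v
#'   (default 3, the value used for medium-sized fruit such as grapes).
#' @return An object of class `"population_subgroup"`.
#' @export
population_subgroup <- function(name, bw, lp = 0, fi = 0,
                                variability_factor = 3) {
  check_scalar_num(bw, "bw", positive = TRUE)
  check_scalar_num(lp, "lp", nonneg = TRUE)
  check_scalar_num(fi, "fi", nonneg = TRUE)
  check_scalar_num(variability_factor, "variability_factor", min = 1)
  structure(
    list(name = as.character(name), bw = bw, lp = lp, fi = fi,
         variability_factor = variability_factor),
    class = "population_subgroup"
  )
}

#' Toxicological reference doses for a compound
#'
#' @param compound Identifier.
#' @param adi Acceptable daily intake, mg/kg bw/day (> 0).
#' @param arfd Acute reference dose, mg/kg bw (> 0).
#' @return An object of class `"toxicology_reference"`.
#' @export
toxicology_reference <- function(compound, adi, arfd) {
  check_scalar_num(adi, "adi", positive = TRUE)
  check_scalar_num(arfd, "arfd", positive = TRUE)
  structure(list(compound = as.character(compound), adi = adi, arfd = arfd),
            class = "toxicology_reference")
}

#' Total residue of a parent compound plus its monitored metabolite
#'
#' Residue definitions for risk assessment often express the metabolite in
#' parent-equivalents; the default `conversion_factor = 1` is a plain
#' concentration sum, and a molecular-weight ratio can be supplied instead.
#' Censored inputs should be substituted before calling (see
#' [apply_censor_policy()] semantics in [fit_first_order()]).
#'
#' @param parent Parent residue, mg/kg (>= 0).
#' @param metabolite Metabolite residue, mg/kg (>= 0).
#' @param conversion_factor Multiplier applied to the metabolite (> 0).
#' @return Total residue, mg/kg.
#' @examples
#' total_residue(0.31, 0.47)  # 0.78
#' @export
total_residue <- function(parent, metabolite, conversion_factor = 1) {
  check_scalar_num(parent, "parent", nonneg = TRUE)
  check_scalar_num(metabolite, "metabolite", nonneg = TRUE)
  check_scalar_num(conversion_factor, "conversion_factor", positive = TRUE)
  parent + conversion_factor * metabolite
}

#' National estimated short-term intake (NESTI)
#'
#' NESTI = LP x HR x v / bw: the large-portion consumption times the highest
#' residue, inflated by the unit-to-unit variability factor, per kilogram
#' bodyweight.
#'
#' @param subgroup A [population_subgroup()] (its `lp`, `bw` and
#'   `variability_factor` are used).
#' @param hr Highest residue from supervised trials, mg/kg (>= 0).
#' @return Acute intake estimate, mg/kg bw.
#' @export
nesti <- function(subgroup, hr) {
  if (!inherits(subgroup, "population_subgroup"))
    stop_field("subgroup", "must be a `population_subgroup`")
  check_scalar_num(hr, "hr", nonneg = TRUE)
  subgroup$lp * hr * subgroup$variability_factor / subgroup$bw
}

#' Acute risk as a percentage of the acute reference dose
#'
#' @param nesti Acute intake estimate, mg/kg bw.
#' @param arfd Acute reference dose, mg/kg bw (> 0).
#' @return A list with `percent` (100 x NESTI/ARfD) and `acceptable`
#'   (`FALSE` strictly above 100%).
#' @export
percent_arfd <- function(nesti, arfd) {
  check_scalar_num(nesti, "nesti", nonneg = TRUE)
  check_scalar_num(arfd, "arfd", positive = TRUE)
  p <- 100 * nesti / arfd
  list(percent = p, acceptable = p <= 100)
}

#' Estimated daily intake (EDI) over the registered foods
#'
#' EDI = sum(STMR_i x F_i) / bw. In a single-commodity assessment the sum has
#' one term.
#'
#' @param stmr Supervised-trials median residues, mg/kg, one per food.
#' @param fi Mean daily intakes, kg/day, one per food.
#' @param bw Bodyweight, kg (> 0).
#' @return Chronic intake estimate, mg/kg bw/day.
#' @export
edi <- function(stmr, fi, bw) {
  check_scalar_num(bw, "bw", positive = TRUE)
  if (length(stmr) != length(fi))
    stop_field("stmr/fi", "must have one intake per residue value")
  if (any(!is.finite(stmr)) || any(stmr < 0))
    stop_field("stmr", "must be finite and >= 0")
  if (any(!is.finite(fi)) || any(fi < 0))
    stop_field("fi", "must be finite and >= 0")
  sum(stmr * fi) / bw
}

#' Chronic risk quotient as a percentage of the ADI
#'
#' @param edi Chronic intake estimate, mg/kg bw/day.
#' @param adi Acceptable daily intake, mg/kg bw/day (> 0).
#' @return A list with `percent` (100 x EDI/ADI) and `acceptable`
#'   (`FALSE` strictly above 100%).
#' @export
risk_quotient <- function(edi, adi) {
  check_scalar_num(edi, "edi", nonneg = TRUE)
  check_scalar_num(adi, "adi", positive = TRUE)
  p <- 100 * edi / adi
  list(percent = p, acceptable = p <= 100)
}

#' Deterministic acute and chronic risk table
#'
#' Convenience wrapper: computes NESTI, %ARfD, EDI and %ADI for every
#' subgroup x compound combination.
#'
#' @param subgroups List of [population_subgroup()] objects.
#' @param residues Data frame with columns `compound`, `hr_mg_per_kg`,
#'   `stmr_mg_per_kg`.
#' @param toxicology List of [toxicology_reference()] objects (or a data
#'   frame with columns `compound`, `adi`, `arfd`).
#' @return Data frame: `compound`, `subgroup`, `nesti`, `percent_arfd`,
#'   `edi`, `percent_adi`, `acceptable` (0/1, both endpoints <= 100%).
#' @export
deterministic_risk_table <- function(subgroups, residues, toxicology) {
  if (is.data.frame(toxicology))
    toxicology <- lapply(seq_len(nrow(toxicology)), function(i)
      toxicology_reference(toxicology$compound[i], toxicology$adi[i],
                           toxicology$arfd[i]))
  tox_by <- stats::setNames(toxicology,
                            vapply(toxicology, `[[`, character(1), "compound"))
  rows <- list()
  for (i in seq_len(nrow(residues))) {
    cmp <- residues$compound[i]
    tox <- tox_by[[cmp]]
    if (is.null(tox))
      stop(sprintf("no toxicology reference for compound '%s'", cmp),
           call. = FALSE)
    for (sg in subgroups) {
      ne <- nesti(sg, residues$hr_mg_per_kg[i])
      ac <- percent_arfd(ne, tox$arfd)
      ed <- edi(residues$stmr_mg_per_kg[i], sg$fi, sg$bw)
      ch <- risk_quotient(ed, tox$adi)
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp, subgroup = sg$name,
        nesti = ne, percent_arfd = ac$percent,
        edi = ed, percent_adi = ch$percent,
        acceptable = as.integer(ac$acceptable && ch$acceptable))
    }
  }
  do.call(rbind, rows)
}
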