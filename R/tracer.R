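# Processing of IC-MS isotopologue tables: calibration-curve quantitation,
# labeling fractions, natural-isotope correction against a U-12C6 control,
# pathway-level labeled totals, the heatmap transform and product/substrate
# ratios. Tables are long data frames with columns metabolite, pathway,
# condition, tracer, mass_shift, amount; amount units are carried opaquely
# (all operations are ratios and sums).

tracer_rows <- function(table, metabolite = NULL, condition = NULL,
                        tracer = NULL, pathway = NULL) {
  sel <- rep(TRUE, nrow(table))
  if (!is.null(metabolite)) sel <- sel & table$metabolite == metabolite
  if (!is.null(condition)) sel <- sel & table$condition == condition
  if (!is.null(tracer)) sel <- sel & table$tracer == tracer
  if (!is.null(pathway)) sel <- sel & table$pathway == pathway
  table[sel, , drop = FALSE]
}

#' Quantify a metabolite amount from a calibration line
#'
#' Inverts the linear calibration `peak_area = slope * amount + intercept`;
#' amounts below zero are floored at zero.
#'
#' @param peak_area Measured peak area (vectorized).
#' @param calibration_line List with `slope` (non-zero) and `intercept`.
#' @return Amount, floored at 0.
#' @export
quantify_from_calibration <- function(peak_area, calibration_line) {
  s <- calibration_line$slope
  if (is.null(s) || !is.finite(s) || s == 0)
    stopf("invalid calibration: slope must be non-zero")
  pmax((peak_area - (calibration_line$intercept %||% 0)) / s, 0)
}

#' Labeling fractions of one metabolite
#'
#' Normalizes the amounts of all mass shifts of a metabolite (one condition,
#' one tracer) to sum 1.
#'
#' @param table Isotopologue table.
#' @param metabolite,condition Row selectors.
#' @param tracer Tracer label (default `"U13C6"`).
#' @return Named fraction vector (`M+0` ... `M+C`).
#' @export
labeling_fractions <- function(table, metabolite, condition = NULL,
                               tracer = "U13C6") {
  rows <- tracer_rows(table, metabolite, condition, tracer)
  if (nrow(rows) == 0L) stopf("no rows for metabolite '%s'", metabolite)
  rows <- rows[order(rows$mass_shift), , drop = FALSE]
  total <- sum(rows$amount)
  if (!is.finite(total) || total <= 0)
    stopf("undefined fractions: total amount of '%s' is 0", metabolite)
  stats::setNames(rows$amount / total, paste0("M+", rows$mass_shift))
}

#' Labeling rate of one metabolite
#'
#' Fraction of the pool carrying at least one tracer carbon:
#' `1 - fraction(M+0)`.
#'
#' @inheritParams labeling_fractions
#' @return Scalar in \[0, 1\].
#' @export
labeling_rate <- function(table, metabolite, condition = NULL,
                          tracer = "U13C6") {
  f <- labeling_fractions(table, metabolite, condition, tracer)
  unname(1 - f["M+0"])
}

#' Natural-isotope correction of a labeled amount
#'
#' Subtracts the amount of the same isotopologue observed in the matched
#' U-12C6 control from the U-13C6 amount; negative results are modeled as
#' zero.
#'
#' @param amount_13C,amount_12C_control Non-negative amounts at the same
#'   mass shift (vectorized).
#' @return `max(amount_13C - amount_12C_control, 0)`.
#' @export
natural_isotope_correct <- function(amount_13C, amount_12C_control) {
  if (any(amount_13C < 0, na.rm = TRUE) ||
      any(amount_12C_control < 0, na.rm = TRUE))
    stopf("amounts must be >= 0")
  pmax(amount_13C - amount_12C_control, 0)
}

#' Apply the natural-isotope correction to a whole table
#'
#' For every labeled isotopologue (mass shift >= 1) of the U-13C6 rows, the
#' amount of the matched U-12C6 control row (same metabolite, mass shift and
#' condition) is subtracted with a zero floor. M+0 rows are kept as
#' measured. Both raw and corrected tables are legitimate inputs for the
#' pathway summaries.
#'
#' @param table Isotopologue table containing both tracers.
#' @param flags Optional data frame of (`metabolite`, `mass_shift`,
#'   `condition`) rows, as returned by [flag_high_natural_isotope()]; when
#'   given, only these isotopologues are corrected (the selective mode in
#'   which the correction is meant to be used), otherwise every labeled
#'   isotopologue is.
#' @return The U-13C6 rows with corrected amounts.
#' @export
correct_table_natural <- function(table, flags = NULL) {
  lab <- table[table$tracer == "U13C6", , drop = FALSE]
  ctl <- table[table$tracer == "U12C6", , drop = FALSE]
  if (nrow(ctl) == 0L)
    stopf("no U-12C6 control rows in table")
  key <- function(d) paste(d$metabolite, d$condition, d$mass_shift)
  ctl_amount <- stats::setNames(ctl$amount, key(ctl))
  m <- ctl_amount[key(lab)]
  m[is.na(m)] <- 0
  shift <- lab$mass_shift >= 1L
  if (!is.null(flags))
    shift <- shift & key(lab) %in% key(flags)
  lab$amount[shift] <- natural_isotope_correct(lab$amount[shift], m[shift])
  lab
}

#' Flag isotopologues with non-negligible natural-isotope signal
#'
#' Returns the (metabolite, mass shift) pairs whose U-12C6-control amount
#' exceeds `threshold` times the U-13C6 amount — isotopologues whose
#' apparent labeling would be overestimated without correction.
#'
#' @param table Isotopologue table containing both tracers.
#' @param threshold Fraction (default 0.05, i.e. 5 percent).
#' @param condition Optional condition selector.
#' @return Data frame with columns `metabolite`, `mass_shift`, `condition`.
#' @export
flag_high_natural_isotope <- function(table, threshold = 0.05,
                                      condition = NULL) {
  tab <- tracer_rows(table, condition = condition)
  lab <- tab[tab$tracer == "U13C6" & tab$mass_shift >= 1L, , drop = FALSE]
  ctl <- tab[tab$tracer == "U12C6", , drop = FALSE]
  if (nrow(ctl) == 0L)
    stopf("missing U-12C6 control condition")
  key <- function(d) paste(d$metabolite, d$condition, d$mass_shift)
  ctl_amount <- stats::setNames(ctl$amount, key(ctl))
  m <- ctl_amount[key(lab)]
  m[is.na(m)] <- 0
  hit <- m > threshold * lab$amount & m > 0
  out <- lab[hit, c("metabolite", "mass_shift", "condition"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total labeled amount of a pathway
#'
#' Sums, over every metabolite assigned to the pathway, the amounts of all
#' isotopologues other than M+0.
#'
#' @param table Isotopologue table (raw or natural-isotope corrected).
#' @param pathway Pathway label (e.g. `"glycolysis"`, `"TCA"`, `"PPP"`,
#'   `"NAS"`).
#' @param condition Optional condition selector.
#' @param tracer Tracer label (default `"U13C6"`).
#' @return Total labeled amount.
#' @export
pathway_total_labeled <- function(table, pathway, condition = NULL,
                                  tracer = "U13C6") {
  if (!pathway %in% table$pathway)
    stopf("unknown pathway '%s'", pathway)
  rows <- tracer_rows(table, condition = condition, tracer = tracer,
                      pathway = pathway)
  sum(rows$amount[rows$mass_shift >= 1L])
}

#' Share of glycolytic metabolites among all labeled metabolites
#'
#' The quantity used to scale the stressed-condition lactate efflux:
#' labeled glycolytic amount divided by total labeled amount over all
#' pathways.
#'
#' @inheritParams pathway_total_labeled
#' @return Fraction in \[0, 1\].
#' @export
labeled_glycolytic_share <- function(table, condition = NULL,
                                     tracer = "U13C6") {
  rows <- tracer_rows(table, condition = condition, tracer = tracer)
  total <- sum(rows$amount[rows$mass_shift >= 1L])
  if (total <= 0) stopf("no labeled amounts in table")
  pathway_total_labeled(table, "glycolysis", condition, tracer) / total
}

#' Heatmap matrix of labeling rates
#'
#' Labeling rate (fraction labeled, mass shift >= 1) per metabolite and
#' condition, plus a pseudo-count of 1 so fully unlabeled metabolites map to
#' 1 and fully labeled to 2 (log-friendly display scale).
#'
#' @param table Isotopologue table.
#' @param tracer Tracer label.
#' @return Matrix metabolites x conditions with entries in \[1, 2\].
#' @export
heatmap_labeling_matrix <- function(table, tracer = "U13C6") {
  tab <- tracer_rows(table, tracer = tracer)
  mets <- unique(tab$metabolite)
  conds <- unique(tab$condition)
  out <- matrix(NA_real_, length(mets), length(conds),
                dimnames = list(mets, conds))
  for (m in mets) for (cc in conds) {
    f <- labeling_fractions(tab, m, cc, tracer)
    out[m, cc] <- 1 + unname(1 - f["M+0"])
  }
  out
}

#' Labeled product/substrate ratio
#'
#' Ratio of total labeled product amount to total labeled substrate amount —
#' e.g. fructose 1,6-bisphosphate over fructose 6-phosphate as a readout of
#' phosphofructokinase engagement.
#'
#' @param table Isotopologue table.
#' @param product,substrate Metabolite names.
#' @param condition Optional condition selector.
#' @param tracer Tracer label.
#' @return Ratio (> 0).
#' @export
product_substrate_ratio <- function(table, product, substrate,
                                    condition = NULL, tracer = "U13C6") {
  labeled_total <- function(met) {
    rows <- tracer_rows(table, met, condition, tracer)
    sum(rows$amount[rows$mass_shift >= 1L])
  }
  denom <- labeled_total(substrate)
  if (denom <= 0)
    stopf("undefined ratio: no labeled substrate '%s'", substrate)
  labeled_total(product) / denom
}

#' Extract MDVs from an isotopologue table for flux fitting
#'
#' @param table Isotopologue table.
#' @param metabolites Metabolites to extract (default: all in the table).
#' @param condition,tracer Row selectors.
#' @return Named list of fraction vectors, as [fit_fluxes()] expects.
#' @export
mdvs_from_table <- function(table, metabolites = NULL, condition = NULL,
                            tracer = "U13C6") {
  metabolites <- metabolites %||% unique(table$metabolite)
  stats::setNames(lapply(metabolites, function(m)
    unname(labeling_fractions(table, m, condition, tracer))), metabolites)
}
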