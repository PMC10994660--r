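# Metabolic network with carbon-atom transitions.
#
# A flux_model holds metabolites (with carbon counts and a role: internal or
# input), reactions with one or more atom maps (equal- or stated-weight
# alternatives encode molecular symmetry, e.g. succinate/fumarate), boundary
# constraints and fitting metadata. Atom maps are written in the compact
# transition notation "OAA[abcd] + AcCoA[ef] -> CIT[dcbfea]": each letter
# names one carbon and must appear exactly once on each side; an empty
# right-hand side denotes an efflux (sink).

parse_side <- function(s) {
  s <- trimws(s)
  if (s == "") return(list())
  parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([A-Za-z0-9_]+)\\[([a-z]*)\\]$", p))[[1L]]
    if (length(m) != 3L)
      stopf("cannot parse species term '%s' (expected Name[letters])", p)
    list(met = m[2L], carbons = strsplit(m[3L], "")[[1L]])
  })
}

parse_atom_map <- function(equation) {
  sides <- strsplit(equation, "->", fixed = TRUE)[[1L]]
  if (length(sides) < 1L || length(sides) > 2L)
    stopf("atom map '%s' must contain exactly one '->'", equation)
  list(subs = parse_side(sides[1L]),
       prods = if (length(sides) == 2L) parse_side(sides[2L]) else list())
}

validate_map <- function(map, carbons, rxn, equation) {
  lhs <- unlist(lapply(map$subs, `[[`, "carbons"))
  rhs <- unlist(lapply(map$prods, `[[`, "carbons"))
  for (term in c(map$subs, map$prods)) {
    if (!term$met %in% names(carbons))
      stopf("reaction '%s': unknown metabolite '%s'", rxn, term$met)
    if (length(term$carbons) != carbons[[term$met]])
      stopf("reaction '%s': '%s' written with %d carbons but declared with %d",
            rxn, term$met, length(term$carbons), carbons[[term$met]])
  }
  if (anyDuplicated(lhs) || anyDuplicated(rhs))
    stopf("reaction '%s': atom '%s' mapped more than once in '%s'",
          rxn, c(lhs[duplicated(lhs)], rhs[duplicated(rhs)])[1L], equation)
  if (length(map$prods) > 0L && !setequal(lhs, rhs))
    stopf("reaction '%s': unmapped atom(s) '%s' in '%s'", rxn,
          paste(c(setdiff(lhs, rhs), setdiff(rhs, lhs)), collapse = ","),
          equation)
  invisible(map)
}

#' Build a flux model from a network description
#'
#' Reads a structured network file (YAML or JSON) or an equivalent list and
#' returns a validated `flux_model`. Every carbon atom of every reaction must
#' be mapped exactly once from substrates to products; violations raise an
#' error naming the atom. Reactions may carry several atom maps with weights
#' (summing to 1) to represent molecular symmetry.
#'
#' @param x Path to a YAML/JSON network file, or a list with the same
#'   structure (`metabolites`, `reactions`, `inputs`, `constraints`, ...).
#' @return A `flux_model` object.
#' @seealso [central_carbon_model()] for the packaged default network.
#' @export
build_network <- function(x) {
  spec <- if (is.character(x)) {
    if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = FALSE)
    else yaml::read_yaml(x)
  } else x
  if (is.null(spec$metabolites) || is.null(spec$reactions))
    stopf("network description needs 'metabolites' and 'reactions'")

  met_names <- names(spec$metabolites)
  carbons <- vapply(spec$metabolites, function(m) as.integer(m$carbons), 1L)
  names(carbons) <- met_names
  role <- vapply(spec$metabolites,
                 function(m) as.character(m$role %||% "internal"), "")
  pathway <- vapply(spec$metabolites,
                    function(m) as.character(m$pathway %||% NA_character_), "")
  names(role) <- names(pathway) <- met_names
  if (any(carbons < 1L)) stopf("all metabolites need >= 1 carbon")

  reactions <- lapply(spec$reactions, function(r) {
    if (is.null(r$name)) stopf("every reaction needs a name")
    eqs <- if (!is.null(r[["equation"]])) {
      list(list(map = r[["equation"]], weight = 1))
    } else if (!is.null(r[["equations"]])) {
      lapply(r[["equations"]], function(e)
        list(map = e$map, weight = as.numeric(e$weight %||% 1)))
    } else stopf("reaction '%s' needs 'equation' or 'equations'", r$name)
    maps <- lapply(eqs, function(e) {
      m <- parse_atom_map(e$map)
      validate_map(m, carbons, r$name, e$map)
      m$weight <- e$weight
      m
    })
    w <- vapply(maps, `[[`, 1, "weight")
    if (abs(sum(w) - 1) > 1e-9)
      stopf("reaction '%s': atom-map weights must sum to 1", r$name)
    list(name = r$name, reversible = isTRUE(r$reversible), maps = maps)
  })
  names(reactions) <- vapply(reactions, `[[`, "", "name")
  if (anyDuplicated(names(reactions)))
    stopf("duplicate reaction names")

  model <- structure(list(
    name = spec$name %||% "network",
    metabolites = data.frame(name = met_names,
                             carbons = unname(carbons),
                             role = unname(role),
                             pathway = unname(pathway),
                             stringsAsFactors = FALSE),
    reactions = reactions,
    inputs = spec$inputs %||% list(),
    constraints = spec$constraints %||% list(),
    fixed_effluxes = spec$fixed_effluxes %||% list(),
    free_fluxes = unlist(spec$free_fluxes) %||% character(),
    measured = unlist(spec$measured) %||% character(),
    glycolysis_chain = unlist(spec$glycolysis_chain) %||% character(),
    cache = new.env(parent = emptyenv())
  ), class = "flux_model")

  # every input metabolite must have a declared labeling source
  inputs <- met_names[role == "input"]
  if (!all(inputs %in% names(model$inputs)))
    stopf("input metabolite(s) without labeling source: %s",
          paste(setdiff(inputs, names(model$inputs)), collapse = ", "))
  model
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf("flux_model '%s': %d metabolites (%d internal), %d reactions, %d dof\n",
              x$name, nrow(x$metabolites),
              sum(x$metabolites$role == "internal"),
              length(x$reactions), model_dof(x)))
  invisible(x)
}

#' The packaged central-carbon network
#'
#' Glycolysis, oxidative/non-oxidative PPP and a single-pool TCA cycle with
#' lactate dehydrogenase, citrate synthase, lumped aconitase + isocitrate
#' dehydrogenase and succinate dehydrogenase, an unlabeled acetyl-CoA inflow
#' representing fatty-acid oxidation, and fixed boundary drains. Glucose
#' uptake is constrained to 100 so that all fluxes are on the
#' uptake-normalized scale.
#'
#' @return A `flux_model`.
#' @export
central_carbon_model <- function() {
  build_network(system.file("extdata", "central_carbon.yaml",
                            package = "hscflux", mustWork = TRUE))
}

internal_mets <- function(model)
  model$metabolites$name[model$metabolites$role == "internal"]

carbon_count <- function(model, met)
  model$metabolites$carbons[match(met, model$metabolites$name)]

#' Stoichiometric matrix over internal metabolites
#'
#' @param model A `flux_model`.
#' @return Matrix (internal metabolites x reactions) of net stoichiometric
#'   coefficients (all species enter with coefficient 1 per atom map).
#' @export
stoich_matrix <- function(model) {
  ints <- internal_mets(model)
  S <- matrix(0, length(ints), length(model$reactions),
              dimnames = list(ints, names(model$reactions)))
  for (r in model$reactions) {
    m <- r$maps[[1L]]  # stoichiometry identical across alternative maps
    for (term in m$subs)
      if (term$met %in% ints) S[term$met, r$name] <- S[term$met, r$name] - 1
    for (term in m$prods)
      if (term$met %in% ints) S[term$met, r$name] <- S[term$met, r$name] + 1
  }
  S
}

#' Degrees of freedom of the network
#'
#' Number of free fluxes once steady-state balance is imposed (columns of the
#' stoichiometric matrix minus its rank), before any boundary constraint.
#'
#' @param model A `flux_model`.
#' @return Integer.
#' @export
model_dof <- function(model) {
  S <- stoich_matrix(model)
  ncol(S) - qr(S)$rank
}

#' Check steady-state balance of a flux vector
#'
#' @param model A `flux_model`.
#' @param fluxes Named numeric vector of net fluxes (one per reaction).
#' @param tol Largest tolerated net imbalance at any internal metabolite.
#' @return Invisibly `TRUE`; errors if unbalanced or incomplete.
#' @export
check_balance <- function(model, fluxes, tol = 1e-6) {
  missing <- setdiff(names(model$reactions), names(fluxes))
  if (length(missing) > 0L)
    stopf("flux vector lacks reaction(s): %s", paste(missing, collapse = ", "))
  resid <- stoich_matrix(model) %*% fluxes[names(model$reactions)]
  if (max(abs(resid)) > tol)
    stopf("flux vector violates steady-state balance (worst: %s, %.3g)",
          rownames(resid)[which.max(abs(resid))], max(abs(resid)))
  invisible(TRUE)
}

#' Validate a network against the mammalian central-carbon profile
#'
#' Rejects microbial fermentation chemistry that has no place in a mammalian
#' single-cell model: pyruvate formate lyase and ethanol fermentation of
#' acetyl-CoA (detected by reaction name or by formate / ethanol /
#' acetaldehyde species).
#'
#' @param model A `flux_model`.
#' @return Invisibly `TRUE`; errors naming the offending reaction otherwise.
#' @export
validate_network_profile <- function(model) {
  forbidden_rxn <- "(^|_)(pfl|pyruvate_formate_lyase|adh[e]?|ethanol)"
  forbidden_met <- "^(FOR|formate|ETOH|ethanol|ACALD|acetaldehyde)$"
  for (r in model$reactions) {
    mets <- unlist(lapply(c(r$maps[[1L]]$subs, r$maps[[1L]]$prods),
                          `[[`, "met"))
    if (grepl(forbidden_rxn, tolower(r$name)) ||
        any(grepl(forbidden_met, mets, ignore.case = TRUE)))
      stopf("reaction '%s' is excluded by the mammalian central-carbon profile",
            r$name)
  }
  invisible(TRUE)
}
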