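# Flux estimation: weighted least squares between simulated and measured
# MDVs over the network's free fluxes, with glucose uptake pinned to 100 and
# the lactate efflux pinned to a configured value, solved by multi-start
# bounded local optimization. The flux vector is parameterized by a small set
# of free fluxes; all dependent fluxes are recovered exactly from
# steady-state balance, so every reported vector is balanced by construction.

fit_parameterization <- function(model, fixed_fluxes, free_fluxes) {
  S <- stoich_matrix(model)
  rxns <- colnames(S)
  fixed <- names(fixed_fluxes)
  if (!all(fixed %in% rxns))
    stopf("unknown fixed flux(es): %s",
          paste(setdiff(fixed, rxns), collapse = ", "))
  unknown <- setdiff(rxns, fixed)
  if (is.null(free_fluxes) || length(free_fluxes) == 0L) {
    # pick free fluxes automatically: non-pivot columns of the unknown block
    qrA <- qr(S[, unknown, drop = FALSE])
    free_fluxes <- unknown[qrA$pivot[-seq_len(qrA$rank)]]
  }
  if (!all(free_fluxes %in% unknown))
    stopf("free fluxes overlap fixed fluxes or are unknown")
  dep <- setdiff(unknown, free_fluxes)
  A_dep <- S[, dep, drop = FALSE]
  qrd <- qr(A_dep)
  if (qrd$rank < length(dep))
    stopf("dependent fluxes are not determined: choose different free fluxes")
  b0 <- -S[, fixed, drop = FALSE] %*% unlist(fixed_fluxes)
  A_free <- S[, free_fluxes, drop = FALSE]
  full_v <- function(u) {
    b <- if (length(u)) b0 - A_free %*% u else b0
    vdep <- qr.coef(qrd, b)
    v <- stats::setNames(numeric(length(rxns)), rxns)
    v[fixed] <- unlist(fixed_fluxes)
    v[free_fluxes] <- u
    v[dep] <- vdep
    v
  }
  # consistency: the system must be solvable exactly for any u
  r <- if (length(free_fluxes))
    qr.resid(qrd, b0 - A_free %*% rep(1, length(free_fluxes)))
  else qr.resid(qrd, b0)
  if (max(abs(r)) > 1e-8)
    stopf("infeasible constraint set: balance equations are inconsistent")
  list(full_v = full_v, free = free_fluxes, dep = dep, fixed = fixed)
}

measured_vector <- function(measured) {
  if (is.data.frame(measured)) {
    sp <- split(measured$fraction, measured$metabolite)
    measured <- lapply(sp, as.numeric)
  }
  measured
}

mdv_ssr <- function(sim, measured, weights = NULL) {
  ssr <- 0
  for (met in names(measured)) {
    s <- sim[[met]]
    m <- measured[[met]]
    w <- if (is.null(weights)) 1 else weights[[met]]
    ssr <- ssr + sum(w * (s[seq_along(m)] - m)^2)
  }
  ssr
}

#' Fit network fluxes to measured mass-distribution vectors
#'
#' Minimizes the (weighted) sum of squared differences between simulated and
#' measured MDVs over the model's free fluxes, with all boundary constraints
#' (glucose uptake = 100, the configured lactate efflux, and the fixed
#' drains) imposed exactly. The optimization is restarted `cycles` times from
#' random initial points (restart seeds are `seed + restart index`); the
#' best-residual converged solution is reported along with the per-restart
#' flux matrix and its dispersion.
#'
#' @param model A `flux_model`.
#' @param measured Named list of MDV vectors (as from [simulate_mdvs()] or
#'   [mdvs_from_table()]), or a data frame with columns `metabolite`,
#'   `mass_shift`, `fraction`.
#' @param lactate_efflux Value pinned for the lactate efflux reaction
#'   (default from the model constraints).
#' @param fixed_fluxes Named list of all pinned fluxes; defaults to glucose
#'   uptake, lactate efflux and the model's fixed drains.
#' @param free_fluxes Free fluxes to optimize (default from the model).
#' @param cycles Number of random restarts (modeling cycles).
#' @param max_iterations Iteration cap per restart.
#' @param seed Base seed for the restart stream.
#' @param start_range Range from which free-flux starting values are drawn.
#' @param weights Optional named list of per-MDV weights (e.g. inverse
#'   measurement variances); default uniform.
#' @param tracer,labeling,exchange Passed to the forward simulator.
#' @return A `flux_estimate`: best flux vector, residual, per-restart
#'   fluxes/residuals/convergence, and per-reaction dispersion (sd over
#'   converged restarts).
#' @export
fit_fluxes <- function(model, measured, lactate_efflux = NULL,
                       fixed_fluxes = NULL, free_fluxes = model$free_fluxes,
                       cycles = 100L, max_iterations = 2000L, seed = 1L,
                       start_range = c(0, 100), weights = NULL,
                       tracer = "U13C6", labeling = NULL, exchange = NULL) {
  measured <- measured_vector(measured)
  bad <- setdiff(names(measured), internal_mets(model))
  if (length(bad))
    stopf("measured metabolite(s) not in model: %s", paste(bad, collapse = ", "))
  if (is.null(fixed_fluxes)) {
    fixed_fluxes <- as.list(unlist(model$fixed_effluxes))
    for (cn in model$constraints)
      fixed_fluxes[[cn$reaction]] <- cn$value
  }
  if (!is.null(lactate_efflux)) {
    lac_rxn <- model$constraints$lactate_efflux$reaction %||% "lac_eff"
    fixed_fluxes[[lac_rxn]] <- lactate_efflux
  }
  par <- fit_parameterization(model, fixed_fluxes, free_fluxes)
  comp <- compile_cumomer(model)
  iso <- resolve_labeling(model, tracer, labeling)
  irrev <- names(model$reactions)[!vapply(model$reactions, `[[`, TRUE,
                                          "reversible")]
  penalty_w <- 1e3

  obj <- function(u) {
    v <- par$full_v(u)
    pen <- penalty_w * sum(pmin(v[irrev], 0)^2)
    sim <- tryCatch(sim_mdvs_core(comp, v, iso, exchange),
                    error = function(e) NULL)
    if (is.null(sim)) return(1e8 + pen + sum(u^2))
    mdv_ssr(sim, measured, weights) + pen
  }

  dof <- length(par$free)
  restarts <- vector("list", max(cycles, 1L))
  for (k in seq_len(max(cycles, 1L))) {
    u0 <- with_seed(seed + k, stats::runif(dof, start_range[1L],
                                           start_range[2L]))
    ans <- if (dof == 0L) {
      # fully determined system: nothing to optimize
      list(par = numeric(0), objective = obj(numeric(0)), convergence = 0L)
    } else tryCatch(
      stats::nlminb(u0, obj,
                    control = list(iter.max = max_iterations,
                                   eval.max = 4L * max_iterations)),
      error = function(e) NULL)
    restarts[[k]] <- if (is.null(ans)) {
      list(ok = FALSE, par = rep(NA_real_, dof), objective = Inf,
           convergence = 1L)
    } else {
      list(ok = ans$convergence == 0L, par = ans$par,
           objective = ans$objective, convergence = ans$convergence)
    }
  }
  conv <- vapply(restarts, `[[`, TRUE, "ok")
  residuals <- vapply(restarts, `[[`, 0, "objective")
  if (!any(is.finite(residuals)))
    stopf("flux fit failed: no restart converged (all objectives non-finite)")
  use <- if (any(conv)) which(conv) else which(is.finite(residuals))
  best <- use[which.min(residuals[use])]
  if (residuals[best] >= 1e7)
    stopf("flux fit failed: no restart reached a feasible simulation")
  upar <- restarts[[best]]$par
  v_best <- par$full_v(upar)

  flux_mat <- t(vapply(restarts, function(r) {
    if (all(is.finite(r$par))) par$full_v(r$par)
    else rep(NA_real_, length(v_best))
  }, v_best))
  colnames(flux_mat) <- names(v_best)
  disp <- apply(flux_mat[use, , drop = FALSE], 2L, stats::sd)

  structure(list(fluxes = v_best, free = stats::setNames(upar, par$free),
                 residual = residuals[best], restart_fluxes = flux_mat,
                 restart_residuals = residuals, converged = conv,
                 dispersion = disp, cycles = cycles,
                 fixed_fluxes = fixed_fluxes, model = model$name),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("flux_estimate (%s): residual %.4g, %d/%d restarts converged\n",
              x$model, x$residual, sum(x$converged), x$cycles))
  print(round(x$fluxes, 3))
  invisible(x)
}

classify_fit <- function(model, est, tol_rev = 1e-6, tol_irr = 1e-4) {
  chain <- model$glycolysis_chain
  v <- est$fluxes
  if (length(chain) && any(v[chain] < -tol_rev)) return("reversed_glycolysis")
  irrev <- names(model$reactions)[!vapply(model$reactions, `[[`, TRUE,
                                          "reversible")]
  if (any(v[irrev] < -tol_irr)) return("infeasible")
  "ok"
}

#' Select the lactate efflux by candidate scanning
#'
#' Fits the model once per candidate lactate-efflux value and classifies each
#' attempt: `infeasible` (fit failure or violated irreversibility),
#' `reversed_glycolysis` (a net flux along the hexokinase-to-pyruvate-kinase
#' chain turned negative, i.e. the glycolytic system ran in the reverse
#' direction), or `ok`. Among `ok` candidates the one with minimal residual
#' is selected.
#'
#' @inheritParams fit_fluxes
#' @param candidates Candidate efflux values (default 0 to 100 in steps of 5).
#' @param cycles Restarts per candidate (a scan needs fewer than a final fit).
#' @return List with `selected` (efflux value), `fit` (its `flux_estimate`)
#'   and `table` (per-candidate status and residual).
#' @export
scan_lactate_efflux <- function(model, measured, candidates = seq(0, 100, 5),
                                cycles = 10L, seed = 1L, ...) {
  if (length(candidates) == 0L) stopf("no candidate efflux values given")
  rows <- vector("list", length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    est <- tryCatch(fit_fluxes(model, measured, lactate_efflux = cand,
                               cycles = cycles, seed = seed, ...),
                    error = function(e) e)
    if (inherits(est, "error")) {
      rows[[i]] <- data.frame(candidate = cand, status = "infeasible",
                              residual = NA_real_)
    } else {
      fits[[i]] <- est
      rows[[i]] <- data.frame(candidate = cand,
                              status = classify_fit(model, est),
                              residual = est$residual)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$status == "ok")
  if (length(ok) == 0L) {
    message(paste(utils::capture.output(print(tab)), collapse = "\n"))
    stopf("lactate-efflux scan failed: no candidate with status 'ok'")
  }
  best <- ok[which.min(tab$residual[ok])]
  list(selected = tab$candidate[best], fit = fits[[best]], table = tab)
}

#' Scale the lactate efflux for a stressed condition
#'
#' The stressed-condition efflux is the quiescent baseline scaled by the
#' ratio of the treated to control share of glycolytic metabolites among all
#' 13C-labeled metabolites:
#' \deqn{base \times share_{treated} / share_{control}.}
#' If the scaled value exceeds the largest efflux the model can fit
#' (`max_modelable`), the value is decreased from `max_modelable` in steps of
#' `step` until a feasibility probe passes.
#'
#' @param treated_share,control_share Labeled-glycolytic shares (fractions)
#'   in the treated and control conditions; see
#'   [labeled_glycolytic_share()].
#' @param base Baseline efflux of the quiescent condition (default 65).
#' @param feasibility_probe Optional `function(efflux) -> logical`; when
#'   `NULL` every value is taken as modelable.
#' @param max_modelable Largest efflux assumed modelable (default 85).
#' @param step Decrement used while searching below `max_modelable`.
#' @return Selected efflux value.
#' @export
scaled_efflux <- function(treated_share, control_share, base = 65,
                          feasibility_probe = NULL, max_modelable = 85,
                          step = 5) {
  if (!is.finite(control_share) || control_share <= 0)
    stopf("control share must be > 0")
  probe <- feasibility_probe %||% function(x) TRUE
  raw <- base * treated_share / control_share
  if (raw <= max_modelable && isTRUE(probe(raw))) return(raw)
  cand <- max_modelable
  while (cand >= 0) {
    if (isTRUE(probe(cand))) return(cand)
    cand <- cand - step
  }
  stopf("no feasible lactate efflux value >= 0 found")
}
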