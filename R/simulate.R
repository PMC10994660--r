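# Steady-state isotopologue simulation.
#
# Two independent routes are provided:
#  * simulate_mdvs()      — cumomer decomposition: the balance equations for
#    the fraction of molecules labeled on every carbon subset form, weight by
#    weight, linear systems that are solved in cascade; mass-distribution
#    vectors follow by Moebius inversion. Equivalent to an
#    elementary-metabolite-unit treatment without pruning.
#  * simulate_mdvs_enum() — exhaustive isotopomer enumeration solved by
#    fixed-point (Jacobi) iteration over all 2^C positional isotopomers.
# They share only the network parser; agreement between them is a strong
# internal check and is enforced in the test suite.

pc_table <- function(nbits) {
  pc <- integer(2^nbits)
  for (m in seq_len(2^nbits - 1L))
    pc[m + 1L] <- pc[bitwShiftR(m, 1L) + 1L] + (m %% 2L)
  pc
}

# ---- unidirectional flux directions -----------------------------------------

invert_map <- function(map) list(subs = map$prods, prods = map$subs,
                                 weight = map$weight)

build_dirs <- function(model) {
  dirs <- list()
  for (r in model$reactions) {
    dirs[[length(dirs) + 1L]] <- list(rxn = r$name, sign = 1, maps = r$maps)
    if (r$reversible)
      dirs[[length(dirs) + 1L]] <- list(rxn = r$name, sign = -1,
                                        maps = lapply(r$maps, invert_map))
  }
  dirs
}

# net fluxes + exchange fluxes -> nonnegative unidirectional fluxes
dir_fluxes <- function(dirs, fluxes, exchange = NULL) {
  vapply(dirs, function(d) {
    v <- fluxes[[d$rxn]]
    ex <- if (!is.null(exchange) && d$rxn %in% names(exchange))
      exchange[[d$rxn]] else 0
    if (d$sign > 0) max(v, 0) + ex else max(-v, 0) + ex
  }, 0)
}

# ---- input labeling ---------------------------------------------------------

#' Isotopomer distributions for input metabolites
#'
#' `iso_unlabeled` / `iso_fully_labeled` give a point mass on the all-12C /
#' all-13C positional isotopomer of a `carbons`-carbon metabolite;
#' `iso_natural` is the distribution with each carbon independently 13C with
#' probability `p13`. Distributions are vectors of length `2^carbons`
#' ordered by the bitmask of labeled positions.
#'
#' @param carbons Number of carbon atoms.
#' @param p13 Per-carbon probability of 13C.
#' @return Numeric vector of isotopomer probabilities.
#' @export
iso_unlabeled <- function(carbons) {
  p <- numeric(2^carbons); p[1L] <- 1; p
}

#' @rdname iso_unlabeled
#' @export
iso_fully_labeled <- function(carbons) {
  p <- numeric(2^carbons); p[2^carbons] <- 1; p
}

#' @rdname iso_unlabeled
#' @export
iso_natural <- function(carbons, p13 = 0.011) {
  pc <- pc_table(carbons)
  k <- pc[seq_len(2^carbons)]
  p13^k * (1 - p13)^(carbons - k)
}

resolve_labeling <- function(model, tracer, labeling = NULL) {
  inputs <- model$metabolites$name[model$metabolites$role == "input"]
  out <- list()
  for (met in inputs) {
    C <- carbon_count(model, met)
    if (!is.null(labeling[[met]])) {
      p <- labeling[[met]]
      if (length(p) != 2^C || abs(sum(p) - 1) > 1e-9)
        stopf("labeling for '%s' must be a %d-vector summing to 1", met, 2^C)
      out[[met]] <- p
    } else {
      src <- model$inputs[[met]]
      out[[met]] <- switch(as.character(src),
        tracer = if (tracer == "U13C6") iso_fully_labeled(C) else iso_unlabeled(C),
        unlabeled = iso_unlabeled(C),
        stopf("input '%s' has unknown labeling source '%s'", met, src))
    }
  }
  out
}

# cumomer values (P(all carbons in mask are 13C)) of an isotopomer dist
iso_to_cumomer <- function(p) {
  n <- round(log2(length(p)))
  masks <- 0:(length(p) - 1L)
  vapply(seq_along(p) - 1L, function(S)
    sum(p[bitwAnd(masks, S) == S]), 0)
}

# Moebius inversion matrix: isotopomer probs from cumomer values
mobius_matrix <- function(C) {
  key <- paste0("mob", C)
  if (!is.null(.hscflux_cache[[key]])) return(.hscflux_cache[[key]])
  n <- 2^C
  pc <- pc_table(C)
  M <- matrix(0, n, n)
  for (Tm in 0:(n - 1L)) for (S in 0:(n - 1L))
    if (bitwAnd(S, Tm) == Tm)
      M[Tm + 1L, S + 1L] <- (-1)^(pc[S + 1L] - pc[Tm + 1L])
  .hscflux_cache[[key]] <- M
  M
}

.hscflux_cache <- new.env(parent = emptyenv())

# ---- cumomer system compilation --------------------------------------------

compile_cumomer <- function(model) {
  if (!is.null(model$cache$cumomer)) return(model$cache$cumomer)
  dirs <- build_dirs(model)
  ints <- internal_mets(model)
  carb <- stats::setNames(carbon_count(model, ints), ints)
  inputs <- model$metabolites$name[model$metabolites$role == "input"]
  carb_in <- stats::setNames(carbon_count(model, inputs), inputs)

  # kv layout: [1] constant 1; then input cumomers; then internal cumomers
  in_off <- c(0, cumsum(2^carb_in))[seq_along(inputs)]
  names(in_off) <- inputs
  n_in <- sum(2^carb_in)
  int_off <- c(0, cumsum(2^carb - 1))[seq_along(ints)]
  names(int_off) <- ints
  id_of <- function(met, mask) {
    if (mask == 0L) return(1L)
    if (met %in% inputs) return(1L + in_off[[met]] + mask)
    1L + n_in + int_off[[met]] + mask
  }
  nkv <- 1L + n_in + sum(2^carb - 1L)

  # consumption counts per internal metabolite per direction
  cons <- matrix(0, length(ints), length(dirs),
                 dimnames = list(ints, NULL))
  for (d in seq_along(dirs))
    for (term in dirs[[d]]$maps[[1L]]$subs)
      if (term$met %in% ints)
        cons[term$met, d] <- cons[term$met, d] + 1

  maxC <- max(carb)
  pc <- pc_table(maxC)

  # collect terms
  off_t <- list(row = integer(), col = integer(), di = integer(), mw = numeric())
  b_t <- list(row = integer(), di = integer(), mw = numeric(),
              f1 = integer(), f2 = integer(), f3 = integer())
  for (d in seq_along(dirs)) {
    for (map in dirs[[d]]$maps) {
      for (pt in map$prods) {
        P <- pt$met
        if (!P %in% ints) next
        CP <- carb[[P]]
        # source of each product carbon: (substrate term index, bit)
        src_k <- integer(CP); src_q <- integer(CP)
        for (j in seq_len(CP)) {
          found <- FALSE
          for (k in seq_along(map$subs)) {
            q <- match(pt$carbons[j], map$subs[[k]]$carbons)
            if (!is.na(q)) { src_k[j] <- k; src_q[j] <- q; found <- TRUE; break }
          }
          if (!found) stopf("internal error: unsourced atom in '%s'", P)
        }
        for (S in seq_len(2^CP - 1L)) {
          bits <- which(bitwAnd(bitwShiftR(S, 0:(CP - 1L)), 1L) == 1L)
          submask <- integer(length(map$subs))
          for (j in bits)
            submask[src_k[j]] <- bitwOr(submask[src_k[j]],
                                        bitwShiftL(1L, src_q[j] - 1L))
          ks <- which(submask > 0L)
          row_id <- id_of(P, S)
          single_internal <- length(ks) == 1L &&
            !(map$subs[[ks]]$met %in% inputs)
          if (single_internal) {
            off_t$row <- c(off_t$row, row_id)
            off_t$col <- c(off_t$col, id_of(map$subs[[ks]]$met, submask[ks]))
            off_t$di <- c(off_t$di, d)
            off_t$mw <- c(off_t$mw, map$weight)
          } else {
            if (length(ks) > 3L)
              stopf("atom maps with more than 3 contributing substrates unsupported")
            f <- rep(1L, 3L)
            for (ii in seq_along(ks))
              f[ii] <- id_of(map$subs[[ks[ii]]]$met, submask[ks[ii]])
            b_t$row <- c(b_t$row, row_id)
            b_t$di <- c(b_t$di, d)
            b_t$mw <- c(b_t$mw, map$weight)
            b_t$f1 <- c(b_t$f1, f[1L]); b_t$f2 <- c(b_t$f2, f[2L])
            b_t$f3 <- c(b_t$f3, f[3L])
          }
        }
      }
    }
  }

  # rows grouped by weight
  all_rows <- data.frame(met = rep(ints, 2^carb - 1L))
  all_rows$mask <- unlist(lapply(carb, function(C) seq_len(2^C - 1L)),
                          use.names = FALSE)
  all_rows$gid <- mapply(id_of, all_rows$met, all_rows$mask)
  all_rows$w <- pc[all_rows$mask + 1L]
  all_rows$met_i <- match(all_rows$met, ints)

  weights <- sort(unique(all_rows$w))
  row_w <- all_rows$w[match(off_t$row, all_rows$gid)]
  brow_w <- all_rows$w[match(b_t$row, all_rows$gid)]
  systems <- lapply(weights, function(w) {
    rows <- all_rows[all_rows$w == w, , drop = FALSE]
    loc <- stats::setNames(seq_len(nrow(rows)), rows$gid)
    nw <- nrow(rows)
    sel <- which(row_w == w)
    ri <- unname(loc[as.character(off_t$row[sel])])
    ci <- unname(loc[as.character(off_t$col[sel])])
    selb <- which(brow_w == w)
    list(nw = nw, gid = rows$gid, met_i = rows$met_i,
         diag_lin = (seq_len(nw) - 1L) * nw + seq_len(nw),
         off_key = (ci - 1L) * nw + ri,
         off_di = off_t$di[sel], off_mw = off_t$mw[sel],
         b_ri = unname(loc[as.character(b_t$row[selb])]),
         b_di = b_t$di[selb], b_mw = b_t$mw[selb],
         b_f1 = b_t$f1[selb], b_f2 = b_t$f2[selb], b_f3 = b_t$f3[selb])
  })

  comp <- list(dirs = dirs, ints = ints, carb = carb, inputs = inputs,
               carb_in = carb_in, in_off = in_off, n_in = n_in,
               int_off = int_off, nkv = nkv, cons = cons,
               systems = systems, id_of = id_of)
  model$cache$cumomer <- comp
  comp
}

cumomer_solve <- function(comp, vdir, input_iso) {
  out_flux <- as.vector(comp$cons %*% vdir)
  kv <- numeric(comp$nkv)
  kv[1L] <- 1
  for (met in comp$inputs) {
    x <- iso_to_cumomer(input_iso[[met]])
    kv[1L + comp$in_off[[met]] + seq_len(2^comp$carb_in[[met]] - 1L)] <-
      x[-1L]
  }
  for (st in comp$systems) {
    nw <- st$nw
    A <- matrix(0, nw, nw)
    A[st$diag_lin] <- out_flux[st$met_i]
    if (length(st$off_key)) {
      vals <- -vdir[st$off_di] * st$off_mw
      agg <- rowsum(vals, st$off_key)
      idx <- as.integer(rownames(agg))
      A[idx] <- A[idx] + agg[, 1L]
    }
    b <- numeric(nw)
    if (length(st$b_ri)) {
      vals <- vdir[st$b_di] * st$b_mw * kv[st$b_f1] * kv[st$b_f2] * kv[st$b_f3]
      agg <- rowsum(vals, st$b_ri)
      b[as.integer(rownames(agg))] <- agg[, 1L]
    }
    kv[st$gid] <- solve(A, b)
  }
  list(kv = kv, out_flux = out_flux)
}

kv_to_mdvs <- function(comp, kv) {
  out <- list()
  for (met in comp$ints) {
    C <- comp$carb[[met]]
    x <- c(1, kv[1L + comp$n_in + comp$int_off[[met]] + seq_len(2^C - 1L)])
    p <- mobius_matrix(C) %*% x
    k <- pc_table(C)[seq_len(2^C)]
    mdv <- as.vector(rowsum(p, k))
    names(mdv) <- paste0("M+", sort(unique(k)))
    out[[met]] <- mdv
  }
  out
}

check_sim_inputs <- function(model, fluxes, comp, vdir) {
  check_balance(model, fluxes)
  irrev <- !vapply(model$reactions, `[[`, TRUE, "reversible")
  neg <- names(model$reactions)[irrev &
    fluxes[names(model$reactions)] < -1e-9]
  if (length(neg))
    stopf("irreversible reaction(s) with negative net flux: %s",
          paste(neg, collapse = ", "))
  out_flux <- as.vector(comp$cons %*% vdir)
  dead <- comp$ints[out_flux <= 1e-9]
  if (length(dead))
    stopf("zero-flux subnetwork: metabolite '%s' has no consumption (dead pool)",
          dead[1L])
  invisible(TRUE)
}

#' Simulate steady-state mass-distribution vectors
#'
#' Solves the steady-state carbon-labeling balances of the network for a
#' given net flux vector by cumomer decomposition (cascaded linear systems,
#' one per labeling weight) and returns the mass-distribution vector (MDV) of
#' every internal metabolite. MDV fractions depend only on flux ratios, not
#' on the absolute scale.
#'
#' @param model A `flux_model`.
#' @param fluxes Named numeric vector of net fluxes satisfying steady-state
#'   balance; irreversible reactions must be non-negative.
#' @param tracer `"U13C6"` or `"U12C6"`; resolves input metabolites declared
#'   with labeling source `tracer`.
#' @param labeling Optional named list overriding input isotopomer
#'   distributions (see [iso_fully_labeled()]).
#' @param exchange Optional named vector of exchange (bidirectional) fluxes
#'   for reversible reactions; default 0 for all.
#' @return Named list of MDV vectors (`M+0` ... `M+C`), each summing to 1.
#' @export
simulate_mdvs <- function(model, fluxes, tracer = c("U13C6", "U12C6"),
                          labeling = NULL, exchange = NULL) {
  tracer <- match.arg(tracer)
  comp <- compile_cumomer(model)
  vdir <- dir_fluxes(comp$dirs, fluxes[names(model$reactions)], exchange)
  check_sim_inputs(model, fluxes, comp, vdir)
  iso <- resolve_labeling(model, tracer, labeling)
  kv_to_mdvs(comp, cumomer_solve(comp, vdir, iso)$kv)
}

# lenient core used inside optimization: clamps tiny negative unidirectional
# fluxes, no validation; errors propagate to the caller
sim_mdvs_core <- function(comp, fluxes, iso, exchange = NULL) {
  vdir <- pmax(dir_fluxes(comp$dirs, fluxes, exchange), 0)
  kv_to_mdvs(comp, cumomer_solve(comp, vdir, iso)$kv)
}

# ---- exhaustive isotopomer oracle ------------------------------------------

#' Simulate MDVs by exhaustive isotopomer enumeration
#'
#' Reference implementation: tracks the full positional-isotopomer
#' distribution (2^C states per metabolite) and solves the steady-state
#' balances by damped fixed-point iteration. Exponential in carbon count, so
#' only suitable for small networks; used to cross-validate
#' [simulate_mdvs()].
#'
#' @inheritParams simulate_mdvs
#' @param tol Convergence tolerance on the stationary distributions.
#' @param max_iter Iteration cap.
#' @return Named list of MDV vectors.
#' @export
simulate_mdvs_enum <- function(model, fluxes, tracer = c("U13C6", "U12C6"),
                               labeling = NULL, exchange = NULL,
                               tol = 1e-13, max_iter = 50000L) {
  tracer <- match.arg(tracer)
  comp <- compile_cumomer(model)  # reuse dirs/cons bookkeeping only
  vdir <- dir_fluxes(comp$dirs, fluxes[names(model$reactions)], exchange)
  check_sim_inputs(model, fluxes, comp, vdir)
  iso_in <- resolve_labeling(model, tracer, labeling)

  ints <- comp$ints
  dist <- lapply(comp$carb, iso_unlabeled)
  get_dist <- function(met)
    if (met %in% comp$inputs) iso_in[[met]] else dist[[met]]

  # precompute, per (dir, map, internal product): pattern lookup table over
  # the cross product of substrate isotopomers
  jobs <- list()
  for (d in seq_along(comp$dirs)) {
    if (vdir[d] <= 0) next
    for (map in comp$dirs[[d]]$maps) {
      subs_mets <- vapply(map$subs, `[[`, "", "met")
      sizes <- 2^vapply(map$subs, function(s) length(s$carbons), 1L)
      for (pt in map$prods) {
        if (!pt$met %in% ints) next
        CP <- length(pt$carbons)
        src_k <- integer(CP); src_q <- integer(CP)
        for (j in seq_len(CP)) {
          for (k in seq_along(map$subs)) {
            q <- match(pt$carbons[j], map$subs[[k]]$carbons)
            if (!is.na(q)) { src_k[j] <- k; src_q[j] <- q; break }
          }
        }
        combos <- as.matrix(expand.grid(lapply(sizes, function(s)
          0:(s - 1L))))
        pat <- integer(nrow(combos))
        for (j in seq_len(CP)) {
          bit <- bitwAnd(bitwShiftR(combos[, src_k[j]], src_q[j] - 1L), 1L)
          pat <- pat + bit * 2L^(j - 1L)
        }
        jobs[[length(jobs) + 1L]] <- list(
          d = d, w = map$weight, mets = subs_mets,
          combos = combos, pat = pat + 1L, target = pt$met)
      }
    }
  }

  out_flux <- stats::setNames(as.vector(comp$cons %*% vdir), ints)
  for (it in seq_len(max_iter)) {
    inflow <- lapply(comp$carb, function(C) numeric(2^C))
    for (jb in jobs) {
      pr <- rep(vdir[jb$d] * jb$w, nrow(jb$combos))
      for (k in seq_along(jb$mets))
        pr <- pr * get_dist(jb$mets[k])[jb$combos[, k] + 1L]
      acc <- rowsum(pr, jb$pat)
      tgt <- inflow[[jb$target]]
      tgt[as.integer(rownames(acc))] <-
        tgt[as.integer(rownames(acc))] + acc[, 1L]
      inflow[[jb$target]] <- tgt
    }
    delta <- 0
    for (met in ints) {
      newd <- inflow[[met]] / out_flux[[met]]
      delta <- max(delta, max(abs(newd - dist[[met]])))
      dist[[met]] <- newd
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    stopf("isotopomer fixed point did not converge (delta %.3g)", delta)

  out <- list()
  for (met in ints) {
    C <- comp$carb[[met]]
    k <- pc_table(C)[seq_len(2^C)]
    mdv <- as.vector(rowsum(dist[[met]], k))
    names(mdv) <- paste0("M+", sort(unique(k)))
    out[[met]] <- mdv
  }
  out
}
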