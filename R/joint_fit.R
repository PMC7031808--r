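## Joint multi-contrast ensemble fitting.
##
## One membrane structure is refined simultaneously against all contrasts
## (SAXS + SANS at several D2O fractions).  Because scattering inversion is
## degenerate, the fit is repeated many times with a stochastic global
## optimiser (a real-coded genetic algorithm) started from random
## populations; the per-parameter distribution over runs is summarised by
## its center of mass, with the square root of the second central moment as
## uncertainty.

#' Default free-parameter specification
#'
#' Free structural parameters and their box bounds: the area per unit cell,
#' position and width of each headgroup Gaussian (ENX, PG2, PO4, CG), the
#' hydrocarbon interface width, and (for peptide systems) the peptide
#' Gaussian position and width.  Per-dataset intensity scale and flat
#' background are not listed here: they are profiled analytically inside the
#' cost function.  Group volumes stay fixed at their configured values.
#'
#' @param peptide Include the peptide position/width parameters?
#' @return Tibble with columns `name`, `lo`, `hi`.
#' @export
default_fit_specs <- function(peptide = FALSE) {
  sp <- tibble::tribble(
    ~name,        ~lo,  ~hi,
    "A_U",        55,   72,
    "z_CG",       13,   19,
    "sigma_CG",   1.5,  4,
    "z_PO4",      17,   23,
    "sigma_PO4",  1.5,  4,
    "z_ENX",      18,   26,
    "sigma_ENX",  1.5,  4.5,
    "z_PG2",      17,   26,
    "sigma_PG2",  1.5,  4.5,
    "sigma_HC",   1.5,  4
  )
  if (peptide) {
    sp <- dplyr::bind_rows(sp, tibble::tribble(
      ~name,       ~lo, ~hi,
      "z_pep",     10,  22,
      "sigma_pep", 2.5, 7
    ))
  }
  sp
}

#' Genetic-algorithm configuration
#'
#' Real-coded GA with tournament selection, uniform crossover, per-gene
#' Gaussian mutation (reflected at the box bounds) and elitism, followed by
#' an optional bounded quasi-Newton polish of the best individual.
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param p_crossover Probability that a parent pair is recombined.
#' @param p_mutation Per-gene mutation probability.
#' @param mutation_sd Mutation step (fraction of the box width).
#' @param tournament_k Tournament size.
#' @param elitism Number of best individuals copied unchanged.
#' @param polish Run `stats::optim(method = "L-BFGS-B")` from the GA best?
#' @param polish_maxit Iteration cap for each polish round.
#' @param polish_restarts Additional polish rounds restarted from the last
#'   best (stops early when a round no longer improves the cost).
#' @return List of class `ga_config`.
#' @export
ga_config <- function(pop_size = 40, generations = 80, p_crossover = 0.7,
                      p_mutation = 0.15, mutation_sd = 0.1,
                      tournament_k = 3, elitism = 2,
                      polish = TRUE, polish_maxit = 300,
                      polish_restarts = 1) {
  structure(as.list(environment()), class = "ga_config")
}

## ---- cost function --------------------------------------------------------

## Precompute everything that does not change when geometry parameters move:
## per-dataset fit-window arrays and scattering amplitudes (volumes and
## contrasts are fixed; only z, sigma, A_U vary).
.precompute_fit <- function(study, peptides, PL_ratio, template_params,
                            weights = NULL) {
  template <- build_unit_cell(template_params, peptides = peptides,
                              PL_ratio = PL_ratio)
  ds <- study$datasets
  if (is.null(weights)) weights <- rep(1, length(ds))
  head_names <- c("ENX", "PG2", "PO4", "CG")
  pre <- list(template = template, head_names = head_names,
              V_HC = template$hc$V_HC,
              ch_frac = template$ch_frac,
              sigma_CH = template$sigma_CH, sigma_CH3 = template$sigma_CH3,
              has_pep = PL_ratio > 0, datasets = list())
  Vm <- vapply(template$components,
               function(cp) cp$group$volume * cp$group$multiplicity, 0)
  pre$Vm <- Vm
  for (i in seq_along(ds)) {
    d <- ds[[i]]
    win <- attr(d, "q_window")
    keep <- d$q >= win[1] & d$q <= win[2]
    if (!any(keep)) stop("empty fit window in dataset ", attr(d, "name"),
                         call. = FALSE)
    rho <- .component_slds(template, attr(d, "probe"), attr(d, "x_D"))
    amp_head <- vapply(head_names,
                       function(nm) Vm[[nm]] * (rho[[nm]] - rho$solvent), 0)
    pre$datasets[[i]] <- list(
      name = attr(d, "name"),
      q = d$q[keep], I = d$I[keep], w = 1 / d$sigma[keep]^2,
      weight = weights[i],
      amp_head = amp_head,
      amp_CH  = Vm[["CH"]]  * (rho$CH - rho$CH2),
      amp_CH3 = Vm[["CH3"]] * (rho$CH3 - rho$CH2),
      amp_pep = if (pre$has_pep) {
        Vm[["peptide"]] * (rho$peptide - rho$solvent)
      } else 0,
      drho_CH2 = rho$CH2 - rho$solvent
    )
  }
  ## coarse grid for the packing penalty
  pre$z_pen <- seq(0, 42, by = 1)
  pre
}

## Form factor on one dataset's q grid for a geometry parameter list.
.ff_fast <- function(pd, p, pre) {
  q <- pd$q
  q2 <- q^2
  D_C <- pre$V_HC / p$A_U
  F <- pd$amp_head[[1]] * cos(q * p$z_ENX) * exp(-q2 * p$sigma_ENX^2 / 2) +
       pd$amp_head[[2]] * cos(q * p$z_PG2) * exp(-q2 * p$sigma_PG2^2 / 2) +
       pd$amp_head[[3]] * cos(q * p$z_PO4) * exp(-q2 * p$sigma_PO4^2 / 2) +
       pd$amp_head[[4]] * cos(q * p$z_CG)  * exp(-q2 * p$sigma_CG^2  / 2) +
       pd$amp_CH  * cos(q * pre$ch_frac * D_C) *
         exp(-q2 * pre$sigma_CH^2 / 2) +
       pd$amp_CH3 * exp(-q2 * pre$sigma_CH3^2 / 2)
  if (pre$has_pep) {
    F <- F + pd$amp_pep * cos(q * p$z_pep) * exp(-q2 * p$sigma_pep^2 / 2)
  }
  2 * F / p$A_U +
    2 * pd$drho_CH2 * sin(q * D_C) / q * exp(-q2 * p$sigma_HC^2 / 2)
}

## Packing penalty terms evaluated on the coarse grid.
.penalty_terms <- function(p, pre) {
  z <- pre$z_pen
  D_C <- pre$V_HC / p$A_U
  P_HC <- .hc_envelope(z, D_C, p$sigma_HC)
  g <- function(zc, s, Vm) .gauss_pair(z, zc, s, Vm, p$A_U)
  P_CH <- g(pre$ch_frac * D_C, pre$sigma_CH, pre$Vm[["CH"]])
  P_CH3 <- g(0, pre$sigma_CH3, pre$Vm[["CH3"]])
  tot <- P_HC +
    g(p$z_ENX, p$sigma_ENX, pre$Vm[["ENX"]]) +
    g(p$z_PG2, p$sigma_PG2, pre$Vm[["PG2"]]) +
    g(p$z_PO4, p$sigma_PO4, pre$Vm[["PO4"]]) +
    g(p$z_CG, p$sigma_CG, pre$Vm[["CG"]])
  if (pre$has_pep) tot <- tot + g(p$z_pep, p$sigma_pep, pre$Vm[["peptide"]])
  overfill <- max(0, max(tot - 1))
  neg_CH2 <- max(0, -min(P_HC - P_CH - P_CH3))
  c(overfill = overfill, neg_CH2 = neg_CH2)
}

#' Build the joint-fit cost function
#'
#' Returns a closure mapping a named geometry-parameter vector to the joint
#' weighted chi-square over all datasets in their fit windows, plus packing
#' penalties (volume overfill and negative methylene probability).  The
#' per-dataset intensity scale and flat background are profiled analytically
#' (weighted linear least squares), so they never appear as explicit
#' parameters.
#'
#' @param study An `sdp_study` (see [make_study()]) or a list of
#'   [scattering_dataset()]s in `study$datasets`.
#' @param peptides,PL_ratio Peptide composition of the model (default taken
#'   from `study$truth` when present).
#' @param fixed_params Geometry parameters to hold fixed (completed from
#'   [default_geometry()]); free parameters override these at call time.
#' @param weights Per-dataset weights (default equal).
#' @param lambda_overfill,lambda_neg_ch2 Penalty strengths (quadratic in the
#'   excess beyond the tolerances).
#' @param eps_overfill Packing tolerance: total volume probability may
#'   exceed 1 by this much before the penalty engages.  The default 0.02
#'   accommodates the core penetration of the peptide Gaussian tail at
#'   P:L = 1:200, which the single-Gaussian peptide convention does not
#'   remove from the hydrocarbon envelope.
#' @param eps_neg_ch2 Tolerated negative methylene probability.
#' @param profile_background Profile a flat background together with the
#'   scale?  Default `TRUE`.
#' @return Function `f(params)` -> scalar cost, with attribute
#'   `"details"(params)` returning the per-dataset chi-squares, profiled
#'   scales/backgrounds and penalties.
#' @export
sdp_cost_function <- function(study, peptides = NULL, PL_ratio = NULL,
                              fixed_params = NULL, weights = NULL,
                              lambda_overfill = 1e4, lambda_neg_ch2 = 1e4,
                              eps_overfill = 0.02, eps_neg_ch2 = 1e-3,
                              profile_background = TRUE) {
  if (is.null(PL_ratio)) PL_ratio <- study$truth$PL_ratio %||% 0
  if (is.null(peptides) && PL_ratio > 0) peptides <- study$truth$peptides
  if (!is.null(peptides)) {
    if (inherits(peptides, "peptide_spec")) peptides <- list(peptides)
    peptides <- lapply(peptides, function(p) {
      if (inherits(p, "peptide_spec")) p else {
        peptide_from_sequence(p$sequence, volume = p$volume,
                              name = p$name %||% p$sequence,
                              cterm_amidated = isTRUE(p$cterm_amidated))
      }
    })
  }
  base <- default_geometry()
  if (!is.null(fixed_params)) base[names(fixed_params)] <- fixed_params
  pre <- .precompute_fit(study, peptides, PL_ratio, base, weights)

  eval_parts <- function(params) {
    p <- base
    p[names(params)] <- as.list(params)
    chi2 <- numeric(length(pre$datasets))
    sc <- numeric(length(pre$datasets))
    bg <- numeric(length(pre$datasets))
    for (i in seq_along(pre$datasets)) {
      pd <- pre$datasets[[i]]
      F <- .ff_fast(pd, p, pre)
      M <- F^2 / pd$q^2
      fit <- .profile_scale(M, pd$I, pd$w, profile_background)
      sc[i] <- fit$scale; bg[i] <- fit$background
      chi2[i] <- pd$weight * fit$chi2
    }
    pen <- .penalty_terms(p, pre)
    list(chi2 = chi2, scale = sc, background = bg, penalties = pen,
         cost = sum(chi2) +
           lambda_overfill * max(0, pen[["overfill"]] - eps_overfill)^2 +
           lambda_neg_ch2 * max(0, pen[["neg_CH2"]] - eps_neg_ch2)^2)
  }
  f <- function(params) eval_parts(params)$cost
  attr(f, "details") <- eval_parts
  attr(f, "precomp") <- pre
  f
}

## Weighted LLS profile of I ~ scale * M + background (scale kept positive).
.profile_scale <- function(M, I, w, with_background = TRUE) {
  if (with_background) {
    swm2 <- sum(w * M^2); swm <- sum(w * M); sw <- sum(w)
    swmi <- sum(w * M * I); swi <- sum(w * I)
    det <- swm2 * sw - swm^2
    if (det > 0) {
      s <- (swmi * sw - swm * swi) / det
      b <- (swm2 * swi - swm * swmi) / det
      if (s > 0) {
        r <- I - s * M - b
        return(list(scale = s, background = b, chi2 = sum(w * r^2)))
      }
    }
  }
  s <- sum(w * M * I) / sum(w * M^2)
  s <- max(s, 1e-12)
  r <- I - s * M
  list(scale = s, background = 0, chi2 = sum(w * r^2))
}

## ---- genetic algorithm ----------------------------------------------------

#' Single genetic-algorithm minimisation
#'
#' Minimises `cost` over the box defined by `specs`.  Deterministic given
#' `seed` and `config`.  Genes live on the unit cube and are decoded to the
#' bounds; the optional polish runs bounded L-BFGS-B from the GA best and
#' keeps whichever is lower.
#'
#' @param cost Function of a named parameter vector (see
#'   [sdp_cost_function()]).
#' @param specs Tibble with `name`, `lo`, `hi` ([default_fit_specs()]).
#' @param seed Integer seed.
#' @param config An [ga_config()].
#' @return List with `par` (named vector), `cost`, `trace` (best cost per
#'   generation), `n_eval`.
#' @export
ga_minimize <- function(cost, specs, seed = 1, config = ga_config()) {
  stopifnot(all(c("name", "lo", "hi") %in% names(specs)),
            all(specs$hi > specs$lo))
  set.seed(as.integer(seed))
  n <- nrow(specs)
  lo <- specs$lo; hi <- specs$hi; span <- hi - lo
  decode <- function(u) stats::setNames(lo + u * span, specs$name)
  fit_u <- function(u) cost(decode(u))

  np <- config$pop_size
  pop <- matrix(stats::runif(np * n), nrow = np)
  costs <- apply(pop, 1, fit_u)
  n_eval <- np
  if (all(!is.finite(costs))) {
    stop("initialization error: cost not finite for any starting candidate",
         call. = FALSE)
  }
  costs[!is.finite(costs)] <- Inf
  trace <- numeric(config$generations)

  for (gen in seq_len(config$generations)) {
    ord <- order(costs)
    elite <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
    newpop <- matrix(0, nrow = np, ncol = n)
    newpop[seq_len(config$elitism), ] <- elite
    i <- config$elitism + 1
    while (i <= np) {
      p1 <- pop[.tournament(costs, config$tournament_k), ]
      p2 <- pop[.tournament(costs, config$tournament_k), ]
      if (stats::runif(1) < config$p_crossover) {
        mask <- stats::runif(n) < 0.5
        tmp <- p1[mask]; p1[mask] <- p2[mask]; p2[mask] <- tmp
      }
      for (child in list(p1, p2)) {
        if (i > np) break
        mut <- stats::runif(n) < config$p_mutation
        if (any(mut)) {
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, config$mutation_sd)
          child <- .reflect_unit(child)
        }
        newpop[i, ] <- child
        i <- i + 1
      }
    }
    pop <- newpop
    costs <- apply(pop, 1, fit_u)
    costs[!is.finite(costs)] <- Inf
    n_eval <- n_eval + np
    trace[gen] <- min(costs)
  }

  best_i <- which.min(costs)
  best_u <- pop[best_i, ]
  best_par <- decode(best_u)
  best_cost <- costs[best_i]

  if (isTRUE(config$polish)) {
    ## alternate simplex and quasi-Newton rounds: the simplex escapes the
    ## finite-difference gradient floor, L-BFGS-B then re-tightens
    clamp <- function(par) pmin(pmax(par, lo), hi)
    run_lbfgs <- function() {
      lb <- try(stats::optim(best_par, cost, method = "L-BFGS-B",
                             lower = lo, upper = hi,
                             control = list(maxit = config$polish_maxit)),
                silent = TRUE)
      if (!inherits(lb, "try-error") && is.finite(lb$value) &&
          lb$value < best_cost) {
        best_par <<- stats::setNames(lb$par, specs$name)
        best_cost <<- lb$value
      }
    }
    run_lbfgs()
    for (round in seq_len(if (n > 1) config$polish_restarts else 0)) {
      entry <- best_cost
      nm <- try(stats::optim(best_par, function(par) cost(clamp(par)),
                             method = "Nelder-Mead",
                             control = list(maxit = config$polish_maxit,
                                            reltol = 1e-12)),
                silent = TRUE)
      if (!inherits(nm, "try-error") && is.finite(nm$value) &&
          nm$value < best_cost) {
        best_par <- stats::setNames(clamp(nm$par), specs$name)
        best_cost <- nm$value
      }
      run_lbfgs()
      if (best_cost >= entry * (1 - 1e-10)) break
    }
  }
  list(par = best_par, cost = best_cost, trace = trace, n_eval = n_eval)
}

.tournament <- function(costs, k) {
  idx <- sample.int(length(costs), k)
  idx[which.min(costs[idx])]
}

.reflect_unit <- function(u) {
  u <- abs(u) %% 2
  ifelse(u > 1, 2 - u, u)
}

## ---- ensemble -------------------------------------------------------------

#' Ensemble fit: many independent GA runs, moment-based aggregation
#'
#' Repeats [ga_minimize()] `n_runs` times with run-indexed seeds
#' (`base_seed * 1000 + run`), so results are reproducible and independent
#' of execution order.  Parameter estimates are the center of mass of the
#' per-run best values; uncertainties are square roots of the second central
#' moments of those distributions.
#'
#' @param study An `sdp_study` or a list with `$datasets`.
#' @param n_runs Number of independent runs (the full experimental protocol
#'   uses 400; smaller ensembles trade precision of the uncertainty estimate
#'   for runtime).
#' @param base_seed Integer base seed.
#' @param specs Free-parameter table; default chosen by peptide content.
#' @param config An [ga_config()].
#' @param ... Passed to [sdp_cost_function()].
#' @return Object of class `sdp_fit`: `runs` (tibble of per-run best
#'   parameters and costs), `estimates` (tibble `term`, `estimate`,
#'   `uncertainty`), plus the cost function and metadata.
#' @export
ensemble_fit <- function(study, n_runs = 40, base_seed = 1, specs = NULL,
                         config = ga_config(), ...) {
  stopifnot(n_runs >= 1)
  cost <- sdp_cost_function(study, ...)
  has_pep <- attr(cost, "precomp")$has_pep
  if (is.null(specs)) specs <- default_fit_specs(peptide = has_pep)

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed_r <- as.integer(base_seed) * 1000L + r
    res <- try(ga_minimize(cost, specs, seed = seed_r, config = config),
               silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$cost)) {
      runs[[r]] <- tibble::tibble(run = r, seed = seed_r, cost = NA_real_,
                                  converged = FALSE)
    } else {
      runs[[r]] <- dplyr::bind_cols(
        tibble::tibble(run = r, seed = seed_r, cost = res$cost,
                       converged = TRUE),
        tibble::as_tibble(as.list(res$par))
      )
    }
  }
  runs <- dplyr::bind_rows(runs)
  ok <- sum(runs$converged)
  if (ok < n_runs / 2) {
    stop("ensemble failed: only ", ok, " of ", n_runs, " runs succeeded",
         call. = FALSE)
  }
  fit <- structure(
    list(runs = runs, specs = specs, cost = cost, study = study,
         config = config, base_seed = base_seed, n_runs = n_runs),
    class = "sdp_fit"
  )
  fit$estimates <- aggregate_runs(fit)
  fit
}

#' Aggregate an ensemble of runs into estimates and uncertainties
#'
#' Center of mass (weighted mean, uniform weights by default) of each
#' parameter over successful runs, with the square root of the second
#' central moment as uncertainty.
#'
#' @param fit An `sdp_fit`, or its `runs` tibble.
#' @param weights Optional per-run weights.
#' @return Tibble with columns `term`, `estimate`, `uncertainty`.
#' @export
aggregate_runs <- function(fit, weights = NULL) {
  runs <- if (inherits(fit, "sdp_fit")) fit$runs else fit
  runs <- runs[runs$converged %||% TRUE & !is.na(runs$cost), , drop = FALSE]
  stopifnot(nrow(runs) >= 1)
  pcols <- setdiff(names(runs), c("run", "seed", "cost", "converged"))
  if (is.null(weights)) weights <- rep(1, nrow(runs))
  w <- weights / sum(weights)
  est <- vapply(pcols, function(nm) sum(w * runs[[nm]]), 0)
  unc <- vapply(pcols, function(nm) {
    sqrt(sum(w * (runs[[nm]] - est[[nm]])^2))
  }, 0)
  tibble::tibble(term = pcols, estimate = unname(est),
                 uncertainty = unname(unc))
}

#' @export
print.sdp_fit <- function(x, ...) {
  cat(sprintf("<sdp_fit> %d/%d successful runs, best cost %.4g\n",
              sum(x$runs$converged), x$n_runs,
              min(x$runs$cost, na.rm = TRUE)))
  print(x$estimates)
  invisible(x)
}

#' Rebuild the SDP model from ensemble estimates
#'
#' @param fit An `sdp_fit`.
#' @return An `sdp_model` built from the center-of-mass parameters.
#' @export
model_from_fit <- function(fit) {
  stopifnot(inherits(fit, "sdp_fit"))
  pre <- attr(fit$cost, "precomp")
  params <- default_geometry()
  est <- stats::setNames(fit$estimates$estimate, fit$estimates$term)
  params[names(est)] <- as.list(est)
  tpl <- pre$template
  build_unit_cell(params,
                  peptides = if (pre$has_pep) list(tpl$peptide) else NULL,
                  PL_ratio = tpl$PL_ratio,
                  lipid_fractions = tpl$lipid_fractions,
                  groups = tpl$groups, solvent = tpl$solvent,
                  ch_frac = tpl$ch_frac, sigma_CH = tpl$sigma_CH,
                  sigma_CH3 = tpl$sigma_CH3)
}

## ---- broom-style methods --------------------------------------------------

#' Tidy an ensemble fit
#'
#' @param x An `sdp_fit`.
#' @param ... Unused.
#' @return The estimates tibble (`term`, `estimate`, `uncertainty`).
#' @export
tidy.sdp_fit <- function(x, ...) x$estimates

#' One-row summary of an ensemble fit
#'
#' @param x An `sdp_fit`.
#' @param ... Unused.
#' @return Tibble with run counts and cost summaries.
#' @export
glance.sdp_fit <- function(x, ...) {
  ok <- x$runs$converged
  tibble::tibble(
    n_runs = x$n_runs,
    n_success = sum(ok),
    best_cost = min(x$runs$cost[ok]),
    mean_cost = mean(x$runs$cost[ok]),
    base_seed = x$base_seed
  )
}
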