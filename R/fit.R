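#' Configuration for the hybrid global fit
#'
#' Collects the tunables of the hybrid genetic-algorithm /
#' nonlinear-least-squares optimizer. Rates are optimized in log10 space
#' within box bounds of \[1e-3, 1e4\] s^-1 by default — observed
#' nucleotide-addition rates span roughly 0.1–100 s^-1 and positivity is
#' structural — while the dimensionless `f_inactive` is optimized on its
#' natural \[0, 1\] scale. Only the product bands 11–19 enter the default
#' objective (the nine extension-product time courses are what is fit
#' globally); the 10-mer can be added through `fitted_bands`.
#'
#' @param bounds default box for rate parameters, `c(lo, hi)` in s^-1.
#' @param ga genetic-algorithm settings: `pop_size`, `generations`,
#'   `tournament_k`, `crossover_rate`, `mutation_rate`, `mutation_sd`
#'   (as a fraction of each parameter's transformed range), `elite`
#'   (candidates copied unchanged), `polish_top` (diverse candidates passed
#'   to the final least-squares polish), `phases` (alternating GA/polish
#'   rounds: after each GA round the incumbent is polished and re-injected
#'   into the population), `immigrants` (fresh random candidates injected
#'   per generation to keep the population exploring). Settings left at
#'   their defaults are scaled up by [fit_global()] for schemes with many
#'   parameters (population `4p`, `5p` generations); explicitly supplied
#'   values are never altered.
#' @param nlls least-squares polish settings: `maxiter`, `ftol`.
#' @param seed integer seed making the whole optimization deterministic.
#' @param fitted_bands RNA lengths entering the objective (default `11:19`).
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(bounds = c(1e-3, 1e4),
                       ga = list(), nlls = list(),
                       seed = 1L, fitted_bands = 11:19) {
  ga_def <- list(pop_size = 48L, generations = 60L, tournament_k = 3L,
                 crossover_rate = 0.9, mutation_rate = 0.2,
                 mutation_sd = 0.15, elite = 2L, polish_top = 5L,
                 phases = 3L, immigrants = 6L)
  nlls_def <- list(maxiter = 150L, ftol = 1e-12)
  user_set <- names(ga)
  ga <- utils::modifyList(ga_def, ga)
  attr(ga, "user_set") <- user_set
  nlls <- utils::modifyList(nlls_def, nlls)
  stopifnot(length(bounds) == 2L, bounds[1] > 0, bounds[2] > bounds[1],
            ga$pop_size >= 4L, ga$generations >= 1L, ga$polish_top >= 1L)
  structure(list(bounds = bounds, ga = ga, nlls = nlls,
                 seed = as.integer(seed),
                 fitted_bands = as.integer(fitted_bands)),
            class = "fit_config")
}

# per-parameter box and scale for a scheme: rates log10-scaled in
# config$bounds, f_inactive linear in [0, 1]
param_space <- function(scheme, config) {
  nm <- free_params(scheme)
  is_f <- nm == "f_inactive"
  list(names = nm,
       lower = ifelse(is_f, 0, config$bounds[1]),
       upper = ifelse(is_f, 1, config$bounds[2]),
       log_scale = !is_f)
}

to_internal <- function(x, space) ifelse(space$log_scale, log10(x), x)
from_internal <- function(th, space) {
  x <- ifelse(space$log_scale, 10^th, th)
  stats::setNames(x, space$names)
}

#' Global sum-of-squares objective for a time course
#'
#' Sum over the fitted bands and all time points of the squared difference
#' between observed and model band fractions, the model being
#' [solve_timecourse()] followed by [project_observables()]. Unweighted,
#' matching the reporting of replicate fits without a stated weighting
#' scheme.
#'
#' @param data an `observed_timecourse`.
#' @param scheme a `kinetic_scheme`.
#' @param params named rates for the scheme.
#' @param fitted_bands RNA lengths included (default `11:19`).
#' @return nonnegative scalar sum of squared residuals.
#' @export
timecourse_ssr <- function(data, scheme, params, fitted_bands = 11:19) {
  r <- timecourse_residuals(data, scheme, params, fitted_bands)
  sum(r * r)
}

#' Residual vector for a time course under a scheme
#'
#' The (observed - model) band-fraction residuals that [timecourse_ssr()]
#' squares and sums, exposed for least-squares polishing and residual
#' diagnostics. Ordered band-major: all times of the lowest fitted band
#' first.
#'
#' @inheritParams timecourse_ssr
#' @return numeric vector of length (#fitted bands) x (#times), with
#'   attributes `bands` and `times`.
#' @export
timecourse_residuals <- function(data, scheme, params, fitted_bands = 11:19) {
  stopifnot(inherits(data, "observed_timecourse"))
  if (length(data$times) == 0L) stop("empty time grid", call. = FALSE)
  bands <- intersect(as.character(fitted_bands), rownames(data$bands))
  if (!length(bands)) stop("no fitted band present in the data", call. = FALSE)
  traj <- solve_timecourse(scheme, params, data$times)
  model <- project_observables(traj)
  mrows <- match(bands, rownames(model$bands))
  if (anyNA(mrows)) {
    stop("scheme produces no band at length(s): ",
         paste(bands[is.na(mrows)], collapse = ", "), call. = FALSE)
  }
  res <- t(data$bands[bands, , drop = FALSE] -
             model$bands[mrows, , drop = FALSE])
  structure(as.numeric(res), bands = bands, times = data$times)
}

#' Hybrid genetic-algorithm / least-squares optimization
#'
#' Two-stage global minimizer in the spirit of multi-start evolutionary
#' optimizers used for transient-state kinetic fitting: a genetic algorithm
#' (tournament selection, blend crossover, Gaussian mutation, elitism) run
#' in the transformed (log-rate) parameter space explores the box and seeds
#' a damped-least-squares polish (`minpack.lm::nls.lm` when a residual
#' function is available, otherwise `nlminb`) of the top candidates. The
#' best-so-far objective is non-increasing across generations (elitism) and
#' the whole procedure is deterministic given `config$seed`. Ties between
#' equal-objective polished optima are broken by the smallest transformed
#' parameter-vector norm.
#'
#' @param fn objective: function of a named natural-scale parameter vector
#'   returning a nonnegative scalar.
#' @param lower,upper box bounds on the natural scale.
#' @param config a [fit_config()].
#' @param log_scale logical per parameter: optimize on log10 scale.
#' @param residual_fn optional function returning the residual vector whose
#'   sum of squares is `fn`; enables the Levenberg–Marquardt polish.
#' @param par_names parameter names (defaults to `names(lower)`).
#' @return list with `par` (named, natural scale), `objective`, `trace`
#'   (best objective per GA generation), `convergence` (logical),
#'   `polished` (data frame of polish outcomes).
#' @export
#' @examples
#' cfg <- fit_config(ga = list(pop_size = 24, generations = 20), seed = 7)
#' fn <- function(p) (p[["x"]] - 3)^2 + (p[["y"]] + 1)^2
#' hybrid_optimize(fn, c(x = -5, y = -5), c(x = 5, y = 5), cfg,
#'                 log_scale = c(FALSE, FALSE))$par
hybrid_optimize <- function(fn, lower, upper, config,
                            log_scale = NULL, residual_fn = NULL,
                            par_names = names(lower)) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower), all(is.finite(lower)),
            all(is.finite(upper)))
  if (is.null(log_scale)) log_scale <- rep(TRUE, d)
  if (is.null(par_names)) par_names <- sprintf("p%d", seq_len(d))
  space <- list(names = par_names, lower = lower, upper = upper,
                log_scale = log_scale)
  tlo <- to_internal(lower, space)
  thi <- to_internal(upper, space)
  trange <- thi - tlo

  safe_fn <- function(th) {
    v <- tryCatch(fn(from_internal(th, space)), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  ga <- config$ga
  with_seed(config$seed, {
    pop <- t(tlo + t(lhs::randomLHS(ga$pop_size, d)) * trange)
    obj <- apply(pop, 1, safe_fn)

    n_res <- NULL
    if (!is.null(residual_fn)) {
      r0 <- tryCatch(residual_fn(from_internal(pop[which.min(obj), ], space)),
                     error = function(e) NULL)
      if (is.null(r0)) residual_fn <- NULL else n_res <- length(r0)
    }

    ga_round <- function(pop, obj, n_gen) {
      trace <- numeric(n_gen)
      for (gen in seq_len(n_gen)) {
        ord <- order(obj)
        pop <- pop[ord, , drop = FALSE]
        obj <- obj[ord]
        new_pop <- pop
        new_obj <- obj
        # fresh immigrants replace the worst candidates each generation
        n_imm <- min(ga$immigrants, ga$pop_size - ga$elite)
        imm_rows <- if (n_imm > 0) {
          seq.int(ga$pop_size - n_imm + 1L, ga$pop_size)
        } else integer(0)
        for (i in seq.int(ga$elite + 1L, ga$pop_size)) {
          if (i %in% imm_rows) {
            child <- tlo + stats::runif(d) * trange
          } else {
            pick <- function() {
              cand <- sample.int(ga$pop_size, ga$tournament_k)
              pop[min(cand), ]  # pop is objective-sorted
            }
            p1 <- pick(); p2 <- pick()
            if (stats::runif(1) < ga$crossover_rate) {
              # BLX-alpha blend, alpha = 0.5
              lo <- pmin(p1, p2); hi <- pmax(p1, p2); r <- hi - lo
              child <- stats::runif(d, lo - 0.5 * r, hi + 0.5 * r)
            } else {
              child <- p1
            }
            mut <- stats::runif(d) < ga$mutation_rate
            if (any(mut)) {
              child[mut] <- child[mut] +
                stats::rnorm(sum(mut), 0, ga$mutation_sd * trange[mut])
            }
            child <- pmin(pmax(child, tlo), thi)
          }
          new_pop[i, ] <- child
          new_obj[i] <- safe_fn(child)
        }
        pop <- new_pop
        obj <- new_obj
        trace[gen] <- min(obj)
      }
      list(pop = pop, obj = obj, trace = trace)
    }

    polish_one <- function(th0) {
      if (!is.null(residual_fn)) {
        res_t <- function(th) {
          r <- tryCatch(residual_fn(from_internal(th, space)),
                        error = function(e) NULL)
          if (is.null(r) || any(!is.finite(r))) rep(1e3, n_res) else r
        }
        ans <- tryCatch(
          minpack.lm::nls.lm(par = th0, lower = tlo, upper = thi,
                             fn = res_t,
                             control = minpack.lm::nls.lm.control(
                               maxiter = config$nlls$maxiter,
                               ftol = config$nlls$ftol)),
          error = function(e) NULL)
        if (is.null(ans)) return(NULL)
        list(par = pmin(pmax(ans$par, tlo), thi),
             ok = ans$info %in% 1:4)
      } else {
        ans <- tryCatch(
          stats::nlminb(th0, safe_fn, lower = tlo, upper = thi,
                        control = list(iter.max = config$nlls$maxiter)),
          error = function(e) NULL)
        if (is.null(ans)) return(NULL)
        list(par = ans$par, ok = ans$convergence == 0)
      }
    }

    # alternating GA / least-squares phases: each polished incumbent is
    # re-injected so the population can recombine around it
    n_phase <- max(1L, ga$phases)
    gens_each <- diff(round(seq(0, ga$generations, length.out = n_phase + 1)))
    trace <- numeric(0)
    for (ph in seq_len(n_phase)) {
      if (gens_each[ph] > 0) {
        res <- ga_round(pop, obj, gens_each[ph])
        pop <- res$pop; obj <- res$obj
        trace <- c(trace, res$trace)
      }
      if (ph < n_phase) {
        best_i <- which.min(obj)
        pr <- polish_one(pop[best_i, ])
        if (!is.null(pr)) {
          pobj <- safe_fn(pr$par)
          if (is.finite(pobj) && pobj < obj[best_i]) {
            worst <- which.max(obj)
            pop[worst, ] <- pr$par
            obj[worst] <- pobj
          }
        }
      }
    }

    # final polish of the incumbent plus well-separated alternatives
    # (separation in the transformed space keeps this a true multi-start),
    # topped up with fresh random starts as basin-escape insurance
    ord <- order(obj)
    n_polish <- min(ga$polish_top, ga$pop_size)
    sel <- ord[1]
    for (i in ord[-1]) {
      if (length(sel) >= n_polish) break
      dmin <- min(sqrt(colSums((t(pop[sel, , drop = FALSE]) - pop[i, ])^2)))
      if (dmin > 0.5) sel <- c(sel, i)
    }
    fresh <- t(replicate(2, tlo + stats::runif(d) * trange))
    starts <- rbind(pop[sel, , drop = FALSE], fresh)
    start_obj <- c(obj[sel], apply(fresh, 1, safe_fn))

    polished <- vector("list", nrow(starts))
    for (i in seq_len(nrow(starts))) {
      r <- polish_one(starts[i, ])
      if (is.null(r)) {
        polished[[i]] <- list(par = starts[i, ], obj = start_obj[i], ok = FALSE)
      } else {
        polished[[i]] <- list(par = r$par, obj = safe_fn(r$par), ok = r$ok)
      }
    }
    # GA best competes too, in case a polish diverged
    polished[[length(polished) + 1L]] <- list(par = pop[ord[1], ],
                                              obj = obj[ord[1]], ok = TRUE)

    objs <- vapply(polished, `[[`, 0, "obj")
    if (all(!is.finite(objs))) {
      cond <- simpleError("optimization failed: no start converged to a finite objective")
      cond$trace <- trace
      stop(cond)
    }
    best_obj <- min(objs)
    tied <- which(objs <= best_obj + 1e-12 * max(1, abs(best_obj)))
    norms <- vapply(tied, function(i) sqrt(sum(polished[[i]]$par^2)), 0)
    winner <- polished[[tied[which.min(norms)]]]

    # bound release: a polish ending pinned to the box boundary usually
    # marks a spurious optimum (e.g. a rate pair driven to a fast
    # equilibrium); re-center pinned parameters and re-polish
    # (intermediate release rounds may transiently worsen the objective on
    # the way out of the spurious basin, so the walk continues either way
    # and only the final best is adopted)
    th <- winner$par
    for (round in 1:4) {
      pinned <- th > thi - 1e-4 * trange | th < tlo + 1e-4 * trange
      if (!any(pinned)) break
      th_try <- th
      th_try[pinned] <- if (round == 1L) {
        (tlo[pinned] + thi[pinned]) / 2
      } else {
        # later rounds re-center at random interior points in case the
        # midpoint restart fell straight back into the same basin
        tlo[pinned] + stats::runif(sum(pinned), 0.2, 0.8) * trange[pinned]
      }
      pr <- polish_one(th_try)
      if (is.null(pr)) break
      th <- pr$par
      pobj <- safe_fn(pr$par)
      if (is.finite(pobj) && pobj < winner$obj * (1 - 1e-12)) {
        winner <- list(par = pr$par, obj = pobj, ok = pr$ok)
      }
    }

    list(par = from_internal(winner$par, space),
         objective = winner$obj,
         trace = trace,
         convergence = isTRUE(winner$ok),
         polished = data.frame(
           objective = objs,
           converged = vapply(polished, `[[`, TRUE, "ok")))
  })
}

# fast residual closure for the optimizer: precomputes generator-matrix
# fill indices, the initial-state template and band row groupings once, so
# each evaluation is one compiled linear solve plus a row-group sum.
# Numerically identical to timecourse_residuals() (asserted in the tests).
make_residual_closure <- function(data, scheme, fitted_bands) {
  bands <- intersect(as.character(fitted_bands), rownames(data$bands))
  obs <- data$bands[bands, , drop = FALSE]
  times <- data$times
  nm <- scheme$species$name
  n <- length(nm)
  i_from <- match(scheme$transitions$from, nm)
  i_to <- match(scheme$transitions$to, nm)
  rate_idx_names <- scheme$transitions$rate_name
  off_idx <- cbind(i_to, i_from)
  len <- scheme$species$rna_length
  band_rows <- lapply(bands, function(b) which(!is.na(len) & len == as.integer(b)))
  is_s4 <- scheme$scheme_id == "S4"
  i_ec10 <- match("EC10", nm)
  i_ec10i <- match("EC10i", nm)

  function(params) {
    rates <- unname(params[rate_idx_names])
    K <- matrix(0, n, n)
    for (j in seq_along(rates)) {
      K[i_to[j], i_from[j]] <- K[i_to[j], i_from[j]] + rates[j]
      K[i_from[j], i_from[j]] <- K[i_from[j], i_from[j]] - rates[j]
    }
    x0 <- numeric(n)
    if (is_s4) {
      f <- params[["f_inactive"]]
      x0[i_ec10] <- 1 - f
      x0[i_ec10i] <- f
    } else {
      x0[i_ec10] <- 1
    }
    st <- .solve_linear_cpp(K, x0, times)
    model <- do.call(rbind, lapply(band_rows, function(r) {
      if (length(r) == 1L) st[r, ] else colSums(st[r, , drop = FALSE])
    }))
    as.numeric(t(obs - model))
  }
}

#' Globally fit a kinetic scheme to one replicate's time courses
#'
#' Fits a single shared rate-parameter set to all fitted band time courses
#' of one replicate simultaneously, by running [hybrid_optimize()] over
#' [timecourse_ssr()]. Degenerate inputs (all fitted-band fractions zero)
#' are rejected up front rather than silently "fit".
#'
#' @param data an `observed_timecourse`.
#' @param scheme a `kinetic_scheme`.
#' @param config a [fit_config()].
#' @return a `fit_result`: list with `scheme_id`, `params` (named best-fit
#'   rates), `ssr`, `n_obs`, `n_params`, `trace`, `convergence`.
#' @export
fit_global <- function(data, scheme, config = fit_config()) {
  stopifnot(inherits(data, "observed_timecourse"),
            inherits(scheme, "kinetic_scheme"))
  bands <- intersect(as.character(config$fitted_bands), rownames(data$bands))
  if (!length(bands)) stop("no fitted band present in the data", call. = FALSE)
  obs <- data$bands[bands, , drop = FALSE]
  if (all(obs == 0)) {
    stop("degenerate data: all fitted band fractions are zero", call. = FALSE)
  }
  space <- param_space(scheme, config)
  n_obs <- length(obs)
  n_par <- length(space$names)
  if (n_obs <= n_par) {
    stop(sprintf("underdetermined fit: %d observations for %d parameters",
                 n_obs, n_par), call. = FALSE)
  }
  # larger parameter spaces (the 18-parameter reversible chain) need a
  # larger evolutionary budget to reach the global optimum reliably; scale
  # any GA settings the caller left at their defaults
  user_set <- attr(config$ga, "user_set") %||% character(0)
  scaled <- list(pop_size = max(48L, 4L * n_par),
                 generations = max(60L, 5L * n_par),
                 phases = if (n_par > 14L) 4L else 3L,
                 polish_top = max(5L, ceiling(n_par / 3)))
  for (nm in names(scaled)) {
    if (!nm %in% user_set) config$ga[[nm]] <- scaled[[nm]]
  }

  rf <- make_residual_closure(data, scheme, config$fitted_bands)
  fn <- function(p) { r <- rf(p); sum(r * r) }
  opt <- hybrid_optimize(fn, stats::setNames(space$lower, space$names),
                         stats::setNames(space$upper, space$names),
                         config, log_scale = space$log_scale,
                         residual_fn = rf, par_names = space$names)
  structure(list(scheme_id = scheme$scheme_id,
                 params = opt$par,
                 ssr = timecourse_ssr(data, scheme, opt$par,
                                      config$fitted_bands),
                 n_obs = n_obs,
                 n_params = n_par,
                 trace = opt$trace,
                 convergence = opt$convergence,
                 condition = data$condition,
                 replicate = data$replicate),
            class = "fit_result")
}

#' Fit every replicate of a replicate set individually
#'
#' Replicates are fit one at a time with [fit_global()] (the study's
#' convention: each independent reaction is fit, then parameters are
#' averaged across fits). Each replicate gets a distinct deterministic
#' optimizer seed derived from `config$seed`.
#'
#' @param reps a `replicate_set`.
#' @param scheme scheme to fit; defaults to the generating scheme recorded
#'   in the set's scenario, when present.
#' @param config a [fit_config()].
#' @return list of `fit_result`, one per replicate.
#' @export
fit_replicates <- function(reps, scheme = NULL, config = fit_config()) {
  stopifnot(inherits(reps, "replicate_set"))
  if (is.null(scheme)) {
    if (is.null(reps$scenario)) {
      stop("scheme must be given for external data", call. = FALSE)
    }
    scheme <- build_scheme(reps$scenario$scheme_id)
  }
  lapply(seq_along(reps$replicates), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + 7919L * i
    fit_global(reps$replicates[[i]], scheme, cfg_i)
  })
}

#' Aggregate per-replicate fits into mean and SD per parameter
#'
#' Reproduces the replicate reporting convention: each replicate is fit
#' individually, then each kinetic parameter's arithmetic mean and sample
#' standard deviation (n - 1 denominator) across fits are reported.
#'
#' @param fits list of `fit_result` sharing a scheme and parameter names.
#' @return an `aggregated_fit`: list with `fits`, `mean`, `sd` (named; `sd`
#'   is `NA` with a flag when only one fit is supplied) and `n`.
#' @export
aggregate_replicates <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "fit_result")))
  ids <- unique(vapply(fits, `[[`, "", "scheme_id"))
  if (length(ids) != 1L) stop("fits mix schemes: ", paste(ids, collapse = ", "),
                              call. = FALSE)
  nm <- names(fits[[1]]$params)
  same <- vapply(fits, function(f) identical(names(f$params), nm), TRUE)
  if (!all(same)) stop("fits have mismatched parameter sets", call. = FALSE)
  P <- do.call(rbind, lapply(fits, `[[`, "params"))
  n <- nrow(P)
  structure(list(fits = fits,
                 scheme_id = ids,
                 mean = colMeans(P),
                 sd = if (n >= 2L) apply(P, 2, stats::sd)
                      else stats::setNames(rep(NA_real_, length(nm)), nm),
                 n = n),
            class = "aggregated_fit")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: ssr %.4g over %d obs, %d params%s>\n",
              x$scheme_id, x$ssr, x$n_obs, x$n_params,
              if (x$convergence) "" else " [not converged]"))
  print(signif(x$params, 4))
  invisible(x)
}

#' @export
print.aggregated_fit <- function(x, ...) {
  cat(sprintf("<aggregated_fit %s: %d replicate fits>\n", x$scheme_id, x$n))
  print(data.frame(mean = signif(x$mean, 4), sd = signif(x$sd, 3)))
  invisible(x)
}
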