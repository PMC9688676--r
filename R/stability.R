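#' Fraction of collapsed elongation complexes in one gel lane
#'
#' In the RNase-protection stability assay an intact elongation complex
#' protects its 10-mer RNA from RNase A; a disassembled complex exposes it,
#' yielding a 7-mer. The collapse fraction of a lane is
#' `signal(7-mer) / (signal(7-mer) + signal(10-mer))`, which is invariant to
#' overall lane exposure (scaling both signals by any c > 0).
#'
#' @param signal_7mer,signal_10mer nonnegative band signals (vectorized).
#' @return collapse fraction(s) in \[0, 1\].
#' @export
#' @examples
#' collapse_fraction(50, 50)   # half collapsed
#' collapse_fraction(100, 0)   # fully collapsed
collapse_fraction <- function(signal_7mer, signal_10mer) {
  stopifnot(all(signal_7mer >= 0), all(signal_10mer >= 0))
  tot <- signal_7mer + signal_10mer
  if (any(tot <= 0)) {
    stop("undefined lane: total band signal must be positive", call. = FALSE)
  }
  signal_7mer / tot
}

#' Analyze an elongation-complex stability assay
#'
#' Takes long-format lane data (`time_s`, `band` in \{7, 10\}, `signal`,
#' `condition`, `replicate`), computes each lane's collapse fraction,
#' averages over replicates per condition, and contrasts conditions: the
#' maximum over time of the absolute difference of condition means. The
#' verdict is `"unaffected"` when the difference stays below
#' `sd_mult` replicate standard deviations at every shared time point,
#' mirroring the assay's null conclusion (EC stability unchanged by drug
#' treatment).
#'
#' Optionally fits a single-exponential rise to plateau
#' `f(t) = f0 + A (1 - exp(-k t))` per condition (reusing
#' [hybrid_optimize()]), reporting the decay rate `k` (s^-1), half-life
#' `ln(2)/k` and plateau `f0 + A`. The exponential is a descriptive
#' convenience, not a mechanistic model, and is off by default.
#'
#' @param lanes data frame with columns `time_s`, `band`, `signal`,
#'   `condition`, `replicate`.
#' @param fit_decay fit the exponential collapse model per condition.
#' @param sd_mult SD multiplier of the "unaffected" threshold (default 2).
#' @param config [fit_config()] used for the optional decay fit.
#' @return a `stability_analysis`: per-condition `curves` (data frames:
#'   `time_s`, `mean`, `sd`, `n`), optional `decay_fits`, and when exactly
#'   two conditions are present a `contrast` list with `max_abs_diff`,
#'   `unaffected` verdict and per-time table.
#' @export
analyze_stability <- function(lanes, fit_decay = FALSE, sd_mult = 2,
                              config = fit_config(ga = list(pop_size = 24L,
                                                            generations = 30L))) {
  need <- c("time_s", "band", "signal", "condition", "replicate")
  missing <- setdiff(need, names(lanes))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(lanes$band %in% c(7, 10))) {
    stop("stability lanes carry only 7-mer and 10-mer bands", call. = FALSE)
  }
  wide <- stats::reshape(
    lanes[, need], direction = "wide", idvar = c("time_s", "condition", "replicate"),
    timevar = "band", v.names = "signal")
  if (!all(c("signal.7", "signal.10") %in% names(wide))) {
    stop("each lane needs both a 7-mer and a 10-mer signal", call. = FALSE)
  }
  wide$fraction <- collapse_fraction(wide$signal.7, wide$signal.10)

  conds <- unique(wide$condition)
  curves <- lapply(conds, function(cn) {
    w <- wide[wide$condition == cn, ]
    if (length(unique(w$time_s)) < 2L) {
      stop("need at least two time points per condition", call. = FALSE)
    }
    agg <- do.call(rbind, lapply(split(w, w$time_s), function(g) {
      data.frame(time_s = g$time_s[1], mean = mean(g$fraction),
                 sd = if (nrow(g) >= 2L) stats::sd(g$fraction) else NA_real_,
                 n = nrow(g))
    }))
    agg[order(agg$time_s), , drop = FALSE]
  })
  names(curves) <- conds

  out <- list(curves = curves)

  if (length(conds) == 2L) {
    t1 <- curves[[1]]$time_s; t2 <- curves[[2]]$time_s
    shared <- intersect(t1, t2)
    if (!length(shared)) {
      stop("conditions have disjoint time grids; cannot contrast",
           call. = FALSE)
    }
    a <- curves[[1]][match(shared, t1), ]
    b <- curves[[2]][match(shared, t2), ]
    diff <- a$mean - b$mean
    pooled_sd <- sqrt((ifelse(is.na(a$sd), 0, a$sd)^2 +
                         ifelse(is.na(b$sd), 0, b$sd)^2) / 2)
    within <- abs(diff) <= sd_mult * pooled_sd
    out$contrast <- list(
      conditions = conds,
      table = data.frame(time_s = shared, diff = diff, pooled_sd = pooled_sd,
                         within_band = within),
      max_abs_diff = max(abs(diff)),
      unaffected = all(within))
  }

  if (fit_decay) {
    out$decay_fits <- lapply(curves, function(cv) {
      fit_exponential_collapse(cv$time_s, cv$mean, config)
    })
  }
  structure(out, class = "stability_analysis")
}

# f(t) = f0 + A (1 - exp(-k t)); k log-scaled, f0/A linear in [0, 1]
fit_exponential_collapse <- function(times, fractions, config) {
  stopifnot(length(times) >= 3L)
  tmax <- max(times)
  lower <- c(k = 1e-5, f0 = 0, A = 0)
  upper <- c(k = 1e3, f0 = 1, A = 1)
  model <- function(p) p[["f0"]] + p[["A"]] * (1 - exp(-p[["k"]] * times))
  rf <- function(p) fractions - model(p)
  fn <- function(p) sum(rf(p)^2)
  opt <- hybrid_optimize(fn, lower, upper, config,
                         log_scale = c(TRUE, FALSE, FALSE),
                         residual_fn = rf, par_names = names(lower))
  k <- opt$par[["k"]]
  list(params = opt$par, ssr = opt$objective,
       rate = k, half_life = log(2) / k,
       plateau = opt$par[["f0"]] + opt$par[["A"]])
}

#' Simulate a synthetic stability assay
#'
#' Generates long-format stability lanes whose collapse fraction follows a
#' single-exponential rise `f(t) = f0 + A (1 - exp(-k t))` with additive
#' truncated Gaussian noise, as a stand-in for undeposited stability gels.
#' Total lane signal is fixed at 100 arbitrary units and split between the
#' 7-mer and 10-mer bands according to the noisy collapse fraction.
#'
#' @param k collapse rate constant (s^-1).
#' @param times seconds since the RNase/high-salt challenge.
#' @param f0 initial collapse fraction.
#' @param A collapse amplitude (plateau is `f0 + A`).
#' @param n_replicates replicates per time point.
#' @param noise_sd SD of the additive fraction noise.
#' @param condition condition label.
#' @param seed integer seed.
#' @return data frame of lanes (`time_s`, `band`, `signal`, `condition`,
#'   `replicate`).
#' @export
simulate_stability <- function(k, times, f0 = 0, A = 0.9,
                               n_replicates = 3L, noise_sd = 0.02,
                               condition = "vehicle", seed = 1L) {
  stopifnot(k >= 0, all(times >= 0), f0 >= 0, A >= 0, f0 + A <= 1)
  truth <- f0 + A * (1 - exp(-k * times))
  rows <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      frac <- pmin(pmax(truth + stats::rnorm(length(times), 0, noise_sd),
                        0), 1)
      data.frame(time_s = rep(times, 2L),
                 band = rep(c(7L, 10L), each = length(times)),
                 signal = c(100 * frac, 100 * (1 - frac)),
                 condition = condition,
                 replicate = r)
    }))
  })
  rownames(rows) <- NULL
  rows
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat(sprintf("<stability_analysis: %d condition(s)>\n", length(x$curves)))
  if (!is.null(x$contrast)) {
    cat(sprintf("  max |condition difference| = %.4f -> %s\n",
                x$contrast$max_abs_diff,
                if (x$contrast$unaffected) "unaffected" else "affected"))
  }
  if (!is.null(x$decay_fits)) {
    for (cn in names(x$decay_fits)) {
      f <- x$decay_fits[[cn]]
      cat(sprintf("  %s: k = %.4g s^-1 (half-life %.3g s), plateau %.3f\n",
                  cn, f$rate, f$half_life, f$plateau))
    }
  }
  invisible(x)
}
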