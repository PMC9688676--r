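#' Small-sample corrected Akaike information criterion for an SSR fit
#'
#' `AICc = n log(ssr/n) + 2p + 2p(p+1)/(n - p - 1)` for a least-squares fit
#' with `n` fitted observations and `p` free parameters (Gaussian
#' likelihood, constant-variance form). AICc is used over an F-test because
#' the nested schemes differ by rates pinned at the boundary (rate = 0),
#' which violates the regularity conditions of the nested-F comparison.
#'
#' @param ssr nonnegative sum of squared residuals.
#' @param n number of fitted observations.
#' @param p number of fitted parameters.
#' @return scalar AICc (`-Inf` for an exactly zero SSR).
#' @export
aicc <- function(ssr, n, p) {
  stopifnot(ssr >= 0, n >= 1, p >= 1)
  if (n <= p + 1) {
    stop("AICc undefined: need n > p + 1 observations", call. = FALSE)
  }
  n * log(ssr / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# Wald-Wolfowitz-style runs diagnostic on a residual sign sequence:
# z-score of the observed number of sign runs against randomness.
runs_zscore <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  runs <- 1 + sum(s[-1] != s[-length(s)])
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(NA_real_)
  (runs - mu) / sqrt(v)
}

#' Compare candidate kinetic schemes on one time course
#'
#' Fits each candidate scheme to the same data with [fit_global()] and
#' adjudicates by AICc. Alongside the formal criterion the comparison
#' reports the qualitative failure signature that motivates the paused-state
#' scheme: systematic positive late-time residuals on the 11- and 12-mer
#' bands (a simple chain's best fit falls back to baseline while the
#' observed bands persist), plus a per-band runs diagnostic of residual
#' structure.
#'
#' @param data an `observed_timecourse`.
#' @param candidates list of at least two `kinetic_scheme`s.
#' @param config a [fit_config()].
#' @return a `model_comparison`: per-scheme `fits`, `aicc`, `delta_aicc`,
#'   `preferred` scheme id, `tie` flag, and `diagnostics` (per scheme:
#'   late-time mean residual on bands 11–12 and per-band runs z-scores).
#' @export
compare_schemes <- function(data, candidates, config = fit_config()) {
  stopifnot(length(candidates) >= 2L,
            all(vapply(candidates, inherits, TRUE, "kinetic_scheme")))
  ids <- vapply(candidates, `[[`, "", "scheme_id")
  if (anyDuplicated(ids)) stop("duplicate candidate scheme ids", call. = FALSE)

  fits <- lapply(candidates, function(s) fit_global(data, s, config))
  names(fits) <- ids
  ic <- vapply(fits, function(f) aicc(f$ssr, f$n_obs, f$n_params), 0)
  delta <- ic - min(ic)
  preferred <- ids[which.min(ic)]
  tie <- sum(delta < 1e-9) > 1L

  diagnostics <- lapply(seq_along(candidates), function(i) {
    r <- timecourse_residuals(data, candidates[[i]], fits[[i]]$params,
                              config$fitted_bands)
    bands <- attr(r, "bands")
    nt <- length(attr(r, "times"))
    R <- matrix(r, nrow = nt)
    late <- seq.int(ceiling(2 * nt / 3), nt)
    pause_bands <- bands %in% c("11", "12")
    late_mean <- if (any(pause_bands)) {
      mean(R[late, pause_bands, drop = FALSE])
    } else NA_real_
    runs <- apply(R, 2, runs_zscore)
    names(runs) <- bands
    list(late_mean_residual_11_12 = late_mean, runs_z = runs)
  })
  names(diagnostics) <- ids

  structure(list(fits = fits, aicc = ic, delta_aicc = delta,
                 preferred = preferred, tie = tie,
                 diagnostics = diagnostics),
            class = "model_comparison")
}

#' Compare candidate schemes across all replicates of an experiment
#'
#' Runs [compare_schemes()] on each replicate independently (each with its
#' own deterministic optimizer seed) and adjudicates on the summed AICc:
#' replicates are independent reactions, so their information-criterion
#' evidence adds. A single 20-point time course can carry only marginal
#' evidence against a 4-parameter elaboration; the full 3-replicate
#' experiment decides far more reliably.
#'
#' @param reps a `replicate_set`.
#' @param candidates list of at least two `kinetic_scheme`s.
#' @param config a [fit_config()].
#' @return a `model_comparison_set`: `per_replicate` comparisons, summed
#'   `aicc`, `delta_aicc`, `preferred`, `tie`.
#' @export
compare_schemes_replicates <- function(reps, candidates,
                                       config = fit_config()) {
  stopifnot(inherits(reps, "replicate_set"))
  comps <- lapply(seq_along(reps$replicates), function(i) {
    cfg <- config
    cfg$seed <- config$seed + 31L * i
    compare_schemes(reps$replicates[[i]], candidates, cfg)
  })
  total <- Reduce(`+`, lapply(comps, `[[`, "aicc"))
  delta <- total - min(total)
  structure(list(per_replicate = comps, aicc = total, delta_aicc = delta,
                 preferred = names(total)[which.min(total)],
                 tie = sum(delta < 1e-9) > 1L),
            class = "model_comparison_set")
}

#' @export
print.model_comparison_set <- function(x, ...) {
  cat(sprintf("<model_comparison_set: %d replicates>\n",
              length(x$per_replicate)))
  print(data.frame(scheme = names(x$aicc), total_aicc = x$aicc,
                   delta = x$delta_aicc), row.names = FALSE)
  cat("preferred:", x$preferred, if (x$tie) "(tie)" else "", "\n")
  invisible(x)
}

#' Summary statistics of a fitted kinetic parameter set
#'
#' Computes the derived quantities used to compare conditions:
#'
#' * `mean_kobs` — arithmetic mean of the nine nucleotide-addition rate
#'   constants `k1..k9` (s^-1). The nuclease (`k10`) and activation
#'   (`kact`) parameters are excluded: the averaged quantity concerns
#'   nucleotide-addition steps only.
#' * `fold_change` — per-parameter `reference / fit` ratio against a
#'   reference fit (e.g. vehicle vs drug), when a reference is supplied.
#' * `fr_ratio` — per-step forward/reverse ratio `kF_i / kR_i` for
#'   reversible (Pol II) fits, the tabulated comparison convention.
#'
#' @param fit an `aggregated_fit` or `fit_result`.
#' @param reference optional reference fit of the same scheme for fold
#'   changes.
#' @return a `kinetic_summary` list with `mean_kobs`, optional
#'   `relative_reduction` (vs reference mean), `fold_change`, `fr_ratio`.
#' @export
#' @examples
#' # mean of nine identical 49 s^-1 steps is 49
summarize_kinetics <- function(fit, reference = NULL) {
  get_par <- function(f) {
    if (inherits(f, "aggregated_fit")) f$mean
    else if (inherits(f, "fit_result")) f$params
    else if (is.numeric(f) && !is.null(names(f))) f
    else stop("fit must be an aggregated_fit, fit_result or named vector",
              call. = FALSE)
  }
  p <- get_par(fit)
  k_add <- sprintf("k%d", 1:9)
  kF <- sprintf("kF%d", 1:9)
  kR <- sprintf("kR%d", 1:9)

  out <- list()
  if (all(k_add %in% names(p))) {
    out$mean_kobs <- mean(p[k_add])
  } else if (all(kF %in% names(p))) {
    out$mean_kobs <- mean(p[kF])
  } else {
    out$mean_kobs <- NA_real_
  }

  if (all(c(kF, kR) %in% names(p))) {
    r <- p[kF] / p[kR]
    r[p[kR] <= 0] <- NA_real_
    names(r) <- sprintf("step%d", 1:9)
    out$fr_ratio <- r
  }

  if (!is.null(reference)) {
    pr <- get_par(reference)
    shared <- intersect(names(p), names(pr))
    shared <- shared[p[shared] > 0]
    out$fold_change <- pr[shared] / p[shared]
    ref_summary <- summarize_kinetics(pr)
    if (is.finite(ref_summary$mean_kobs) && ref_summary$mean_kobs > 0 &&
        is.finite(out$mean_kobs)) {
      out$relative_reduction <-
        (ref_summary$mean_kobs - out$mean_kobs) / ref_summary$mean_kobs
    }
  }
  structure(out, class = "kinetic_summary")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  tab <- data.frame(scheme = names(x$aicc),
                    ssr = vapply(x$fits, `[[`, 0, "ssr"),
                    aicc = x$aicc, delta = x$delta_aicc)
  print(tab, row.names = FALSE)
  cat("preferred:", x$preferred, if (x$tie) "(tie)" else "", "\n")
  invisible(x)
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat("<kinetic_summary>\n")
  cat(sprintf("  mean k_obs (addition steps): %.3g s^-1\n", x$mean_kobs))
  if (!is.null(x$relative_reduction)) {
    cat(sprintf("  reduction vs reference: %.1f%%\n",
                100 * x$relative_reduction))
  }
  if (!is.null(x$fr_ratio)) {
    cat("  forward/reverse ratios:\n")
    print(signif(x$fr_ratio, 3))
  }
  invisible(x)
}
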