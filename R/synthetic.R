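#' Define a synthetic quench-flow scenario
#'
#' A scenario bundles everything needed to emulate one polymerase/condition
#' arm of the quench-flow multi-nucleotide addition experiment: the kinetic
#' scheme, the generating ("true") rate constants, the sampling time grid
#' inside the instrument's 0.005–10 s window, the number of independent
#' replicate reactions, and the band-fraction noise level.
#'
#' @param name short identifier, e.g. `"pol1_vehicle"`.
#' @param scheme_id scheme to simulate under (`"S1"`.."S4"`).
#' @param true_params named generating rate constants (see [rate_params()]).
#' @param time_grid seconds; must lie within \[0.005, 10\].
#' @param n_replicates independent replicate reactions (default 3).
#' @param noise_sd standard deviation of the additive band-fraction noise
#'   (default 0.02).
#' @param condition_label free-text condition tag.
#' @return an object of class `scenario`.
#' @export
scenario <- function(name, scheme_id, true_params, time_grid,
                     n_replicates = 3L, noise_sd = 0.02,
                     condition_label = name) {
  stopifnot(is.character(name), length(name) == 1L,
            scheme_id %in% SCHEME_IDS,
            is.numeric(time_grid), length(time_grid) >= 2L,
            n_replicates >= 1L, noise_sd >= 0)
  if (any(time_grid < 0.005 - 1e-12) || any(time_grid > 10 + 1e-12)) {
    stop("time_grid must lie within the 0.005-10 s quench-flow window",
         call. = FALSE)
  }
  true_params <- rate_params(unlist(true_params))
  scheme <- build_scheme(scheme_id)
  missing <- setdiff(free_params(scheme), names(true_params))
  if (length(missing)) {
    stop("true_params missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, scheme_id = scheme_id,
                 true_params = true_params,
                 time_grid = as.numeric(time_grid),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd,
                 condition_label = condition_label),
            class = "scenario")
}

#' Log-spaced quench-flow time grid
#'
#' @param n number of points (default 20).
#' @param t_min,t_max window endpoints in seconds (defaults 0.005 and 10,
#'   the instrument's sampling window).
#' @return numeric vector of `n` log-spaced times with exact endpoints.
#' @export
quench_flow_grid <- function(n = 20L, t_min = 0.005, t_max = 10) {
  g <- exp(seq(log(t_min), log(t_max), length.out = n))
  g[1] <- t_min
  g[n] <- t_max
  g
}

#' Default synthetic scenarios for the six polymerase/condition arms
#'
#' Six scenarios emulating the study conditions: Pol I vehicle (`S1`) and
#' Pol I + BMH-21 (`S2`, strong pausing at the 11-/12-mer), Pol II vehicle
#' and + BMH-21 (`S3`, identical rate constants — the drug leaves Pol II
#' unaffected), Pol III vehicle and + BMH-21 (`S4`). Each uses 3 replicates,
#' 20 log-spaced time points over 0.005–10 s and band-fraction noise of
#' SD 0.02.
#'
#' Anchors taken from the study's printed summary relationships:
#' * Pol III mean nucleotide-addition rate constants are exactly
#'   49 s^-1 (vehicle) and 39 s^-1 (BMH-21) — the reported ~20% reduction.
#' * Pol I + BMH-21 rate constants for the 13-mer and 14-mer appearance
#'   steps are less than half their vehicle values (the reported > 2-fold
#'   reduction).
#' * Pol I is the fastest polymerase, Pol II the slowest.
#'
#' All other values are invented regimes of realistic magnitude, not
#' reproductions of the study's fitted tables (the raw data are not
#' deposited).
#'
#' @return named list of six `scenario` objects.
#' @export
#' @examples
#' sc <- default_scenarios()
#' mean(sc$pol3_vehicle$true_params[sprintf("k%d", 1:9)])  # 49
default_scenarios <- function() {
  grid <- quench_flow_grid()
  k9 <- function(x) stats::setNames(x, sprintf("k%d", 1:9))

  pol1_veh <- c(k9(c(75, 70, 80, 60, 65, 55, 50, 45, 40)), k10 = 0.2)
  pol1_bmh <- c(k9(c(40, 35, 30, 25, 35, 30, 28, 26, 24)), k10 = 0.2,
                kon1 = 20, koff1 = 0.5, kon2 = 15, koff2 = 0.6)
  pol2 <- c(stats::setNames(c(12, 10, 11, 9, 10, 8, 9, 8, 7),
                            sprintf("kF%d", 1:9)),
            stats::setNames(c(2, 1.5, 2, 1.8, 1.5, 1.2, 1.5, 1.3, 1),
                            sprintf("kR%d", 1:9)))
  # Pol III means constrained exactly: sum(k1..k9) = 441 and 351
  pol3_veh <- c(k9(c(60, 55, 58, 50, 48, 45, 44, 42, 39)), k10 = 0.3,
                kact = 8, f_inactive = 0.3)
  pol3_bmh <- c(k9(c(48, 44, 40, 38, 39, 36, 38, 35, 33)), k10 = 0.3,
                kact = 8, f_inactive = 0.3)

  list(
    pol1_vehicle = scenario("pol1_vehicle", "S1", pol1_veh, grid,
                            condition_label = "vehicle"),
    pol1_bmh21   = scenario("pol1_bmh21", "S2", pol1_bmh, grid,
                            condition_label = "BMH-21 1 uM"),
    pol2_vehicle = scenario("pol2_vehicle", "S3", pol2, grid,
                            condition_label = "vehicle"),
    pol2_bmh21   = scenario("pol2_bmh21", "S3", pol2, grid,
                            condition_label = "BMH-21 1 uM"),
    pol3_vehicle = scenario("pol3_vehicle", "S4", pol3_veh, grid,
                            condition_label = "vehicle"),
    pol3_bmh21   = scenario("pol3_bmh21", "S4", pol3_bmh, grid,
                            condition_label = "BMH-21 1 uM"))
}

# run code with a temporary RNG state derived from `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a noisy replicate dataset from a scenario
#'
#' Computes the noiseless band fractions with [solve_timecourse()] and
#' [project_observables()], then adds independent Gaussian noise
#' (SD = `scenario$noise_sd`) to every band at every time, truncating to
#' \[0, 1\]. The noise emulates phosphorimager quantification error, which is
#' approximately signal-independent at the band-fraction scale; lanes are not
#' renormalized after noising unless `renormalize = TRUE`.
#'
#' One master seed is split into independent per-replicate streams, so
#' generation is deterministic given `(scenario, seed)` and replicate `i` of
#' a 3-replicate run equals replicate `i` of any larger run with the same
#' master seed.
#'
#' @param scenario a [scenario()].
#' @param seed integer master seed.
#' @param renormalize if `TRUE`, rescale each lane's bands to their
#'   pre-noise total after noising (default `FALSE`).
#' @return a `replicate_set`: list with `replicates` (list of
#'   `observed_timecourse`), the `scenario` and the `seed`.
#' @export
generate_dataset <- function(scenario, seed, renormalize = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  scheme <- build_scheme(scenario$scheme_id)
  traj <- solve_timecourse(scheme, scenario$true_params, scenario$time_grid)
  clean <- project_observables(traj, scenario$condition_label, 1L)

  rep_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max - 1L, scenario$n_replicates))

  replicates <- lapply(seq_len(scenario$n_replicates), function(i) {
    bands <- clean$bands
    if (scenario$noise_sd > 0) {
      noise <- with_seed(rep_seeds[i],
        matrix(stats::rnorm(length(bands), 0, scenario$noise_sd),
               nrow(bands), ncol(bands)))
      tot0 <- colSums(bands)
      bands <- pmin(pmax(bands + noise, 0), 1)
      if (renormalize) {
        tot <- colSums(bands)
        ok <- tot > 0
        bands[, ok] <- sweep(bands[, ok, drop = FALSE], 2,
                             tot0[ok] / tot[ok], `*`)
      }
    }
    # independent per-band noise can push a lane total above 1 by up to
    # ~sqrt(n_bands)*noise_sd; widen the sum check to a 6-sigma bound
    # (bands themselves stay in [0,1])
    new_observed_timecourse(scenario$time_grid, bands,
                            scenario$condition_label, i,
                            tol_sum = max(1e-9, 6 * sqrt(nrow(bands)) *
                                            scenario$noise_sd))
  })

  structure(list(replicates = replicates, scenario = scenario, seed = seed),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set: %d replicates of %s (%s), %d times>\n",
              length(x$replicates),
              if (!is.null(x$scenario)) x$scenario$name else "(external data)",
              x$replicates[[1]]$condition,
              length(x$replicates[[1]]$times)))
  invisible(x)
}

#' Read scenario definitions from a JSON file
#'
#' Scenario files hold the fields of [scenario()] (one object or a list of
#' objects), so custom simulation regimes can be supplied without code
#' changes.
#'
#' @param path JSON file path.
#' @return a named list of `scenario` objects.
#' @export
read_scenarios <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.null(obj$name)) obj <- list(obj)
  out <- lapply(obj, function(o) {
    scenario(o$name, o$scheme_id, unlist(o$true_params),
             as.numeric(o$time_grid),
             n_replicates = o$n_replicates %||% 3L,
             noise_sd = o$noise_sd %||% 0.02,
             condition_label = o$condition_label %||% o$name)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
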