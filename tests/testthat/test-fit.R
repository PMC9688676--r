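test_that("objective is zero at the generating parameters and sums squares", {
  p <- params_for("S1")
  otc <- noiseless_dataset("S1", p)
  s1 <- build_scheme("S1")
  expect_lt(timecourse_ssr(otc, s1, p), 1e-16)
  # offsetting one band by +0.1 over 20 times adds exactly 20 * 0.01
  shifted <- otc
  shifted$bands["13", ] <- pmin(shifted$bands["13", ] + 0.1, 1)
  # keep the shift exact (no values near 1 on this band)
  stopifnot(all(otc$bands["13", ] + 0.1 <= 1))
  expect_equal(timecourse_ssr(shifted, s1, p), 0.2, tolerance = 1e-12)
  # permutation of time points leaves the objective unchanged
  perm <- sample(length(otc$times))
  permuted <- otc
  permuted$times <- otc$times[perm]
  permuted$bands <- otc$bands[, perm]
  expect_equal(timecourse_ssr(permuted, s1, p), timecourse_ssr(otc, s1, p))
})

test_that("objective respects the fitted-band subset", {
  p <- params_for("S1")
  otc <- noiseless_dataset("S1", p)
  s1 <- build_scheme("S1")
  shifted <- otc
  shifted$bands["11", ] <- pmin(shifted$bands["11", ] + 0.05, 1)
  expect_gt(timecourse_ssr(shifted, s1, p, fitted_bands = 11:19), 0.01)
  expect_lt(timecourse_ssr(shifted, s1, p, fitted_bands = 12:19), 1e-16)
})

test_that("hybrid optimizer solves analytic benchmarks deterministically", {
  cfg <- fit_config(ga = list(pop_size = 30L, generations = 25L,
                              polish_top = 3L, phases = 2L), seed = 5)
  quad <- function(p) (p[["x"]] - 3)^2 + (p[["y"]] + 1)^2
  r <- hybrid_optimize(quad, c(x = -5, y = -5), c(x = 5, y = 5), cfg,
                       log_scale = c(FALSE, FALSE))
  expect_equal(unname(r$par), c(3, -1), tolerance = 1e-6)
  expect_lt(r$objective, 1e-10)
  rosen <- function(p) {
    100 * (p[["y"]] - p[["x"]]^2)^2 + (1 - p[["x"]])^2
  }
  r2 <- hybrid_optimize(rosen, c(x = -5, y = -5), c(x = 5, y = 5), cfg,
                        log_scale = c(FALSE, FALSE))
  expect_equal(unname(r2$par), c(1, 1), tolerance = 1e-3)
  # determinism under a fixed seed
  r3 <- hybrid_optimize(rosen, c(x = -5, y = -5), c(x = 5, y = 5), cfg,
                        log_scale = c(FALSE, FALSE))
  expect_identical(r2, r3)
  # the best-so-far trace never increases
  expect_true(all(diff(r2$trace) <= 1e-12))
})

test_that("noiseless S1 data round-trips through the global fit", {
  p <- params_for("S1")
  otc <- noiseless_dataset("S1", p)
  s1 <- build_scheme("S1")
  fit <- fit_global(otc, s1, quick_config(seed = 2))
  expect_true(fit$convergence)
  expect_lt(fit$ssr, 1e-10)
  rel <- abs(fit$params - p) / pmax(p, 1e-12)
  expect_lt(max(rel[sprintf("k%d", 1:9)]), 1e-3)
})

test_that("noiseless strong-pausing S2 data recovers the pause rates", {
  p <- params_for("S2")
  otc <- noiseless_dataset("S2", p)
  s2 <- build_scheme("S2")
  fit <- fit_global(otc, s2, fit_config(seed = 4))
  expect_lt(fit$ssr, 1e-6)
  pp <- c("kon1", "koff1", "kon2", "koff2")
  expect_lt(max(abs(fit$params[pp] - p[pp]) / p[pp]), 0.05)
})

test_that("noiseless S3 data recovers per-step forward/reverse ratios", {
  kF <- c(12, 10, 11, 9, 9.5, 8, 8.5, 7.5, 7)
  kR <- c(2, 1.5, 2, 1.8, 1.5, 1.2, 1.5, 1.3, 1)
  p <- rate_params(c(stats::setNames(kF, sprintf("kF%d", 1:9)),
                     stats::setNames(kR, sprintf("kR%d", 1:9))))
  otc <- noiseless_dataset("S3", p)
  s3 <- build_scheme("S3")
  fit <- fit_global(otc, s3, fit_config(seed = 6))
  got <- fit$params[sprintf("kF%d", 1:9)] / fit$params[sprintf("kR%d", 1:9)]
  expect_lt(max(abs(got - kF / kR) / (kF / kR)), 0.1)
})

test_that("optimizer residual closure equals the reference residuals", {
  sc <- default_scenarios()
  for (nm in c("pol1_bmh21", "pol2_vehicle", "pol3_vehicle")) {
    scheme <- build_scheme(sc[[nm]]$scheme_id)
    data <- generate_dataset(sc[[nm]], 42)$replicates[[1]]
    fast <- polkin:::make_residual_closure(data, scheme, 11:19)
    p <- sc[[nm]]$true_params
    ref <- as.numeric(timecourse_residuals(data, scheme, p))
    # the reference path clamps sub-1e-9 round-off negatives; agreement is
    # to solver precision rather than bitwise
    expect_lt(max(abs(fast(p) - ref)), 1e-12)
  }
})

test_that("degenerate all-zero data is rejected, not silently fit", {
  otc <- noiseless_dataset("S1")
  otc$bands[] <- 0
  expect_error(fit_global(otc, build_scheme("S1"), quick_config()),
               "degenerate")
})

test_that("replicate aggregation reports textbook means and SDs", {
  mk <- function(k) {
    structure(list(scheme_id = "S1",
                   params = stats::setNames(c(k, 2 * k), c("k1", "k2")),
                   ssr = 0.1, n_obs = 100, n_params = 2,
                   trace = 1, convergence = TRUE),
              class = "fit_result")
  }
  agg <- aggregate_replicates(list(mk(1), mk(2), mk(3)))
  expect_equal(unname(agg$mean), c(2, 4))
  expect_equal(unname(agg$sd), c(1, 2))
  expect_identical(agg$n, 3L)
  # single fit: mean passes through, SD flagged as NA
  one <- aggregate_replicates(list(mk(5)))
  expect_equal(unname(one$mean), c(5, 10))
  expect_true(all(is.na(one$sd)))
  # identical fits: zero spread
  same <- aggregate_replicates(list(mk(2), mk(2)))
  expect_equal(unname(same$sd), c(0, 0))
  # mismatched parameter sets are a schema error
  bad <- mk(1)
  names(bad$params) <- c("k1", "kX")
  expect_error(aggregate_replicates(list(mk(1), bad)), "mismatched")
})

test_that("hybrid search beats pure multi-start polishing on pausing data", {
  # the benchmark the GA earns its cost on: same number of least-squares
  # polishes from random starts, no evolutionary pre-search
  sc <- default_scenarios()
  ds <- generate_dataset(sc$pol1_bmh21, 77)
  data <- ds$replicates[[1]]
  s2 <- build_scheme("S2")
  cfg <- quick_config(seed = 9)
  fit <- fit_global(data, s2, cfg)

  space <- polkin:::param_space(s2, cfg)
  tlo <- ifelse(space$log_scale, log10(space$lower), space$lower)
  thi <- ifelse(space$log_scale, log10(space$upper), space$upper)
  rf_nat <- function(th) {
    p <- stats::setNames(ifelse(space$log_scale, 10^th, th), space$names)
    timecourse_residuals(data, s2, p, cfg$fitted_bands)
  }
  best_pure <- withr::with_seed(9, {
    n_starts <- cfg$ga$polish_top + cfg$ga$phases - 1L
    min(vapply(seq_len(n_starts), function(i) {
      th0 <- tlo + stats::runif(length(tlo)) * (thi - tlo)
      r <- tryCatch(
        minpack.lm::nls.lm(par = th0, lower = tlo, upper = thi, fn = rf_nat),
        error = function(e) NULL)
      if (is.null(r)) Inf else sum(r$fvec^2)
    }, 0))
  })
  expect_lte(fit$ssr, best_pure + 1e-9)
})
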