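test_that("default scenarios encode the study's anchor relationships", {
  sc <- default_scenarios()
  expect_named(sc, c("pol1_vehicle", "pol1_bmh21", "pol2_vehicle",
                     "pol2_bmh21", "pol3_vehicle", "pol3_bmh21"))
  k_add <- sprintf("k%d", 1:9)
  # Pol III mean addition rate constants: 49 (vehicle) vs 39 (drug), exact
  expect_equal(mean(sc$pol3_vehicle$true_params[k_add]), 49)
  expect_equal(mean(sc$pol3_bmh21$true_params[k_add]), 39)
  # Pol I drug arm: > 2-fold reduction at the 13-mer and 14-mer steps
  expect_lte(sc$pol1_bmh21$true_params[["k3"]] /
               sc$pol1_vehicle$true_params[["k3"]], 0.5)
  expect_lte(sc$pol1_bmh21$true_params[["k4"]] /
               sc$pol1_vehicle$true_params[["k4"]], 0.5)
  # experimental window and replicate structure
  for (s in sc) {
    expect_equal(range(s$time_grid), c(0.005, 10))
    expect_length(s$time_grid, 20L)
    expect_identical(s$n_replicates, 3L)
    expect_equal(s$noise_sd, 0.02)
  }
  # Pol II is unaffected: both arms share one parameter set
  expect_identical(sc$pol2_vehicle$true_params, sc$pol2_bmh21$true_params)
})

test_that("scenario constructor enforces the quench-flow window", {
  p <- params_for("S1")
  expect_error(scenario("x", "S1", p, c(0.001, 1)), "window")
  expect_error(scenario("x", "S1", p, c(0.01, 11)), "window")
  expect_error(scenario("x", "S1", p[-1], c(0.01, 1)), "missing")
  s <- scenario("x", "S1", p, quench_flow_grid(5))
  expect_s3_class(s, "scenario")
})

test_that("generation is deterministic and noiseless at sd zero", {
  sc <- default_scenarios()
  d1 <- generate_dataset(sc$pol1_vehicle, 11)
  d2 <- generate_dataset(sc$pol1_vehicle, 11)
  expect_identical(d1, d2)
  d3 <- generate_dataset(sc$pol1_vehicle, 12)
  expect_false(identical(d1$replicates[[1]]$bands, d3$replicates[[1]]$bands))
  # noiseless limit reproduces the forward model exactly
  s0 <- sc$pol1_vehicle; s0$noise_sd <- 0
  d0 <- generate_dataset(s0, 11)
  clean <- noiseless_dataset("S1", sc$pol1_vehicle$true_params,
                             sc$pol1_vehicle$time_grid)
  for (r in d0$replicates) expect_equal(r$bands, clean$bands)
})

test_that("replicates satisfy band-fraction constraints", {
  sc <- default_scenarios()
  for (nm in c("pol1_bmh21", "pol2_vehicle", "pol3_vehicle")) {
    ds <- generate_dataset(sc[[nm]], 5)
    expect_length(ds$replicates, 3L)
    for (r in ds$replicates) {
      expect_true(all(r$bands >= 0 & r$bands <= 1))
      expect_identical(dim(r$bands)[2], 20L)
      expect_identical(r$times, sc[[nm]]$time_grid)
    }
  }
})

test_that("ensemble mean tracks the noiseless curve within Monte-Carlo error", {
  sc <- default_scenarios()
  s1k <- sc$pol1_vehicle
  s1k$n_replicates <- 1000L
  ds <- generate_dataset(s1k, 2024)
  clean <- noiseless_dataset("S1", s1k$true_params, s1k$time_grid)$bands
  avg <- Reduce(`+`, lapply(ds$replicates, `[[`, "bands")) / 1000
  # oracle: analytic mean of a N(c, sd^2) draw clipped to [0, 1]; clipping
  # at 0 shifts near-zero bands upward by up to sd*phi(0) ~ 0.008, so the
  # ensemble mean is compared against the clipped mean, not the raw truth
  sd_ <- 0.02
  a <- (0 - clean) / sd_
  b <- (1 - clean) / sd_
  clip_mean <- clean * (pnorm(b) - pnorm(a)) +
    sd_ * (dnorm(a) - dnorm(b)) + (1 - pnorm(b))
  se <- sd_ / sqrt(1000)
  expect_gte(mean(abs(avg - clip_mean) <= 3 * se), 0.99)
  # truncation bias vs the raw truth stays small on average (dominated by
  # the ~0.008 upward shift at the many near-zero band points)
  expect_lt(mean(abs(avg - clean)), 0.006)
})

test_that("per-replicate noise streams are independent of replicate count", {
  sc <- default_scenarios()
  small <- generate_dataset(sc$pol1_vehicle, 99)
  big_sc <- sc$pol1_vehicle
  big_sc$n_replicates <- 5L
  big <- generate_dataset(big_sc, 99)
  for (i in 1:3) {
    expect_identical(small$replicates[[i]]$bands, big$replicates[[i]]$bands)
  }
})

test_that("scenario JSON files round-trip through read_scenarios", {
  sc <- default_scenarios()[["pol1_vehicle"]]
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(
    name = sc$name, scheme_id = sc$scheme_id,
    true_params = as.list(sc$true_params), time_grid = sc$time_grid,
    n_replicates = sc$n_replicates, noise_sd = sc$noise_sd,
    condition_label = sc$condition_label)), path,
    auto_unbox = TRUE, digits = NA)
  got <- read_scenarios(path)
  expect_named(got, "pol1_vehicle")
  expect_equal(unclass(got$pol1_vehicle$true_params),
               unclass(sc$true_params))
  expect_equal(got$pol1_vehicle$time_grid, sc$time_grid)
})
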