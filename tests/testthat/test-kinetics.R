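test_that("frozen and single-decay systems solve exactly", {
  s1 <- build_scheme("S1")
  nm <- free_params(s1)
  # all rates zero: state equals the initial state at any time
  tr <- solve_timecourse(s1, stats::setNames(rep(0, 10), nm), c(0, 0.5, 10))
  expect_equal(tr$state["EC10", ], rep(1, 3))
  expect_true(all(tr$state[-1, ] == 0))
  # single exponential decay EC10 -> sink at 2 /s
  p <- stats::setNames(c(rep(0, 9), 2), nm)
  tr2 <- solve_timecourse(s1, p, 0.5)
  expect_equal(unname(tr2$state["EC10", 1]), exp(-1), tolerance = 1e-12)
  expect_equal(unname(tr2$state["sink", 1]), 1 - exp(-1), tolerance = 1e-12)
})

test_that("three-species chain matches the Bateman closed form", {
  # A -> B -> C with k = (1, 0.5) at t = 1
  bc <- bateman_chain(c(1, 0.5), 1.0)
  expect_equal(unname(bc$state[, 1]),
               c(0.3678794, 0.4773024, 0.1548181), tolerance = 1e-6)
  s1 <- build_scheme("S1")
  p <- stats::setNames(c(1, 0.5, rep(0, 8)), free_params(s1))
  tr <- solve_timecourse(s1, p, 1.0)
  expect_equal(unname(tr$state[c("EC10", "EC11", "EC12"), 1]),
               unname(bc$state[, 1]), tolerance = 1e-8)
})

test_that("bateman_chain honors limits and rejects confluent rates", {
  expect_equal(unname(bateman_chain(c(2, 1, 0.5), 0)$state[, 1]),
               c(1, 0, 0, 0))
  expect_equal(unname(bateman_chain(5, 1e4)$state[2, 1]), 1, tolerance = 1e-9)
  expect_error(bateman_chain(c(1, 1 + 1e-8), 1), "confluent")
})

test_that("solver agrees with the Bateman oracle on random irreversible chains", {
  set.seed(101)
  s1 <- build_scheme("S1")
  nm <- free_params(s1)
  times <- quench_flow_grid(15)
  for (i in 1:25) {
    repeat {
      k <- 10^stats::runif(9, -1, 2)
      seps <- abs(outer(k, k, "-")) / outer(k, k, pmax)
      if (min(seps[upper.tri(seps)]) > 1e-3) break
    }
    p <- stats::setNames(c(k, 0), nm)
    tr <- solve_timecourse(s1, p, times)
    bc <- bateman_chain(k, times)
    expect_lt(max(abs(tr$state[1:10, ] - bc$state)), 1e-7)
  }
})

test_that("eigen, matrix-exponential and stiff-ODE paths agree", {
  for (id in c("S2", "S3", "S4")) {
    s <- build_scheme(id)
    p <- params_for(id)
    times <- quench_flow_grid(10)
    a <- solve_timecourse(s, p, times, method = "eigen")$state
    b <- solve_timecourse(s, p, times, method = "expm")$state
    c_ <- solve_timecourse(s, p, times, method = "ode")$state
    expect_lt(max(abs(a - b)), 1e-6)
    expect_lt(max(abs(a - c_)), 1e-6)
  }
  # confluent rates defeat diagonalization; the fallback must still be exact
  s1 <- build_scheme("S1")
  p_conf <- stats::setNames(c(rep(2, 9), 0), free_params(s1))
  a <- solve_timecourse(s1, p_conf, c(0.5, 2), method = "eigen")$state
  b <- solve_timecourse(s1, p_conf, c(0.5, 2), method = "ode")$state
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("trajectories conserve mass and stay within [0, 1]", {
  set.seed(202)
  for (i in 1:10) {
    id <- sample(c("S1", "S2", "S3", "S4"), 1)
    s <- build_scheme(id)
    nm <- setdiff(free_params(s), "f_inactive")
    p <- stats::setNames(10^stats::runif(length(nm), -1, 2), nm)
    if (id == "S4") p <- c(p, f_inactive = stats::runif(1))
    tr <- solve_timecourse(s, p, quench_flow_grid(10))
    expect_lt(max(abs(colSums(tr$state) - 1)), 1e-9)
    expect_true(all(tr$state >= 0 & tr$state <= 1 + 1e-9))
  }
})

test_that("band projection co-migrates paused species and excludes the sink", {
  s2 <- build_scheme("S2")
  p <- params_for("S2")
  times <- quench_flow_grid(12)
  tr <- solve_timecourse(s2, p, times)
  otc <- project_observables(tr)
  expect_equal(otc$bands["11", ], tr$state["EC11", ] + tr$state["EC11p", ])
  expect_equal(otc$bands["12", ], tr$state["EC12", ] + tr$state["EC12p", ])
  # band totals equal 1 minus accumulated sink mass: non-increasing, and
  # strictly decreasing while the 10-mer still feeds the nuclease
  tot <- colSums(otc$bands)
  expect_equal(tot, 1 - tr$state["sink", ])
  expect_true(all(diff(tot) <= 1e-12))
  expect_lt(tot[5], tot[1])
  # without paused species the mapping is the identity
  s1 <- build_scheme("S1")
  tr1 <- solve_timecourse(s1, params_for("S1"), times)
  otc1 <- project_observables(tr1)
  expect_equal(unname(otc1$bands),
               unname(tr1$state[sprintf("EC%d", 10:19), ]))
})

test_that("terminal 19-mer band is non-decreasing for irreversible schemes", {
  times <- quench_flow_grid(40)
  for (id in c("S1", "S2", "S4")) {
    otc <- noiseless_dataset(id, times = times)
    expect_true(all(diff(otc$bands["19", ]) >= -1e-12))
  }
})

test_that("strong pausing imprints a biphasic, persistent 11-mer band", {
  # elongation ~40 /s with pause entry 20 /s and slow exit 0.5 /s: the
  # active 11-mers transit in milliseconds while the paused pool drains at
  # ~koff1, so the band decays in two well-separated phases and persists
  # far longer than without pausing
  grid <- quench_flow_grid(1e4)
  y2 <- noiseless_dataset("S2", times = grid)$bands["11", ]
  y1 <- noiseless_dataset("S1", times = grid)$bands["11", ]
  peak_t <- function(y) grid[which.max(y)]
  # time at which the band has decayed to 10% of its peak: pausing extends
  # it by more than an order of magnitude
  decay_t <- function(y) grid[grid > peak_t(y)][
    which(y[grid > peak_t(y)] < 0.1 * max(y))[1]]
  expect_gt(decay_t(y2) / decay_t(y1), 10)
  # two kinetic phases: the peak forms in the fast elongation-limited
  # phase, but the terminal decay is pause-exit limited (~koff1 scale,
  # sub-1 /s) -- whereas the S1 band decays at elongation rates throughout
  rate_at <- function(y, frac) {
    i <- which(grid > peak_t(y) & y < frac * max(y))[1]
    -(log(y[i + 1]) - log(y[i - 1])) / (grid[i + 1] - grid[i - 1])
  }
  expect_lt(peak_t(y2), 0.1)
  expect_lt(rate_at(y2, 0.05), 1)
  expect_gt(rate_at(y1, 0.05), 20)
})

test_that("scheme limits reduce to their simpler counterparts", {
  times <- quench_flow_grid(20)
  b1 <- noiseless_dataset("S1")$bands
  # S2 with pause rates 0 reproduces S1 band fractions
  b2 <- noiseless_dataset("S2",
    params_for("S2", kon1 = 0, koff1 = 0, kon2 = 0, koff2 = 0))$bands
  expect_lt(max(abs(b2 - b1)), 1e-9)
  # S4 with no inactive subpopulation reproduces S1
  b4 <- noiseless_dataset("S4", params_for("S4", f_inactive = 0))$bands
  expect_lt(max(abs(b4 - b1)), 1e-9)
  # S3 with reverse rates 0 reproduces the irreversible chain (no
  # nuclease); pairwise-distinct forward rates so the Bateman form applies
  kF <- c(12, 10, 11, 9, 9.5, 8, 8.5, 7.5, 7)
  p3 <- rate_params(c(stats::setNames(kF, sprintf("kF%d", 1:9)),
                      stats::setNames(rep(0, 9), sprintf("kR%d", 1:9))))
  b3 <- noiseless_dataset("S3", p3)$bands
  s1 <- build_scheme("S1")
  b_chain <- noiseless_dataset("S1",
    rate_params(c(stats::setNames(kF, sprintf("k%d", 1:9)), k10 = 0)))$bands
  expect_lt(max(abs(b3 - b_chain)), 1e-9)
  # and both agree with the closed form at oracle precision
  bc <- bateman_chain(kF, quench_flow_grid(20))
  expect_lt(max(abs(b3 - bc$state)), 1e-7)
})

test_that("solver rejects invalid inputs and flags real negativity", {
  s1 <- build_scheme("S1")
  p <- params_for("S1")
  expect_error(solve_timecourse(s1, p, c(-1, 1)), "nonnegative")
  p_bad <- p; p_bad[1] <- NaN
  expect_error(solve_timecourse(s1, p_bad, 1), "finite|missing")
})
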