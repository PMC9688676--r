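# shared fixtures: canonical parameter sets and a lean optimizer config for
# unit tests (acceptance tests use the package defaults)

params_for <- function(scheme_id, ...) {
  base <- switch(scheme_id,
    S1 = c(stats::setNames(c(40, 35, 30, 25, 35, 30, 28, 26, 24),
                           sprintf("k%d", 1:9)), k10 = 0.2),
    S2 = c(stats::setNames(c(40, 35, 30, 25, 35, 30, 28, 26, 24),
                           sprintf("k%d", 1:9)), k10 = 0.2,
           kon1 = 20, koff1 = 0.5, kon2 = 15, koff2 = 0.6),
    S3 = c(stats::setNames(c(12, 10, 11, 9, 10, 8, 9, 8, 7),
                           sprintf("kF%d", 1:9)),
           stats::setNames(c(2, 1.5, 2, 1.8, 1.5, 1.2, 1.5, 1.3, 1),
                           sprintf("kR%d", 1:9))),
    S4 = c(stats::setNames(c(40, 35, 30, 25, 35, 30, 28, 26, 24),
                           sprintf("k%d", 1:9)), k10 = 0.2,
           kact = 8, f_inactive = 0.3))
  p <- rate_params(base)
  dots <- c(...)
  if (length(dots)) p[names(dots)] <- dots
  rate_params(p)
}

quick_config <- function(seed = 1L, ...) {
  fit_config(ga = list(pop_size = 24L, generations = 20L, polish_top = 3L,
                       phases = 2L),
             seed = seed, ...)
}

noiseless_dataset <- function(scheme_id, params = params_for(scheme_id),
                              times = quench_flow_grid(20)) {
  scheme <- build_scheme(scheme_id)
  traj <- solve_timecourse(scheme, params, times)
  project_observables(traj, condition_label = "synthetic", replicate_id = 1L)
}
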