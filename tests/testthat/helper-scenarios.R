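# Shared fixtures: the default study conditions and a lazily-computed cache
# of the expensive experiment runs, so several test files can share one E1 /
# E2 simulation.

default_retention <- function() {
  vg_retention(theta_r = 0.06, theta_s = 0.45, alpha = 367, n = 1.56,
               ks_sat = 2.9e-6)
}

test_day <- function(scenario = "e1a", seed = 1) {
  e1_day(scenario, seed = seed)
}

# noon-ish forcing row used by solver-level tests
test_frow <- function(hour = 14, seed = 1) {
  as.list(test_day(seed = seed)[hour + 1, ])
}

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

e1_runs <- function() {
  cached("e1", run_e1(n_days = 250, seed = 1))
}

e2_runs <- function() {
  cached("e2", run_e2(seed = 1))
}
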