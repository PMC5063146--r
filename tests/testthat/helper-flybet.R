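# Shared fixtures: everything is generated in code at test time.

# A Boston-like baseline season (climate normals only: no deviations, no
# cloud) and the matching default preference grid at the resolution used
# for calibration work in the tests.
boston_normals <- function() synthetic_normals()

test_grid <- function(K = 31L) pref_grid(default_pref_dist(), K)

# Plausible (beta, delta) used by structural tests that do not themselves
# depend on the equilibrium calibration.
test_params <- function(strategy = "BH", ...) {
  model_params(beta = 0.1, delta = 0.04, strategy = strategy, ...)
}

expect_no_na <- function(x) expect_false(anyNA(x))
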