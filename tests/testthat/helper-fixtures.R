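# Replicate sets with an exact sample mean and exact sample RSD%: scale a
# zero-mean unit-SD base vector.  Used to rebuild validation tables whose
# printed summaries (mean recovery, RSD, Er) must be reproduced exactly.
make_replicates <- function(mean, rsd_pct, n = 6) {
  z <- seq_len(n) - (n + 1) / 2
  z <- z / stats::sd(z)
  mean * (1 + (rsd_pct / 100) * z)
}

# Base kinetic parameters used across simulator tests (package defaults).
default_base_params <- function() config_simulation(default_config())$base_params

# Quadrature oracle for an AUC over [0, upper].
quad_auc <- function(f, upper = 2000) {
  stats::integrate(f, 0, upper, rel.tol = 1e-10, subdivisions = 2000L)$value
}
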