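# Shared fixtures: scatterer specs on the standard size-parameter lattice and
# cached phase tables (built once per test run).

.fixture_cache <- new.env(parent = emptyenv())

spec_for_alpha <- function(alpha, m_rel = 1.2, n_med = 1.33, lambda = 0.488) {
  scatterer_spec(alpha * lambda / (pi * n_med), n_med, m_rel * n_med, lambda)
}

tables_for_alpha <- function(alpha, m = 1000L, n = 360L) {
  key <- sprintf("tab_%g_%d_%d", alpha, m, n)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_phase_tables(spec_for_alpha(alpha), m, n)
  .fixture_cache[[key]]
}

# Composite Simpson quadrature on a uniform grid (independent of the
# package's Gauss-Legendre machinery).
simpson <- function(y, h) {
  n <- length(y)
  stopifnot(n %% 2 == 1)
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, 2)]) +
             2 * sum(y[seq(3, n - 2, 2)]))
}
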