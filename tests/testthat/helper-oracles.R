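# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the Mie oracle uses R's Bessel functions for the
# Riccati-Bessel terms and a doubled truncation order; the angle-sampling
# oracle is plain rejection sampling from the phase-function definition.

# Second implementation of the Mie recurrences: psi/chi from half-integer
# Bessel functions, logarithmic derivative by downward recurrence started at
# a doubled order, series truncated at twice the package's order.
oracle_mie_amplitudes <- function(spec, theta) {
  x <- spec$size_parameter
  m <- spec$relative_index
  nmax <- 2L * (ceiling(x + 4 * x^(1/3) + 2) + 15L)
  mx <- m * x
  nstart <- nmax + 40L
  D <- complex(nstart + 1L)
  for (n in nstart:1) {
    r <- (n + 1) / mx
    D[n] <- r - 1 / (D[n + 1L] + r)
  }
  nn <- seq_len(nmax)
  psi <- sqrt(pi * x / 2) * besselJ(x, nn + 0.5)
  chi <- -sqrt(pi * x / 2) * besselY(x, nn + 0.5)
  psi0 <- sin(x); chi0 <- cos(x)
  psim1 <- c(psi0, psi[-nmax]); chim1 <- c(chi0, chi[-nmax])
  xi <- complex(real = psi, imaginary = -chi)
  xim1 <- complex(real = psim1, imaginary = -chim1)
  da <- D[nn] / m + nn / x
  db <- D[nn] * m + nn / x
  a <- (da * psi - psim1) / (da * xi - xim1)
  b <- (db * psi - psim1) / (db * xi - xim1)
  mu <- cos(theta)
  S1 <- complex(length(mu)); S2 <- complex(length(mu))
  pi_nm1 <- numeric(length(mu)); pi_n <- rep(1, length(mu))
  for (n in nn) {
    tau_n <- n * mu * pi_n - (n + 1) * pi_nm1
    fn <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fn * (a[n] * pi_n + b[n] * tau_n)
    S2 <- S2 + fn * (a[n] * tau_n + b[n] * pi_n)
    if (n < nmax) {
      pi_np1 <- ((2 * n + 1) * mu * pi_n - (n + 1) * pi_nm1) / n
      pi_nm1 <- pi_n; pi_n <- pi_np1
    }
  }
  list(S1 = S1, S2 = S2)
}

# Rejection sampling of (theta, phi) directly from
# F ~ |S2|^2 + |S1|^2 + L (|S2|^2 - |S1|^2) cos(2 phi) on the uniform
# (cos theta, phi) measure.
rejection_sample_phase <- function(spec, L, n, chunk = 4e5) {
  thg <- acos(seq(-1, 1, length.out = 4001))
  amp <- mie_amplitudes(spec, thg)
  Fmax <- max(Mod(amp$S2)^2 + Mod(amp$S1)^2 +
                abs(Mod(amp$S2)^2 - Mod(amp$S1)^2)) * 1.02
  th <- numeric(0); ph <- numeric(0)
  while (length(th) < n) {
    mu <- stats::runif(chunk, -1, 1)
    p <- stats::runif(chunk, 0, 2 * pi)
    a <- mie_amplitudes(spec, acos(mu))
    F <- Mod(a$S2)^2 + Mod(a$S1)^2 +
      L * (Mod(a$S2)^2 - Mod(a$S1)^2) * cos(2 * p)
    acc <- stats::runif(chunk) * Fmax < F
    th <- c(th, acos(mu[acc])); ph <- c(ph, p[acc])
  }
  list(theta = th[seq_len(n)], phi = ph[seq_len(n)])
}

# Two-sample chi-square p-value on a (cos theta, phi) product binning; bins
# with low joint counts are pooled out.
chisq2_p <- function(d1, d2, nb_t = 24, nb_p = 12, min_count = 10) {
  b <- function(d) {
    it <- pmin(floor((cos(d$theta) + 1) / 2 * nb_t) + 1L, nb_t)
    ip <- pmin(floor(d$phi / (2 * pi) * nb_p) + 1L, nb_p)
    tabulate(it + nb_t * (ip - 1L), nb_t * nb_p)
  }
  c1 <- b(d1); c2 <- b(d2)
  keep <- (c1 + c2) >= min_count
  k1 <- sqrt(sum(c2) / sum(c1)); k2 <- sqrt(sum(c1) / sum(c2))
  chi <- sum((k1 * c1[keep] - k2 * c2[keep])^2 / (c1[keep] + c2[keep]))
  stats::pchisq(chi, sum(keep) - 1, lower.tail = FALSE)
}

# One-sample chi-square of angles against a density on equal-probability or
# uniform bins.
chisq1_p <- function(x, breaks, probs) {
  obs <- tabulate(cut(x, breaks, labels = FALSE, include.lowest = TRUE),
                  length(breaks) - 1)
  stats::chisq.test(obs, p = probs / sum(probs))$p.value
}
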