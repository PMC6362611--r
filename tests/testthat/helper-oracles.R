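# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's Abeles/smearing code paths.

# Parratt recursive-ratio reflectivity, written in the fully "physical"
# convention (absorption as rho - i*rho_im, so Im(k) >= 0 and layer phases
# exp(2i k d) decay). Slow scalar code, independent of the matrix kernel.
parratt_oracle <- function(tab, q) {
  sldc <- (tab$sld - 1i * tab$sld_i) * 1e-6
  m <- nrow(tab)
  vapply(q, function(qq) {
    k <- vapply(seq_len(m), function(j)
      sqrt(as.complex((qq / 2)^2 - 4 * pi * (sldc[j] - sldc[1]))),
      complex(1))
    r <- 0 + 0i
    for (j in seq(m - 1, 1)) {
      fres <- (k[j] - k[j + 1]) / (k[j] + k[j + 1]) *
        exp(-2 * k[j] * k[j + 1] * tab$rough[j + 1]^2)
      if (j == m - 1) {
        r <- fres
      } else {
        ph <- exp(2i * k[j + 1] * tab$thick[j + 1])
        r <- (fres + r * ph) / (1 + fres * r * ph)
      }
    }
    Mod(r)^2
  }, numeric(1))
}

# A random but physically sensible slab stack (moderate SLDs, thicknesses,
# roughnesses, non-negative absorption).
random_stack <- function(n_layers = sample(0:8, 1)) {
  slab_table(
    thick = c(0, stats::runif(n_layers, 1, 300), 0),
    sld = c(stats::runif(1, -1, 3), stats::runif(n_layers, -2, 10),
            stats::runif(1, -1, 7)),
    sld_i = c(0, stats::runif(n_layers, 0, 0.1),
              abs(stats::rnorm(1, 0, 0.01))),
    rough = c(0, stats::runif(n_layers + 1, 0, 8))
  )
}

# Micro-sliced error-function interface: a bare rough interface rendered as
# hundreds of thin zero-roughness slices following the erf profile.
microslice_erf_table <- function(rho0, rho1, sigma, dz = sigma / 40,
                                 extent = 7) {
  z <- seq(-extent * sigma, extent * sigma, by = dz)
  mid <- z[-length(z)] + dz / 2
  sld <- rho0 + (rho1 - rho0) * stats::pnorm(mid / sigma)
  slab_table(thick = c(0, rep(dz, length(mid)), 0),
             sld = c(rho0, sld, rho1), rough = 0)
}

# Brute-force Gaussian smearing by adaptive quadrature over +/- 3.5 sd,
# renormalised for the truncation (matching the kernel's convention).
smear_quadrature_oracle <- function(r_of_q, q, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  mass <- diff(stats::pnorm(c(-3.5, 3.5)))
  vapply(seq_along(q), function(i) {
    if (s[i] == 0) return(r_of_q(q[i]))
    stats::integrate(function(x) r_of_q(abs(x)) *
                       stats::dnorm(x, q[i], s[i]),
                     q[i] - 3.5 * s[i], q[i] + 3.5 * s[i],
                     rel.tol = 1e-12)$value / mass
  }, numeric(1))
}

# Simple Si / SiO2 / solvent structure used by several tests.
simple_structure <- function(sio2_thick = 15, solvent = 6.36) {
  structure_model(
    slab(0, 2.07, name = "Si"),
    slab(sio2_thick, 3.47, rough = 3, name = "SiO2"),
    slab(0, solvent, rough = 3, name = "solvent"),
    name = "simple"
  )
}

expect_rel_equal <- function(actual, expected, rtol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), rtol)
}
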