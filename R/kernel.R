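#' Momentum transfer from angle of incidence and wavelength
#'
#' `Q = (4*pi/lambda) * sin(omega)`, the independent variable of a specular
#' reflectivity curve.
#' @param omega Angle of incidence in degrees.
#' @param lam Wavelength in Angstrom (`> 0`).
#' @return Momentum transfer in inverse Angstrom.
#' @examples
#' q_from_angle(0.5, 2.8)
#' @export
q_from_angle <- function(omega, lam) {
  if (any(lam <= 0)) stop("wavelength must be positive")
  (4 * pi / lam) * sin(omega * pi / 180)
}

#' Build a slab table
#'
#' A slab table describes a stratified medium as rows from the fronting
#' (incident) medium to the backing medium. Each row holds a thickness in
#' Angstrom (ignored for the semi-infinite fronting and backing rows), a
#' scattering length density in 1e-6 Angstrom^-2 (real and imaginary /
#' absorption parts) and a Gaussian roughness in Angstrom between the row and
#' the *previous* row (ignored for the fronting row).
#'
#' @param thick,sld,sld_i,rough Equal-length numeric vectors (first and last
#'   entries are the fronting/backing media).
#' @return A tibble with columns `thick`, `sld`, `sld_i`, `rough`.
#' @export
slab_table <- function(thick, sld, sld_i = 0, rough = 0) {
  n <- length(thick)
  tab <- tibble::tibble(thick = as.numeric(thick),
                        sld = as.numeric(sld),
                        sld_i = rep_len(as.numeric(sld_i), n),
                        rough = rep_len(as.numeric(rough), n))
  validate_slab_table(tab)
  tab
}

validate_slab_table <- function(tab) {
  need <- c("thick", "sld", "sld_i", "rough")
  if (!all(need %in% names(tab)))
    stop("slab table needs columns: ", paste(need, collapse = ", "))
  if (nrow(tab) < 2)
    stop("slab table needs at least fronting and backing rows")
  if (!all(vapply(tab[need], function(x) all(is.finite(x)), logical(1))))
    stop("non-finite entries in slab table")
  inner <- seq_len(nrow(tab))[-c(1, nrow(tab))]
  if (any(tab$thick[inner] < 0)) stop("internal slab thicknesses must be >= 0")
  if (any(tab$rough < 0)) stop("roughnesses must be >= 0")
  if (any(tab$sld_i < 0)) stop("imaginary SLD (absorption) must be >= 0")
  invisible(tab)
}

# Principal complex sqrt (Re >= 0; pure-evanescent arguments, negative real,
# give +i*sqrt(A)). With absorption entering k^2 through -4*pi*i*rho_im this
# branch keeps Fresnel ratios bounded and damps R below the critical edge.
csqrt_k <- function(z) sqrt(z)

#' Specular reflectivity of a slab stack (Abeles matrix method)
#'
#' Computes `R(Q)` for a stratified medium by the 2x2 characteristic-matrix
#' (Abeles) method. The per-medium normal wavevector is
#' `k_j = sqrt((Q/2)^2 - 4*pi*(rho_j - rho_fronting))` with a complex square
#' root (absorption enters as the imaginary SLD part); each interfacial
#' Fresnel coefficient is attenuated by the Nevot-Croce factor
#' `exp(-2 k_j k_{j+1} sigma^2)` for Gaussian roughness `sigma`, applied at
#' every interface including those to the semi-infinite media.
#'
#' SLDs are supplied in the conventional units of 1e-6 Angstrom^-2 and
#' converted internally. Cost is O(length(q) * nrow(slabs)).
#'
#' @param slabs A slab table (see [slab_table()]).
#' @param q Momentum transfer values, inverse Angstrom, `>= 0`. At `Q = 0`
#'   exactly, the total-reflection limit is returned: 1 when backing and
#'   fronting real SLDs differ, 0 otherwise.
#' @return Numeric vector of reflectivities in `[0, 1]` for physical inputs.
#' @examples
#' s <- slab_table(thick = c(0, 100, 0), sld = c(0, 4, 6.36), rough = c(0, 3, 3))
#' reflectivity(s, c(0.01, 0.05, 0.2))
#' @export
reflectivity <- function(slabs, q) {
  validate_slab_table(slabs)
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  m <- nrow(slabs)
  n <- length(q)
  out <- numeric(n)
  zero <- q == 0
  if (any(zero))
    out[zero] <- if (slabs$sld[m] != slabs$sld[1]) 1 else 0
  if (any(!zero))
    out[!zero] <- abeles(q[!zero],
                         thick = slabs$thick,
                         sldc = (slabs$sld + 1i * slabs$sld_i) * 1e-6,
                         rough = slabs$rough)
  out
}

abeles <- function(q, thick, sldc, rough) {
  m <- length(sldc)
  n <- length(q)
  qsq4 <- (q / 2)^2
  k <- sqrt(as.complex(qsq4)) # fronting: rho - rho_fronting = 0
  M11 <- M22 <- rep(1 + 0i, n)
  M12 <- M21 <- rep(0 + 0i, n)
  for (j in seq_len(m - 1)) {
    k_next <- csqrt_k(qsq4 - 4 * pi * (sldc[j + 1] - sldc[1]))
    rj <- (k - k_next) / (k + k_next) *
      exp(-2 * k * k_next * rough[j + 1]^2)
    if (j == 1) {
      beta <- rep(1 + 0i, n)
    } else {
      beta <- exp(1i * k * thick[j])
    }
    C11 <- beta
    C12 <- rj * beta
    C21 <- rj / beta
    C22 <- 1 / beta
    n11 <- M11 * C11 + M12 * C21
    n12 <- M11 * C12 + M12 * C22
    n21 <- M21 * C11 + M22 * C21
    n22 <- M21 * C12 + M22 * C22
    M11 <- n11; M12 <- n12; M21 <- n21; M22 <- n22
    k <- k_next
  }
  Mod(M21 / M11)^2
}

# ---- instrument resolution ----------------------------------------------

#' Instrument resolution specifications
#'
#' The measured curve is the true reflectivity convolved with the
#' instrument's Q-resolution function. Three smearing types are supported:
#' a constant relative width `dQ/Q`, a per-point width read from the
#' dataset, and an arbitrary discrete probability kernel. Widths are always
#' full widths at half maximum (FWHM) of a Gaussian; the standard deviation
#' used in the convolution is `FWHM / (2*sqrt(2*log(2)))`.
#'
#' @param dqq Constant `dQ/Q` as a FWHM fraction (e.g. `0.05` for 5%).
#' @param dq Per-point FWHM values (inverse Angstrom), or `NULL` to take
#'   them from the dataset at evaluation time.
#' @param offsets Numeric vector of Q offsets (inverse Angstrom) of the
#'   discrete kernel.
#' @param weights Kernel weights: a vector (same kernel at every point) or a
#'   matrix with one row per Q point. Each kernel must be non-negative and
#'   sum to 1 within 1e-9.
#' @return An object of class `slabs_resolution`.
#' @name resolution
NULL

#' @rdname resolution
#' @export
res_none <- function() structure(list(kind = "none"),
                                 class = "slabs_resolution")

#' @rdname resolution
#' @export
res_constant <- function(dqq) {
  stopifnot(is.numeric(dqq), length(dqq) == 1L)
  if (dqq < 0) stop("dQ/Q fraction must be >= 0")
  structure(list(kind = "constant", dqq = dqq), class = "slabs_resolution")
}

#' @rdname resolution
#' @export
res_pointwise <- function(dq = NULL) {
  if (!is.null(dq) && any(dq < 0)) stop("pointwise dQ must be >= 0")
  structure(list(kind = "pointwise", dq = dq), class = "slabs_resolution")
}

#' @rdname resolution
#' @export
res_kernel <- function(offsets, weights) {
  w <- if (is.matrix(weights)) weights else matrix(weights, nrow = 1)
  if (ncol(w) != length(offsets))
    stop("kernel weights must have one column per offset")
  if (any(w < 0)) stop("kernel weights must be >= 0")
  sums <- rowSums(w)
  if (any(abs(sums - 1) > 1e-9))
    stop("kernel weights must sum to 1 (within 1e-9) for every point")
  structure(list(kind = "kernel", offsets = offsets, weights = w),
            class = "slabs_resolution")
}

#' @export
print.slabs_resolution <- function(x, ...) {
  extra <- switch(x$kind,
                  constant = sprintf(" dQ/Q = %g", x$dqq),
                  pointwise = " per-point dQ",
                  "")
  cat(sprintf("<resolution: %s%s>\n", x$kind, extra))
  invisible(x)
}

FWHM_TO_SD <- 2 * sqrt(2 * log(2)) # 2.35482

# 17-point Gauss-Legendre rule, cached per session
gl_rule <- local({
  rule <- NULL
  function() {
    if (is.null(rule)) rule <<- pracma::gaussLegendre(17, -3.5, 3.5)
    rule
  }
})

gaussian_smear <- function(r_of_q, q, fwhm) {
  s <- fwhm / FWHM_TO_SD
  gl <- gl_rule()
  w <- gl$w * stats::dnorm(gl$x)
  w <- w / sum(w)
  qmat <- q + outer(s, gl$x) # n x 17; evaluate at |Q| (R is even in Q)
  rall <- r_of_q(abs(as.vector(qmat)))
  drop(matrix(rall, nrow = length(q)) %*% w)
}

#' Apply resolution smearing to a reflectivity function
#'
#' Gaussian smearing (constant `dQ/Q` or pointwise FWHM) is evaluated by a
#' fixed 17-point Gauss-Legendre quadrature over +/- 3.5 standard deviations
#' around each Q point; a discrete kernel is applied as a weighted sum of
#' shifted evaluations.
#'
#' @param r_of_q Function mapping a Q vector to reflectivities (typically a
#'   closure over [reflectivity()]).
#' @param q Q points at which the smeared curve is wanted.
#' @param res A [resolution][resolution] specification.
#' @param dq Per-point FWHM vector, required when `res` is pointwise with no
#'   stored widths.
#' @return Numeric vector, same length as `q`.
#' @export
smear <- function(r_of_q, q, res = res_none(), dq = NULL) {
  stopifnot(inherits(res, "slabs_resolution"))
  switch(res$kind,
    none = r_of_q(q),
    constant = {
      if (res$dqq == 0) r_of_q(q)
      else gaussian_smear(r_of_q, q, fwhm = res$dqq * q)
    },
    pointwise = {
      fw <- if (!is.null(res$dq)) res$dq else dq
      if (is.null(fw))
        stop("pointwise resolution requires per-point dQ values")
      if (length(fw) != length(q))
        stop("dQ must have the same length as q")
      gaussian_smear(r_of_q, q, fwhm = fw)
    },
    kernel = {
      w <- res$weights
      if (nrow(w) == 1L) w <- w[rep(1L, length(q)), , drop = FALSE]
      if (nrow(w) != length(q))
        stop("kernel weight matrix must have one row per q point")
      qmat <- outer(q, res$offsets, `+`)
      rall <- matrix(r_of_q(abs(as.vector(qmat))), nrow = length(q))
      rowSums(rall * w)
    },
    stop("unknown resolution kind: ", res$kind)
  )
}
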