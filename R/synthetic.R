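#' Noise model for synthetic reflectivity data
#'
#' Synthetic datasets mimic reduced instrument data: the reported
#' uncertainty is `dR = rel * R` with an absolute floor, or, in Poisson
#' mode, derived from counting statistics `counts = R * flux(Q)` so that
#' `dR = sqrt(counts) / flux(Q)`. Observations are drawn as
#' `R_obs = R_true + Normal(0, dR)`; the reported `dR` is exactly the sigma
#' used to draw the noise.
#'
#' @param rel Relative uncertainty (fraction of R); must be `> 0` unless
#'   `flux` is given.
#' @param floor Absolute lower bound on `dR` (keeps `dR > 0` at deep minima).
#' @param flux Optional function of Q returning an effective incident count
#'   rate; switches on Poisson-count mode.
#' @return An object of class `slabs_noise`.
#' @export
noise_model <- function(rel = 0.025, floor = 1e-10, flux = NULL) {
  if (is.null(flux) && rel <= 0) stop("relative noise level must be > 0")
  if (floor <= 0) stop("noise floor must be > 0")
  structure(list(rel = rel, floor = floor, flux = flux),
            class = "slabs_noise")
}

noise_sigma <- function(noise, q, r_true) {
  if (!is.null(noise$flux)) {
    counts <- pmax(r_true * noise$flux(q), 1)
    pmax(sqrt(counts) / noise$flux(q), noise$floor)
  } else {
    pmax(noise$rel * r_true, noise$floor)
  }
}

#' Default Q grid for synthetic datasets
#'
#' 120 log-spaced points in `[0.008, 0.3]` inverse Angstrom — typical of a
#' time-of-flight neutron reflectometer.
#' @param n Number of points.
#' @param qmin,qmax Range (inverse Angstrom).
#' @return Numeric vector.
#' @export
default_q_grid <- function(n = 120, qmin = 0.008, qmax = 0.3)
  exp(seq(log(qmin), log(qmax), length.out = n))

#' Generate one synthetic reflectivity dataset from a model
#'
#' Evaluates the model curve on a Q grid, attaches uncertainties from the
#' noise model, perturbs with Gaussian noise and returns (optionally
#' writing) a 4-column dataset whose `dq` column carries the FWHM implied
#' by the model's resolution. With `noise = NULL` the returned curve is the
#' noise-free truth.
#'
#' @param model A [reflect_model()] or [mixed_reflect_model()].
#' @param q Q grid; default [default_q_grid()].
#' @param noise A [noise_model()], or `NULL` for no noise.
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @param file Optional path: write the dataset in the 4-column text
#'   dialect.
#' @param name Dataset label.
#' @return A [refl_data] tibble.
#' @export
generate_dataset <- function(model, q = default_q_grid(), noise = noise_model(),
                             seed = NULL, file = NULL, name = "synthetic") {
  stopifnot(inherits(model, "slabs_model"))
  if (!is.null(seed)) set.seed(seed)
  dq <- switch(model$resolution$kind,
               constant = model$resolution$dqq * q,
               pointwise = model$resolution$dq %||%
                 stop("pointwise resolution needs stored dq to simulate"),
               rep(0, length(q)))
  r_true <- model_curve(model, q, dq = dq)
  if (is.null(noise)) {
    dr <- pmax(0.01 * r_true, 1e-12) # nominal bars for plotting/weighting
    r_obs <- r_true
  } else {
    stopifnot(inherits(noise, "slabs_noise"))
    dr <- noise_sigma(noise, q, r_true)
    r_obs <- r_true + stats::rnorm(length(q), 0, dr)
  }
  d <- refl_data(q, r_obs, dr, dq = dq, name = name)
  attr(d, "r_true") <- r_true
  if (!is.null(file)) write_refl_data(d, file, header = name)
  d
}

#' Fixture constants for a DMPC-like phospholipid
#'
#' Synthetic-fixture values for the head and tail group scattering lengths
#' (Angstrom) and partial volumes (Angstrom^3) of a
#' phosphatidylcholine-type lipid, with nominal region thicknesses. These
#' are generator inputs for tests and demos, not asserted experimental
#' ground truth.
#' @return Named list: `b_heads`, `v_heads`, `thick_heads`, `b_tails`,
#'   `v_tails`, `thick_tails`.
#' @export
dmpc_constants <- function() {
  list(b_heads = 6.01e-4, v_heads = 319, thick_heads = 9,
       b_tails = -2.92e-4, v_tails = 782, thick_tails = 14)
}

#' Default solvent contrasts for a solid-liquid experiment
#'
#' D2O, the silicon contrast-matched water mixture (SLD 2.07e-6) and H2O,
#' in 1e-6 Angstrom^-2.
#' @return Named numeric vector.
#' @export
default_contrasts <- function()
  c(d2o = 6.36, hdmix = 2.07, h2o = -0.56)

#' Synthetic three-contrast supported-bilayer suite
#'
#' Builds a silicon / silicon-oxide / lipid-bilayer / solvent structure for
#' each solvent contrast — the two leaflets are [lipid_leaflet()] components
#' sharing one area-per-molecule parameter, with the inner leaflet
#' head-first and the outer leaflet reversed — and generates one noisy
#' dataset per contrast. All lipid constants and the substrate parameters
#' are shared across contrasts, so co-refining the suite mirrors a real
#' contrast-variation experiment with one underlying structure.
#'
#' @param apm True area per molecule (Angstrom^2) used to generate.
#' @param lipid Lipid constants, as from [dmpc_constants()].
#' @param contrasts Named vector of solvent SLDs (1e-6 Angstrom^-2).
#' @param sio2_thick,sio2_rough,substrate_rough Substrate geometry
#'   (Angstrom).
#' @param bkg Background level per contrast (recycled).
#' @param noise A [noise_model()], or `NULL` for noise-free curves.
#' @param q Q grid.
#' @param resolution Resolution specification for every contrast.
#' @param seed Integer seed; contrast `i` uses `seed + i - 1`.
#' @param dir Optional directory: write one 4-column file per contrast plus
#'   a JSON truth sidecar recording the generator parameters.
#' @return A list with `datasets` (named list of [refl_data]), `objective`
#'   (the co-refinement [global_objective()] built on the same shared
#'   parameters used to generate), `apm` (the shared area-per-molecule
#'   parameter object) and `truth` (named list of generating values).
#' @export
make_bilayer_suite <- function(apm = 57,
                               lipid = dmpc_constants(),
                               contrasts = default_contrasts(),
                               sio2_thick = 15, sio2_rough = 3,
                               substrate_rough = 3,
                               bkg = c(3e-7, 2e-7, 1e-7),
                               noise = noise_model(),
                               q = default_q_grid(),
                               resolution = res_constant(0.05),
                               seed = 1, dir = NULL) {
  if (length(contrasts) < 2) stop("need at least 2 solvent contrasts")
  bkg <- rep_len(bkg, length(contrasts))
  apm_par <- as_parameter(apm, "area per molecule")
  sio2_t <- as_parameter(sio2_thick, "SiO2 thick")
  sio2_r <- as_parameter(sio2_rough, "SiO2 rough")
  sub_r <- as_parameter(substrate_rough, "substrate rough")

  objectives <- list()
  datasets <- list()
  for (i in seq_along(contrasts)) {
    cname <- names(contrasts)[i] %||% sprintf("contrast%d", i)
    solv <- material(contrasts[[i]], name = cname)
    inner <- lipid_leaflet(apm_par, lipid$b_heads, lipid$v_heads,
                           lipid$thick_heads, lipid$b_tails, lipid$v_tails,
                           lipid$thick_tails, rough_head_tail = 3,
                           rough_preceding = sub_r,
                           name = paste(cname, "inner"))
    outer <- lipid_leaflet(apm_par, lipid$b_heads, lipid$v_heads,
                           lipid$thick_heads, lipid$b_tails, lipid$v_tails,
                           lipid$thick_tails, rough_head_tail = 3,
                           rough_preceding = 0, reverse = TRUE,
                           name = paste(cname, "outer"))
    s <- structure_model(
      slab(0, 2.07, name = "Si"),
      slab(sio2_t, 3.47, rough = sio2_r, vfsolv = 0.1, name = "SiO2"),
      inner, outer,
      slab(0, solv, rough = 3, name = cname),
      name = cname
    )
    mod <- reflect_model(s, scale = 1, bkg = bkg[i], resolution = resolution,
                         name = cname)
    d <- generate_dataset(mod, q = q, noise = noise, seed = seed + i - 1,
                          name = cname,
                          file = if (!is.null(dir))
                            file.path(dir, sprintf("synthetic_%s.dat", cname)))
    datasets[[cname]] <- d
    objectives[[cname]] <- objective(mod, d, name = cname)
  }
  truth <- list(apm = apm, lipid = lipid, contrasts = as.list(contrasts),
                sio2_thick = sio2_thick, sio2_rough = sio2_rough,
                substrate_rough = substrate_rough, bkg = as.list(bkg),
                seed = seed)
  if (!is.null(dir))
    jsonlite::write_json(truth, file.path(dir, "synthetic_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(datasets = datasets,
       objective = global_objective(objectives),
       apm = apm_par,
       truth = truth)
}
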