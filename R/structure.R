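#' Materials
#'
#' A material is a scattering length density: a real part and a non-negative
#' imaginary (absorption) part, both in 1e-6 Angstrom^-2 and both ordinary
#' [parameter()] objects so they can vary in a fit or be shared between
#' components.
#'
#' @param sld Real SLD (1e-6 Angstrom^-2); number or parameter.
#' @param sld_i Imaginary SLD; number or parameter.
#' @param name Material name, used to label auto-created parameters.
#' @return An object of class `slabs_material`.
#' @examples
#' d2o <- material(6.36, name = "D2O")
#' @export
material <- function(sld, sld_i = 0, name = "") {
  structure(list(
    name = name,
    sld = as_parameter(sld, paste(name, "sld")),
    sld_i = as_parameter(sld_i, paste(name, "sld_i"))
  ), class = "slabs_material")
}

as_material <- function(x, name = "") {
  if (inherits(x, "slabs_material")) return(x)
  material(x, name = name)
}

#' @export
collect_parameters.slabs_material <- function(x) list(x$sld, x$sld_i)

# ---- components ----------------------------------------------------------
# A component contributes >= 0 rows to the slab table of a structure and may
# add its own term to the log-prior (0 by default). New component kinds only
# need methods for component_slabs() and collect_parameters().

component_slabs <- function(comp, solvent, solvate = TRUE)
  UseMethod("component_slabs")

component_log_prior <- function(comp) UseMethod("component_log_prior")

#' @export
component_log_prior.default <- function(comp) 0

#' Uniform slab component
#'
#' The basic building block: a layer of uniform SLD with a thickness, a
#' roughness to the preceding component and a volume fraction of solvent.
#' The effective SLD is `(1 - vfsolv) * sld + vfsolv * sld_solvent`, with the
#' solvent taken from the enclosing structure.
#'
#' @param thick Thickness in Angstrom (number or parameter).
#' @param sld SLD (1e-6 Angstrom^-2): number, parameter or [material()].
#' @param rough Roughness (Angstrom) to the previous component.
#' @param vfsolv Volume fraction of solvent in `[0, 1]`.
#' @param name Component name.
#' @return A component of class `slabs_slab`.
#' @examples
#' sio2 <- slab(15, 3.47, rough = 3, name = "SiO2")
#' @export
slab <- function(thick, sld, rough = 0, vfsolv = 0, name = "") {
  comp <- list(
    kind = "slab",
    name = name,
    thick = as_parameter(thick, paste(name, "thick")),
    material = as_material(sld, name),
    rough = as_parameter(rough, paste(name, "rough")),
    vfsolv = as_parameter(vfsolv, paste(name, "vfsolv"))
  )
  class(comp) <- c("slabs_slab", "slabs_component")
  comp
}

#' @export
collect_parameters.slabs_slab <- function(x)
  list(x$thick, x$material, x$rough, x$vfsolv)

#' @export
component_slabs.slabs_slab <- function(comp, solvent, solvate = TRUE) {
  phi <- if (solvate) par_value(comp$vfsolv) else 0
  sld <- par_value(comp$material$sld)
  sld_i <- par_value(comp$material$sld_i)
  if (phi != 0) {
    sld <- (1 - phi) * sld + phi * par_value(solvent$sld)
    sld_i <- (1 - phi) * sld_i + phi * par_value(solvent$sld_i)
  }
  tibble::new_tibble(list(thick = par_value(comp$thick), sld = sld,
                          sld_i = sld_i, rough = par_value(comp$rough)),
                     nrow = 1L)
}

#' @export
component_log_prior.slabs_slab <- function(comp) {
  phi <- par_value(comp$vfsolv)
  if (phi < 0 || phi > 1) -Inf else 0
}

#' Lipid leaflet component
#'
#' One half of a lipid bilayer (or a monolayer), parameterised chemically:
#' the area per molecule `A` (Angstrom^2), head and tail region thicknesses
#' `t_x` (Angstrom), summed coherent scattering lengths `b_x` (Angstrom) and
#' partial molecular volumes `V_x` (Angstrom^3). The leaflet contributes two
#' slab rows — head and tail — whose SLDs follow from volume-fraction
#' mixing: the lipid fills a fraction `V_x / (A * t_x)` of region `x`, so
#'
#'   `rho_x = b_x / (A * t_x) + (1 - V_x / (A * t_x)) * rho_x_solv`
#'
#' with the remainder solvent. Because a single `A` enters both regions,
#' heads and tails stay in 1:1 correspondence. Head and tail solvents
#' default to the structure's solvent (the usual solid-liquid situation) but
#' can be overridden for air-liquid or liquid-liquid work. When either
#' region's lipid volume fraction leaves `[0, 1]` the leaflet contributes
#' `-Inf` to the log-prior rather than clipping silently.
#'
#' @param apm Area per molecule, Angstrom^2 (number or parameter; share one
#'   parameter between leaflets/contrasts to link them).
#' @param b_heads,b_tails Summed scattering lengths (Angstrom) of head and
#'   tail groups.
#' @param v_heads,v_tails Partial volumes (Angstrom^3).
#' @param thick_heads,thick_tails Region thicknesses (Angstrom).
#' @param rough_head_tail Roughness between head and tail rows (Angstrom).
#' @param rough_preceding Roughness to the preceding component (Angstrom).
#' @param head_solvent,tail_solvent Optional [material()] overrides for the
#'   solvent in each region; `NULL` uses the structure solvent.
#' @param reverse If `FALSE` the rows are (head, tail) going from fronting
#'   to backing; `TRUE` swaps them (tails first), as needed for the outer
#'   leaflet of a supported bilayer.
#' @param name Component name.
#' @return A component of class `slabs_lipid_leaflet`.
#' @examples
#' inner <- lipid_leaflet(57, 6.01e-4, 319, 9, -2.92e-4, 782, 14, 3, 3)
#' @export
lipid_leaflet <- function(apm, b_heads, v_heads, thick_heads,
                          b_tails, v_tails, thick_tails,
                          rough_head_tail, rough_preceding,
                          head_solvent = NULL, tail_solvent = NULL,
                          reverse = FALSE, name = "leaflet") {
  comp <- list(
    kind = "lipid_leaflet",
    name = name,
    apm = as_parameter(apm, paste(name, "apm")),
    b_heads = as_parameter(b_heads, paste(name, "b_heads")),
    v_heads = as_parameter(v_heads, paste(name, "v_heads")),
    thick_heads = as_parameter(thick_heads, paste(name, "thick_heads")),
    b_tails = as_parameter(b_tails, paste(name, "b_tails")),
    v_tails = as_parameter(v_tails, paste(name, "v_tails")),
    thick_tails = as_parameter(thick_tails, paste(name, "thick_tails")),
    rough_head_tail = as_parameter(rough_head_tail,
                                   paste(name, "rough_head_tail")),
    rough_preceding = as_parameter(rough_preceding,
                                   paste(name, "rough_preceding")),
    head_solvent = if (!is.null(head_solvent))
      as_material(head_solvent, paste(name, "head_solvent")),
    tail_solvent = if (!is.null(tail_solvent))
      as_material(tail_solvent, paste(name, "tail_solvent")),
    reverse = isTRUE(reverse)
  )
  class(comp) <- c("slabs_lipid_leaflet", "slabs_component")
  comp
}

#' @export
collect_parameters.slabs_lipid_leaflet <- function(x) {
  out <- list(x$apm, x$b_heads, x$v_heads, x$thick_heads,
              x$b_tails, x$v_tails, x$thick_tails,
              x$rough_head_tail, x$rough_preceding)
  if (!is.null(x$head_solvent)) out <- c(out, list(x$head_solvent))
  if (!is.null(x$tail_solvent)) out <- c(out, list(x$tail_solvent))
  out
}

leaflet_fractions <- function(comp) {
  a <- par_value(comp$apm)
  c(heads = par_value(comp$v_heads) / (a * par_value(comp$thick_heads)),
    tails = par_value(comp$v_tails) / (a * par_value(comp$thick_tails)))
}

#' @export
component_slabs.slabs_lipid_leaflet <- function(comp, solvent,
                                                solvate = TRUE) {
  a <- par_value(comp$apm)
  row_for <- function(b, v, t, solv_override) {
    vf <- v / (a * t)
    solv <- if (!is.null(solv_override)) solv_override else solvent
    sld <- 1e6 * b / (a * t) + (1 - vf) * par_value(solv$sld)
    sld_i <- (1 - vf) * par_value(solv$sld_i)
    c(thick = t, sld = sld, sld_i = max(sld_i, 0))
  }
  head_row <- row_for(par_value(comp$b_heads), par_value(comp$v_heads),
                      par_value(comp$thick_heads), comp$head_solvent)
  tail_row <- row_for(par_value(comp$b_tails), par_value(comp$v_tails),
                      par_value(comp$thick_tails), comp$tail_solvent)
  first <- if (comp$reverse) tail_row else head_row
  second <- if (comp$reverse) head_row else tail_row
  tibble::new_tibble(list(
    thick = c(first[["thick"]], second[["thick"]]),
    sld = c(first[["sld"]], second[["sld"]]),
    sld_i = c(first[["sld_i"]], second[["sld_i"]]),
    rough = c(par_value(comp$rough_preceding),
              par_value(comp$rough_head_tail))), nrow = 2L)
}

#' @export
component_log_prior.slabs_lipid_leaflet <- function(comp) {
  vf <- leaflet_fractions(comp)
  if (any(vf < 0) || any(vf > 1)) -Inf else 0
}

#' Free-form spline component
#'
#' Models a smooth SLD region by monotone (shape-preserving) cubic
#' interpolation through knots, discretised into `m` equal-thickness slices
#' evaluated at slice midpoints. Slice roughnesses are zero: smoothness
#' comes from the slicing itself.
#'
#' @param dists Knot positions (Angstrom) from the start of the component;
#'   strictly increasing, first knot at 0.
#' @param slds Knot SLD values (1e-6 Angstrom^-2); numbers or parameters.
#' @param m Number of slices (`>= 2`); default one slice per 0.5 Angstrom of
#'   extent, capped at 500.
#' @param rough_preceding Roughness of the first slice to the previous
#'   component.
#' @param name Component name.
#' @return A component of class `slabs_spline`.
#' @export
sld_spline <- function(dists, slds, m = NULL, rough_preceding = 0,
                       name = "spline") {
  if (length(dists) < 2 || length(dists) != length(slds))
    stop("need >= 2 knots with one SLD per knot")
  if (any(diff(dists) <= 0)) stop("knot distances must be strictly increasing")
  extent <- max(dists) - min(dists)
  if (is.null(m)) m <- min(500L, max(2L, ceiling(extent / 0.5)))
  if (m < 2) stop("m must be >= 2")
  comp <- list(
    kind = "spline",
    name = name,
    dists = as.numeric(dists),
    slds = lapply(seq_along(slds), function(i)
      as_parameter(slds[[i]], sprintf("%s sld%d", name, i))),
    m = as.integer(m),
    rough_preceding = as_parameter(rough_preceding,
                                   paste(name, "rough_preceding"))
  )
  class(comp) <- c("slabs_spline", "slabs_component")
  comp
}

#' @export
collect_parameters.slabs_spline <- function(x)
  c(x$slds, list(x$rough_preceding))

#' @export
component_slabs.slabs_spline <- function(comp, solvent, solvate = TRUE) {
  vals <- vapply(comp$slds, par_value, numeric(1))
  f <- stats::splinefun(comp$dists, vals, method = "monoH.FC")
  extent <- max(comp$dists) - min(comp$dists)
  dz <- extent / comp$m
  mid <- min(comp$dists) + (seq_len(comp$m) - 0.5) * dz
  tibble::new_tibble(list(thick = rep(dz, comp$m), sld = f(mid),
                          sld_i = rep(0, comp$m),
                          rough = c(par_value(comp$rough_preceding),
                                    rep(0, comp$m - 1))), nrow = comp$m)
}

# ---- structure -----------------------------------------------------------

#' Assemble components into an interfacial structure
#'
#' A structure is an ordered series of components: the first is the
#' semi-infinite fronting (incident) medium, the last the semi-infinite
#' backing medium. Its slab table is the concatenation of the component
#' rows, with solvent volume fractions resolved against the structure's
#' solvent — by default the backing medium, the usual choice for
#' solid-liquid experiments; pass `solvent =` a [material()] to override
#' (e.g. at the air-liquid interface).
#'
#' @param ... Components, fronting first. The fronting and backing must be
#'   [slab()] components (their thicknesses are ignored).
#' @param solvent Optional [material()] (or SLD value) used to solvate
#'   internal components; `NULL` means the backing medium.
#' @param name Structure name.
#' @return An object of class `slabs_structure`.
#' @examples
#' s <- structure_model(slab(0, 2.07, name = "Si"),
#'                      slab(15, 3.47, rough = 3, name = "SiO2"),
#'                      slab(0, 6.36, rough = 3, name = "D2O"))
#' slabs_of(s)
#' @export
structure_model <- function(..., solvent = NULL, name = "") {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1]]) &&
      !inherits(comps[[1]], "slabs_component"))
    comps <- comps[[1]]
  ok <- vapply(comps, inherits, logical(1), "slabs_component")
  if (!all(ok)) stop("all elements of a structure must be components")
  structure(list(
    components = comps,
    solvent = if (!is.null(solvent)) as_material(solvent, "solvent"),
    name = name
  ), class = "slabs_structure")
}

structure_solvent <- function(s) {
  if (!is.null(s$solvent)) return(s$solvent)
  backing <- s$components[[length(s$components)]]
  if (!inherits(backing, "slabs_slab"))
    stop("structure solvent defaults to the backing medium, which must ",
         "then be a slab; pass `solvent =` explicitly otherwise")
  backing$material
}

#' Slab table of a structure
#'
#' Concatenates the slab rows of every component (fronting and backing rows
#' are never solvated) into the table consumed by [reflectivity()].
#' @param s A `slabs_structure`.
#' @return A slab table (see [slab_table()]).
#' @export
slabs_of <- function(s) {
  stopifnot(inherits(s, "slabs_structure"))
  if (length(s$components) < 2)
    stop("a structure needs at least 2 components (fronting and backing)")
  solv <- structure_solvent(s)
  n <- length(s$components)
  rows <- vector("list", n)
  for (i in seq_len(n))
    rows[[i]] <- component_slabs(s$components[[i]], solvent = solv,
                                 solvate = !(i == 1L || i == n))
  tab <- tibble::new_tibble(list(
    thick = unlist(lapply(rows, `[[`, "thick"), use.names = FALSE),
    sld = unlist(lapply(rows, `[[`, "sld"), use.names = FALSE),
    sld_i = unlist(lapply(rows, `[[`, "sld_i"), use.names = FALSE),
    rough = unlist(lapply(rows, `[[`, "rough"), use.names = FALSE)),
    nrow = sum(vapply(rows, nrow, integer(1))))
  validate_slab_table(tab)
  tab
}

#' @export
collect_parameters.slabs_structure <- function(x) {
  out <- lapply(x$components, collect_parameters)
  if (!is.null(x$solvent)) out <- c(out, list(collect_parameters(x$solvent)))
  out
}

structure_log_prior <- function(s)
  sum(vapply(s$components, component_log_prior, numeric(1)))

#' @export
print.slabs_structure <- function(x, ...) {
  cat(sprintf("<structure '%s': %d components>\n", x$name,
              length(x$components)))
  print(slabs_of(x))
  invisible(x)
}

#' Continuous SLD depth profile of a structure
#'
#' Joins the slab SLDs by error-function transitions of width sigma at each
#' interface — the real-space profile consistent with the Nevot-Croce
#' roughness treatment. `z = 0` is the interface between the fronting medium
#' and the first internal slab; z increases towards the backing.
#'
#' @param s A `slabs_structure`.
#' @param z Depths (Angstrom) at which to evaluate; default a 500-point grid
#'   covering the stack plus margins of 4 roughnesses either side.
#' @return A tibble with columns `z` and `sld` (1e-6 Angstrom^-2).
#' @export
sld_profile <- function(s, z = NULL) {
  tab <- slabs_of(s)
  m <- nrow(tab)
  zi <- c(0, cumsum(tab$thick[-c(1, m)])) # interface positions
  if (is.null(z)) {
    pad <- 4 * max(tab$rough, 5)
    z <- seq(min(zi) - pad, max(zi) + pad, length.out = 500L)
  }
  sld <- rep(tab$sld[1], length(z))
  for (i in seq_len(m - 1)) {
    step <- tab$sld[i + 1] - tab$sld[i]
    sig <- tab$rough[i + 1]
    frac <- if (sig > 0) stats::pnorm((z - zi[i]) / sig)
            else as.numeric(z >= zi[i])
    sld <- sld + step * frac
  }
  tibble::tibble(z = z, sld = sld)
}

# ---- reflectivity models -------------------------------------------------

#' Reflectivity model: structure + scale + background + resolution
#'
#' The model curve is `scale * smear(R(Q)) + background`: the kernel
#' reflectivity of the structure's slab table, resolution-smeared, scaled
#' (for imperfect normalisation of the data) and offset by a Q-independent
#' constant background.
#'
#' @param structure A `slabs_structure`.
#' @param scale,bkg Numbers or parameters.
#' @param resolution A [resolution][resolution] specification; default 5%
#'   constant dQ/Q.
#' @param name Model name.
#' @return An object of class `slabs_model`.
#' @export
reflect_model <- function(structure, scale = 1, bkg = 0,
                          resolution = res_constant(0.05), name = "") {
  stopifnot(inherits(structure, "slabs_structure"),
            inherits(resolution, "slabs_resolution"))
  structure(list(
    structure = structure,
    scale = as_parameter(scale, paste(name, "scale")),
    bkg = as_parameter(bkg, paste(name, "bkg")),
    resolution = resolution,
    name = name
  ), class = c("slabs_reflect_model", "slabs_model"))
}

#' Incoherent mixture of reflectivity models
#'
#' For laterally patchy samples the measured reflectivity is the
#' area-fraction-weighted (incoherent) sum of the reflectivities of the
#' distinct regions: `sum(s_i * smear(R_i(Q))) + background`.
#'
#' @param structures List of `slabs_structure` objects.
#' @param fractions Area fractions (numbers or parameters), one per
#'   structure, each `>= 0`.
#' @param bkg,resolution,name As in [reflect_model()].
#' @return An object of class `slabs_mixed_model`.
#' @export
mixed_reflect_model <- function(structures, fractions, bkg = 0,
                                resolution = res_constant(0.05), name = "") {
  stopifnot(length(structures) == length(fractions), length(structures) >= 1)
  structure(list(
    structures = structures,
    fractions = lapply(seq_along(fractions), function(i)
      as_parameter(fractions[[i]], sprintf("%s fraction%d", name, i))),
    bkg = as_parameter(bkg, paste(name, "bkg")),
    resolution = resolution,
    name = name
  ), class = c("slabs_mixed_model", "slabs_model"))
}

#' @export
collect_parameters.slabs_reflect_model <- function(x)
  list(x$scale, x$bkg, collect_parameters(x$structure))

#' @export
collect_parameters.slabs_mixed_model <- function(x)
  c(lapply(x$structures, collect_parameters), x$fractions, list(x$bkg))

model_log_prior_extra <- function(model) UseMethod("model_log_prior_extra")

#' @export
model_log_prior_extra.slabs_reflect_model <- function(model)
  structure_log_prior(model$structure)

#' @export
model_log_prior_extra.slabs_mixed_model <- function(model) {
  if (any(vapply(model$fractions, par_value, numeric(1)) < 0)) return(-Inf)
  sum(vapply(model$structures, structure_log_prior, numeric(1)))
}

#' Evaluate a model's resolution-smeared reflectivity curve
#'
#' @param model A [reflect_model()] or [mixed_reflect_model()].
#' @param q Q points (inverse Angstrom).
#' @param dq Optional per-point FWHM resolution (inverse Angstrom), required
#'   when the model's resolution is pointwise without stored widths.
#' @return Numeric vector of model reflectivities.
#' @export
model_curve <- function(model, q, dq = NULL) UseMethod("model_curve")

#' @export
model_curve.slabs_reflect_model <- function(model, q, dq = NULL) {
  tab <- slabs_of(model$structure)
  r_of_q <- function(qq) reflectivity(tab, qq)
  par_value(model$scale) * smear(r_of_q, q, model$resolution, dq) +
    par_value(model$bkg)
}

#' @export
model_curve.slabs_mixed_model <- function(model, q, dq = NULL) {
  total <- numeric(length(q))
  for (i in seq_along(model$structures)) {
    tab <- slabs_of(model$structures[[i]])
    r_of_q <- function(qq) reflectivity(tab, qq)
    total <- total +
      par_value(model$fractions[[i]]) * smear(r_of_q, q, model$resolution, dq)
  }
  total + par_value(model$bkg)
}
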