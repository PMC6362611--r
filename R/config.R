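#' Declarative model configuration
#'
#' A fit is reproducible only if the full model — parameters, priors,
#' links, constraints, structures and instrument settings — can be written
#' down and rebuilt exactly. The config is a JSON document with four
#' blocks: `parameters` (name, value, vary, prior, optional constraint
#' string), `structures` (component stacks whose fields are numbers or
#' names of shared parameters), `models` (structure + scale + background +
#' resolution) and optional `datasets` (file per model plus transform).
#' Parameter linking is expressed by referring to the same parameter name
#' from several places; constraints are arithmetic expressions over
#' parameter names.
#'
#' @param path File path.
#' @param config A config list (as returned by [read_model_config()] before
#'   building, or hand-assembled).
#' @name model_config
NULL

prior_to_config <- function(prior) {
  if (is.null(prior)) return(NULL)
  switch(prior$kind,
    interval = list(kind = "interval", lower = prior$lower,
                    upper = prior$upper),
    uniform = list(kind = "uniform", lower = prior$lower,
                   upper = prior$upper),
    normal = {
      # recover mean/sd from the stored support (mean +/- 38 sd)
      mean <- (prior$lower + prior$upper) / 2
      sd <- (prior$upper - prior$lower) / 76
      list(kind = "normal", mean = mean, sd = sd)
    },
    stop("cannot serialise a prior of kind '", prior$kind, "'")
  )
}

prior_from_config <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  switch(cfg$kind,
    interval = prior_interval(cfg$lower, cfg$upper),
    uniform = prior_uniform(cfg$lower, cfg$upper),
    normal = prior_normal(cfg$mean, cfg$sd),
    stop("unknown prior kind in config: ", cfg$kind)
  )
}

#' Serialise a parameter set to a config list (and back)
#'
#' `params_from_config()` rebuilds parameters including constraints, which
#' are parsed as arithmetic over the other parameters' names.
#' @param pset A parameter set.
#' @param cfg A list of parameter records.
#' @return `params_to_config`: list of records. `params_from_config`: a
#'   named list of `slabs_parameter` objects.
#' @export
params_to_config <- function(pset) {
  pset <- parameters(pset)
  lapply(pset, function(p) {
    rec <- list(name = p$name, value = par_value(p),
                vary = p$vary && is.null(p$constraint))
    rec$prior <- prior_to_config(p$prior)
    if (!is.null(p$constraint))
      rec$constraint <- par_expr_deparse(p$constraint)
    rec
  })
}

#' @rdname params_to_config
#' @export
params_from_config <- function(cfg) {
  out <- list()
  for (rec in cfg) {
    if (is.null(rec$name) || !nzchar(rec$name))
      stop("config parameter without a name")
    out[[rec$name]] <- parameter(rec$value, rec$name,
                                 vary = isTRUE(rec$vary),
                                 prior = prior_from_config(rec$prior))
  }
  # second pass: constraints may reference any parameter
  env <- list2env(out, parent = baseenv())
  for (rec in cfg) {
    if (!is.null(rec$constraint)) {
      expr <- tryCatch(eval(parse(text = rec$constraint)[[1]], env),
                       error = function(e)
                         stop("bad constraint for '", rec$name, "': ",
                              conditionMessage(e)))
      set_constraint(out[[rec$name]], expr)
    }
  }
  out
}

# Resolve a config field: a number -> fixed parameter; a string -> named
# parameter from the registry.
field_par <- function(x, registry, where) {
  if (is.null(x)) stop("missing required field in ", where)
  if (is.character(x)) {
    p <- registry[[x]]
    if (is.null(p))
      stop("config field in ", where, " references unknown parameter '",
           x, "'")
    return(p)
  }
  as_parameter(x, where)
}

component_from_config <- function(cfg, registry) {
  kind <- cfg$kind %||% stop("component without a 'kind'")
  name <- cfg$name %||% kind
  where <- paste0("component '", name, "'")
  switch(kind,
    slab = slab(field_par(cfg$thick %||% 0, registry, where),
                material(field_par(cfg$sld, registry, where),
                         field_par(cfg$sld_i %||% 0, registry, where),
                         name = name),
                rough = field_par(cfg$rough %||% 0, registry, where),
                vfsolv = field_par(cfg$vfsolv %||% 0, registry, where),
                name = name),
    lipid_leaflet = lipid_leaflet(
      field_par(cfg$apm, registry, where),
      field_par(cfg$b_heads, registry, where),
      field_par(cfg$v_heads, registry, where),
      field_par(cfg$thick_heads, registry, where),
      field_par(cfg$b_tails, registry, where),
      field_par(cfg$v_tails, registry, where),
      field_par(cfg$thick_tails, registry, where),
      rough_head_tail = field_par(cfg$rough_head_tail %||% 3, registry,
                                  where),
      rough_preceding = field_par(cfg$rough_preceding %||% 3, registry,
                                  where),
      reverse = isTRUE(cfg$reverse), name = name),
    spline = sld_spline(unlist(cfg$dists),
                        lapply(cfg$slds, field_par, registry, where),
                        m = cfg$m,
                        rough_preceding = field_par(
                          cfg$rough_preceding %||% 0, registry, where),
                        name = name),
    stop("unknown component kind in config: ", kind)
  )
}

resolution_from_config <- function(cfg) {
  if (is.null(cfg)) return(res_constant(0.05))
  switch(cfg$kind %||% "constant",
    none = res_none(),
    constant = res_constant(cfg$dqq %||% 0.05),
    pointwise = res_pointwise(),
    kernel = res_kernel(unlist(cfg$offsets), unlist(cfg$weights)),
    stop("unknown resolution kind in config: ", cfg$kind)
  )
}

resolution_to_config <- function(res) {
  switch(res$kind,
    none = list(kind = "none"),
    constant = list(kind = "constant", dqq = res$dqq),
    pointwise = list(kind = "pointwise"),
    kernel = list(kind = "kernel", offsets = res$offsets,
                  weights = res$weights),
  )
}

#' Read and build a model configuration
#'
#' Parses the JSON config and constructs the shared parameters, structures
#' and models. Malformed configs fail with a message naming the offending
#' key.
#'
#' @param path Path to a JSON config file.
#' @return A list with `registry` (named shared parameters), `models`
#'   (named list of models), `datasets` (config records) and `config` (the
#'   raw parsed list).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  registry <- params_from_config(cfg$parameters %||% list())
  structures <- list()
  for (scfg in cfg$structures %||% list()) {
    sname <- scfg$name %||% sprintf("structure%d", length(structures) + 1L)
    comps <- lapply(scfg$components %||%
                      stop("structure '", sname, "' has no components"),
                    component_from_config, registry = registry)
    solvent <- if (!is.null(scfg$solvent))
      material(field_par(scfg$solvent, registry,
                         paste0("solvent of '", sname, "'")))
    structures[[sname]] <- structure_model(comps, solvent = solvent,
                                           name = sname)
  }
  models <- list()
  for (mcfg in cfg$models %||% list()) {
    mname <- mcfg$name %||% sprintf("model%d", length(models) + 1L)
    sname <- mcfg$structure %||% stop("model '", mname,
                                      "' names no structure")
    if (is.null(structures[[sname]]))
      stop("model '", mname, "' references unknown structure '", sname, "'")
    models[[mname]] <- reflect_model(
      structures[[sname]],
      scale = field_par(mcfg$scale %||% 1, registry,
                        paste0("scale of '", mname, "'")),
      bkg = field_par(mcfg$bkg %||% 0, registry,
                      paste0("bkg of '", mname, "'")),
      resolution = resolution_from_config(mcfg$resolution),
      name = mname)
  }
  list(registry = registry, structures = structures, models = models,
       datasets = cfg$datasets %||% list(), config = cfg)
}

#' Build a co-refinement objective from a built config and data files
#'
#' @param built Result of [read_model_config()].
#' @param data_files Named (by model) or ordered character vector of data
#'   file paths; overrides any `datasets` block in the config.
#' @return A `slabs_objective` (one dataset) or `slabs_global_objective`.
#' @export
objective_from_config <- function(built, data_files = NULL) {
  models <- built$models
  if (length(models) == 0) stop("config defines no models")
  if (is.null(data_files)) {
    recs <- built$datasets
    if (length(recs) == 0) stop("config has no datasets block and no data ",
                                "files were supplied")
    data_files <- vapply(recs, function(r)
      r$file %||% stop("datasets entry without 'file'"), character(1))
    names(data_files) <- vapply(recs, function(r)
      r$model %||% names(models)[1], character(1))
  }
  if (is.null(names(data_files)) || !all(nzchar(names(data_files))))
    names(data_files) <- names(models)[seq_along(data_files)]
  objs <- lapply(names(data_files), function(mn) {
    if (is.null(models[[mn]]))
      stop("dataset mapped to unknown model '", mn, "'")
    objective(models[[mn]], read_refl_data(data_files[[mn]]), name = mn)
  })
  if (length(objs) == 1L) objs[[1]] else global_objective(objs)
}

# ---- writing configs -----------------------------------------------------

component_to_config <- function(comp, par_name) {
  if (inherits(comp, "slabs_slab")) {
    list(kind = "slab", name = comp$name,
         thick = par_name(comp$thick), sld = par_name(comp$material$sld),
         sld_i = par_name(comp$material$sld_i),
         rough = par_name(comp$rough), vfsolv = par_name(comp$vfsolv))
  } else if (inherits(comp, "slabs_lipid_leaflet")) {
    list(kind = "lipid_leaflet", name = comp$name,
         apm = par_name(comp$apm),
         b_heads = par_name(comp$b_heads), v_heads = par_name(comp$v_heads),
         thick_heads = par_name(comp$thick_heads),
         b_tails = par_name(comp$b_tails), v_tails = par_name(comp$v_tails),
         thick_tails = par_name(comp$thick_tails),
         rough_head_tail = par_name(comp$rough_head_tail),
         rough_preceding = par_name(comp$rough_preceding),
         reverse = comp$reverse)
  } else if (inherits(comp, "slabs_spline")) {
    list(kind = "spline", name = comp$name, dists = comp$dists,
         slds = lapply(comp$slds, par_name), m = comp$m,
         rough_preceding = par_name(comp$rough_preceding))
  } else stop("cannot serialise component of class ", class(comp)[1])
}

#' Serialise models (and their shared parameters) to a config file
#'
#' Every parameter reachable from the models is written once to the
#' `parameters` block under a unique name; component fields then refer to
#' those names, so sharing and constraints survive a round trip.
#'
#' @param models Named list of models (or a single model).
#' @param path Output JSON path.
#' @param datasets Optional named character vector mapping model names to
#'   data files, written to the `datasets` block.
#' @param extra Optional named list merged into the top level (e.g.
#'   simulation settings).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(models, path, datasets = NULL, extra = NULL) {
  if (inherits(models, "slabs_model")) {
    models <- stats::setNames(list(models),
                              if (nzchar(models$name)) models$name
                              else "model1")
  }
  pset <- parameters(models)
  nms <- character(length(pset))
  for (i in seq_along(pset)) {
    base <- if (nzchar(pset[[i]]$name)) gsub("^\\s+|\\s+$", "",
                                             pset[[i]]$name) else "par"
    nm <- base
    j <- 1L
    while (nm %in% nms) {
      j <- j + 1L
      nm <- sprintf("%s#%d", base, j)
    }
    nms[i] <- nm
    pset[[i]]$name <- nm # unique names are needed for referencing
  }
  par_name <- function(p) p$name
  structures <- list()
  model_recs <- list()
  for (mn in names(models)) {
    m <- models[[mn]]
    if (!inherits(m, "slabs_reflect_model"))
      stop("only single-structure models can be serialised to config")
    sname <- if (nzchar(m$structure$name)) m$structure$name else mn
    structures[[sname]] <- list(
      name = sname,
      solvent = if (!is.null(m$structure$solvent))
        par_name(m$structure$solvent$sld),
      components = lapply(m$structure$components, component_to_config,
                          par_name = par_name))
    model_recs[[mn]] <- list(name = mn, structure = sname,
                             scale = par_name(m$scale),
                             bkg = par_name(m$bkg),
                             resolution = resolution_to_config(m$resolution))
  }
  cfg <- c(list(parameters = params_to_config(pset),
                structures = unname(structures),
                models = unname(model_recs)),
           if (!is.null(datasets))
             list(datasets = lapply(names(datasets), function(mn)
               list(model = mn, file = unname(datasets[[mn]])))),
           extra)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
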