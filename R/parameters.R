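#' Model parameters
#'
#' A parameter is a named scalar model value (a thickness in Angstrom, a
#' scattering length density in 1e-6 Angstrom^-2, a unitless scale ...)
#' together with a `vary` flag saying whether a fit may change it and a prior
#' distribution encoding what is known about it beforehand. Parameters have
#' reference semantics: the same parameter object can appear in several
#' components or several models, and changing its value changes it
#' everywhere. That sharing — by object identity, not by name — is the
#' mechanism for linking parameters between datasets during co-refinement.
#'
#' @param value Initial numeric value.
#' @param name Parameter name. Names need not be unique (identity, not the
#'   name, links parameters), but duplicated names in one set trigger a
#'   warning when flattened.
#' @param vary Logical; should a fit vary this value?
#' @param prior A [prior][priors] object, or `NULL` for an improper flat
#'   prior.
#' @return An object of class `slabs_parameter`.
#' @examples
#' th <- parameter(100, "thickness", vary = TRUE, prior = prior_interval(50, 150))
#' par_value(th)
#' @seealso [set_constraint()], [parameters()]
#' @export
parameter <- function(value, name = "", vary = FALSE, prior = NULL) {
  stopifnot(is.numeric(value), length(value) == 1L, is.character(name))
  if (!is.null(prior) && !inherits(prior, "slabs_prior"))
    stop("`prior` must be a slabs_prior object (see prior_interval())")
  p <- new.env(parent = emptyenv())
  p$name <- name
  p$value <- as.numeric(value)
  p$vary <- isTRUE(vary)
  p$prior <- prior
  p$constraint <- NULL
  p$.evaluating <- FALSE
  class(p) <- "slabs_parameter"
  p
}

#' Coerce a number or parameter to a parameter
#'
#' Plain numbers given to component constructors become fixed (non-varying)
#' parameters; existing parameters pass through untouched so they stay
#' shared.
#' @param x Numeric scalar or `slabs_parameter`.
#' @param name Name used when a new parameter is created.
#' @return A `slabs_parameter`.
#' @export
as_parameter <- function(x, name = "") {
  if (inherits(x, "slabs_parameter")) return(x)
  if (inherits(x, "slabs_parexpr")) {
    p <- parameter(par_expr_value(x), name)
    set_constraint(p, x)
    return(p)
  }
  parameter(x, name)
}

#' Read a parameter's current value
#'
#' Constrained parameters re-evaluate their defining expression, so the
#' returned value always reflects the current values of the parameters they
#' depend on.
#' @param p A `slabs_parameter`.
#' @return Numeric scalar.
#' @export
par_value <- function(p) {
  if (is.null(p$constraint)) return(p$value)
  if (p$.evaluating)
    stop(sprintf("constraint cycle detected while evaluating parameter '%s'",
                 p$name))
  p$.evaluating <- TRUE
  on.exit(p$.evaluating <- FALSE)
  val <- par_expr_value(p$constraint)
  p$value <- val
  val
}

#' Set a parameter's value
#' @param p A `slabs_parameter`.
#' @param value New numeric value.
#' @return The parameter, invisibly.
#' @export
set_value <- function(p, value) {
  if (!is.null(p$constraint))
    stop(sprintf("parameter '%s' is constrained; clear the constraint first",
                 p$name))
  p$value <- as.numeric(value)
  invisible(p)
}

#' @export
print.slabs_parameter <- function(x, ...) {
  tag <- if (!is.null(x$constraint)) "constrained"
         else if (x$vary) "vary" else "fixed"
  cat(sprintf("<parameter '%s' = %g (%s)>\n", x$name, par_value(x), tag))
  invisible(x)
}

# ---- constraint expressions ---------------------------------------------
# Arithmetic on parameters builds an expression tree instead of a number;
# assigning the tree to another parameter with set_constraint() ties its
# value to the tree, re-evaluated on every read.

new_parexpr <- function(op, args) {
  structure(list(op = op, args = args), class = "slabs_parexpr")
}

#' @export
Ops.slabs_parameter <- function(e1, e2) {
  if (missing(e2)) new_parexpr(.Generic, list(e1))
  else new_parexpr(.Generic, list(e1, e2))
}

#' @export
Ops.slabs_parexpr <- function(e1, e2) {
  if (missing(e2)) new_parexpr(.Generic, list(e1))
  else new_parexpr(.Generic, list(e1, e2))
}

#' @export
Math.slabs_parameter <- function(x, ...) new_parexpr(.Generic, list(x))

#' @export
Math.slabs_parexpr <- function(x, ...) new_parexpr(.Generic, list(x))

par_expr_value <- function(x) {
  if (is.numeric(x)) return(x)
  if (inherits(x, "slabs_parameter")) return(par_value(x))
  if (inherits(x, "slabs_parexpr")) {
    vals <- lapply(x$args, par_expr_value)
    return(do.call(x$op, unname(vals)))
  }
  stop("invalid constraint expression element of class ",
       paste(class(x), collapse = "/"))
}

par_expr_leaves <- function(x) {
  if (inherits(x, "slabs_parameter")) return(list(x))
  if (inherits(x, "slabs_parexpr"))
    return(do.call(c, lapply(x$args, par_expr_leaves)))
  list()
}

par_expr_deparse <- function(x) {
  if (is.numeric(x)) return(format(x, digits = 17))
  if (inherits(x, "slabs_parameter")) {
    if (!nzchar(x$name))
      stop("cannot serialise a constraint involving an unnamed parameter")
    return(x$name)
  }
  a <- vapply(x$args, par_expr_deparse, character(1))
  if (length(a) == 1L) {
    if (x$op == "-") return(sprintf("(-%s)", a[1]))
    if (x$op == "+") return(a[1])
    return(sprintf("%s(%s)", x$op, a[1]))
  }
  sprintf("(%s %s %s)", a[1], x$op, a[2])
}

# All parameters a constraint (transitively) depends on.
constraint_closure <- function(expr) {
  seen <- list()
  stack <- par_expr_leaves(expr)
  while (length(stack)) {
    p <- stack[[1]]
    stack <- stack[-1]
    if (any(vapply(seen, identical, logical(1), p))) next
    seen <- c(seen, list(p))
    if (!is.null(p$constraint))
      stack <- c(stack, par_expr_leaves(p$constraint))
  }
  seen
}

#' Constrain a parameter to an algebraic expression of other parameters
#'
#' The expression is built with ordinary arithmetic on parameter objects,
#' e.g. `set_constraint(t3, total - t1 - t2)` keeps a third thickness equal
#' to a known total minus the other two. A constrained parameter stops
#' varying and its value follows its dependencies lazily: reading it after a
#' dependency changed returns the re-evaluated expression. Cycles are
#' rejected at assignment time.
#'
#' @param p The parameter to constrain.
#' @param expr A `slabs_parexpr` (from arithmetic on parameters), another
#'   parameter, or a numeric constant. `NULL` removes the constraint.
#' @return `p`, invisibly.
#' @examples
#' p1 <- parameter(1, "p1"); p2 <- parameter(2, "p2"); p3 <- parameter(0, "p3")
#' set_constraint(p3, p1 + p2)
#' par_value(p3) # 3
#' @export
set_constraint <- function(p, expr) {
  if (is.null(expr)) {
    p$constraint <- NULL
    return(invisible(p))
  }
  if (!(is.numeric(expr) || inherits(expr, "slabs_parameter") ||
        inherits(expr, "slabs_parexpr")))
    stop("constraint must be a parameter expression, a parameter or a number")
  closure <- constraint_closure(expr)
  if (any(vapply(closure, identical, logical(1), p))) {
    nms <- vapply(closure, function(q) q$name, character(1))
    stop(sprintf("constraint would create a cycle through: %s",
                 paste(unique(c(p$name, nms)), collapse = " -> ")))
  }
  p$constraint <- expr
  p$vary <- FALSE
  par_value(p) # evaluate once so value is current
  invisible(p)
}

# ---- parameter sets ------------------------------------------------------

#' Collect parameters into a set
#'
#' Flattens any mix of parameters, lists, other sets, components, structures,
#' models and objectives into one ordered set. Each underlying parameter
#' object appears exactly once, however many components share it — the
#' deduplication key is object identity, never the name.
#'
#' @param ... Parameters or objects holding parameters.
#' @return An object of class `slabs_parameters` (a list of parameters).
#' @export
parameters <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L) {
    # objectives carry a cache: their parameter graph is fixed at
    # construction and the identity dedup is quadratic
    cache <- attr(objs[[1]], "pset_cache", exact = TRUE)
    if (is.environment(cache)) {
      if (is.null(cache$pset)) cache$pset <- parameters_build(objs)
      return(cache$pset)
    }
  }
  parameters_build(objs)
}

parameters_build <- function(objs) {
  flat <- list()
  grab <- function(x) {
    if (is.null(x)) return()
    if (inherits(x, "slabs_parameter")) {
      flat[[length(flat) + 1L]] <<- x
      return()
    }
    has_method <- any(vapply(class(x), function(cl)
      !is.null(utils::getS3method("collect_parameters", cl,
                                  optional = TRUE)), logical(1)))
    if (has_method) {
      grab(collect_parameters(x))
    } else if (is.list(x)) {
      for (el in unclass(x)) grab(el)
    } else {
      stop("cannot collect parameters from object of class ", class(x)[1])
    }
  }
  for (o in objs) grab(o)
  out <- list()
  for (p in flat)
    if (!any(vapply(out, identical, logical(1), p)))
      out[[length(out) + 1L]] <- p
  structure(out, class = c("slabs_parameters", "list"))
}

# Internal generic: objects that own parameters implement this.
collect_parameters <- function(x) UseMethod("collect_parameters")

#' @export
collect_parameters.default <- function(x)
  stop("no parameters in object of class ", class(x)[1])

#' Varying (free) parameters of a set
#'
#' Constrained parameters are never free, whatever their `vary` flag was
#' before the constraint was applied.
#' @param pset A `slabs_parameters` set (or anything [parameters()] accepts).
#' @return A `slabs_parameters` set containing the free parameters, in the
#'   stable order of the parent set.
#' @export
varying_parameters <- function(pset) {
  if (!inherits(pset, "slabs_parameters")) pset <- parameters(pset)
  keep <- vapply(pset, function(p) p$vary && is.null(p$constraint), logical(1))
  structure(unclass(pset)[keep], class = c("slabs_parameters", "list"))
}

#' Sum of log-prior densities over the varying parameters
#'
#' Returns `-Inf` as soon as any varying value falls outside its prior's
#' support. Fixed and constrained parameters contribute nothing.
#' @param pset A parameter set, or any object holding parameters (objectives
#'   add their components' extra prior terms through their own methods).
#' @return Numeric scalar.
#' @export
log_prior <- function(pset) UseMethod("log_prior")

#' @export
log_prior.default <- function(pset) {
  vp <- varying_parameters(pset)
  total <- 0
  for (p in vp) {
    lp <- prior_logpdf(p$prior, par_value(p))
    if (!is.finite(lp)) return(-Inf)
    total <- total + lp
  }
  total
}

#' Flatten the free parameters to a numeric vector (and back)
#'
#' `flatten_varying()` returns the current values of the free parameters in
#' stable order; `set_from_vector()` is its inverse and round-trips exactly.
#' These two functions are the bridge between the parameter graph and the
#' optimisers/samplers, which see a plain numeric vector.
#'
#' @param pset A parameter set.
#' @param x Numeric vector of length `length(varying_parameters(pset))`.
#' @return `flatten_varying`: named numeric vector. `set_from_vector`: the
#'   set, invisibly.
#' @export
flatten_varying <- function(pset) {
  vp <- varying_parameters(pset)
  nms <- vapply(vp, function(p) p$name, character(1))
  if (anyDuplicated(nms[nzchar(nms)]))
    warning("duplicated parameter names in set: ",
            paste(unique(nms[duplicated(nms)]), collapse = ", "))
  stats::setNames(vapply(vp, par_value, numeric(1)), nms)
}

#' @rdname flatten_varying
#' @export
set_from_vector <- function(pset, x) {
  vp <- varying_parameters(pset)
  if (length(x) != length(vp))
    stop(sprintf("expected %d values for varying parameters, got %d",
                 length(vp), length(x)))
  for (i in seq_along(vp)) vp[[i]]$value <- as.numeric(x[[i]])
  invisible(pset)
}

#' @export
print.slabs_parameters <- function(x, ...) {
  cat(sprintf("<parameter set: %d parameters, %d varying>\n",
              length(x), length(varying_parameters(x))))
  print(tidy_parameters(x))
  invisible(x)
}

#' Tabular view of a parameter set
#' @param pset A parameter set.
#' @return A tibble with one row per parameter: name, value, vary,
#'   constrained, prior kind and bounds.
#' @export
tidy_parameters <- function(pset) {
  pset <- parameters(pset)
  tibble::tibble(
    name = vapply(pset, function(p) p$name, character(1)),
    value = vapply(pset, par_value, numeric(1)),
    vary = vapply(pset, function(p) p$vary && is.null(p$constraint),
                  logical(1)),
    constrained = vapply(pset, function(p) !is.null(p$constraint), logical(1)),
    prior = vapply(pset, function(p) if (is.null(p$prior)) "none"
                   else p$prior$kind, character(1)),
    lower = vapply(pset, function(p) if (is.null(p$prior)) -Inf
                   else p$prior$lower, numeric(1)),
    upper = vapply(pset, function(p) if (is.null(p$prior)) Inf
                   else p$prior$upper, numeric(1))
  )
}

# Finite bounds for bounded optimisers, taken from the prior support.
varying_bounds <- function(pset) {
  vp <- varying_parameters(pset)
  lower <- vapply(vp, function(p) if (is.null(p$prior)) -Inf else p$prior$lower,
                  numeric(1))
  upper <- vapply(vp, function(p) if (is.null(p$prior)) Inf else p$prior$upper,
                  numeric(1))
  list(lower = lower, upper = upper)
}
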