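#' Reflectivity datasets
#'
#' A reflectivity dataset is a tibble with columns `q` (momentum transfer,
#' inverse Angstrom), `r` (reflectivity), `dr` (one standard deviation of
#' `r`) and optionally `dq` (FWHM of the instrument resolution function,
#' inverse Angstrom), sorted by ascending `q`. This mirrors the common
#' three- and four-column plain-text reflectometry file dialect.
#'
#' @param q,r,dr,dq Equal-length numeric vectors (`dq` optional).
#' @param name Dataset label.
#' @return A tibble of class `slabs_data`.
#' @export
refl_data <- function(q, r, dr, dq = NULL, name = "") {
  n <- length(q)
  if (length(r) != n || length(dr) != n || (!is.null(dq) && length(dq) != n))
    stop("q, r, dr (and dq if given) must have equal lengths")
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and > 0")
  if (any(dr <= 0)) stop("dr must be > 0 (one standard deviation of r)")
  if (!is.null(dq) && any(dq < 0)) stop("dq must be >= 0")
  d <- tibble::tibble(q = as.numeric(q), r = as.numeric(r),
                      dr = as.numeric(dr))
  if (!is.null(dq)) d$dq <- as.numeric(dq)
  d <- d[order(d$q), ]
  attr(d, "name") <- name
  class(d) <- c("slabs_data", class(d))
  d
}

has_dq <- function(data) "dq" %in% names(data)

#' Read a 3- or 4-column reflectivity data file
#'
#' Parses whitespace- or comma-delimited numeric rows. Lines starting with
#' `#` and non-numeric header lines are skipped. Three columns are read as
#' `Q, R, dR`; four as `Q, R, dR, dQ` with `dR` one standard deviation and
#' `dQ` the resolution FWHM. Columns beyond the fourth are ignored with a
#' warning (some reduction programs append extras). Rows are sorted by
#' ascending Q.
#'
#' @param path Path to the file.
#' @param name Dataset label; defaults to the file name.
#' @return A [refl_data] tibble.
#' @export
read_refl_data <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  ncol_seen <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[,[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      if (length(rows) == 0L) next # header line before the numbers start
      stop(sprintf("non-numeric row at line %d of %s", i, path))
    }
    if (length(vals) < 3)
      stop(sprintf("line %d of %s has %d numeric columns; need >= 3",
                   i, path, length(vals)))
    if (is.null(ncol_seen)) {
      ncol_seen <- length(vals)
      if (ncol_seen > 4)
        warning(sprintf("%s has %d columns; columns beyond 4 are ignored",
                        path, ncol_seen))
    } else if (length(vals) != ncol_seen) {
      stop(sprintf("ragged row at line %d of %s: %d columns, expected %d",
                   i, path, length(vals), ncol_seen))
    }
    rows[[length(rows) + 1L]] <- vals[seq_len(min(4L, length(vals)))]
  }
  if (length(rows) == 0L) stop("no numeric data rows in ", path)
  mat <- do.call(rbind, rows)
  refl_data(q = mat[, 1], r = mat[, 2], dr = mat[, 3],
            dq = if (ncol(mat) >= 4) mat[, 4], name = name)
}

#' Write a reflectivity dataset as a plain-text 3/4-column file
#'
#' @param data A [refl_data] tibble (or any data frame with `q`, `r`, `dr`
#'   and optionally `dq` columns).
#' @param path Output file path.
#' @param header Optional comment lines written with a `#` prefix.
#' @return `path`, invisibly.
#' @export
write_refl_data <- function(data, path, header = NULL) {
  cols <- c("q", "r", "dr", if (has_dq(data)) "dq")
  mat <- as.matrix(as.data.frame(data)[cols])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines(apply(mat, 1, function(row)
    paste(formatC(row, format = "e", digits = 12), collapse = " ")), con)
  invisible(path)
}

#' Fitting-space transforms
#'
#' Reflectivity spans many decades, so fits are often performed on a
#' transformed scale: `logY` fits `log10(R)` versus Q and `YX4` fits
#' `R*Q^4` versus Q (removing the asymptotic Fresnel decay). Uncertainties
#' follow by first-order propagation: `dR/(R*ln 10)` and `dR*Q^4`
#' respectively. The default, `none`, fits R versus Q untransformed.
#'
#' @param kind One of `"none"`, `"logY"`, `"YX4"`.
#' @return An object of class `slabs_transform`.
#' @export
transform_spec <- function(kind = c("none", "logY", "YX4")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "slabs_transform")
}

as_transform <- function(x) {
  if (inherits(x, "slabs_transform")) return(x)
  transform_spec(x)
}

#' Apply a fitting-space transform to a curve and its uncertainties
#'
#' @param t A [transform_spec()] (or its kind as a string).
#' @param q,r Q and reflectivity vectors.
#' @param dr Optional uncertainty vector (one standard deviation).
#' @return A list with `y` and (when `dr` was given) `dy`.
#' @export
apply_transform <- function(t, q, r, dr = NULL) {
  t <- as_transform(t)
  switch(t$kind,
    none = list(y = r, dy = dr),
    logY = {
      bad <- which(r <= 0)
      if (length(bad))
        stop("logY transform requires R > 0; offending indices: ",
             paste(utils::head(bad, 10), collapse = ", "))
      list(y = log10(r), dy = if (!is.null(dr)) dr / (r * log(10)))
    },
    YX4 = list(y = r * q^4, dy = if (!is.null(dr)) dr * q^4)
  )
}
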