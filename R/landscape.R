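#' Define a rectangular landscape
#'
#' A landscape is a planar rectangle of area `A` with one side of length
#' `L`; its extent is `[0, L] x [0, A/L]`. Large `L` relative to `sqrt(A)`
#' gives elongated, valley-like landscapes; `L = sqrt(A)` gives a square.
#'
#' @param A landscape area (squared length units, `A > 0`).
#' @param L length of one side (length units, `L > 0`).
#' @return An object of class `"ahn_landscape"` with fields `A`, `L`,
#'   `width` (= `L`) and `height` (= `A / L`).
#' @examples
#' landscape(A = 25, L = 5)    # square 5 x 5
#' landscape(A = 25, L = 50)   # narrow strip 50 x 0.5
#' @export
landscape <- function(A, L) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("'A' must be a single positive number", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("'L' must be a single positive number", call. = FALSE)
  structure(list(A = A, L = L, width = L, height = A / L),
            class = "ahn_landscape")
}

#' @export
print.ahn_landscape <- function(x, ...) {
  cat(sprintf("Rectangular landscape: area %g, extent %g x %g (aspect ratio %g)\n",
              x$A, x$width, x$height, x$width / x$height))
  invisible(x)
}

#' Sample a uniform patch layout
#'
#' Draws `N` habitat-patch coordinates independently and uniformly on the
#' landscape extent `[0, L] x [0, A/L]`. Optional per-patch attributes
#' `u` (heterogeneity / qualitative properties) and `v` (size / quantitative
#' properties) are produced by caller-supplied samplers; they are left unset
#' otherwise, as no default distribution is assumed for them.
#'
#' @param land an [landscape()] object.
#' @param N number of patches (positive integer).
#' @param seed optional integer seed; a fixed seed reproduces the layout
#'   exactly. `NULL` uses the ambient RNG stream.
#' @param u_sampler,v_sampler optional functions of one argument `n`
#'   returning `n` attribute values (e.g. `function(n) runif(n)`).
#' @return An object of class `"ahn_layout"`: a `data.frame` with columns
#'   `id`, `x`, `y` and optionally `u`, `v`, carrying the landscape as
#'   attribute `"landscape"`.
#' @examples
#' land <- landscape(25, 5)
#' sample_layout(land, 30, seed = 1)
#' @export
sample_layout <- function(land, N, seed = NULL,
                          u_sampler = NULL, v_sampler = NULL) {
  stopifnot(inherits(land, "ahn_landscape"))
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer", call. = FALSE)
  N <- as.integer(N)
  out <- with_seed(seed, {
    df <- data.frame(id = seq_len(N),
                     x = runif(N, 0, land$width),
                     y = runif(N, 0, land$height))
    if (!is.null(u_sampler)) df$u <- u_sampler(N)
    if (!is.null(v_sampler)) df$v <- v_sampler(N)
    df
  })
  attr(out, "landscape") <- land
  class(out) <- c("ahn_layout", "data.frame")
  out
}

#' Validate a user-supplied patch layout
#'
#' Accepts externally defined coordinates (e.g. from observed habitats or a
#' point-process simulator) after checking that every point lies inside the
#' landscape and that no two patches coincide. Coincident patches are
#' rejected because the reciprocal distance kernel is undefined at
#' distance zero.
#'
#' @param land an [landscape()] object.
#' @param coords a data.frame (or matrix) with numeric columns `x` and `y`
#'   (the first two columns are used if unnamed); optional columns `id`,
#'   `u`, `v` are carried through.
#' @return An `"ahn_layout"` object; coordinates pass through unchanged.
#' @examples
#' land <- landscape(25, 5)
#' validate_layout(land, data.frame(x = c(0, 5, 0, 5), y = c(0, 0, 5, 5)))
#' @export
validate_layout <- function(land, coords) {
  stopifnot(inherits(land, "ahn_landscape"))
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords))) {
    if (ncol(coords) < 2L)
      stop("'coords' needs two numeric columns (x, y)", call. = FALSE)
    names(coords)[1:2] <- c("x", "y")
  }
  if (!is.numeric(coords$x) || !is.numeric(coords$y))
    stop("'coords' columns x and y must be numeric", call. = FALSE)
  n <- nrow(coords)
  if (n < 1L) stop("'coords' must contain at least one point", call. = FALSE)
  bad <- which(coords$x < 0 | coords$x > land$width |
               coords$y < 0 | coords$y > land$height |
               !is.finite(coords$x) | !is.finite(coords$y))
  if (length(bad))
    stop(sprintf("point(s) outside landscape bounds at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  dup <- which(duplicated(coords[, c("x", "y")]))
  if (length(dup))
    stop(sprintf(paste0("duplicate coordinates at row(s): %s ",
                        "(coincident patches give undefined reciprocal-distance weights)"),
                 paste(dup, collapse = ", ")), call. = FALSE)
  out <- data.frame(id = if ("id" %in% names(coords)) coords$id else seq_len(n),
                    x = coords$x, y = coords$y)
  for (a in c("u", "v")) if (a %in% names(coords)) out[[a]] <- coords[[a]]
  attr(out, "landscape") <- land
  class(out) <- c("ahn_layout", "data.frame")
  out
}

#' @export
print.ahn_layout <- function(x, ...) {
  land <- attr(x, "landscape")
  cat(sprintf("Patch layout: %d patches on a %g x %g landscape\n",
              nrow(x), land$width, land$height))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more patches\n", nrow(x) - 6L))
  invisible(x)
}

#' Read / write patch layouts as CSV
#'
#' The on-disk format is a delimited table with columns `id, x, y` and
#' optional `u, v`.
#'
#' @param land an [landscape()] object used to validate the coordinates.
#' @param path file path.
#' @return `read_layout()` returns an `"ahn_layout"`; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(land, path) {
  validate_layout(land, utils::read.csv(path))
}

#' @rdname read_layout
#' @param layout an `"ahn_layout"` object.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "ahn_layout"))
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}
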