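#' Grayordinate geometry
#'
#' A geometry describes the combined spatial axis used throughout the package:
#' `n_total` grayordinates of which the first block (indexed by `cortex_index`)
#' are cortical surface vertices and the remainder subcortical voxels.
#' Coordinates are 3-D positions in mm used for distance-based operations
#' (geodesic masking, spatial smoothing of synthetic fields).
#'
#' @param n_total total number of grayordinates.
#' @param n_cortex number of cortical surface vertices (`n_cortex <= n_total`).
#' @param cortex_index integer index of the cortical vertices within the
#'   grayordinate axis; defaults to `1:n_cortex`.
#' @param coordinates numeric `n_total x 3` matrix of positions (mm), or `NULL`
#'   if no distance-based operation will be requested.
#' @param radius radius (mm) of the sphere carrying the cortical vertices, when
#'   the geometry is spherical (synthetic geometries); `NA` otherwise.
#'
#' @return An object of class `"geometry"`.
#' @export
geometry <- function(n_total, n_cortex, cortex_index = seq_len(n_cortex),
                     coordinates = NULL, radius = NA_real_) {
  stopifnot(n_cortex <= n_total, n_total >= 1)
  cortex_index <- as.integer(cortex_index)
  if (anyDuplicated(cortex_index) > 0) {
    stop("cortex_index must not contain duplicates", call. = FALSE)
  }
  if (length(cortex_index) != n_cortex) {
    stop("cortex_index must have length n_cortex", call. = FALSE)
  }
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != n_total || ncol(coordinates) != 3) {
      stop("coordinates must be an n_total x 3 matrix", call. = FALSE)
    }
  }
  structure(
    list(
      n_total = as.integer(n_total),
      n_cortex = as.integer(n_cortex),
      cortex_index = cortex_index,
      coordinates = coordinates,
      radius = radius
    ),
    class = "geometry"
  )
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf(
    "<geometry> %d grayordinates (%d cortical, %d subcortical)%s\n",
    x$n_total, x$n_cortex, x$n_total - x$n_cortex,
    if (is.null(x$coordinates)) ", no coordinates" else ""
  ))
  invisible(x)
}

is_cortical <- function(geom) {
  out <- logical(geom$n_total)
  out[geom$cortex_index] <- TRUE
  out
}

#' Pairwise grayordinate distances
#'
#' Distances between grayordinates in mm. Cortical-cortical pairs use the
#' great-circle (geodesic) metric when the geometry is spherical; any pair
#' involving a subcortical voxel uses the Euclidean metric, as does a
#' non-spherical geometry throughout.
#'
#' @param geom a [geometry()] with coordinates.
#' @param from,to integer grayordinate indices; defaults to all.
#' @return numeric `length(from) x length(to)` matrix of distances (mm).
#' @export
grayordinate_distances <- function(geom, from = seq_len(geom$n_total),
                                   to = seq_len(geom$n_total)) {
  if (is.null(geom$coordinates)) {
    stop("geometry carries no coordinates; distances unavailable", call. = FALSE)
  }
  P <- geom$coordinates[from, , drop = FALSE]
  Q <- geom$coordinates[to, , drop = FALSE]
  ## Euclidean distances for all pairs first
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * tcrossprod(P, Q)
  d2[d2 < 1e-8] <- 0   # clamp numerically negative / coincident points
  D <- sqrt(d2)
  if (!is.na(geom$radius)) {
    ctx <- is_cortical(geom)
    ci <- which(ctx[from])
    cj <- which(ctx[to])
    if (length(ci) && length(cj)) {
      r <- geom$radius
      ## chord length -> central angle -> arc length
      chord <- D[ci, cj, drop = FALSE] / (2 * r)
      chord[chord > 1] <- 1
      D[ci, cj] <- 2 * r * asin(chord)
    }
  }
  dimnames(D) <- NULL
  D
}

#' Grayordinates within a radius of a cortical vertex set
#'
#' Returns the indices of all grayordinates lying within `radius_mm` of any
#' vertex in `vertex_set` (cortical targets by the great-circle metric on a
#' spherical geometry, subcortical targets by the Euclidean metric).
#'
#' @param geom a [geometry()] with coordinates.
#' @param vertex_set integer grayordinate indices (typically a parcel's
#'   cortical vertices).
#' @param radius_mm neighborhood radius in mm.
#' @return sorted integer vector of grayordinate indices (includes
#'   `vertex_set` itself: every point is within 0 mm of itself).
#' @export
vertex_neighborhood <- function(geom, vertex_set, radius_mm) {
  if (length(vertex_set) == 0) return(integer(0))
  D <- grayordinate_distances(geom, from = vertex_set)
  which(apply(D <= radius_mm, 2, any))
}

#' Deterministic spherical geometry for synthetic cohorts
#'
#' Places `n_cortex` cortical vertices on a sphere of radius 80 mm using a
#' Fibonacci (golden-angle) lattice -- a deterministic low-discrepancy layout
#' with near-uniform spacing -- and the remaining grayordinates inside a
#' separate subcortical ball (radius 20 mm, centered 120 mm below the sphere
#' center), also laid out deterministically.
#'
#' @param n_total total grayordinates.
#' @param n_cortex cortical vertices (`>= 3`).
#' @param radius cortical sphere radius in mm.
#' @return a [geometry()].
#' @export
make_geometry <- function(n_total, n_cortex, radius = 80) {
  stopifnot(n_cortex >= 3, n_total >= n_cortex)
  coords <- matrix(0, n_total, 3)
  coords[seq_len(n_cortex), ] <- fibonacci_sphere(n_cortex) * radius
  n_sub <- n_total - n_cortex
  if (n_sub > 0) {
    ## shells of a Fibonacci lattice filling a ball, center (0, 0, -120)
    u <- (seq_len(n_sub) - 0.5) / n_sub
    shell <- fibonacci_sphere(n_sub) * (20 * u^(1 / 3))
    shell[, 3] <- shell[, 3] - 120
    coords[n_cortex + seq_len(n_sub), ] <- shell
  }
  geometry(n_total, n_cortex, coordinates = coords, radius = radius)
}

## golden-angle lattice on the unit sphere; rows are unit vectors
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
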