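#' @name geometry
#' @title Structure-derived geometric quantities
#' @description
#' Five quantities describe a candidate residue pair: the mean (`D1`) and
#' population standard deviation (`SD D1`) of all cross heavy-atom distances,
#' the Calpha-Calpha distance (`Dalpha`), the relative residue angle `delta`
#' between the two residue-plane normals, and the inter-helical tilt angle
#' `theta` between the axes of the helices carrying the two residues. All
#' five are invariant under rigid transforms of the chain, which is what
#' makes them transferable between experimentally determined and predicted
#' structures.
NULL

unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Helix axis from carbonyl-to-amide vectors
#'
#' The axis direction of an alpha-helix is estimated as the average direction
#' of the vectors from the carbonyl oxygen O(i) to the amide nitrogen N(i+4)
#' of its hydrogen-bond partner, over all residues i of the segment for which
#' both atoms exist. Individual vectors are normalized before averaging and
#' the mean renormalized, so each helical turn contributes equal weight.
#'
#' @param chain a [chain_structure()].
#' @param segment length-2 integer vector `c(start, end)` (inclusive), or a
#'   one-row segment data.frame with `start`/`end`.
#' @return A `helix_axis` object: unit `direction` (3-vector) and
#'   `n_vectors`, the number of (O, N+4) vector pairs averaged.
#' @export
helix_axis <- function(chain, segment) {
  if (is.data.frame(segment)) segment <- c(segment$start[1L], segment$end[1L])
  start <- as.integer(segment[1L]); end <- as.integer(segment[2L])
  if (end - start + 1L < 5L)
    stop("helix_axis: segment [", start, ",", end,
         "] shorter than 5 residues; axis undefined")
  acc <- c(0, 0, 0); nvec <- 0L
  for (i in start:(end - 4L)) {
    r1 <- get_residue(chain, i)
    r2 <- get_residue(chain, i + 4L)
    if (is.null(r1) || is.null(r2)) next
    if (!("O" %in% rownames(r1$coords)) || !("N" %in% rownames(r2$coords))) next
    acc <- acc + unit(r2$coords["N", ] - r1$coords["O", ])
    nvec <- nvec + 1L
  }
  if (nvec == 0L)
    stop("helix_axis: no residue i in [", start, ",", end - 4L,
         "] with O(i) and N(i+4) present; axis undefined")
  structure(list(direction = unname(unit(acc)), n_vectors = nvec),
            class = "helix_axis")
}

#' Inter-helical tilt angle
#'
#' The angle between two helix axis directions, in degrees, in \[0, 180\]:
#' 0 for parallel and 180 for antiparallel packing (the two are biologically
#' distinct, so the angle is not folded to \[0, 90\] by default).
#'
#' @param a,b `helix_axis` objects or unit 3-vectors.
#' @param fold if `TRUE`, fold to \[0, 90\] (axis treated as undirected).
#' @return Angle in degrees.
#' @export
tilt_angle <- function(a, b, fold = FALSE) {
  va <- if (inherits(a, "helix_axis")) a$direction else unit(a)
  vb <- if (inherits(b, "helix_axis")) b$direction else unit(b)
  ang <- acos(clamp1(sum(va * vb))) * 180 / pi
  if (fold && ang > 90) ang <- 180 - ang
  ang
}

#' Residue plane normal
#'
#' The plane of a residue is spanned by the vectors Calpha->N and Calpha->C;
#' the normal is their cross product (in that fixed order), normalized.
#'
#' @param r a residue from [get_residue()]; atoms N, CA and C must be present.
#' @return Unit 3-vector.
#' @export
residue_plane_normal <- function(r) {
  cc <- r$coords
  need <- c("N", "CA", "C")
  if (is.null(r) || !all(need %in% rownames(cc)))
    stop("residue_plane_normal: residue lacks one of N, CA, C")
  v1 <- cc["N", ] - cc["CA", ]
  v2 <- cc["C", ] - cc["CA", ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(nrm * nrm)) < 1e-9)
    stop("residue_plane_normal: N-CA and C-CA are collinear; plane degenerate")
  unit(nrm)
}

#' Relative residue angle
#'
#' The angle between the plane normals of two residues, in degrees,
#' in \[0, 180\]; symmetric in its arguments.
#'
#' @param r1,r2 residues from [get_residue()].
#' @return Angle in degrees.
#' @export
relative_residue_angle <- function(r1, r2) {
  n1 <- residue_plane_normal(r1)
  n2 <- residue_plane_normal(r2)
  acos(clamp1(sum(n1 * n2))) * 180 / pi
}

#' Relative residue distances
#'
#' `d1_mean` is the mean Euclidean distance over all M x N cross pairs of the
#' two residues' heavy atoms; `d1_sd` is the population standard deviation of
#' those M x N distances (divisor MN, not MN - 1); `d_alpha` is the distance
#' between the two alpha carbons.
#'
#' @param r1,r2 residues from [get_residue()].
#' @return Distance(s) in Angstrom.
#' @export
d1_mean <- function(r1, r2) mean(cross_dists(r1, r2))

#' @rdname d1_mean
#' @export
d1_sd <- function(r1, r2) {
  d <- cross_dists(r1, r2)
  sqrt(mean((d - mean(d))^2))
}

#' @rdname d1_mean
#' @export
d_alpha <- function(r1, r2) {
  if (!("CA" %in% rownames(r1$coords)) || !("CA" %in% rownames(r2$coords)))
    stop("d_alpha: residue lacks a CA atom")
  sqrt(sum((r1$coords["CA", ] - r2$coords["CA", ])^2))
}

cross_dists <- function(r1, r2) {
  if (is.null(r1) || is.null(r2) || nrow(r1$coords) == 0L || nrow(r2$coords) == 0L)
    stop("relative residue distance: residue with no atoms")
  sqrt(cross_sqdist(r1$coords, r2$coords))
}

#' All five geometric quantities for one residue pair
#'
#' @param r1,r2 residues from [get_residue()].
#' @param axis1,axis2 `helix_axis` objects (or unit vectors) for the helices
#'   carrying `r1` and `r2`.
#' @return Named numeric vector `c(d1_mean, d1_sd, d_alpha, delta, theta)`.
#' @export
pair_geometry <- function(r1, r2, axis1, axis2) {
  d <- cross_dists(r1, r2)
  m <- mean(d)
  c(d1_mean = m,
    d1_sd   = sqrt(mean((d - m)^2)),
    d_alpha = d_alpha(r1, r2),
    delta   = relative_residue_angle(r1, r2),
    theta   = tilt_angle(axis1, axis2))
}
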