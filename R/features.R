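# The sixteen trajectory-topology descriptors. Three families:
#   area      - SACC SACT STTC SATCC SDTTC SATTC
#   distortion- SAC BC ACU SDCP
#   center    - SD45 SD135 SP SDCO DBNF DGCO
# All operate on an ordered n x 2 point matrix (a planar trajectory).

#' Names of the sixteen topological features
#' @return Character vector in canonical order.
#' @export
topo_feature_names <- function() {
  c("SACC", "SACT", "STTC", "SATCC", "SDTTC", "SATTC",
    "SAC", "BC", "ACU", "SDCP",
    "SD45", "SD135", "SP", "SDCO", "DBNF", "DGCO")
}

.traj_mat <- function(traj, min_n, what) {
  if (inherits(traj, "planar_trajectory")) traj <- traj$points
  traj <- as.matrix(traj)
  if (ncol(traj) != 2L) .fail("%s needs an n x 2 trajectory", what)
  if (nrow(traj) < min_n)
    .fail("%s needs at least %d points, got %d", what, min_n, nrow(traj))
  unname(traj)
}

# consecutive segment vectors (n-1 x 2)
.segs <- function(m) diff(m)

# angle in degrees between consecutive vectors of a vector sequence;
# zero-length vectors contribute angle 0
.turn_angles_deg <- function(v) {
  u <- v[-nrow(v), , drop = FALSE]
  w <- v[-1L, , drop = FALSE]
  nu <- .row_norms(u); nw <- .row_norms(w)
  cosang <- rowSums(u * w) / (nu * nw)
  cosang[nu == 0 | nw == 0] <- 1       # degenerate: no turn
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# incircle radius of triangles given side lengths (Heron, clipped at 0)
.heron_area <- function(a, b, c) {
  s <- (a + b + c) / 2
  sqrt(pmax(s * (s - a) * (s - b) * (s - c), 0))
}

# triangle "tangent circle" centers: the per-triangle vertex centroid
.tri_centers <- function(m) {
  n <- nrow(m)
  (m[1:(n - 2L), , drop = FALSE] + m[2:(n - 1L), , drop = FALSE] +
      m[3:n, , drop = FALSE]) / 3
}

#' Sum of the areas of consecutive-segment circles (SACC)
#'
#' Each consecutive point pair defines a circle whose diameter is the
#' segment length; SACC is the total area `sum(pi/4 * l_i^2)`.
#' @param traj ordered n x 2 matrix or `planar_trajectory` (n >= 2).
#' @return A nonnegative number.
#' @export
sacc <- function(traj) {
  m <- .traj_mat(traj, 2L, "SACC")
  sum(pi / 4 * rowSums(.segs(m)^2))
}

#' Sum of the areas of consecutive-point triangles (SACT)
#'
#' Unsigned area of every triangle of three consecutive points, summed
#' (determinant formula, absolute value per triangle).
#' @inheritParams sacc
#' @export
sact <- function(traj) {
  m <- .traj_mat(traj, 3L, "SACT")
  n <- nrow(m)
  i <- 1:(n - 2L)
  x1 <- m[i, 1]; y1 <- m[i, 2]
  x2 <- m[i + 1L, 1]; y2 <- m[i + 1L, 2]
  x3 <- m[i + 2L, 1]; y3 <- m[i + 2L, 2]
  sum(abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2)
}

#' Sum of the areas of the triangles' incircles (STTC)
#'
#' For each consecutive-point triangle, the inscribed-circle radius is
#' `r = 2*Area/perimeter`; STTC sums `pi r^2`. Degenerate (zero-side or
#' collinear) triangles contribute zero.
#' @inheritParams sacc
#' @export
sttc <- function(traj) {
  m <- .traj_mat(traj, 3L, "STTC")
  n <- nrow(m)
  a <- .row_norms(m[2:(n - 1L), , drop = FALSE] - m[1:(n - 2L), , drop = FALSE])
  b <- .row_norms(m[3:n, , drop = FALSE] - m[2:(n - 1L), , drop = FALSE])
  cc <- .row_norms(m[3:n, , drop = FALSE] - m[1:(n - 2L), , drop = FALSE])
  S <- .heron_area(a, b, cc)
  per <- a + b + cc
  r <- ifelse(per > 0, 2 * S / per, 0)
  sum(pi * r^2)
}

#' Sum of the areas of consecutive-point/origin triangles (SATCC)
#'
#' Every consecutive point pair forms a triangle with the coordinate
#' origin; areas via Heron's formula on the three side lengths, summed
#' over the n-1 pairs.
#' @inheritParams sacc
#' @export
satcc <- function(traj) {
  m <- .traj_mat(traj, 2L, "SATCC")
  n <- nrow(m)
  alpha <- .row_norms(m[1:(n - 1L), , drop = FALSE])
  beta <- .row_norms(m[2:n, , drop = FALSE])
  gam <- .row_norms(.segs(m))
  sum(.heron_area(alpha, beta, gam))
}

#' Path length through the triangle centers (SDTTC)
#'
#' The centers of the consecutive-point triangles (vertex centroids) form a
#' secondary path; SDTTC is its total length (n-3 center-to-center
#' distances from n-2 centers).
#' @param traj ordered n x 2 matrix or `planar_trajectory` (n >= 4).
#' @export
sdttc <- function(traj) {
  m <- .traj_mat(traj, 4L, "SDTTC")
  sum(.row_norms(.segs(.tri_centers(m))))
}

#' Sum of turn angles along the center path (SATTC)
#'
#' Angles, in degrees, between consecutive center-to-center vectors of the
#' triangle-center path (n-4 angles).
#' @param traj ordered n x 2 matrix or `planar_trajectory` (n >= 5).
#' @export
sattc <- function(traj) {
  m <- .traj_mat(traj, 5L, "SATTC")
  sum(.turn_angles_deg(.segs(.tri_centers(m))))
}

#' Area-family features
#'
#' All six at once: [sacc()], [sact()], [sttc()], [satcc()], [sdttc()],
#' [sattc()]. The umbrella call requires n >= 5 (the smallest n at which
#' every member is defined); the individual functions go down to their own
#' minima.
#' @inheritParams sattc
#' @return Named numeric vector of length 6.
#' @export
area_features <- function(traj) {
  m <- .traj_mat(traj, 5L, "area_features")
  c(SACC = sacc(m), SACT = sact(m), STTC = sttc(m),
    SATCC = satcc(m), SDTTC = sdttc(m), SATTC = sattc(m))
}

#' Sum of trajectory turn angles (SAC)
#'
#' Angles, in degrees, between consecutive segment vectors of the
#' trajectory itself (n-2 angles); zero-length segments contribute 0.
#' @param traj ordered n x 2 matrix or `planar_trajectory` (n >= 3).
#' @export
sac <- function(traj) {
  m <- .traj_mat(traj, 3L, "SAC")
  sum(.turn_angles_deg(.segs(m)))
}

#' Boundary complexity (BC)
#'
#' Convex-hull perimeter divided by convex-hull area. A degenerate
#' (collinear or coincident) point set has zero hull area; BC is then
#' `Inf`, with a warning.
#' @inheritParams sac
#' @export
bc <- function(traj) {
  m <- .traj_mat(traj, 3L, "BC")
  h <- grDevices::chull(m[, 1], m[, 2])
  hull <- m[h, , drop = FALSE]
  k <- nrow(hull)
  closed <- rbind(hull, hull[1L, ])
  per <- sum(.row_norms(diff(closed)))
  area <- abs(sum(closed[-(k + 1L), 1] * closed[-1L, 2] -
                    closed[-1L, 1] * closed[-(k + 1L), 2])) / 2
  if (area <= 0) {
    warning("degenerate hull (zero area): BC is Inf")
    return(Inf)
  }
  per / area
}

#' Average curvature along the trajectory (ACU)
#'
#' Menger curvature at each interior point (the inverse circumradius of the
#' three consecutive points, `2|u x v| / (|u||v||u+v|)`), with the endpoint
#' curvatures copied from their neighbours, averaged over all n points.
#' `mode = "as_printed"` instead uses `2/(|u||v|)` for non-collinear point
#' triples and 0 for collinear ones.
#' @inheritParams sac
#' @param mode `"menger"` (default) or `"as_printed"`.
#' @export
acu <- function(traj, mode = c("menger", "as_printed")) {
  mode <- match.arg(mode)
  m <- .traj_mat(traj, 3L, "ACU")
  v <- .segs(m)
  u <- v[-nrow(v), , drop = FALSE]
  w <- v[-1L, , drop = FALSE]
  cross <- abs(u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nu <- .row_norms(u); nw <- .row_norms(w); nuw <- .row_norms(u + w)
  if (mode == "menger") {
    den <- nu * nw * nuw
    cu <- ifelse(den > 0, 2 * cross / den, 0)
  } else {
    cu <- ifelse(cross > 0, 2 / (nu * nw), 0)
  }
  cu <- c(cu[1L], cu, cu[length(cu)])   # CU1 = CU2, CUN = CU(N-1)
  mean(cu)
}

#' Trajectory path length (SDCP)
#'
#' Sum of consecutive-point distances.
#' @param traj ordered n x 2 matrix or `planar_trajectory` (n >= 2).
#' @export
sdcp <- function(traj) {
  m <- .traj_mat(traj, 2L, "SDCP")
  sum(.row_norms(.segs(m)))
}

#' Distortion-family features
#'
#' [sac()], [bc()], [acu()] and [sdcp()] together (n >= 3).
#' @inheritParams acu
#' @return Named numeric vector of length 4.
#' @export
distortion_features <- function(traj, mode = c("menger", "as_printed")) {
  m <- .traj_mat(traj, 3L, "distortion_features")
  c(SAC = sac(m), BC = bc(m), ACU = acu(m, mode), SDCP = sdcp(m))
}

#' Center-family features
#'
#' Distances of the trajectory points to the coordinate frame:
#' `SD45 = sum |Y - X| / sqrt(2)` (distance to the 45-degree bisector),
#' `SD135 = sum |X + Y| / sqrt(2)` (distance to the 135-degree bisector),
#' `SP` = product of the population standard deviations of those two
#' distance sequences, `SDCO` = summed distance to the origin, `DBNF` =
#' distance between the origin-nearest and origin-farthest points (ties to
#' the lower index), `DGCO` = distance of the centroid from the origin.
#' @param traj ordered n x 2 matrix or `planar_trajectory` (n >= 1).
#' @return Named numeric vector of length 6.
#' @export
center_features <- function(traj) {
  m <- .traj_mat(traj, 1L, "center_features")
  x <- m[, 1]; y <- m[, 2]
  d45 <- abs(y - x) / sqrt(2)
  d135 <- abs(x + y) / sqrt(2)
  r <- sqrt(x^2 + y^2)
  near <- which.min(r); far <- which.max(r)
  c(SD45 = sum(d45), SD135 = sum(d135),
    SP = pop_sd(d45) * pop_sd(d135),
    SDCO = sum(r),
    DBNF = sqrt(sum((m[far, ] - m[near, ])^2)),
    DGCO = sqrt(sum(colMeans(m)^2)))
}

#' All sixteen topological features of a planar trajectory
#'
#' @inheritParams acu
#' @param traj ordered n x 2 matrix or `planar_trajectory` (n >= 5).
#' @return Named numeric vector of length 16 in [topo_feature_names()]
#'   order.
#' @examples
#' tri <- rbind(c(0, 0), c(3, 0), c(3, 4), c(0, 4), c(0, 1))
#' topo_features(tri)[c("SACC", "BC")]
#' @export
topo_features <- function(traj, mode = c("menger", "as_printed")) {
  m <- .traj_mat(traj, 5L, "topo_features")
  c(area_features(m), distortion_features(m, mode), center_features(m))
}
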