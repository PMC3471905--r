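#' Subdomain centers of mass
#'
#' Unweighted mean Calpha position of each of the four subdomains (all
#' network beads are identical particles, so the geometric mean is the
#' center of mass).
#'
#' @param coords n x 3 coordinate matrix for the protein beads, in the
#'   structure's row order.
#' @param s an [en_structure()] with subdomains assigned.
#' @return A 4 x 3 matrix with rows `S1..S4`.
#' @export
subdomain_com <- function(coords, s) {
  labs <- c("S1", "S2", "S3", "S4")
  out <- matrix(NA_real_, 4L, 3L, dimnames = list(labs, c("x", "y", "z")))
  for (k in seq_along(labs)) {
    idx <- which(s$subdomain == labs[k])
    if (length(idx) == 0L) stop("subdomain ", labs[k], " is empty", call. = FALSE)
    out[k, ] <- colMeans(coords[idx, , drop = FALSE])
  }
  out
}

signed_dihedral <- function(p1, p2, p3, p4) {
  # dihedral of the point sequence p1-p2-p3-p4 about the p2->p3 axis,
  # right-handed, degrees in (-180, 180]
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  b2n <- sqrt(sum(b2^2))
  if (b2n < 1e-12) stop("dihedral axis degenerate (coincident centers)", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / b2n
  phi <- atan2(y, x) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  phi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Domain order parameters d13, d24 and phi
#'
#' Reduces a conformation to three numbers: `d13`, the distance between the
#' centers of mass of subdomains S1 and S3; `d24`, the distance between the
#' centers of mass of S2 and S4 (the scissor coordinate of the inter-domain
#' cleft); and `phi`, the signed dihedral angle between the plane through
#' the centers of S1, S2, S3 and the plane through S1, S3, S4, measured
#' right-handed about the S1-S3 axis (the propeller-twist coordinate).
#' All three are invariant under rigid motions of the whole coordinate set;
#' `phi` changes sign under mirror reflection.
#'
#' @inheritParams subdomain_com
#' @return A one-row tibble with columns `d13`, `d24`, `phi` (degrees,
#'   in (-180, 180]).
#' @export
compute_order_parameters <- function(coords, s) {
  com <- subdomain_com(coords, s)
  d13 <- sqrt(sum((com["S1", ] - com["S3", ])^2))
  d24 <- sqrt(sum((com["S2", ] - com["S4", ])^2))
  if (d13 < 1e-12) stop("S1 and S3 centers coincide; dihedral undefined", call. = FALSE)
  phi <- signed_dihedral(com["S2", ], com["S1", ], com["S3", ], com["S4", ])
  tibble::tibble(d13 = d13, d24 = d24, phi = phi)
}

wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Order-parameter changes relative to a reference state
#'
#' Distance changes are relative (dimensionless), the angle change is in
#' degrees and wrapped to (-180, 180].
#'
#' @param state,ref_state one-row tibbles as returned by
#'   [compute_order_parameters()].
#' @return A one-row tibble with columns `dd13_rel`, `dd24_rel`, `dphi`.
#' @export
deltas_vs_reference <- function(state, ref_state) {
  tibble::tibble(
    dd13_rel = (state$d13 - ref_state$d13) / ref_state$d13,
    dd24_rel = (state$d24 - ref_state$d24) / ref_state$d24,
    dphi = wrap_angle(state$phi - ref_state$phi)
  )
}
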