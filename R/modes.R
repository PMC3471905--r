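#' Hessian (linearization matrix) of the network potential
#'
#' Analytic second derivative of the full network potential at the given
#' coordinates, in the 3m x 3m super-element form: for every pair
#' interaction with radial potential U(r), the off-diagonal block is
#' `-(U''(r) P + (U'(r)/r) (I - P))` with `P` the outer product of the unit
#' separation vector, and diagonal blocks accumulate the negatives. At the
#' reference coordinates of an unstrained harmonic network this reduces to
#' the standard ANM Hessian `kappa P` per link. Breakable pairs contribute
#' only within their truncation length. Coordinates are interleaved
#' `(x1, y1, z1, x2, ...)`.
#'
#' @param net an `elastic_network`.
#' @param coords coordinates at which to linearize (default: reference).
#' @return A symmetric 3m x 3m matrix.
#' @export
network_hessian <- function(net, coords = network_coords(net)) {
  coords <- check_coords(net, coords)
  m <- nrow(coords)
  H <- matrix(0, 3L * m, 3L * m)
  add_pair <- function(H, i, j, upp, up_r) {
    d <- coords[j, ] - coords[i, ]
    r <- sqrt(sum(d^2))
    u <- d / r
    P <- tcrossprod(u)
    K <- upp * P + up_r * (diag(3) - P)
    bi <- (3L * (i - 1L) + 1L):(3L * i)
    bj <- (3L * (j - 1L) + 1L):(3L * j)
    H[bi, bj] <- H[bi, bj] - K
    H[bj, bi] <- H[bj, bi] - K
    H[bi, bi] <- H[bi, bi] + K
    H[bj, bj] <- H[bj, bj] + K
    H
  }
  for (k in seq_len(nrow(net$links))) {
    i <- net$links$i[k]; j <- net$links$j[k]
    d <- coords[j, ] - coords[i, ]
    r <- sqrt(sum(d^2))
    H <- add_pair(H, i, j, net$kappa, net$kappa * (r - net$links$r0[k]) / r)
  }
  if (!is.null(net$breakable)) {
    b <- net$breakable
    for (k in seq_len(nrow(b$pairs))) {
      i <- b$pairs$i[k]; j <- b$pairs$j[k]
      d <- coords[j, ] - coords[i, ]
      r <- sqrt(sum(d^2))
      if (r >= b$truncation) next
      upp <- b$strength * (156 * b$r0^12 / r^14 - 84 * b$r0^6 / r^8)
      up <- lj_breakable(r, b$strength, b$r0, b$truncation, deriv = 1)
      H <- add_pair(H, i, j, upp, up / r)
    }
  }
  (H + t(H)) / 2
}

#' Normal relaxation modes of the linearized network
#'
#' Full eigendecomposition of the Hessian. In the overdamped dynamics the
#' eigenvalues are the relaxation rate constants of the normal modes; a
#' connected network has exactly six zero eigenvalues (rigid translations
#' and rotations), and the slowest nonzero modes carry the collective
#' domain motions.
#'
#' @param net an `elastic_network`.
#' @param tol zero-mode tolerance relative to the largest eigenvalue.
#' @return An object of class `normal_mode_set` with `eigenvalues`
#'   (ascending), `vectors` (orthonormal columns, same order),
#'   `zero_count`, and the absolute tolerance used.
#' @export
normal_modes <- function(net, tol = 1e-8) {
  H <- network_hessian(net)
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  ev <- e$values[ord]
  vec <- e$vectors[, ord, drop = FALSE]
  tol_abs <- tol * max(abs(ev))
  nm <- list(eigenvalues = ev, vectors = vec,
             zero_count = sum(abs(ev) < tol_abs), tol = tol_abs,
             n_nodes = n_nodes(net))
  class(nm) <- "normal_mode_set"
  nm
}

#' @export
print.normal_mode_set <- function(x, ...) {
  nz <- x$eigenvalues[abs(x$eigenvalues) >= x$tol]
  cat(sprintf(
    "# normal_mode_set: %d nodes, %d modes, %d zero mode(s); slowest nonzero %.4g\n",
    x$n_nodes, length(x$eigenvalues), x$zero_count,
    if (length(nz)) min(nz) else NA_real_))
  invisible(x)
}

#' @export
tidy.normal_mode_set <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
                 zero = abs(x$eigenvalues) < x$tol)
}

#' @export
glance.normal_mode_set <- function(x, ...) {
  nz <- x$eigenvalues[abs(x$eigenvalues) >= x$tol]
  tibble::tibble(n_nodes = x$n_nodes, n_modes = length(x$eigenvalues),
                 zero_count = x$zero_count,
                 lambda_slowest = if (length(nz)) min(nz) else NA_real_,
                 lambda_max = max(x$eigenvalues))
}

mode_displacement <- function(nm, mode) {
  v <- nm$vectors[, mode]
  matrix(v, ncol = 3L, byrow = TRUE)
}

#' Coordinate frames along a single normal mode
#'
#' Assuming only one normal mode is excited, bead motions follow the mode
#' eigenvector; this samples one sinusoidal period of that motion, scaled
#' so the largest per-bead excursion equals `amplitude`. The frames feed
#' [write_conformations()] for animation.
#'
#' @param net an `elastic_network`.
#' @param nm a [normal_modes()] result.
#' @param mode mode index (must be a nonzero mode).
#' @param amplitude maximum per-bead displacement, Angstrom (> 0).
#' @param n_frames number of frames over one period.
#' @return List of m x 3 coordinate matrices.
#' @export
mode_trajectory <- function(net, nm, mode, amplitude = 2, n_frames = 21L) {
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (abs(nm$eigenvalues[mode]) < nm$tol) {
    stop("mode ", mode, " is a rigid-body (zero) mode", call. = FALSE)
  }
  disp <- mode_displacement(nm, mode)
  disp <- disp / max(sqrt(rowSums(disp^2)))
  ref <- network_coords(net)
  lapply(sin(2 * pi * seq(0, 1, length.out = n_frames)), function(s) {
    ref + amplitude * s * disp
  })
}

#' Label slow modes as propeller or scissor by order-parameter projection
#'
#' Displaces the reference along each of the slowest nonzero modes and
#' measures the induced change in the dihedral angle and in the relative
#' S2-S4 distance. Within the examined set, the mode whose (normalized)
#' dihedral response dominates is labelled `"propeller"`, the one dominated
#' by the d24 response `"scissor"`. The label is assigned empirically, by
#' projection, rather than by eigenvalue rank, and each mode is oriented so
#' that its dominant order parameter increases.
#'
#' @param net an `elastic_network` whose structure has subdomain labels.
#' @param nm a [normal_modes()] result.
#' @param n_slow how many of the slowest nonzero modes to examine.
#' @param amplitude probe displacement, Angstrom (small, linear regime).
#' @return Tibble with `mode`, `eigenvalue`, `dphi`, `dd24_rel`,
#'   `dd13_rel`, `label`.
#' @export
label_slow_modes <- function(net, nm, n_slow = 2L, amplitude = 0.5) {
  nonzero <- which(abs(nm$eigenvalues) >= nm$tol)
  modes <- utils::head(nonzero, n_slow)
  s <- net$structure
  np <- nrow(s)
  ref <- network_coords(net)
  ref_state <- compute_order_parameters(ref[seq_len(np), , drop = FALSE], s)
  rows <- purrr::map(modes, function(k) {
    disp <- mode_displacement(nm, k)
    disp <- disp / max(sqrt(rowSums(disp^2)))
    st <- compute_order_parameters((ref + amplitude * disp)[seq_len(np), ,
                                                            drop = FALSE], s)
    d <- deltas_vs_reference(st, ref_state)
    tibble::tibble(mode = k, eigenvalue = nm$eigenvalues[k],
                   dphi = d$dphi, dd24_rel = d$dd24_rel, dd13_rel = d$dd13_rel)
  })
  out <- dplyr::bind_rows(rows)
  z_phi <- abs(out$dphi) / max(abs(out$dphi), 1e-300)
  z_d24 <- abs(out$dd24_rel) / max(abs(out$dd24_rel), 1e-300)
  out$label <- ifelse(z_phi >= z_d24, "propeller", "scissor")
  out
}
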