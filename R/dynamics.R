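#' Integration options for the overdamped dynamics
#'
#' The equations of motion are integrated with the explicit Euler method
#' (Euler-Maruyama when noise is on). In the rescaled units used, the
#' friction coefficient and the spring stiffness are both 1, so relaxation
#' rates are Hessian eigenvalues and a force of 1 stretches one link by
#' 1 Angstrom. Stationarity is declared when, per step, the sum of the six
#' pairwise subdomain-COM distances changes by less than `eps_dist` and the
#' dihedral angle by less than `eps_angle`.
#'
#' @param dt Euler time step, rescaled time units. The default 0.01 is
#'   safely below the stability limit `2 / lambda_max` for networks with
#'   typical ANM coordination; [check_timestep()] verifies a given choice.
#' @param max_steps maximum number of integration steps.
#' @param eps_dist stationarity threshold on the summed subdomain-COM
#'   distances, Angstrom per step.
#' @param eps_angle stationarity threshold on the dihedral, degrees per step.
#' @param record_stride record order parameters every this many steps.
#' @param seed integer seed for the noise generator (ignored when
#'   `noise_D = 0`).
#' @param noise_D thermal noise intensity D; each coordinate receives an
#'   independent Gaussian increment of variance `2 D dt` per step. 0 gives
#'   deterministic relaxation.
#' @param immobilize `NULL` (default) applies rigid-body balancing forces
#'   exactly when a nonzero external field is present; `TRUE`/`FALSE`
#'   force it on or off.
#' @return A list of class `integration_options`.
#' @export
integration_options <- function(dt = 0.01, max_steps = 500000L,
                                eps_dist = 1e-6, eps_angle = 1e-6,
                                record_stride = 100L, seed = NULL,
                                noise_D = 0, immobilize = NULL) {
  stopifnot(dt > 0, eps_dist > 0, eps_angle > 0, noise_D >= 0)
  opts <- list(dt = dt, max_steps = as.integer(max_steps),
               eps_dist = eps_dist, eps_angle = eps_angle,
               record_stride = as.integer(record_stride), seed = seed,
               noise_D = noise_D, immobilize = immobilize)
  class(opts) <- "integration_options"
  opts
}

subdomain_index_list <- function(net) {
  s <- net$structure
  labs <- c("S1", "S2", "S3", "S4")
  idx <- lapply(labs, function(l) which(s$subdomain == l))
  if (any(vapply(idx, length, integer(1)) == 0L)) list() else idx
}

zero_field <- function(net) matrix(0, n_nodes(net), 3L)

pad_field <- function(net, field) {
  if (is.null(field)) return(zero_field(net))
  field <- as.matrix(field)
  m <- n_nodes(net)
  if (nrow(field) == nrow(net$structure) && m > nrow(field)) {
    field <- rbind(field, matrix(0, m - nrow(field), 3L))
  }
  if (nrow(field) != m || ncol(field) != 3L) {
    stop("force field must be ", m, " x 3 (ligand nodes may be omitted)",
         call. = FALSE)
  }
  if (!all(is.finite(field))) stop("force field must be finite", call. = FALSE)
  field
}

run_integrator <- function(net, coords, field, opts, check_stationarity,
                           max_steps = opts$max_steps,
                           record_frames = FALSE, frame_stride = 1000L) {
  coords <- check_coords(net, coords)
  field <- pad_field(net, field)
  b <- breakable_cols(net)
  immob <- opts$immobilize %||% any(field != 0)
  if (!is.null(opts$seed)) set.seed(opts$seed)
  cpp_integrate(coords, net$links$i, net$links$j, net$links$r0, net$kappa,
                b$i, b$j, b$A, b$r0, b$dt, field,
                subdomain_index_list(net), opts$dt, as.integer(max_steps),
                opts$eps_dist, opts$eps_angle, opts$noise_D, immob,
                check_stationarity, opts$record_stride, record_frames,
                as.integer(frame_stride))
}

#' Advance the network by Euler steps
#'
#' One (or a few) explicit Euler steps of the full nonlinear overdamped
#' dynamics: elastic, breakable and ligand-link forces, plus the external
#' field, its rigid-body balancing counterpart when immobilization is on,
#' and Gaussian noise when `noise_D > 0`.
#'
#' @param net an `elastic_network`.
#' @param coords current m x 3 coordinates.
#' @param field external static force field (m x 3, or protein beads only),
#'   or `NULL`.
#' @param opts an [integration_options()].
#' @param n_steps number of steps to take.
#' @return The new coordinate matrix.
#' @export
step_network <- function(net, coords, field = NULL,
                         opts = integration_options(), n_steps = 1L) {
  res <- run_integrator(net, coords, field, opts, check_stationarity = FALSE,
                        max_steps = n_steps)
  res$coords
}

#' Rigid-body balancing forces (immobilization)
#'
#' Given an external static field, returns the unique rigid-body generator
#' field (a uniform translation plus a linear rotation field about the
#' center of mass) whose addition cancels the total force and total torque
#' of the input. Because it is a rigid-body generator, it causes no
#' internal strain to first order; this removes drift without pinning any
#' bead.
#'
#' @param coords m x 3 coordinates.
#' @param field m x 3 external force field.
#' @return m x 3 balancing field.
#' @export
immobilizing_forces <- function(coords, field) {
  coords <- as.matrix(coords)
  field <- as.matrix(field)
  m <- nrow(coords)
  if (m < 3L) stop("need at least 3 beads for immobilization", call. = FALSE)
  com <- colMeans(coords)
  d <- sweep(coords, 2L, com)
  a <- -colSums(field) / m
  tau <- colSums(t(vapply(seq_len(m), function(i) cross3(d[i, ], field[i, ]),
                          numeric(3))))
  S <- crossprod(d)
  M <- sum(diag(S)) * diag(3) - S
  if (rcond(M) < 1e-12) {
    stop("degenerate (collinear) geometry: cannot balance torque", call. = FALSE)
  }
  b <- solve(M, -tau)
  out <- t(vapply(seq_len(m), function(i) a + cross3(b, d[i, ]), numeric(3)))
  dimnames(out) <- NULL
  out
}

#' Relax the network to a stationary state
#'
#' Integrates the deterministic overdamped dynamics until the
#' order-parameter stationarity criterion is met (see
#' [integration_options()]) or `max_steps` is exhausted. Non-convergence is
#' reported, not fatal. For networks without the four subdomain labels the
#' criterion falls back to the maximum per-bead displacement per step.
#'
#' @inheritParams step_network
#' @param coords0 starting coordinates (defaults to the reference).
#' @return A list with `coords` (final), `converged`, `steps`, `state`
#'   (final order parameters, if subdomains are labelled) and `trajectory`
#'   (tibble of `step`, `d13`, `d24`, `phi`, `energy` at the record
#'   stride).
#' @export
relax_to_stationary <- function(net, coords0 = network_coords(net),
                                field = NULL, opts = integration_options()) {
  if (opts$noise_D > 0) {
    stop("stationarity detection requires deterministic dynamics (noise_D = 0)",
         call. = FALSE)
  }
  res <- run_integrator(net, coords0, field, opts, check_stationarity = TRUE)
  traj <- tibble::as_tibble(res$traj)
  state <- if (length(subdomain_index_list(net)) == 4L) {
    compute_order_parameters(res$coords[seq_len(nrow(net$structure)), ,
                                        drop = FALSE], net$structure)
  } else NULL
  list(coords = res$coords, converged = res$converged, steps = res$steps,
       state = state, trajectory = traj)
}

#' Compare stationary states obtained with two time steps
#'
#' Integrates the same problem to stationarity with `dt` and with a smaller
#' `dt_small` and reports the maximum node-wise distance between the two
#' final states -- the standard guard that the Euler step is small enough.
#'
#' @inheritParams relax_to_stationary
#' @param dt,dt_small the two time steps (`dt_small <= dt`).
#' @return A list with `max_discrepancy` (Angstrom), and the two
#'   convergence flags.
#' @export
check_timestep <- function(net, coords0 = network_coords(net), field = NULL,
                           dt = 0.01, dt_small = dt / 5,
                           opts = integration_options()) {
  stopifnot(dt_small <= dt)
  o1 <- opts; o1$dt <- dt
  o2 <- opts; o2$dt <- dt_small
  o2$max_steps <- as.integer(ceiling(opts$max_steps * dt / dt_small))
  r1 <- relax_to_stationary(net, coords0, field, o1)
  r2 <- relax_to_stationary(net, coords0, field, o2)
  if (!r1$converged || !r2$converged) {
    warning("at least one run did not reach stationarity; discrepancy is ",
            "not meaningful", call. = FALSE)
  }
  list(max_discrepancy = max(sqrt(rowSums((r1$coords - r2$coords)^2))),
       converged = c(dt = r1$converged, dt_small = r2$converged))
}
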