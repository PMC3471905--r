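#' Draw a random static force field
#'
#' Independent, uniformly distributed random unit direction for every
#' target bead (isotropic, via normalized Gaussian triples), with either a
#' fixed magnitude or a magnitude drawn uniformly from an interval; zero
#' force elsewhere. Draws consume the current RNG stream, so protocols are
#' reproducible from a single seed.
#'
#' @param s an [en_structure()] (or the structure of the network probed).
#' @param targets residue ids receiving a force (default: all).
#' @param magnitude fixed force magnitude (rescaled units: a force of 1
#'   stretches a single link by 1 Angstrom); ignored when `interval` given.
#' @param interval length-2 interval for uniformly random magnitudes.
#' @return n x 3 force-field matrix over the protein beads.
#' @export
draw_force_field <- function(s, targets = s$residue_id, magnitude = 1,
                             interval = NULL) {
  idx <- match(targets, s$residue_id)
  if (anyNA(idx)) stop("target residue id(s) not in the structure", call. = FALSE)
  field <- matrix(0, nrow(s), 3L)
  k <- length(idx)
  if (k == 0L) return(field)
  dirs <- matrix(stats::rnorm(3L * k), k, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  mag <- if (is.null(interval)) rep(magnitude, k) else {
    stats::runif(k, interval[1], interval[2])
  }
  field[idx, ] <- dirs * mag
  field
}

#' Classify relaxation endpoints by order-parameter clustering
#'
#' Agglomerative (complete-linkage) clustering in the space of
#' order-parameter changes relative to the reference, with each coordinate
#' scaled by its tolerance; endpoints closer than one tolerance unit in
#' every scaled coordinate join one cluster. The reference scale makes the
#' default tolerances read as 0.5% relative distance change and half a
#' degree of twist.
#'
#' @param deltas tibble with columns `dd13_rel`, `dd24_rel`, `dphi` (one
#'   row per endpoint; see [deltas_vs_reference()]).
#' @param tol length-3 tolerances for (dd13_rel, dd24_rel, dphi).
#' @return A list with `assignment` (integer per endpoint) and `clusters`
#'   (tibble: cluster, n, mean dd13_rel/dd24_rel/dphi).
#' @export
classify_endpoints <- function(deltas, tol = c(0.005, 0.005, 0.5)) {
  x <- cbind(deltas$dd13_rel / tol[1], deltas$dd24_rel / tol[2],
             deltas$dphi / tol[3])
  assignment <- if (nrow(x) == 1L) 1L else {
    hc <- stats::hclust(stats::dist(x), method = "complete")
    stats::cutree(hc, h = 1)
  }
  clusters <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(deltas, cluster = assignment), .data$cluster),
    n = dplyr::n(),
    dd13_rel = mean(.data$dd13_rel), dd24_rel = mean(.data$dd24_rel),
    dphi = mean(.data$dphi), .groups = "drop")
  list(assignment = assignment, clusters = clusters)
}

ref_state_of <- function(net) {
  np <- nrow(net$structure)
  compute_order_parameters(network_coords(net)[seq_len(np), , drop = FALSE],
                           net$structure)
}

state_of <- function(net, coords) {
  np <- nrow(net$structure)
  compute_order_parameters(coords[seq_len(np), , drop = FALSE], net$structure)
}

response_ensemble <- function(net, targets, n, magnitude = NULL,
                              interval = NULL, opts = integration_options(),
                              seed = 1L, tol = c(0.005, 0.005, 0.5),
                              keep_trajectories = FALSE) {
  opts$seed <- NULL   # protocol seeding is done here, once
  set.seed(seed)
  ref <- ref_state_of(net)
  ref_coords <- network_coords(net)
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    field <- draw_force_field(net$structure, targets,
                              magnitude = magnitude %||% 1,
                              interval = interval)
    forced <- relax_to_stationary(net, ref_coords, field, opts)
    relaxed <- relax_to_stationary(net, forced$coords, NULL, opts)
    rows[[r]] <- dplyr::bind_cols(
      tibble::tibble(id = r, converged_forced = forced$converged,
                     converged = forced$converged && relaxed$converged),
      stats::setNames(deltas_vs_reference(forced$state, ref),
                      c("deformed_dd13_rel", "deformed_dd24_rel",
                        "deformed_dphi")),
      deltas_vs_reference(relaxed$state, ref))
    if (keep_trajectories) trajs[[r]] <- relaxed$trajectory
  }
  res <- dplyr::bind_rows(rows)
  ok <- res$converged
  cl <- classify_endpoints(res[ok, c("dd13_rel", "dd24_rel", "dphi")], tol)
  res$cluster <- NA_integer_
  res$cluster[ok] <- cl$assignment
  out <- list(realizations = res, clusters = cl$clusters, reference = ref,
              n_nonconverged = sum(!ok),
              meta = list(targets = targets, n = n, magnitude = magnitude,
                          interval = interval, seed = seed, tol = tol),
              trajectories = trajs)
  class(out) <- "en_ensemble"
  out
}

#' @export
print.en_ensemble <- function(x, ...) {
  cat(sprintf("# en_ensemble: %d realization(s), %d endpoint cluster(s), %d non-converged\n",
              nrow(x$realizations), nrow(x$clusters), x$n_nonconverged))
  print(x$clusters)
  invisible(x)
}

#' @export
tidy.en_ensemble <- function(x, ...) x$realizations

#' @export
glance.en_ensemble <- function(x, ...) {
  tibble::tibble(n = nrow(x$realizations), n_clusters = nrow(x$clusters),
                 n_nonconverged = x$n_nonconverged,
                 max_abs_dd24_rel = max(abs(x$realizations$deformed_dd24_rel),
                                        na.rm = TRUE),
                 max_abs_dphi = max(abs(x$realizations$deformed_dphi),
                                    na.rm = TRUE))
}

#' Global random-force response ensemble
#'
#' The global-perturbation experiment: for each realization, random static
#' forces (random direction, magnitude uniform in `interval`) are applied
#' to every bead, the network is integrated with immobilization to a
#' stationary deformed state, the forces are lifted, and the relaxation
#' back is followed to its endpoint. Endpoints of converged runs are
#' clustered in order-parameter space; non-converged runs are counted and
#' reported, never silently dropped.
#'
#' @param net an `elastic_network`.
#' @param n number of realizations.
#' @param interval magnitude interval, rescaled force units.
#' @param opts an [integration_options()].
#' @param seed integer seed for all force draws.
#' @param tol endpoint-clustering tolerances, see [classify_endpoints()].
#' @param keep_trajectories record each relaxation's order-parameter series.
#' @return An `en_ensemble` object; `tidy()` gives per-realization rows,
#'   `glance()` a one-row summary, `autoplot()` the trajectory/endpoint
#'   figure.
#' @export
global_response_ensemble <- function(net, n = 100L, interval = c(0, 2),
                                     opts = integration_options(), seed = 1L,
                                     tol = c(0.005, 0.005, 0.5),
                                     keep_trajectories = FALSE) {
  response_ensemble(net, targets = net$structure$residue_id, n = n,
                    interval = interval, opts = opts, seed = seed, tol = tol,
                    keep_trajectories = keep_trajectories)
}

#' Group-perturbation response ensemble
#'
#' Same force-relax-release-relax protocol as
#' [global_response_ensemble()], with forces restricted to a small residue
#' group (for actin, the three sensitive pocket residues 16, 73, 159).
#'
#' @inheritParams global_response_ensemble
#' @param group residue ids receiving forces.
#' @export
group_perturbation_ensemble <- function(net, group, n = 100L,
                                        interval = c(0, 2),
                                        opts = integration_options(),
                                        seed = 1L, tol = c(0.005, 0.005, 0.5),
                                        keep_trajectories = FALSE) {
  response_ensemble(net, targets = group, n = n, interval = interval,
                    opts = opts, seed = seed, tol = tol,
                    keep_trajectories = keep_trajectories)
}

#' Mechanical sensitivity of a single residue
#'
#' Applies `n` static forces of fixed magnitude and random orientation to
#' one residue, relaxes each (with immobilization) to a stationary state,
#' and reports the maxima over the ensemble of the absolute dihedral
#' change and the relative changes of the two inter-subdomain distances --
#' one row of the sensitivity table.
#'
#' @param net an `elastic_network`.
#' @param residue residue id to probe.
#' @param n ensemble size.
#' @param magnitude force magnitude (rescaled units).
#' @param opts an [integration_options()].
#' @param seed integer seed.
#' @return One-row tibble: `residue`, `max_dphi` (degrees), `max_dd13_rel`,
#'   `max_dd24_rel`, `n`, `magnitude`, `n_nonconverged`.
#' @export
probe_sensitivity <- function(net, residue, n = 200L, magnitude = 1,
                              opts = integration_options(), seed = 1L) {
  opts$seed <- NULL
  set.seed(seed)
  ref <- ref_state_of(net)
  ref_coords <- network_coords(net)
  d <- purrr::map(seq_len(n), function(r) {
    field <- draw_force_field(net$structure, residue, magnitude = magnitude)
    forced <- relax_to_stationary(net, ref_coords, field, opts)
    dplyr::mutate(deltas_vs_reference(forced$state, ref),
                  converged = forced$converged)
  })
  d <- dplyr::bind_rows(d)
  ok <- d$converged
  tibble::tibble(residue = residue,
                 max_dphi = max(abs(d$dphi[ok]), 0),
                 max_dd13_rel = max(abs(d$dd13_rel[ok]), 0),
                 max_dd24_rel = max(abs(d$dd24_rel[ok]), 0),
                 n = n, magnitude = magnitude, seed = seed,
                 n_nonconverged = sum(!ok))
}

#' Sensitivity scan over a residue set
#'
#' Runs [probe_sensitivity()] for every residue in the set and flags the
#' "sensitive" ones: residues whose maximum dihedral response and maximum
#' relative S2-S4 distance response both clear the thresholds. The default
#' thresholds (6.9 degrees, 11%) mark residues whose perturbation induces
#' large-amplitude domain motions.
#'
#' @inheritParams probe_sensitivity
#' @param residues residue ids to probe (for actin, the 17 pocket residues
#'   12-16, 71-75, 155-160 and 301).
#' @param thresholds named vector `c(dphi = ..., dd24 = ...)`.
#' @return A tibble of class `en_sensitivity`, one row per residue, with a
#'   logical `sensitive` column; thresholds kept as an attribute.
#' @export
scan_nbp <- function(net, residues, n = 200L, magnitude = 1,
                     opts = integration_options(), seed = 1L,
                     thresholds = c(dphi = 6.9, dd24 = 0.11)) {
  rows <- purrr::imap(residues, function(res, k) {
    probe_sensitivity(net, res, n = n, magnitude = magnitude, opts = opts,
                      seed = seed + k - 1L)
  })
  out <- dplyr::bind_rows(rows)
  out$sensitive <- out$max_dphi >= thresholds[["dphi"]] &
    out$max_dd24_rel >= thresholds[["dd24"]]
  class(out) <- c("en_sensitivity", class(out))
  attr(out, "thresholds") <- thresholds
  out
}

#' Ligand-driven open-to-closed transition run
#'
#' Phase 1: the phosphate node is added (turning the bound ADP into the
#' ATP dimer, with pre-strained links) and the complex is relaxed from the
#' open reference. Phase 2: the phosphate is released and the system is
#' relaxed again. Reports per-phase final order parameters and how many
#' breakable links are engaged -- with strong breakable links the cleft
#' stays locked after release (metastable closed state); with soft links
#' it reopens.
#'
#' @param net an `elastic_network` with breakable links and an ADP node.
#' @param sensitive three residue ids the phosphate binds (with the ADP).
#' @param prestrain retained-length fraction of the phosphate links.
#' @param opts an [integration_options()].
#' @return A tibble with one row per phase (`atp_bound`, `pi_released`):
#'   convergence flag, `d13`, `d24`, `phi`, `n_engaged`.
#' @export
ligand_transition_run <- function(net, sensitive, prestrain = 0.2,
                                  opts = integration_options()) {
  if (is.na(ligand_node_index(net, "ADP"))) {
    stop("the network must carry an ADP node (see add_adp())", call. = FALSE)
  }
  net_atp <- add_atp(net, sensitive = sensitive, prestrain = prestrain)
  r1 <- relax_to_stationary(net_atp, network_coords(net_atp), NULL, opts)
  net_rel <- release_pi(net_atp)
  pi_node <- ligand_node_index(net_atp, "Pi")
  coords2 <- r1$coords[-pi_node, , drop = FALSE]
  r2 <- relax_to_stationary(net_rel, coords2, NULL, opts)
  summarize_phase <- function(tag, nn, r) {
    dplyr::bind_cols(
      tibble::tibble(phase = tag, converged = r$converged),
      r$state,
      tibble::tibble(n_engaged = sum(engaged_breakable(nn, r$coords))))
  }
  dplyr::bind_rows(summarize_phase("atp_bound", net_atp, r1),
                   summarize_phase("pi_released", net_rel, r2))
}

#' Thermal sampling of the interdomain distance
#'
#' Langevin (Euler-Maruyama) run at noise intensity `D`; after a burn-in,
#' the order parameters are sampled every `stride` steps. Returns the
#' sample series plus the empirical mean and variance of `d24`, whose
#' distribution distinguishes open-dominated from closed-dominated (and
#' soft from stiff) states of the network.
#'
#' @param net an `elastic_network`.
#' @param D noise intensity (variance `2 D dt` per coordinate per step).
#' @param n_samples number of retained sample points.
#' @param stride steps between samples.
#' @param burn_in initial steps discarded.
#' @param opts an [integration_options()]; `opts$seed` seeds the noise.
#' @param coords0 starting coordinates (default reference).
#' @return An `en_thermal` object: `samples` tibble and metadata;
#'   `glance()` gives mean/variance of `d24`.
#' @export
thermal_distribution <- function(net, D, n_samples = 10000L, stride = 400L,
                                 burn_in = 20000L,
                                 opts = integration_options(seed = 1L),
                                 coords0 = network_coords(net)) {
  stopifnot(D > 0)
  if (n_samples < 100L) {
    warning("fewer than 100 samples: variance estimate unreliable", call. = FALSE)
  }
  opts$noise_D <- D
  opts$record_stride <- as.integer(stride)
  total <- as.integer(burn_in + n_samples * stride)
  res <- run_integrator(net, coords0, NULL, opts, check_stationarity = FALSE,
                        max_steps = total)
  samples <- tibble::as_tibble(res$traj)
  samples <- samples[samples$step > burn_in, , drop = FALSE]
  samples <- utils::head(samples, n_samples)
  out <- list(samples = samples, D = D, stride = stride, burn_in = burn_in,
              seed = opts$seed, dt = opts$dt)
  class(out) <- "en_thermal"
  out
}

#' @export
print.en_thermal <- function(x, ...) {
  cat(sprintf("# en_thermal: %d samples, D = %g; d24 mean %.3f, var %.4g\n",
              nrow(x$samples), x$D, mean(x$samples$d24),
              stats::var(x$samples$d24)))
  invisible(x)
}

#' @export
glance.en_thermal <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$samples), D = x$D,
                 d24_mean = mean(x$samples$d24),
                 d24_var = stats::var(x$samples$d24))
}
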