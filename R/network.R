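#' Build an anisotropic elastic network from a structure
#'
#' Connects every pair of beads whose reference distance is strictly below
#' the cutoff by a harmonic spring whose natural length equals that
#' distance, so the reference conformation is the state of lowest (zero)
#' elastic energy. All springs share one stiffness `kappa`; in the rescaled
#' units used throughout, `kappa = 1` and a force of magnitude 1 stretches
#' a single link by 1 Angstrom. Sequence neighbours get no special
#' treatment (pure cutoff ANM).
#'
#' @param s an [en_structure()].
#' @param cutoff cutoff distance d_c in Angstrom; pairs at exactly `cutoff`
#'   are excluded ("smaller than").
#' @param kappa spring stiffness (energy/Angstrom^2); default 1 (rescaled).
#' @return An object of class `elastic_network`: a list with the structure,
#'   the cutoff, `kappa`, a `links` tibble (`i`, `j`, `r0`, `res_i`,
#'   `res_j`), an optional breakable-link set, and a `ligands` tibble.
#' @export
build_network <- function(s, cutoff, kappa = 1) {
  stopifnot(cutoff > 0)
  if (nrow(s) < 2L) stop("need at least 2 beads to build a network", call. = FALSE)
  xyz <- coords_matrix(s)
  d <- as.matrix(stats::dist(xyz))
  sel <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  links <- tibble::tibble(
    i = as.integer(sel[, 1]), j = as.integer(sel[, 2]),
    r0 = d[sel],
    res_i = s$residue_id[sel[, 1]], res_j = s$residue_id[sel[, 2]]
  )
  links <- dplyr::arrange(links, .data$i, .data$j)
  net <- list(structure = s, cutoff = cutoff, kappa = kappa, links = links,
              breakable = NULL,
              ligands = tibble::tibble(name = character(), x = numeric(),
                                       y = numeric(), z = numeric()))
  class(net) <- "elastic_network"
  net
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("# elastic_network: %d protein beads, %d links, cutoff %.2f A\n",
              nrow(x$structure), nrow(x$links), x$cutoff))
  if (!is.null(x$breakable)) {
    cat(sprintf("#   breakable: %d truncated-LJ pairs (A = %g, r0 = %.2f, d_t = %.2f)\n",
                nrow(x$breakable$pairs), x$breakable$strength,
                x$breakable$r0, x$breakable$truncation))
  }
  if (nrow(x$ligands) > 0L) {
    cat("#   ligands: ", paste(x$ligands$name, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Reference coordinates of a network (protein beads plus ligand nodes)
#'
#' @param net an `elastic_network`.
#' @return m x 3 matrix; ligand nodes, if any, follow the protein beads.
#' @export
network_coords <- function(net) {
  xyz <- coords_matrix(net$structure)
  if (nrow(net$ligands) > 0L) {
    xyz <- rbind(xyz, cbind(net$ligands$x, net$ligands$y, net$ligands$z))
  }
  dimnames(xyz) <- NULL
  xyz
}

n_nodes <- function(net) nrow(net$structure) + nrow(net$ligands)

check_coords <- function(net, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != n_nodes(net) || ncol(coords) != 3L) {
    stop("coords must be ", n_nodes(net), " x 3 for this network", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  coords
}

breakable_cols <- function(net) {
  b <- net$breakable
  if (is.null(b)) {
    list(i = integer(), j = integer(), A = 1, r0 = 1, dt = 2)
  } else {
    list(i = b$pairs$i, j = b$pairs$j, A = b$strength, r0 = b$r0,
         dt = b$truncation)
  }
}

#' Total potential energy of a network configuration
#'
#' Sum over unordered linked pairs of `kappa/2 (r_ij - r_ij^0)^2`, plus the
#' truncated Lennard-Jones energy of any breakable pairs. Zero at the
#' reference coordinates when no breakable pair is within its truncation
#' length and no ligand link is pre-strained.
#'
#' @param net an `elastic_network`.
#' @param coords m x 3 coordinate matrix (see [network_coords()]).
#' @return Scalar energy in rescaled units (Angstrom^2 when `kappa = 1`).
#' @export
elastic_energy <- function(net, coords) {
  coords <- check_coords(net, coords)
  b <- breakable_cols(net)
  cpp_en_energy(coords, net$links$i, net$links$j, net$links$r0, net$kappa,
                b$i, b$j, b$A, b$r0, b$dt)
}

#' Forces on every node (negative energy gradient)
#'
#' @inheritParams elastic_energy
#' @return m x 3 matrix of forces in rescaled units (a force of 1 stretches
#'   a single link by 1 Angstrom).
#' @export
elastic_forces <- function(net, coords) {
  coords <- check_coords(net, coords)
  b <- breakable_cols(net)
  cpp_en_forces(coords, net$links$i, net$links$j, net$links$r0, net$kappa,
                b$i, b$j, b$A, b$r0, b$dt)
}

#' Select the ANM cutoff by the six-zero-eigenvalue criterion
#'
#' Builds a network at each candidate cutoff and counts the near-zero
#' eigenvalues of its Hessian. A connected three-dimensional network has
#' exactly six (three translations, three rotations); more indicate
#' disconnected components or free internal rotations. Returns the smallest
#' candidate with exactly six, together with the per-candidate count so the
#' decision is auditable.
#'
#' @param s an [en_structure()].
#' @param candidates increasing vector of cutoff values, Angstrom.
#' @param tol zero-eigenvalue tolerance, relative to the largest eigenvalue.
#' @return A list with `cutoff` (the selected value) and `table` (a tibble
#'   of `cutoff`, `zero_count`, `gap` = smallest retained eigenvalue).
#' @export
select_cutoff <- function(s, candidates, tol = 1e-8) {
  stopifnot(length(candidates) > 0L)
  candidates <- sort(candidates)
  rows <- purrr::map(candidates, function(dc) {
    net <- build_network(s, dc)
    ev <- eigen(network_hessian(net), symmetric = TRUE, only.values = TRUE)$values
    thr <- tol * max(abs(ev))
    nz <- sum(abs(ev) < thr)
    tibble::tibble(cutoff = dc, zero_count = nz,
                   gap = min(abs(ev)[abs(ev) >= thr], Inf))
  })
  tab <- dplyr::bind_rows(rows)
  hit <- which(tab$zero_count == 6L)
  if (length(hit) == 0L) {
    print(tab)
    stop("no candidate cutoff yields exactly 6 zero modes", call. = FALSE)
  }
  list(cutoff = tab$cutoff[hit[1]], table = tab)
}

#' Emergent contacts between two subdomains in a second conformation
#'
#' Finds residue pairs from subdomains `domA` and `domB` that are not
#' linked in the reference network but fall within its cutoff in a second
#' conformation (for actin: pairs of S2/S4 residues that touch in the
#' filament form but not in the monomer). These are the candidate breakable
#' links. Pairs are ordered by ascending distance in the second
#' conformation, so `head(n = 5)` gives the closest-pair subset.
#'
#' @param netG reference `elastic_network` (subdomains assigned).
#' @param sF an [en_structure()] for the second conformation, same residue
#'   numbering.
#' @param domA,domB subdomain labels.
#' @return Tibble with `res_i`, `res_j`, `dist_F`, `dist_G` sorted by
#'   `dist_F`.
#' @export
find_emergent_contacts <- function(netG, sF, domA = "S2", domB = "S4") {
  sG <- netG$structure
  idsA <- sG$residue_id[which(sG$subdomain == domA)]
  idsB <- sG$residue_id[which(sG$subdomain == domB)]
  if (length(idsA) == 0L || length(idsB) == 0L) {
    stop("empty subdomain selection", call. = FALSE)
  }
  need <- c(idsA, idsB)
  if (!all(need %in% sF$residue_id)) {
    stop("residue-id mismatch: second conformation lacks ",
         sum(!(need %in% sF$residue_id)), " residue(s) of ", domA, "/", domB,
         call. = FALSE)
  }
  xyzF <- coords_matrix(sF)
  xyzG <- coords_matrix(sG)
  posF <- function(id) xyzF[match(id, sF$residue_id), , drop = FALSE]
  posG <- function(id) xyzG[match(id, sG$residue_id), , drop = FALSE]
  grid <- expand.grid(res_i = idsA, res_j = idsB, KEEP.OUT.ATTRS = FALSE)
  dF <- sqrt(rowSums((posF(grid$res_i) - posF(grid$res_j))^2))
  dG <- sqrt(rowSums((posG(grid$res_i) - posG(grid$res_j))^2))
  linked <- paste(netG$links$res_i, netG$links$res_j) # i<j by construction
  key1 <- paste(pmin(grid$res_i, grid$res_j), pmax(grid$res_i, grid$res_j))
  keep <- dF < netG$cutoff & !(key1 %in% linked)
  out <- tibble::tibble(res_i = grid$res_i[keep], res_j = grid$res_j[keep],
                        dist_F = dF[keep], dist_G = dG[keep])
  dplyr::arrange(out, .data$dist_F)
}

#' Truncated Lennard-Jones pair potential for breakable links
#'
#' The bare potential `A ((r0/r)^12 - 2 (r0/r)^6)` has its minimum of depth
#' `A` at `r0`. It is truncated by the shifted-force construction: energy
#' and force are both continuous and exactly zero at the truncation length
#' `d_t`, and identically zero beyond it, so a breakable pair exerts no
#' interaction whatsoever once the two residues separate past `d_t`. The
#' linear shift leaves the curvature at `r0` untouched: `U''(r0) = 72 A /
#' r0^2`.
#'
#' @param r distances (vectorized).
#' @param strength well depth `A`, rescaled energy units (Angstrom^2).
#' @param r0 equilibrium distance, Angstrom.
#' @param truncation truncation length `d_t`, Angstrom (`> r0`).
#' @param deriv 0 for the energy, 1 for dU/dr.
#' @return Numeric vector.
#' @export
lj_breakable <- function(r, strength, r0, truncation, deriv = 0) {
  u <- function(x) strength * ((r0 / x)^12 - 2 * (r0 / x)^6)
  du <- function(x) (12 * strength / x) * ((r0 / x)^6 - (r0 / x)^12)
  s <- du(truncation)
  out <- numeric(length(r))
  inside <- r < truncation
  if (deriv == 0) {
    out[inside] <- u(r[inside]) - u(truncation) - (r[inside] - truncation) * s
  } else {
    out[inside] <- du(r[inside]) - s
  }
  out
}

#' Attach a breakable-link set to a network
#'
#' Validates the three parameter requirements before attaching: (i) the
#' potential is flat at and beyond the truncation length (force there below
#' 1e-9, guaranteed by the shifted-force form); (ii) the equilibrium
#' distance `r0` lies between the minimum and maximum natural lengths of
#' the host network's elastic links; (iii) the curvature of the pair
#' potential at `r0` relative to `kappa` (the factor by which an engaged
#' breakable link is stiffer than a regular elastic link) is computed and
#' stored for reporting. The listed pairs must not already be elastic links.
#'
#' @param net an `elastic_network`.
#' @param pairs two-column matrix or tibble of residue ids (`res_i`,
#'   `res_j`).
#' @param strength well depth `A` (> 0), rescaled units.
#' @param r0 equilibrium distance of the pair potential, Angstrom.
#' @param truncation truncation length `d_t` (> `r0`); defaults to the
#'   network cutoff, the distance at which an elastic link would have been
#'   drawn.
#' @return The network with `net$breakable` set (pairs as node indices and
#'   residue ids, the three parameters, and `curvature_ratio`).
#' @export
add_breakable_links <- function(net, pairs, strength, r0,
                                truncation = net$cutoff) {
  if (!(strength > 0)) stop("breakable-link strength must be > 0", call. = FALSE)
  if (!(r0 < truncation)) {
    stop("requirement (i) violated: need r0 < truncation so the potential ",
         "can flatten at d_t", call. = FALSE)
  }
  rng <- range(net$links$r0)
  if (r0 < rng[1] || r0 > rng[2]) {
    stop(sprintf(paste0("requirement (ii) violated: r0 = %.3f outside the ",
                        "natural-length range [%.3f, %.3f] of the elastic links"),
                 r0, rng[1], rng[2]), call. = FALSE)
  }
  f_at_dt <- abs(lj_breakable(truncation - 1e-12, strength, r0, truncation,
                              deriv = 1))
  if (f_at_dt > 1e-9) {
    stop("requirement (i) violated: force at the truncation length is ",
         f_at_dt, call. = FALSE)
  }
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("res_i", "res_j")
  ids <- net$structure$residue_id
  pi_ <- match(pairs$res_i, ids)
  pj_ <- match(pairs$res_j, ids)
  if (anyNA(pi_) || anyNA(pj_)) {
    stop("breakable pair references residue id(s) absent from the structure",
         call. = FALSE)
  }
  i <- pmin(pi_, pj_); j <- pmax(pi_, pj_)
  if (any(paste(i, j) %in% paste(net$links$i, net$links$j))) {
    stop("breakable pairs must not coincide with elastic links", call. = FALSE)
  }
  net$breakable <- list(
    pairs = tibble::tibble(i = as.integer(i), j = as.integer(j),
                           res_i = ids[i], res_j = ids[j]),
    strength = strength, r0 = r0, truncation = truncation,
    curvature_ratio = 72 * strength / r0^2 / net$kappa
  )
  net
}

#' Serialize / restore a network as JSON
#'
#' Everything needed to rebuild the network bit-for-bit (to within the
#' 15-significant-digit JSON number representation): beads, links with
#' natural lengths, parameters, breakable pairs and ligand nodes.
#'
#' @param net an `elastic_network`.
#' @param path output / input JSON path.
#' @return `write_network()` returns `path` invisibly; `read_network()` the
#'   network.
#' @export
write_network <- function(net, path) {
  obj <- list(
    structure = as.data.frame(net$structure),
    source = attr(net$structure, "source") %||% "",
    cutoff = net$cutoff, kappa = net$kappa,
    links = as.data.frame(net$links),
    breakable = if (is.null(net$breakable)) NULL else {
      list(pairs = as.data.frame(net$breakable$pairs),
           strength = net$breakable$strength, r0 = net$breakable$r0,
           truncation = net$breakable$truncation)
    },
    ligands = as.data.frame(net$ligands),
    ligand_links = if (is.null(net$ligand_links)) NULL else {
      as.data.frame(net$ligand_links)
    }
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- en_structure(obj$structure$residue_id,
                    cbind(obj$structure$x, obj$structure$y, obj$structure$z),
                    chain = obj$structure$chain,
                    subdomain = obj$structure$subdomain,
                    source = obj$source)
  net <- build_network(s, obj$cutoff, obj$kappa)
  if (!is.null(obj$breakable)) {
    net <- add_breakable_links(net, obj$breakable$pairs[, c("res_i", "res_j")],
                               obj$breakable$strength, obj$breakable$r0,
                               obj$breakable$truncation)
  }
  # `links` in the file is the full harmonic set (protein + ligand links)
  net$links <- tibble::as_tibble(obj$links)
  if (!is.null(obj$ligands) && NROW(obj$ligands) > 0L) {
    net$ligands <- tibble::as_tibble(obj$ligands)
    net$ligand_links <- tibble::as_tibble(obj$ligand_links)
  }
  net
}
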