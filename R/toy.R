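#' Specification for the synthetic two-domain test structure
#'
#' The toy emulates the mechanical organisation the actin analysis assumes,
#' at desk scale: 60 beads in four subdomains. The two lower subdomains
#' (S1, S3) are the halves of one rigid two-layer slab (the analogue of the
#' rigidly bridged lower actin subdomains, whose separation d13 barely
#' moves). Each upper subdomain (S2, S4) is a 15-bead cluster -- wide
#' three-by-three face up, narrow two-bead stalk down -- standing on its
#' stalk above one end of the slab, so it can tilt about the soft stalk
#' hinge. In the open (reference) form both upper clusters lean outward
#' and the cleft between their inner faces exceeds the cutoff; in the
#' closed form they stand upright and a designed set of S2 x S4 bead pairs
#' meets across the cleft at contact distance. Three cleft-facing "pocket"
#' beads (from S2, S4 and S3) play the role of the sensitive
#' nucleotide-binding residues, and a site between them on the slab top
#' hosts the ADP node.
#'
#' @param beads_per_subdomain beads per subdomain; the designed template
#'   has 15 (60 beads total), the only supported value.
#' @param domain_separation horizontal distance between the two upper
#'   clusters' stalk positions; larger values widen the cleft.
#' @param hinge_gap vertical gap between the slab top and the stalk beads;
#'   smaller gaps add hinge links and stiffen the tilt (the link-density
#'   proxy for hinge stiffness).
#' @param open_angle outward tilt (radians) of each upper cluster in the
#'   open form.
#' @param cutoff elastic-network cutoff used for the toy.
#' @param jitter isotropic Gaussian displacement (sd, Angstrom) applied to
#'   each template bead, identical in the open and closed forms; breaks
#'   lattice symmetry so spectra and responses are generic.
#' @param seed integer seed making the jitter reproducible.
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(beads_per_subdomain = 15L, domain_separation = 3.1,
                     hinge_gap = 0.45, open_angle = 0.35, cutoff = 1.6,
                     jitter = 0.05, seed = 1L) {
  if (beads_per_subdomain != 15L) {
    stop("the designed cluster template has 15 beads per subdomain", call. = FALSE)
  }
  spec <- list(beads_per_subdomain = 15L,
               domain_separation = domain_separation, hinge_gap = hinge_gap,
               open_angle = open_angle, cutoff = cutoff, jitter = jitter,
               seed = as.integer(seed))
  class(spec) <- "toy_spec"
  spec
}

# lower slab: 5 x 3 x 2 unit lattice (x 0..4, y -1..1, z {0, 0.8});
# S1 = the 15 beads with x <= 1 plus the bottom row at x = 2, S3 the rest
slab_template <- function() {
  g <- expand.grid(x = 0:4, y = -1:1, z = c(0, 0.8))
  slab <- as.matrix(g)
  list(coords = slab, s1 = slab[, 1] <= 1 | (slab[, 1] == 2 & slab[, 3] == 0))
}

# upper cluster: 3x3 top face, 2x2 middle, 2-bead stalk (with y offsets so
# the hinge resists torsion); stalk base at z = 0
upper_template <- function(stalk_y = 0.35) {
  A <- cbind(rep(c(-1, 0, 1), each = 3), rep(c(-1, 0, 1), 3), 1.6)
  B <- cbind(rep(c(-0.5, 0.5), each = 2), rep(c(-0.5, 0.5), 2), 0.8)
  C <- cbind(c(-0.5, 0.5), c(-stalk_y, stalk_y), 0)
  rbind(A, B, C)
}

rot_y <- function(theta) {
  matrix(c(cos(theta), 0, sin(theta), 0, 1, 0, -sin(theta), 0, cos(theta)),
         3L, 3L)
}

#' Generate the open and closed forms of the two-domain toy
#'
#' Deterministic from the spec's seed. The open form is the network
#' reference (zero elastic energy); the closed form shares all
#' cluster-internal geometry and differs only by rigid upright rotations
#' of the two upper clusters, so elastic strain in the closed form is
#' confined to the hinges while the designed contact pairs meet across the
#' cleft.
#'
#' @param spec a [toy_spec()].
#' @return A list with `open` and `closed` ([en_structure()]s sharing
#'   residue numbering 1..60, subdomains assigned), `contact_pairs`
#'   (tibble of the S2 x S4 residue pairs within the cutoff in the closed
#'   form), `pocket_nodes` (three residue ids facing the cleft, from S2,
#'   S4, S3), `adp_position`, and `scheme` (the toy subdomain scheme).
#' @export
make_two_domain_toy <- function(spec = toy_spec()) {
  slab <- slab_template()
  up <- upper_template()
  set.seed(spec$seed)
  jslab <- matrix(stats::rnorm(90, 0, spec$jitter), 30L, 3L)
  j2 <- matrix(stats::rnorm(45, 0, spec$jitter), 15L, 3L)
  j4 <- matrix(stats::rnorm(45, 0, spec$jitter), 15L, 3L)
  slab_xyz <- slab$coords + jslab
  slab_top <- 0.8
  slab_mid <- 2
  inset <- (4 - spec$domain_separation) / 2
  x2 <- inset
  x4 <- 4 - inset
  mirror <- function(m) cbind(-m[, 1], m[, 2], m[, 3])
  # rot_y(theta) tilts the +z axis toward -x for theta > 0, so the left
  # upper cluster (S2) leans outward with +theta, the right (S4) with -theta
  upper <- function(tplj, xc, theta) {
    pivot <- colMeans(tplj[tplj[, 3] < 0.2, , drop = FALSE])
    m <- sweep(sweep(tplj, 2L, pivot) %*% t(rot_y(theta)), 2L, pivot, `+`)
    sweep(m, 2L, c(xc, 0, slab_top + spec$hinge_gap), `+`)
  }
  build_form <- function(theta) {
    rbind(slab_xyz[slab$s1, , drop = FALSE],
          upper(up + j2, x2, theta),
          slab_xyz[!slab$s1, , drop = FALSE],
          upper(mirror(up + j4), x4, -theta))
  }
  open_xyz <- build_form(spec$open_angle)
  closed_xyz <- build_form(0)

  scheme <- list(S1 = list(c(1L, 15L)), S2 = list(c(16L, 30L)),
                 S3 = list(c(31L, 45L)), S4 = list(c(46L, 60L)))
  mk <- function(xyz, tag) {
    assign_subdomains(en_structure(1:60, xyz, chain = "A",
                                   source = paste0("toy-", tag)), scheme)
  }
  open_s <- mk(open_xyz, "open")
  closed_s <- mk(closed_xyz, "closed")

  # designed contacts: S2 x S4 pairs inside the cutoff in the closed form
  netO <- build_network(open_s, spec$cutoff)
  contacts <- find_emergent_contacts(netO, closed_s, "S2", "S4")
  if (nrow(contacts) == 0L) {
    stop("toy geometry yields no closed-form contacts; widen open_angle or ",
         "reduce domain_separation", call. = FALSE)
  }
  nm <- normal_modes(netO)
  if (nm$zero_count != 6L) {
    stop("open toy network has ", nm$zero_count, " zero modes (expected 6); ",
         "the network is disconnected or under-linked - use a denser spec",
         call. = FALSE)
  }

  # cleft-facing beads: top-inner of S2 and S4, top-inner of S3
  pocket <- c(
    pick_bead(open_s, "S2", function(b) b$x + 0.5 * b$z - 0.2 * abs(b$y)),
    pick_bead(open_s, "S4", function(b) -b$x + 0.5 * b$z - 0.2 * abs(b$y)),
    pick_bead(open_s, "S3", function(b) -b$x + 0.5 * b$z - 0.2 * abs(b$y))
  )
  adp_position <- c(slab_mid, 0, slab_top + 0.7)

  list(open = open_s, closed = closed_s, contact_pairs = contacts,
       pocket_nodes = pocket, adp_position = adp_position, scheme = scheme,
       spec = spec)
}

pick_bead <- function(s, subdomain, score) {
  sub <- s[s$subdomain == subdomain, ]
  sub$residue_id[which.max(score(sub))]
}

#' Build the bistable toy network (open reference + breakable links)
#'
#' Expands the open toy network with truncated-LJ breakable links on the
#' designed contact pairs and verifies the two-basin structure: a
#' relaxation started from the open reference stays open, and one started
#' from the closed geometry stays closed (cleft held shut by engaged
#' breakable links). Failure of either check is an error carrying the
#' offending relaxation summary.
#'
#' @param spec a [toy_spec()].
#' @param strength breakable-link well depth A (rescaled units). The
#'   default 0.6 makes an engaged pair markedly stiffer than a regular
#'   link (curvature ratio `72 A / r0^2` reported on the network) and is
#'   strong enough to lock the closed basin; see [toy_soft_strength()].
#' @param r0 equilibrium distance of the pair potential; must lie within
#'   the elastic natural-length range of the toy.
#' @param truncation truncation length; defaults to the toy cutoff.
#' @param n_pairs how many of the closest designed contact pairs carry
#'   breakable links (mirroring the closest-subset convention used for the
#'   actin network). The default 3 takes the aligned trio across the
#'   cleft; including the diagonal pairs as well admits additional
#'   twist-shifted locked states.
#' @param verify set `FALSE` to skip the bistability check (used when
#'   deliberately building soft/monostable variants).
#' @return An `elastic_network` with the breakable set attached, plus
#'   attributes `toy` (the generator output) and `closed_coords`.
#' @export
make_bistable_toy <- function(spec = toy_spec(), strength = 0.6, r0 = 1.1,
                              truncation = NULL, n_pairs = 3L,
                              verify = TRUE) {
  toy <- make_two_domain_toy(spec)
  net <- build_network(toy$open, spec$cutoff)
  pairs <- utils::head(toy$contact_pairs, n_pairs)
  net <- add_breakable_links(net, pairs[, c("res_i", "res_j")],
                             strength = strength, r0 = r0,
                             truncation = truncation %||% spec$cutoff)
  closed_coords <- coords_matrix(toy$closed)
  if (verify) {
    ro <- relax_to_stationary(net)
    rc <- relax_to_stationary(net, closed_coords)
    open_d24 <- compute_order_parameters(coords_matrix(toy$open), toy$open)$d24
    closed_d24 <- compute_order_parameters(closed_coords, toy$closed)$d24
    mid <- (open_d24 + closed_d24) / 2
    ok_open <- ro$converged && ro$state$d24 > mid
    ok_closed <- rc$converged && rc$state$d24 < mid &&
      any(engaged_breakable(net, rc$coords))
    if (!ok_open || !ok_closed) {
      stop("bistability check failed: open run (converged = ", ro$converged,
           ", d24 = ", signif(ro$state$d24, 4), "), closed run (converged = ",
           rc$converged, ", d24 = ", signif(rc$state$d24, 4),
           "); open/closed reference d24 = ", signif(open_d24, 4), "/",
           signif(closed_d24, 4), call. = FALSE)
    }
  }
  attr(net, "toy") <- toy
  attr(net, "closed_coords") <- closed_coords
  net
}

#' @rdname make_bistable_toy
#' @details `toy_soft_strength()` returns the soft breakable-link strength
#'   used for the monostable contrast: strong links lock the closed state
#'   on their own, soft links cannot, though a pre-strained ligand dimer
#'   can still hold the cleft shut.
#' @export
toy_soft_strength <- function() 0.01

#' Which breakable pairs are engaged (within truncation) at given coordinates?
#'
#' @param net an `elastic_network` with a breakable set.
#' @param coords m x 3 coordinates.
#' @return Logical vector, one entry per breakable pair.
#' @export
engaged_breakable <- function(net, coords) {
  if (is.null(net$breakable)) return(logical(0))
  p <- net$breakable$pairs
  d <- sqrt(rowSums((coords[p$j, , drop = FALSE] -
                       coords[p$i, , drop = FALSE])^2))
  d < net$breakable$truncation
}

#' Write toy fixture files (pseudo-PDB forms, config, golden values)
#'
#' Writes `toy_open.pdb` and `toy_closed.pdb` (CA-only ATOM records read
#' back by [load_ca_structure()]), `toy_config.yaml` (the generating spec
#' plus the subdomain scheme and pocket/contact annotations), and
#' `toy_golden.csv` (order parameters of both forms). Regeneration with
#' the same spec is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [toy_spec()].
#' @return Invisibly, the vector of file paths.
#' @export
make_fixture_files <- function(out_dir, spec = toy_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_two_domain_toy(spec)
  p_open <- file.path(out_dir, "toy_open.pdb")
  p_closed <- file.path(out_dir, "toy_closed.pdb")
  write_conformations(coords_matrix(toy$open), toy$open, p_open)
  write_conformations(coords_matrix(toy$closed), toy$closed, p_closed)
  p_cfg <- file.path(out_dir, "toy_config.yaml")
  yaml::write_yaml(list(
    spec = unclass(spec),
    scheme = lapply(toy$scheme, function(iv) lapply(iv, as.integer)),
    pocket_nodes = as.integer(toy$pocket_nodes),
    adp_position = as.numeric(toy$adp_position),
    contact_pairs = as.data.frame(toy$contact_pairs[, c("res_i", "res_j")])
  ), p_cfg)
  p_gold <- file.path(out_dir, "toy_golden.csv")
  gold <- dplyr::bind_rows(
    dplyr::mutate(compute_order_parameters(coords_matrix(toy$open), toy$open),
                  form = "open", .before = 1),
    dplyr::mutate(compute_order_parameters(coords_matrix(toy$closed),
                                           toy$closed),
                  form = "closed", .before = 1))
  utils::write.csv(gold, p_gold, row.names = FALSE)
  invisible(c(p_open, p_closed, p_cfg, p_gold))
}
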