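# Shared fixtures, built in code. The toy generator is deterministic, but
# ensembles are slow enough that per-file caching pays off.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

get_toy <- function() cached("toy", make_two_domain_toy())

get_toy_net <- function() {
  cached("toy_net", build_network(get_toy()$open, get_toy()$spec$cutoff))
}

get_bistable <- function() cached("bistable", make_bistable_toy(verify = FALSE))

# group-perturbation ensembles on the pocket beads; forces span [0, 0.3]
# rescaled units, matched to the toy's unit-length links. Stationarity is
# tightened below the default so endpoints are resolved much finer than
# the clustering tolerance.
ens_opts <- function() integration_options(eps_dist = 1e-8, eps_angle = 1e-8)

get_ens_strong <- function() {
  cached("ens_strong", {
    net <- get_bistable()
    group_perturbation_ensemble(net, attr(net, "toy")$pocket_nodes, n = 40L,
                                interval = c(0, 0.3), seed = 7L,
                                opts = ens_opts())
  })
}

get_ens_none <- function() {
  cached("ens_none", {
    toy <- get_toy()
    group_perturbation_ensemble(get_toy_net(), toy$pocket_nodes, n = 40L,
                                interval = c(0, 0.3), seed = 7L,
                                opts = ens_opts())
  })
}

# two beads joined by one spring of natural length L
dumbbell_structure <- function(L = 5) {
  en_structure(1:2, rbind(c(0, 0, 0), c(L, 0, 0)))
}

dumbbell_net <- function(L = 5, cutoff = 2 * L, kappa = 1) {
  build_network(dumbbell_structure(L), cutoff, kappa)
}

# one harmonic link whose distance is recorded as d13: the linked pair is
# labelled S1/S3 and two distant free beads stand in for S2/S4
ou_fixture_net <- function(L = 5) {
  s <- en_structure(1:4, rbind(c(0, 0, 0), c(L, 0, 0),
                               c(100, 0, 0), c(200, 0, 0)))
  s$subdomain <- c("S1", "S3", "S2", "S4")
  net <- build_network(s, cutoff = L + 1)
  stopifnot(nrow(net$links) == 1L)
  net
}

# a compact 5-bead cluster, rigid at cutoff 1.8
blob5 <- function(center = c(0, 0, 0)) {
  sweep(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, 0.4, 1),
              c(1.2, 0.9, 0.8)), 2L, center, `+`)
}

# hand-rolled PDB ATOM records (fixed-column format) for reader edge cases
pdb_atom_line <- function(serial, elety, altloc, resid, chain, resno, icode,
                          x, y, z, occ = 1) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, paste0(" ", elety), altloc, resid, chain, resno, icode,
          x, y, z, occ, 0)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
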