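test_that("en_structure enforces its invariants", {
  s <- en_structure(c(1L, 3L, 7L), diag(3))
  expect_s3_class(s, "en_structure")
  expect_equal(nrow(s), 3L)
  expect_error(en_structure(c(1L, 1L, 2L), diag(3)), "strictly increasing")
  expect_error(en_structure(1:2, diag(3)), "one row per residue")
  expect_error(en_structure(1:3, matrix(c(1, NA, rep(0, 7)), 3)), "finite")
})

test_that("a CA-only file round-trips with ids preserved", {
  toy <- get_toy()
  path <- tempfile(fileext = ".pdb")
  write_conformations(coords_matrix(toy$open), toy$open, path)
  s <- load_ca_structure(path, chain = "A")
  expect_equal(s$residue_id, toy$open$residue_id)
  expect_equal(coords_matrix(s), coords_matrix(toy$open), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("reader skips residues without a Calpha, with a warning", {
  lines <- c(
    pdb_atom_line(1, "CA", " ", "ALA", "A", 1, " ", 0, 0, 0),
    pdb_atom_line(2, "CA", " ", "ALA", "A", 2, " ", 3.8, 0, 0),
    pdb_atom_line(3, "CB", " ", "ALA", "A", 3, " ", 7.6, 0, 0),
    pdb_atom_line(4, "CA", " ", "ALA", "A", 4, " ", 11.4, 0, 0))
  path <- write_pdb_fixture(lines)
  expect_warning(s <- load_ca_structure(path, "A"), "lack a Calpha")
  expect_equal(s$residue_id, c(1L, 2L, 4L))
})

test_that("altlocs collapse to the highest occupancy", {
  lines <- c(
    pdb_atom_line(1, "CA", "A", "SER", "A", 1, " ", 0, 0, 0, occ = 0.4),
    pdb_atom_line(2, "CA", "B", "SER", "A", 1, " ", 1, 0, 0, occ = 0.6),
    pdb_atom_line(3, "CA", " ", "ALA", "A", 2, " ", 3.8, 0, 0))
  s <- load_ca_structure(write_pdb_fixture(lines), "A")
  expect_equal(nrow(s), 2L)
  expect_equal(s$x[1], 1)
})

test_that("insertion codes and missing chains are fatal", {
  lines <- c(
    pdb_atom_line(1, "CA", " ", "ALA", "A", 1, "A", 0, 0, 0),
    pdb_atom_line(2, "CA", " ", "ALA", "A", 2, " ", 3.8, 0, 0))
  path <- write_pdb_fixture(lines)
  expect_error(load_ca_structure(path, "A"), "insertion codes")
  expect_error(load_ca_structure(path, "Z"), "not found")
})

test_that("the actin subdomain scheme labels every one of 372 residues", {
  ids <- 1:372
  s <- en_structure(ids, cbind(ids, 0, 0))
  s <- assign_subdomains(s)
  expect_false(any(is.na(s$subdomain)))
  # scheme boundaries, inclusive
  lab <- function(i) s$subdomain[match(i, s$residue_id)]
  expect_equal(lab(33), "S2")
  expect_equal(lab(69), "S2")
  expect_equal(lab(50), "S2")
  expect_equal(lab(200), "S4")
  expect_equal(lab(145), "S3")
  expect_equal(lab(338), "S1")
  # counts per subdomain from the published ranges
  expect_equal(sum(s$subdomain == "S2"), 37L)
  expect_equal(sum(s$subdomain == "S4"), 89L)
})

test_that("subdomain assignment is a pure function of residue id", {
  scheme <- list(S1 = list(c(1L, 2L)), S2 = list(c(3L, 4L)),
                 S3 = list(c(5L, 6L)), S4 = list(c(7L, 8L)))
  s1 <- assign_subdomains(en_structure(1:8, matrix(rnorm(24), 8)), scheme)
  s2 <- assign_subdomains(en_structure(1:8, matrix(rnorm(24), 8)), scheme)
  expect_equal(s1$subdomain, s2$subdomain)
  overlapping <- list(S1 = list(c(1L, 4L)), S2 = list(c(4L, 8L)))
  expect_error(assign_subdomains(s1, overlapping), "overlap")
})

test_that("multi-frame conformations preserve frame count and order parameters", {
  toy <- get_toy()
  frames <- list(coords_matrix(toy$open), coords_matrix(toy$closed))
  for (ext in c(".pdb", ".xyz")) {
    path <- tempfile(fileext = ext)
    write_conformations(frames, toy$open, path)
    back <- read_conformations(path)
    expect_length(back, 2L)
    for (k in 1:2) {
      op0 <- compute_order_parameters(frames[[k]], toy$open)
      op1 <- compute_order_parameters(back[[k]], toy$open)
      expect_equal(op1$d24, op0$d24, tolerance = 1e-3)
      expect_equal(op1$phi, op0$phi, tolerance = 1e-2)
    }
  }
  expect_error(write_conformations(frames[[1]][-1, ], toy$open,
                                   tempfile(fileext = ".pdb")),
               "frame")
})

test_that("subdomain schemes read back from YAML and JSON", {
  scheme <- actin_subdomains()
  py <- tempfile(fileext = ".yaml")
  yaml::write_yaml(scheme, py)
  expect_equal(read_subdomain_scheme(py), scheme)
})
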