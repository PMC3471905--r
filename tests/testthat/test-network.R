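test_that("link construction follows the strict-cutoff rule", {
  s <- en_structure(1:2, rbind(c(0, 0, 0), c(5, 0, 0)))
  net <- build_network(s, 9)
  expect_equal(nrow(net$links), 1L)
  expect_equal(net$links$r0, 5)
  # pairs at exactly the cutoff are excluded ("smaller than")
  expect_equal(nrow(build_network(s, 5)$links), 0L)
  expect_error(build_network(s[1, ], 9), "at least 2 beads")
})

test_that("link set equals a brute-force all-pairs scan on the toy", {
  toy <- get_toy()
  net <- get_toy_net()
  xyz <- coords_matrix(toy$open)
  manual <- list()
  for (i in 1:(nrow(xyz) - 1)) {
    for (j in (i + 1):nrow(xyz)) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < net$cutoff) manual[[length(manual) + 1]] <- c(i, j, d)
    }
  }
  manual <- do.call(rbind, manual)
  expect_equal(nrow(net$links), nrow(manual))
  expect_equal(cbind(net$links$i, net$links$j), manual[, 1:2],
               ignore_attr = TRUE)
  expect_equal(net$links$r0, manual[, 3])
})

test_that("elastic energy: zero at reference, closed form for one link, per-link sum", {
  net <- get_toy_net()
  ref <- network_coords(net)
  expect_equal(elastic_energy(net, ref), 0)
  # one link stretched by 1 at kappa = 1 stores 1/2
  db <- dumbbell_net(L = 5)
  stretched <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(elastic_energy(db, stretched), 0.5)
  # random displacement: term-by-term oracle
  set.seed(3)
  coords <- ref + matrix(rnorm(length(ref), sd = 0.2), nrow(ref))
  manual <- 0
  for (k in seq_len(nrow(net$links))) {
    d <- sqrt(sum((coords[net$links$j[k], ] - coords[net$links$i[k], ])^2))
    manual <- manual + 0.5 * net$kappa * (d - net$links$r0[k])^2
  }
  expect_equal(elastic_energy(net, coords), manual)
})

fd_forces <- function(net, coords, h = 1e-5) {
  g <- matrix(0, nrow(coords), 3L)
  for (i in seq_len(nrow(coords))) {
    for (c in 1:3) {
      cp <- coords; cp[i, c] <- cp[i, c] + h
      cm <- coords; cm[i, c] <- cm[i, c] - h
      g[i, c] <- -(elastic_energy(net, cp) - elastic_energy(net, cm)) / (2 * h)
    }
  }
  g
}

test_that("forces are the negative energy gradient and sum to zero", {
  net <- get_bistable()
  ref <- network_coords(net)
  expect_equal(elastic_forces(net, ref), matrix(0, nrow(ref), 3))
  set.seed(11)
  for (base in list(ref, attr(net, "closed_coords"))) {
    coords <- base + matrix(rnorm(length(base), sd = 0.1), nrow(base))
    f <- elastic_forces(net, coords)
    expect_lt(max(abs(f - fd_forces(net, coords))), 1e-6)
    expect_lt(max(abs(colSums(f))), 1e-10)  # Newton's third law
  }
  # coincident linked beads are fatal for forces
  bad <- ref; bad[2, ] <- bad[1, ]
  if (any(net$links$i == 1 & net$links$j == 2)) {
    expect_error(elastic_forces(net, bad), "coincide")
  }
})

test_that("cutoff selection counts zero modes per rigid component", {
  # two disconnected 5-bead blobs: 12 zero modes below the bridging cutoff,
  # 6 once the cutoff links everything
  xyz <- rbind(blob5(), blob5(center = c(6, 0, 0)))
  s <- en_structure(1:10, xyz)
  sel <- select_cutoff(s, candidates = c(2.0, 9.0))
  tab <- sel$table
  expect_equal(tab$zero_count[tab$cutoff == 2.0], 12L)
  expect_equal(sel$cutoff, 9.0)
  expect_error(suppressMessages(select_cutoff(s, candidates = 2.0)),
               "no candidate")
})

test_that("a bead attached by a single link leaves free rotations", {
  xyz <- rbind(blob5(), c(0, 0, -1.5))  # pendant linked only to bead 1
  s <- en_structure(1:6, xyz)
  net <- build_network(s, 1.6)
  pend <- net$links$i == 6 | net$links$j == 6
  expect_equal(sum(pend), 1L)
  nm <- normal_modes(net)
  expect_gt(nm$zero_count, 6L)
})

test_that("emergent contacts reproduce the designed pairs, empty when F = G", {
  toy <- get_toy()
  net <- get_toy_net()
  found <- find_emergent_contacts(net, toy$closed, "S2", "S4")
  expect_equal(found, toy$contact_pairs)
  expect_true(all(diff(found$dist_F) >= 0))       # sorted ascending
  expect_true(all(found$dist_G >= net$cutoff))    # cleft open in reference
  expect_equal(nrow(find_emergent_contacts(net, toy$open, "S2", "S4")), 0L)
  dropped <- toy$closed[toy$closed$residue_id != 52L, ]
  expect_error(find_emergent_contacts(net, dropped, "S2", "S4"), "mismatch")
})

test_that("breakable-link requirements are enforced and curvature scales with strength", {
  net <- get_toy_net()
  pairs <- get_toy()$contact_pairs[1:3, c("res_i", "res_j")]
  b1 <- add_breakable_links(net, pairs, strength = 0.6, r0 = 1.1)
  expect_equal(b1$breakable$curvature_ratio, 72 * 0.6 / 1.1^2)
  b4 <- add_breakable_links(net, pairs, strength = 2.4, r0 = 1.1)
  expect_equal(b4$breakable$curvature_ratio / b1$breakable$curvature_ratio, 4)
  # requirement (ii): r0 must lie inside the elastic natural-length range
  expect_error(add_breakable_links(net, pairs, strength = 0.6, r0 = 0.3),
               "requirement \\(ii\\)")
  # requirement (i): r0 below the truncation length
  expect_error(add_breakable_links(net, pairs, strength = 0.6, r0 = 1.1,
                                   truncation = 1.0),
               "requirement \\(i\\)")
  expect_error(add_breakable_links(net, net$links[1, c("res_i", "res_j")],
                                   strength = 0.6, r0 = 1.1),
               "coincide with elastic links")
})

test_that("the truncated LJ potential is flat beyond d_t and analytic below", {
  A <- 0.6; r0 <- 1.1; dt <- 1.6
  r_out <- seq(dt, 3, length.out = 20)
  expect_equal(lj_breakable(r_out, A, r0, dt), rep(0, 20))
  expect_equal(lj_breakable(r_out, A, r0, dt, deriv = 1), rep(0, 20))
  # continuity at d_t from below
  expect_lt(abs(lj_breakable(dt - 1e-8, A, r0, dt)), 1e-14)
  expect_lt(abs(lj_breakable(dt - 1e-8, A, r0, dt, deriv = 1)), 1e-6)
  # finite-difference check of the derivative inside
  r <- seq(1.0, 1.55, by = 0.05); h <- 1e-6
  fd <- (lj_breakable(r + h, A, r0, dt) - lj_breakable(r - h, A, r0, dt)) / (2 * h)
  expect_equal(lj_breakable(r, A, r0, dt, deriv = 1), fd, tolerance = 1e-6)
})

test_that("networks serialize to JSON and back, including ligands", {
  net <- get_bistable()
  toy <- attr(net, "toy")
  net <- add_adp(net, toy$adp_position)
  net <- add_atp(net, toy$pocket_nodes)
  path <- tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$links$r0, net$links$r0, tolerance = 1e-12)
  expect_equal(back$breakable$strength, net$breakable$strength)
  expect_equal(back$ligands$name, c("ADP", "Pi"))
  set.seed(1)
  coords <- network_coords(net) + matrix(rnorm(3 * 62, sd = 0.1), 62)
  expect_equal(elastic_energy(back, coords), elastic_energy(net, coords),
               tolerance = 1e-10)
})
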