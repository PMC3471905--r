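test_that("random force fields have the requested support, norms and isotropy", {
  toy <- get_toy()
  set.seed(1)
  f0 <- draw_force_field(toy$open, magnitude = 0)
  expect_equal(f0, matrix(0, 60, 3))
  f <- draw_force_field(toy$open, targets = c(23L, 53L), magnitude = 0.7)
  norms <- sqrt(rowSums(f^2))
  expect_equal(norms[c(23, 53)], c(0.7, 0.7))
  expect_equal(sum(norms > 0), 2L)
  fi <- draw_force_field(toy$open, interval = c(0.2, 0.5))
  expect_true(all(sqrt(rowSums(fi^2)) >= 0.2 - 1e-12))
  expect_true(all(sqrt(rowSums(fi^2)) <= 0.5 + 1e-12))
  # sphere-uniform directions: the mean of many unit vectors is near zero
  s1 <- en_structure(1L:2L, rbind(0, c(5, 0, 0)))
  dirs <- t(replicate(10000, draw_force_field(s1, targets = 1L,
                                              magnitude = 1)[1, ]))
  expect_lt(sqrt(sum(colMeans(dirs)^2)), 0.05)
})

test_that("endpoint classification clusters by scaled tolerance", {
  d <- tibble::tibble(dd13_rel = c(0, 0.001, 0.2), dd24_rel = c(0, 0.001, -0.3),
                      dphi = c(0, 0.1, 25))
  cl <- classify_endpoints(d)
  expect_equal(cl$assignment[1], cl$assignment[2])
  expect_false(cl$assignment[3] == cl$assignment[1])
  expect_equal(nrow(cl$clusters), 2L)
  one <- classify_endpoints(d[1, ])
  expect_equal(one$assignment, 1L)
})

test_that("zero-magnitude sensitivity probes report zero maxima", {
  net <- get_toy_net()
  row <- probe_sensitivity(net, residue = 23L, n = 3L, magnitude = 0)
  expect_equal(row$max_dphi, 0)
  expect_equal(row$max_dd13_rel, 0)
  expect_equal(row$max_dd24_rel, 0)
  expect_equal(row$n_nonconverged, 0L)
})

test_that("responses scale linearly with force magnitude in the linear regime", {
  net <- get_toy_net()
  rows <- lapply(c(0.02, 0.04, 0.08), function(m) {
    probe_sensitivity(net, residue = 23L, n = 10L, magnitude = m, seed = 3L)
  })
  r <- dplyr::bind_rows(rows)
  expect_equal(r$max_dd24_rel[2] / r$max_dd24_rel[1], 2, tolerance = 0.1)
  expect_equal(r$max_dd24_rel[3] / r$max_dd24_rel[2], 2, tolerance = 0.1)
  expect_equal(r$max_dphi[2] / r$max_dphi[1], 2, tolerance = 0.1)
})

test_that("sensitivity maxima are non-decreasing in the nested ensemble size", {
  net <- get_toy_net()
  r5 <- probe_sensitivity(net, residue = 23L, n = 5L, magnitude = 0.1, seed = 2L)
  r10 <- probe_sensitivity(net, residue = 23L, n = 10L, magnitude = 0.1, seed = 2L)
  expect_gte(r10$max_dphi, r5$max_dphi)
  expect_gte(r10$max_dd24_rel, r5$max_dd24_rel)
  expect_gte(r10$max_dd13_rel, r5$max_dd13_rel)
})

test_that("the pocket beads out-respond slab beads in a scan, and thresholds flag them", {
  net <- get_toy_net()
  toy <- get_toy()
  probed <- c(toy$pocket_nodes[1:2], 1L, 35L)  # two pocket, two slab-bottom
  scan <- scan_nbp(net, probed, n = 15L, magnitude = 0.15, seed = 4L,
                   thresholds = c(dphi = 1, dd24 = 0.02))
  expect_s3_class(scan, "en_sensitivity")
  expect_equal(nrow(scan), length(probed))
  pocket_rows <- scan$residue %in% toy$pocket_nodes
  expect_gt(min(scan$max_dd24_rel[pocket_rows]),
            max(scan$max_dd24_rel[!pocket_rows]))
  # thresholds above every response empty the sensitive set
  high <- scan_nbp(net, probed, n = 3L, magnitude = 0.05, seed = 4L,
                   thresholds = c(dphi = 1e6, dd24 = 1e6))
  expect_false(any(high$sensitive))
})

test_that("ensembles flag rather than drop non-converged runs and are seed-reproducible", {
  net <- get_toy_net()
  toy <- get_toy()
  e1 <- group_perturbation_ensemble(net, toy$pocket_nodes, n = 6L,
                                    interval = c(0, 0.2), seed = 11L)
  e2 <- group_perturbation_ensemble(net, toy$pocket_nodes, n = 6L,
                                    interval = c(0, 0.2), seed = 11L)
  expect_equal(e1$realizations, e2$realizations)
  expect_equal(nrow(e1$realizations), 6L)
  expect_equal(e1$n_nonconverged,
               sum(is.na(e1$realizations$cluster)))
  g <- glance(e1)
  expect_equal(g$n, 6L)
})

test_that("global random-force ensembles on the plain network return to equilibrium", {
  net <- get_toy_net()
  ens <- global_response_ensemble(net, n = 8L, interval = c(0, 0.1),
                                  seed = 13L, opts = ens_opts())
  expect_equal(nrow(ens$realizations), 8L)
  expect_equal(ens$n_nonconverged, 0L)
  # deformed states move, endpoints all come home to the single open basin
  expect_gt(max(abs(ens$realizations$deformed_dd24_rel)), 0.001)
  expect_equal(nrow(ens$clusters), 1L)
  expect_lt(abs(ens$clusters$dd24_rel), 0.005)
  # stronger global forces may strand a few runs in locally modified
  # states, but the dominant endpoint remains the equilibrium
  big <- global_response_ensemble(net, n = 8L, interval = c(0, 0.2),
                                  seed = 13L, opts = ens_opts())
  main <- big$clusters[which.max(big$clusters$n), ]
  expect_gte(main$n, 5L)
  expect_lt(abs(main$dd24_rel), 0.005)
})

test_that("endpoint classification of the bistable ensemble is stable under halved tolerance", {
  ens <- get_ens_strong()
  d <- ens$realizations[ens$realizations$converged,
                        c("dd13_rel", "dd24_rel", "dphi")]
  full <- classify_endpoints(d, tol = c(0.005, 0.005, 0.5))
  half <- classify_endpoints(d, tol = c(0.005, 0.005, 0.5) / 2)
  expect_equal(nrow(half$clusters), nrow(full$clusters))
})

test_that("thermal variance shrinks with the noise intensity", {
  net <- get_toy_net()
  expect_warning(
    thermal_distribution(net, D = 1e-4, n_samples = 50L, stride = 10L,
                         burn_in = 100L,
                         opts = integration_options(seed = 1L)),
    "variance")
  t_hi <- thermal_distribution(net, D = 2e-4, n_samples = 500L, stride = 50L,
                               burn_in = 1000L,
                               opts = integration_options(seed = 5L))
  t_lo <- thermal_distribution(net, D = 5e-5, n_samples = 500L, stride = 50L,
                               burn_in = 1000L,
                               opts = integration_options(seed = 5L))
  expect_gt(stats::var(t_hi$samples$d24), stats::var(t_lo$samples$d24))
  expect_equal(nrow(t_hi$samples), 500L)
})

test_that("plot methods return ggplot objects", {
  ens <- get_ens_strong()
  expect_s3_class(autoplot(ens), "ggplot")
  nm <- cached("toy_modes", normal_modes(get_toy_net()))
  expect_s3_class(autoplot(nm), "ggplot")
  net <- get_toy_net()
  scan <- cached("mini_scan",
                 scan_nbp(net, c(23L, 1L), n = 2L, magnitude = 0.05,
                          thresholds = c(dphi = 1, dd24 = 0.02)))
  expect_s3_class(autoplot(scan), "ggplot")
  th <- thermal_distribution(net, D = 1e-4, n_samples = 200L, stride = 20L,
                             burn_in = 200L,
                             opts = integration_options(seed = 2L))
  expect_s3_class(autoplot(th), "ggplot")
})
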