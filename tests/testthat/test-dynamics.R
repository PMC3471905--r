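test_that("the equilibrium state is a fixed point of the deterministic dynamics", {
  net <- get_toy_net()
  ref <- network_coords(net)
  after <- step_network(net, ref, n_steps = 50L)
  expect_equal(after, ref)
})

test_that("a stretched dumbbell relaxes as exp(-2 t) in rescaled units", {
  db <- dumbbell_net(L = 5)
  x0 <- rbind(c(-0.5, 0, 0), c(5.5, 0, 0))  # stretched by 1
  opts <- integration_options(dt = 0.01)
  xt <- step_network(db, x0, opts = opts, n_steps = 100L)  # t = 1
  dev <- (xt[2, 1] - xt[1, 1]) - 5
  expect_equal(dev, exp(-2), tolerance = 3 * opts$dt)
  # halving dt halves the discretisation error (first-order Euler)
  xt2 <- step_network(db, x0, opts = integration_options(dt = 0.005),
                      n_steps = 200L)
  dev2 <- (xt2[2, 1] - xt2[1, 1]) - 5
  expect_lt(abs(dev2 - exp(-2)), abs(dev - exp(-2)))
})

test_that("free diffusion has mean-square displacement 2 D t per axis", {
  s <- en_structure(1:2, rbind(c(0, 0, 0), c(100, 0, 0)))
  net <- build_network(s, 1)   # no links: two independent free beads
  expect_equal(nrow(net$links), 0L)
  D <- 0.01; nsteps <- 200L; dt <- 0.01
  disp2 <- replicate(300, {
    opts <- integration_options(dt = dt, noise_D = D)
    xt <- step_network(net, network_coords(net), opts = opts,
                       n_steps = nsteps)
    (xt - network_coords(net))^2
  })
  msd <- mean(disp2)  # over 300 runs x 2 beads x 3 axes
  expect_equal(msd, 2 * D * nsteps * dt, tolerance = 0.15)
})

test_that("immobilizing forces cancel net force and torque without strain", {
  toy <- get_toy()
  xyz <- coords_matrix(toy$open)
  # zero field -> zero balancing field
  expect_equal(immobilizing_forces(xyz, matrix(0, 60, 3)), matrix(0, 60, 3))
  # uniform translation field -> exact negation
  unif <- matrix(rep(c(1, -2, 0.5), each = 60), 60)
  expect_equal(immobilizing_forces(xyz, unif), -unif)
  # random fields: residual force and torque below 1e-10
  set.seed(8)
  for (rep in 1:5) {
    field <- matrix(rnorm(180), 60)
    bal <- immobilizing_forces(xyz, field)
    tot <- field + bal
    expect_lt(sqrt(sum(colSums(tot)^2)), 1e-10)
    com <- colMeans(xyz)
    tau <- colSums(t(vapply(1:60, function(i) {
      d <- xyz[i, ] - com
      c(d[2] * tot[i, 3] - d[3] * tot[i, 2],
        d[3] * tot[i, 1] - d[1] * tot[i, 3],
        d[1] * tot[i, 2] - d[2] * tot[i, 1])
    }, numeric(3))))
    expect_lt(sqrt(sum(tau^2)), 1e-10)
  }
  expect_error(immobilizing_forces(xyz[1:2, ], matrix(1, 2, 3)), "3 beads")
})

test_that("immobilized integration does not drift the center of mass", {
  net <- get_toy_net()
  set.seed(9)
  field <- matrix(rnorm(180, sd = 0.1), 60)
  x0 <- network_coords(net)
  xt <- step_network(net, x0, field = field,
                     opts = integration_options(immobilize = TRUE),
                     n_steps = 200L)
  expect_lt(sqrt(sum((colMeans(xt) - colMeans(x0))^2)), 1e-9 * 200)
})

test_that("deterministic relaxation dissipates elastic energy monotonically", {
  net <- get_toy_net()
  set.seed(10)
  x0 <- network_coords(net) + matrix(rnorm(180, sd = 0.15), 60)
  r <- relax_to_stationary(net, x0,
                           opts = integration_options(record_stride = 50L))
  expect_true(r$converged)
  expect_true(all(diff(r$trajectory$energy) <= 1e-12))
  # small perturbations relax back to the open equilibrium
  ref <- compute_order_parameters(coords_matrix(net$structure), net$structure)
  d <- deltas_vs_reference(r$state, ref)
  expect_lt(abs(d$dd24_rel), 5e-3)
  expect_lt(abs(d$dphi), 0.5)
})

test_that("relaxation from equilibrium converges immediately", {
  net <- get_toy_net()
  r <- relax_to_stationary(net)
  expect_true(r$converged)
  expect_lte(r$steps, 100L)
  expect_equal(r$coords, network_coords(net))
})

test_that("the bistable toy relaxes into the basin it starts in", {
  net <- get_bistable()
  toy <- attr(net, "toy")
  open_d24 <- compute_order_parameters(coords_matrix(toy$open), toy$open)$d24
  closed_d24 <- compute_order_parameters(coords_matrix(toy$closed),
                                         toy$closed)$d24
  mid <- (open_d24 + closed_d24) / 2
  rc <- relax_to_stationary(net, attr(net, "closed_coords"))
  expect_true(rc$converged)
  expect_lt(rc$state$d24, mid)
  expect_true(any(engaged_breakable(net, rc$coords)))
  ro <- relax_to_stationary(net)
  expect_gt(ro$state$d24, mid)
})

test_that("check_timestep reports a small discrepancy in the linear regime", {
  db <- dumbbell_net(L = 5)
  x0 <- rbind(c(-0.2, 0, 0), c(5.2, 0, 0))
  chk <- check_timestep(db, x0, dt = 0.01, dt_small = 0.002,
                        opts = integration_options(eps_dist = 1e-9))
  expect_true(all(chk$converged))
  expect_lt(chk$max_discrepancy, 1e-3)
  same <- check_timestep(db, x0, dt = 0.01, dt_small = 0.01)
  expect_equal(same$max_discrepancy, 0)
})

test_that("noisy runs refuse stationarity detection and support seeds", {
  net <- get_toy_net()
  expect_error(relax_to_stationary(net, opts = integration_options(noise_D = 1e-4)),
               "deterministic")
  o <- integration_options(noise_D = 1e-4, seed = 99L)
  x1 <- step_network(net, network_coords(net), opts = o, n_steps = 50L)
  x2 <- step_network(net, network_coords(net), opts = o, n_steps = 50L)
  expect_equal(x1, x2)  # same seed, same path
})
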