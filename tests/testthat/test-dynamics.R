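test_that("forces and energies match the independent direct-sum oracle", {
  ff <- kh_forcefield()

  # hand-built 5-bead mixed system: charged, bonded, near and far pairs
  df <- data.frame(chain = "A", resnum = 1:5, code = c("K", "L", "E", "F", "G"),
                   x = c(0, 3.8, 7.6, 12, 30), y = c(0, 0.5, 0, 4, 0),
                   z = c(0, 0, 1, 0, 2))
  topo <- build_system(df, flexible_spec = "A", box_side = 80)
  pos <- bead_positions(topo)
  got <- compute_forces(topo, pos, ff)
  want <- r_energy_oracle(topo, pos, ff)
  expect_equal(got$energies$bond, want$bond, tolerance = 1e-12)
  expect_equal(got$energies$vdw, want$vdw, tolerance = 1e-12)
  expect_equal(got$energies$elec, want$elec, tolerance = 1e-12)

  # random 50-bead systems, including periodic minimum image
  for (seed in 1:3) {
    topo <- random_system(50, box = 40, seed = seed)
    pos <- bead_positions(topo)
    got <- compute_forces(topo, pos, ff)
    want <- r_energy_oracle(topo, pos, ff)
    expect_equal(got$energies$total, want$total, tolerance = 1e-10)
  }
})

test_that("neighbor-list runs reproduce energies for any rebuild interval", {
  topo <- random_system(40, box = 35, seed = 5)
  st <- init_state(topo, temperature = 300, seed = 5)
  it <- function(rb) integrator_params(temperature = 300, seed = 5,
                                       rebuild_every = rb)
  logs <- lapply(c(1, 17, 1000), function(rb)
    run_dynamics(topo, st, 500, it(rb), output_every = 50)$energy)
  expect_identical(logs[[1]], logs[[2]])
  expect_identical(logs[[1]], logs[[3]])
})

test_that("pairs beyond every cutoff contribute nothing; bonded forces obey Newton's third law", {
  df <- data.frame(chain = c("A", "B"), resnum = c(1, 1), code = c("K", "K"),
                   x = c(0, 45), y = 0, z = 0)
  topo <- build_system(df, flexible_spec = c("A", "B"), box_side = 200)
  cf <- compute_forces(topo)
  expect_identical(cf$energies$total, 0)
  expect_true(all(cf$forces == 0))

  topo <- flexible_dimer()
  pos <- bead_positions(topo); pos[2, 1] <- 4.4
  cf <- compute_forces(topo, pos)
  expect_equal(colSums(cf$forces), c(0, 0, 0), tolerance = 1e-12)
})

test_that("deterministic and degenerate propagation behave as contracted", {
  topo <- flexible_dimer()

  # zero steps: no frames, but the initial energies are logged
  st <- init_state(topo)
  tr0 <- run_dynamics(topo, st, 0, output_every = 100)
  expect_equal(tr0$nframes, 0)
  expect_equal(nrow(tr0$energy), 1)
  expect_equal(tr0$energy$total[1], 0)

  # T = 0, zero velocities, equilibrium configuration: state unchanged
  trz <- run_dynamics(topo, st, 100,
                      integrator_params(temperature = 0, seed = 1),
                      output_every = 50)
  expect_equal(trz$state$pos, st$pos, tolerance = 1e-12,
               ignore_attr = TRUE)

  # bit-identical energy logs for the same seed
  st <- init_state(topo, temperature = 300, seed = 6)
  a <- run_dynamics(topo, st, 300, integrator_params(seed = 6),
                    output_every = 30)
  b <- run_dynamics(topo, st, 300, integrator_params(seed = 6),
                    output_every = 30)
  expect_identical(a$energy, b$energy)
  expect_identical(a$state$pos, b$state$pos)
})

test_that("Langevin thermostat holds the kinetic temperature", {
  topo <- flexible_dimer()
  st <- init_state(topo, temperature = 300, seed = 7)
  # fine time step: the kinetic temperature read-out at full steps carries an
  # O((w dt)^2) discretisation bias for the stiff bond mode at dt = 10
  tr <- run_dynamics(topo, st, 1e5,
                     integrator_params(dt = 5, temperature = 300, seed = 7),
                     output_every = 10)
  second_half <- tr$energy$temp_kinetic[(nrow(tr$energy) %/% 2):nrow(tr$energy)]
  expect_equal(mean(second_half), 300, tolerance = 0.03)
})

test_that("a flexible bead in a harmonic trap satisfies equipartition", {
  topo <- harmonic_trap(K = 1)
  st <- init_state(topo, temperature = 300, seed = 4)
  tr <- run_dynamics(topo, st, 5e5,
                     integrator_params(dt = 5, damping = 200,
                                       temperature = 300, seed = 4),
                     output_every = 10)
  # U = K r^2 gives per-axis variance kB T / (2 K)
  for (ax in 1:3)
    expect_equal(var(tr$frames[2, ax, ]), kB * 300 / 2, tolerance = 0.05)
})

test_that("bond-length distribution is Boltzmann (KS < 0.02)", {
  topo <- flexible_dimer()
  st <- init_state(topo, temperature = 300, seed = 3)
  tr <- run_dynamics(topo, st, 1e6,
                     integrator_params(temperature = 300, damping = 100,
                                       seed = 3),
                     output_every = 1)
  r <- bond_lengths(tr)
  grid <- seq(3.0, 4.7, length.out = 4000)
  dens <- grid^2 * exp(-189 * (grid - 3.81)^2 / (kB * 300))
  cdf <- cumsum(dens) / sum(dens)
  ks <- max(abs(stats::ecdf(r)(grid) - cdf))
  expect_lt(ks, 0.02)
})

test_that("rigid bodies keep internal distances fixed over 1e5 steps", {
  df <- data.frame(chain = "A", resnum = 1:3, code = c("L", "A", "K"),
                   x = c(0, 3.8, 7.6), y = c(0, 1.5, 0), z = c(0, 0, 2))
  topo <- build_system(df, rigid_spec = list(body = "A"), box_side = 100)
  st <- init_state(topo, temperature = 300, seed = 9)
  tr <- run_dynamics(topo, st, 1e5, integrator_params(temperature = 300,
                                                      seed = 9),
                     output_every = 1e4)
  d0 <- stats::dist(bead_positions(topo))
  for (f in seq_len(tr$nframes))
    expect_lt(max(abs(stats::dist(traj_frame(tr, f)) - d0)), 1e-6)
})

test_that("NVE propagation conserves energy, momentum and the oscillator period", {
  topo <- flexible_dimer()
  st <- init_state(topo)
  st$pos[2, 1] <- 4.11                      # 0.3 A initial stretch
  it <- integrator_params(dt = 1, damping = 0, temperature = 0, seed = 5)
  tr <- nve_run(topo, st, 1e5, it, output_every = 10)

  etot <- tr$energy$total + tr$energy$kinetic
  amplitude <- max(tr$energy$total) - min(tr$energy$total)
  drift <- abs(mean(utils::tail(etot, 500)) - mean(utils::head(etot, 500)))
  expect_lt(drift, 0.001 * amplitude)

  # linear momentum of the isolated pair is conserved to machine precision
  m <- topo$beads$mass
  p_end <- colSums(tr$state$vel * m)
  expect_equal(p_end, c(0, 0, 0), tolerance = 1e-12)

  # period against the reduced-mass closed form 2 pi sqrt(mu / (2k))
  r <- bond_lengths(tr)
  crossings <- which(diff(sign(r - 3.81)) != 0)
  period <- 2 * mean(diff(crossings)) * 10       # frames every 10 fs
  mu <- m[1] / 2
  k_int <- 189 * khmd_constants()$kcal2internal
  expect_equal(period, 2 * pi * sqrt(mu / (2 * k_int)), tolerance = 0.01)

  # equilibrium at rest stays at rest
  st0 <- init_state(topo)
  tr0 <- nve_run(topo, st0, 1000, it, output_every = 500)
  expect_equal(tr0$state$pos, st0$pos, tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("overlapping beads are flagged as a hazard, not an error", {
  df <- data.frame(chain = c("A", "B"), resnum = c(1, 1), code = c("A", "A"),
                   x = c(0, 0.05), y = 0, z = 0)
  topo <- build_system(df, flexible_spec = c("A", "B"), box_side = 50)
  expect_message(cf <- compute_forces(topo), "hazard")
  expect_true(is.finite(cf$energies$total))
})
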