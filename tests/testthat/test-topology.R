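pdb_lines <- function(records) {
  vapply(records, function(r) {
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
            r$serial, r$name, r$res, r$chain, r$resno,
            if (is.null(r$icode)) " " else r$icode, r$x, r$y, r$z)
  }, character(1))
}

test_that("C-alpha reader round-trips coordinates and reports missing C-alphas", {
  recs <- list(
    list(serial = 1, name = "CA", res = "ALA", chain = "A", resno = 1,
         x = 1.1, y = 2.2, z = 3.3),
    list(serial = 2, name = "CA", res = "LEU", chain = "A", resno = 2,
         x = 4.4, y = 5.5, z = 6.6),
    list(serial = 3, name = "CA", res = "LYS", chain = "A", resno = 3,
         x = 7.7, y = 8.8, z = 9.9))
  st <- read_calpha_structure(paste(pdb_lines(recs), collapse = "\n"))
  expect_equal(nrow(st$beads), 3)
  expect_equal(st$beads$code, c("A", "L", "K"))
  expect_equal(st$beads$x, c(1.1, 4.4, 7.7))
  expect_equal(nrow(st$missing), 0)

  # residue 2 has only a CB: must be reported, not dropped silently
  recs2 <- recs
  recs2[[2]]$name <- "CB"
  st2 <- read_calpha_structure(paste(pdb_lines(recs2), collapse = "\n"))
  expect_equal(nrow(st2$beads), 2)
  expect_equal(st2$missing$resnum, 2)

  expect_error(read_calpha_structure(tempfile(fileext = ".pdb")))
})

test_that("insertion codes yield one bead per distinct (resnum, icode)", {
  recs <- list(
    list(serial = 1, name = "CA", res = "GLY", chain = "A", resno = 10,
         x = 0, y = 0, z = 0),
    list(serial = 2, name = "CA", res = "GLY", chain = "A", resno = 10,
         icode = "A", x = 3.8, y = 0, z = 0),
    list(serial = 3, name = "CA", res = "GLY", chain = "A", resno = 11,
         x = 7.6, y = 0, z = 0))
  st <- read_calpha_structure(paste(pdb_lines(recs), collapse = "\n"))
  expect_equal(nrow(st$beads), 3)
})

test_that("system builder creates junction bonds and rigid-internal exclusions", {
  hx <- make_alpha_helix(rep("A", 10))
  df <- data.frame(chain = "A", resnum = 1:10, code = "A",
                   x = hx[, 1], y = hx[, 2], z = hx[, 3])

  # fully rigid: no bonds, and the lone rigid body has zero nonbonded energy
  t_rig <- build_system(df, rigid_spec = list(dom = "A"), box_side = 100)
  expect_equal(nrow(t_rig$bonds), 0)
  cf <- compute_forces(t_rig)
  expect_identical(cf$energies$total, 0)
  expect_true(all(cf$forces == 0))

  # fully flexible 10-mer: 9 bonds
  t_flex <- build_system(df, flexible_spec = "A", box_side = 100)
  expect_equal(nrow(t_flex$bonds), 9)

  # rigid(1-5)+flexible(6-10): junction 5-6 plus the four tail bonds
  t_mix <- build_system(df, rigid_spec = list(dom = "A:1-5"),
                        flexible_spec = "A:6-10", box_side = 100)
  expect_equal(nrow(t_mix$bonds), 5)
  expect_true(any(t_mix$bonds$i == 5 & t_mix$bonds$j == 6))

  # bond graph is a union of paths: no bead has more than two bonds
  deg <- table(c(t_mix$bonds$i, t_mix$bonds$j))
  expect_true(all(deg <= 2))

  expect_error(build_system(df, rigid_spec = list(a = "A:1-5", b = "A:4-10")),
               "overlaps")
  expect_error(build_system(df, rigid_spec = list(a = "A:1-5")),
               "neither rigid nor flexible")
})

test_that("Kabsch superposition recovers exact transforms and is rotation invariant", {
  set.seed(42)
  x <- matrix(rnorm(150), 50, 3)

  id <- kabsch_superpose(x, x)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)

  # 90 degrees about z plus a shift
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  target <- x %*% t(R90) + matrix(c(5, -3, 2), 50, 3, byrow = TRUE)
  tr <- kabsch_superpose(x, target)
  expect_lt(tr$rmsd, 1e-10)
  expect_equal(tr$rotation, R90, tolerance = 1e-8)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_transform(x, tr), target, tolerance = 1e-8)

  # RMSD invariant to pre-rotation of the mobile set
  th <- 0.83
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  noisy <- target + matrix(rnorm(150, sd = 0.3), 50, 3)
  expect_equal(kabsch_superpose(x, noisy)$rmsd,
               kabsch_superpose(x %*% t(Rz), noisy)$rmsd, tolerance = 1e-10)

  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition RMSD of noisy correspondences matches the Monte-Carlo band", {
  rmsds <- vapply(1:100, function(s) {
    set.seed(s)
    x <- matrix(rnorm(150), 50, 3)
    y <- x + matrix(rnorm(150, sd = 0.1), 50, 3)
    kabsch_superpose(x, y)$rmsd
  }, numeric(1))
  expect_true(all(rmsds > 0.05 & rmsds < 0.25))
})

test_that("reference construction composes per-component transforms", {
  bp <- make_binding_pair()
  topo <- bp$topology

  ref0 <- make_reference(topo)
  expect_equal(ref0$pos, bead_positions(topo))

  shift <- structure(list(rotation = diag(3), translation = c(100, 0, 0),
                          rmsd = 0), class = "kh_transform")
  ref1 <- make_reference(topo, transforms = list(B = shift))
  iA <- which(ref1$component == "A"); iB <- which(ref1$component == "B")
  d0 <- sqrt(outer(rowSums(ref0$pos[iA, ]^2), rowSums(ref0$pos[iB, ]^2), "+") -
             2 * ref0$pos[iA, ] %*% t(ref0$pos[iB, ]))
  d1 <- sqrt(outer(rowSums(ref1$pos[iA, ]^2), rowSums(ref1$pos[iB, ]^2), "+") -
             2 * ref1$pos[iA, ] %*% t(ref1$pos[iB, ]))
  expect_true(all(d1 > d0))

  # the fixture's designed dock places the components in contact
  dref <- as.matrix(stats::dist(bp$reference$pos))[iA, iB]
  expect_lt(min(dref), 8)

  expect_error(make_reference(topo, transforms = list(Z = shift)),
               "not present")
})

test_that("capping beads are immobile, repulsive, and block approach", {
  topo <- flexible_dimer(box = 200)
  expect_identical(add_capping_beads(topo, matrix(0, 0, 3), 20), topo)
  expect_error(add_capping_beads(topo, c(0, 0, 0), -1), "positive")

  capped <- add_capping_beads(topo, c(100, 0, 0), sigma_large = 20)
  expect_equal(nrow(capped$beads), 3)
  expect_true(capped$beads$fixed[3])

  # 1D scan of a probe approaching the cap: strong repulsion inside the
  # contact distance, zero beyond the truncation
  probe_u <- function(x) {
    pos <- bead_positions(capped)
    pos[1, ] <- c(x, 0, 0); pos[2, ] <- c(x - 3.81, 0, 0)
    compute_forces(capped, pos)$energies$vdw
  }
  sig_pair <- (20 + capped$beads$sigma[1]) / 2
  inside <- probe_u(100 - 0.8 * sig_pair)
  at_contact <- probe_u(100 - 2^(1/6) * sig_pair)
  expect_gt(inside, at_contact)
  expect_gt(inside, 0)
  expect_equal(probe_u(100 - 3.5 * sig_pair), 0)
})

test_that("mass scaling changes dynamics only, never the potential", {
  bp <- make_binding_pair()
  topo0 <- bp$topology
  topo0$groups$A$mass_scale <- 1
  topo0$groups$B$mass_scale <- 1
  topo100 <- set_mass_scaling(set_mass_scaling(topo0, "A", 100), "B", 100)

  pos <- bp$bound_positions
  e0 <- compute_forces(topo0, pos)$energies
  e100 <- compute_forces(topo100, pos)$energies
  expect_identical(e0, e100)

  # factor 1 is a no-op: identical trajectories for the same seed
  t1 <- set_mass_scaling(topo0, "A", 1)
  st <- init_state(topo0, temperature = 300, seed = 8)
  a <- run_dynamics(topo0, st, 200, integrator_params(seed = 8),
                    output_every = 100)
  b <- run_dynamics(t1, st, 200, integrator_params(seed = 8),
                    output_every = 100)
  expect_identical(a$state$pos, b$state$pos)

  expect_error(set_mass_scaling(topo0, "nope", 10), "unknown group")
  expect_error(set_mass_scaling(topo0, "A", 0), "positive")
})

test_that("equilibrium averages are invariant to mass scaling (tethered rigid body)", {
  # rigid tri-bead body on a 12 A harmonic tether to a fixed bead (long
  # enough that no member enters the anchor's LJ core); the sampled radial
  # variance must agree between scaled and unscaled dynamical masses and
  # with the harmonic estimate kB T / (2 k)
  mk <- function(scale) {
    df <- data.frame(chain = "A", resnum = 1:4, code = c("A", "A", "L", "S"),
                     x = c(-12, 0.2, 3.9, 7.7), y = c(0, 0, 1.2, 0),
                     z = c(0, 0, 0, 1.1))
    topo <- build_system(df, rigid_spec = list(body = "A:2-4"),
                         flexible_spec = "A:1-1", box_side = 80)
    topo$beads$fixed[1] <- TRUE
    topo$bonds$r0 <- 12; topo$bonds$k <- 0.5
    set_mass_scaling(topo, "body", scale)
  }
  sample_var <- function(topo, seed) {
    st <- init_state(topo, temperature = 300, seed = seed)
    tr <- run_dynamics(topo, st, 2e5,
                       integrator_params(dt = 5, damping = 200,
                                         temperature = 300, seed = seed),
                       output_every = 40)
    r <- sqrt(colSums((tr$frames[2, , ] - tr$frames[1, , ])^2))
    var(r[-(1:500)])
  }
  v1 <- sample_var(mk(1), 21)
  v100 <- sample_var(mk(100), 120)
  expect_equal(v100 / v1, 1, tolerance = 0.1)
  expect_equal(v1, kB * 300 / (2 * 0.5), tolerance = 0.12)
})
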