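# Force/energy evaluation and Langevin propagation of mixed flexible-bead /
# rigid-body systems.  The inner loop lives in src/engine.cpp; this file owns
# state construction (rigid-body frames, inertia), packing, and the user API.

#' Bundle force-field constants and the pair table
#'
#' @param params Global constants, [kh_params()].
#' @param contact_matrix 20x20 contact-energy matrix ([load_contact_matrix()]).
#' @param residues Residue parameter table ([residue_params()]).
#' @return A `kh_forcefield`: list(params, table).
#' @export
kh_forcefield <- function(params = kh_params(),
                          contact_matrix = load_contact_matrix(),
                          residues = residue_params()) {
  structure(list(params = params,
                 table = build_pair_table(contact_matrix, params, residues)),
            class = "kh_forcefield")
}

#' Integrator parameters
#'
#' Defaults follow the simulation protocol this package implements: 10 fs
#' time step, Langevin damping time 1,000 fs (friction = mass / damping),
#' neighbor-list rebuild every 1,000 steps with a 4 Angstrom skin (plus an
#' automatic early rebuild whenever any bead has moved more than skin/2).
#'
#' @param dt Time step, fs.
#' @param damping Langevin relaxation time, fs; `0` disables the thermostat
#'   (NVE velocity-Verlet limit).
#' @param temperature Target temperature, Kelvin.
#' @param seed Integer seed of the counter-based RNG stream.
#' @param replica Replica-stream index (distinct replicas draw independent
#'   noise from the same seed).
#' @param skin Neighbor-list skin, Angstrom.
#' @param rebuild_every Scheduled neighbor-list rebuild interval, steps.
#' @return An `integrator_params` list.
#' @export
integrator_params <- function(dt = 10, damping = 1000, temperature = 300,
                              seed = 1, replica = 0, skin = 4,
                              rebuild_every = 1000) {
  stopifnot(dt > 0, damping >= 0, temperature >= 0, rebuild_every >= 1,
            skin >= 0)
  structure(list(dt = dt, damping = damping, temperature = temperature,
                 seed = as.double(seed), replica = as.double(replica),
                 skin = skin, rebuild_every = as.integer(rebuild_every)),
            class = "integrator_params")
}

# pack topology + force field into the flat list the C++ engine consumes
.pack_system <- function(topology, forcefield) {
  b <- topology$beads
  rc <- forcefield$table$residues$code
  type <- ifelse(is.na(b$code), -1L, match(b$code, rc) - 1L)
  if (anyNA(type)) stop("bead residue codes not covered by the pair table")
  gid <- rep(-1L, nrow(b))
  for (g in seq_along(topology$groups))
    gid[topology$groups[[g]]$members] <- g - 1L
  p <- forcefield$params
  list(type = as.integer(type), sigma = b$sigma, charge = b$charge,
       mass = b$mass, gid = gid, fixed = as.integer(b$fixed),
       eps = as.double(forcefield$table$epsilon),
       cap_eps = topology$cap_eps,
       globals = c(p$dielectric, p$debye_length, p$elec_cutoff,
                   p$lj_cutoff_factor, p$coulomb_constant,
                   if (isTRUE(p$bond_half_convention)) 0.5 else 1),
       bond_i = as.integer(topology$bonds$i - 1L),
       bond_j = as.integer(topology$bonds$j - 1L),
       bond_r0 = topology$bonds$r0, bond_k = topology$bonds$k,
       box = if (isTRUE(topology$box$periodic)) topology$box$side else 0)
}

# rotation matrix (columns = principal axes) -> unit quaternion (w,x,y,z)
.mat2quat <- function(E) {
  tr <- sum(diag(E))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (E[3, 2] - E[2, 3]) / s, (E[1, 3] - E[3, 1]) / s,
           (E[2, 1] - E[1, 2]) / s)
  } else {
    i <- which.max(diag(E))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(E[i, i] - E[j, j] - E[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (E[k, j] - E[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (E[j, i] + E[i, j]) / s
    q[k + 1] <- (E[k, i] + E[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Initialise a simulation state
#'
#' Computes per-rigid-group centre of mass, principal axes (body frame),
#' effective mass and inertia after mass scaling, and optionally draws
#' Maxwell-Boltzmann velocities at a temperature.
#'
#' @param topology A `kh_topology`.
#' @param positions Optional n x 3 starting coordinates (default: as built).
#' @param temperature If non-NULL, draw initial velocities at this
#'   temperature (Kelvin); otherwise start at rest.
#' @param seed RNG seed for the velocity draw.
#' @return A `kh_state`: positions, velocities, per-group rigid-body state
#'   (com, V, quaternion, body-frame angular velocity), step counter.
#' @export
init_state <- function(topology, positions = NULL, temperature = NULL,
                       seed = 1) {
  b <- topology$beads
  pos <- if (is.null(positions)) bead_positions(topology) else as.matrix(positions)
  stopifnot(nrow(pos) == nrow(b))
  vel <- matrix(0, nrow(b), 3)
  kT_int <- if (is.null(temperature)) 0 else .kB * temperature * .kcal2int
  set.seed(seed)
  flex <- is.na(b$group) & !b$fixed
  if (kT_int > 0 && any(flex))
    vel[flex, ] <- rnorm(3 * sum(flex)) *
      sqrt(kT_int / b$mass[flex])
  groups <- lapply(names(topology$groups), function(g) {
    gr <- topology$groups[[g]]
    mem <- gr$members
    m <- b$mass[mem]
    pm <- pos[mem, , drop = FALSE]
    com <- colSums(pm * m) / sum(m)
    r <- sweep(pm, 2, com)
    Iraw <- matrix(0, 3, 3)
    for (k in seq_along(mem)) {
      rk <- r[k, ]
      Iraw <- Iraw + m[k] * (sum(rk^2) * diag(3) - tcrossprod(rk))
    }
    sc <- gr$mass_scale
    eg <- eigen(Iraw / sc, symmetric = TRUE)
    E <- eg$vectors
    if (det(E) < 0) E[, 3] <- -E[, 3]
    Iprin <- pmax(eg$values, 1e-12)
    if (min(eg$values) < 1e-8)
      stop("rigid group '", g, "' has a near-zero principal moment (collinear)")
    M <- sum(m) / sc
    V <- c(0, 0, 0); w <- c(0, 0, 0)
    if (kT_int > 0 && !isTRUE(gr$fixed)) {
      V <- rnorm(3) * sqrt(kT_int / M)
      w <- rnorm(3) * sqrt(kT_int / Iprin)
    }
    list(members = mem, Xb = r %*% E, Iprin = Iprin, M = M,
         fixed = isTRUE(gr$fixed), com = com, V = V,
         q = .mat2quat(E), omega = w)
  })
  names(groups) <- names(topology$groups)
  structure(list(pos = pos, vel = vel, groups = groups, step = 0),
            class = "kh_state")
}

#' Forces and decomposed energies of a configuration
#'
#' Exact negative gradient of the implemented truncated potential, with
#' minimum image when the box is periodic; excluded pairs (intra-rigid-group,
#' bonded 1-2) contribute nothing.
#'
#' @param topology A `kh_topology`.
#' @param positions Optional n x 3 coordinates (default: topology's own).
#' @param forcefield A [kh_forcefield()].
#' @return List with `forces` (n x 3, kcal/(mol A)) and `energies` (tibble:
#'   bond, vdw, elec, total kcal/mol).  `n_close` counts pairs seen below
#'   0.1 Angstrom (numerical-hazard flag, not an error).
#' @export
compute_forces <- function(topology, positions = NULL,
                           forcefield = kh_forcefield()) {
  pos <- if (is.null(positions)) bead_positions(topology) else as.matrix(positions)
  out <- cpp_energy_forces(pos, .pack_system(topology, forcefield))
  if (out$n_close > 0)
    message("numerical hazard: ", out$n_close, " pair(s) below 0.1 A")
  list(forces = out$forces,
       energies = tibble::tibble(bond = out$bond, vdw = out$vdw,
                                 elec = out$elec, total = out$total),
       n_close = out$n_close)
}

#' Run Langevin (or NVE) dynamics
#'
#' Propagates the system with a BAOAB splitting integrator: flexible beads
#' as Langevin particles, rigid groups as quaternion rigid bodies with
#' Langevin friction and noise on both translation and body-frame rotation
#' (same damping time).  With `damping = 0` the scheme reduces to symplectic
#' velocity Verlet (NVE).  Bit-reproducible for a given seed.
#'
#' @param topology A `kh_topology`.
#' @param state A `kh_state` from [init_state()].
#' @param nsteps Number of steps.
#' @param integrator [integrator_params()].
#' @param forcefield [kh_forcefield()].
#' @param output_every Frame/energy cadence in steps (0 = no frames).
#' @return A `kh_trajectory`: `frames` (n x 3 x nframes array), `energy`
#'   tibble (step, temp_kinetic, bond, vdw, elec, total, kinetic), final
#'   `state`, and bookkeeping fields.
#' @export
run_dynamics <- function(topology, state, nsteps,
                         integrator = integrator_params(),
                         forcefield = kh_forcefield(),
                         output_every = 1000) {
  sys <- .pack_system(topology, forcefield)
  st <- list(pos = state$pos, vel = state$vel,
             groups = unname(state$groups), step = as.double(state$step))
  out <- cpp_run(sys, st, unclass(integrator), as.integer(nsteps),
                 as.integer(output_every))
  groups <- out$groups
  names(groups) <- names(state$groups)
  new_state <- structure(list(pos = out$pos, vel = out$vel, groups = groups,
                              step = out$step), class = "kh_state")
  el <- out$energy
  colnames(el) <- c("step", "temp_kinetic", "bond", "vdw", "elec", "total",
                    "kinetic")
  structure(list(frames = if (out$nframes > 0) out$frames else
                   array(0, c(nrow(out$pos), 3, 0)),
                 nframes = out$nframes,
                 energy = tibble::as_tibble(as.data.frame(el)),
                 state = new_state, topology = topology,
                 integrator = integrator, output_every = output_every,
                 nrebuild = out$nrebuild, n_close = out$n_close),
            class = "kh_trajectory")
}

#' Run microcanonical (NVE) dynamics
#'
#' Thermostat-off validation mode: velocity-Verlet propagation used for
#' energy-conservation checks.
#'
#' @inheritParams run_dynamics
#' @export
nve_run <- function(topology, state, nsteps,
                    integrator = integrator_params(damping = 0),
                    forcefield = kh_forcefield(), output_every = 1000) {
  integrator$damping <- 0
  run_dynamics(topology, state, nsteps, integrator, forcefield, output_every)
}

#' @export
print.kh_trajectory <- function(x, ...) {
  cat("kh_trajectory:", x$nframes, "frames x", nrow(x$state$pos), "beads |",
      "final step", x$state$step, "\n")
  invisible(x)
}

#' Extract one frame of a trajectory
#'
#' @param trajectory A `kh_trajectory`.
#' @param i Frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
traj_frame <- function(trajectory, i) {
  stopifnot(i >= 1, i <= trajectory$nframes)
  trajectory$frames[, , i]
}

#' Write a trajectory as XYZ
#'
#' @param trajectory A `kh_trajectory`.
#' @param file Output path.
#' @param names Per-bead element labels (default "CA").
#' @export
write_xyz <- function(trajectory, file, names = NULL) {
  n <- nrow(trajectory$state$pos)
  if (is.null(names)) names <- rep("CA", n)
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(trajectory$nframes)) {
    fr <- traj_frame(trajectory, f)
    writeLines(c(as.character(n), paste("frame", f)), con)
    writeLines(sprintf("%s %.4f %.4f %.4f", names, fr[, 1], fr[, 2], fr[, 3]),
               con)
  }
  invisible(file)
}

#' Write topology coordinates (or a trajectory) as PDB
#'
#' Writes C-alpha ATOM records; a trajectory becomes a multi-MODEL file.
#'
#' @param x A `kh_topology` or `kh_trajectory`.
#' @param file Output path.
#' @export
write_calpha_pdb <- function(x, file) {
  topo <- if (inherits(x, "kh_trajectory")) x$topology else x
  b <- topo$beads
  frames <- if (inherits(x, "kh_trajectory")) {
    lapply(seq_len(x$nframes), function(f) traj_frame(x, f))
  } else list(bead_positions(topo))
  aa3 <- ifelse(is.na(b$code), "CAP", bio3d::aa123(b$code))
  con <- file(file, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (f in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL %8d", f), con)
    fr <- frames[[f]]
    writeLines(sprintf(
      "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(b)) %% 100000, aa3, substr(b$chain, 1, 1), b$resnum %% 10000,
      fr[, 1], fr[, 2], fr[, 3]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
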