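# Deterministic synthetic mini-protein fixtures: rigid helical binders with a
# designed attractive interface, rigid cores with flexible tails, and
# filament-like stacks with flexible loops.  All constructions are
# deterministic functions of their arguments (bit-reproducible), and the
# binding-pair dock is found with the shipped pair table itself, so fixtures
# exercise the real force-field path.

#' Ideal alpha-helix C-alpha coordinates
#'
#' Canonical helix: 1.5 Angstrom rise and 100 degrees rotation per residue on
#' a 2.3 Angstrom radius, giving consecutive C-alpha distances of about
#' 3.83 Angstrom.
#'
#' @param sequence 1-letter amino-acid string or character vector (length
#'   >= 4).
#' @return n x 3 coordinate matrix with the sequence as an attribute.
#' @export
make_alpha_helix <- function(sequence) {
  codes <- if (length(sequence) == 1) strsplit(sequence, "")[[1]] else sequence
  n <- length(codes)
  if (n < 4) stop("helix too short: need at least 4 residues")
  i <- seq_len(n) - 1
  ang <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  attr(xyz, "sequence") <- codes
  xyz
}

.struct_df <- function(chain, codes, xyz) {
  tibble::tibble(chain = chain, resnum = seq_along(codes), code = codes,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

.rotz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

.rotx <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

.roty <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# vectorised cross energy (KH + electrostatics) between two coordinate sets,
# given precomputed pair-parameter matrices
.cross_energy_r <- function(pa, pb, epsM, sigM, qqM, params) {
  d <- sqrt(pmax(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb),
                 1e-12))
  sr6 <- (sigM / d)^6
  lj <- 4 * (sr6^2 - sr6)
  rmin <- 2^(1/6) * sigM
  u <- ifelse(epsM < 0, abs(epsM) * lj,
              ifelse(d < rmin, epsM * lj + 2 * epsM, -epsM * lj))
  u[d >= params$lj_cutoff_factor * sigM | epsM == 0] <- 0
  ue <- params$coulomb_constant * qqM / (params$dielectric * d) *
    exp(-d / params$debye_length)
  ue[d >= params$elec_cutoff] <- 0
  sum(u) + sum(ue)
}

#' Synthetic rigid binding pair with a designed interface
#'
#' Two rigid alpha-helices whose facing residues are strongly attractive
#' hydrophobic types (Leu) framed by complementary charges (Glu/Lys) that
#' single out one docking registry.  The bound reference is found by a
#' deterministic grid scan of the docking geometry (axis separation, twist,
#' axial offset) minimising the cross-interface energy evaluated with the
#' shipped pair table.  The initial state has the two helices separated
#' along x, beyond all interaction cutoffs.
#'
#' @param seq_a,seq_b Helix sequences; the defaults put Leu at the five
#'   facing positions and a complementary E/K pair at the helix ends, sized
#'   so the bound state dominates at 180 K while the hottest default rung
#'   (540 K) unbinds.
#' @param box_side Cubic box side, Angstrom.
#' @param separation Initial centre separation, Angstrom.
#' @param mass_scale Mass scaling applied to both rigid bodies (fast
#'   diffusion of fully rigid objects; potential energy unaffected).
#' @param forcefield [kh_forcefield()] used for the dock scan.
#' @return List: `topology` (initial, separated state), `reference`
#'   (`kh_reference` of the bound dock, components "A"/"B"),
#'   `bound_positions`, `dock_energy` (kcal/mol).
#' @export
make_binding_pair <- function(seq_a = "ESSLLSSLMSSLSSKM",
                              seq_b = "KSSLLSSLMSSLSSEM",
                              box_side = 100, separation = 60,
                              mass_scale = 100,
                              forcefield = kh_forcefield()) {
  ca <- strsplit(seq_a, "")[[1]]
  cb <- strsplit(seq_b, "")[[1]]
  ha <- make_alpha_helix(ca)
  hb0 <- make_alpha_helix(cb)
  ha <- sweep(ha, 2, colMeans(ha))
  hb0 <- sweep(hb0, 2, colMeans(hb0))
  tab <- forcefield$table
  params <- forcefield$params
  epsM <- tab$epsilon[ca, cb, drop = FALSE]
  sigM <- tab$sigma[ca, cb, drop = FALSE]
  qqM <- outer(assign_charge(ca), assign_charge(cb))
  best <- list(e = Inf)
  for (phi in seq(150, 210, by = 5))
    for (dx in seq(7, 12, by = 0.25))
      for (dz in seq(-2, 2, by = 0.5)) {
        pb <- hb0 %*% t(.rotz(phi))
        pb[, 1] <- pb[, 1] + dx
        pb[, 3] <- pb[, 3] + dz
        e <- .cross_energy_r(ha, pb, epsM, sigM, qqM, params)
        if (e < best$e) best <- list(e = e, phi = phi, dx = dx, dz = dz)
      }
  # local 6-DOF refinement so the reference sits at the actual energy minimum
  place_b <- function(par) {
    rot <- .rotz(best$phi + par[1]) %*%
      .rotx(par[2]) %*% .roty(par[3])
    pb <- hb0 %*% t(rot)
    sweep(pb, 2, c(best$dx + par[4], par[5], best$dz + par[6]), "+")
  }
  opt <- stats::optim(rep(0, 6), function(par)
    .cross_energy_r(ha, place_b(par), epsM, sigM, qqM, params),
    method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-10))
  pb <- place_b(opt$par)
  best$e <- opt$value
  bound <- rbind(ha, pb)

  d <- sqrt(outer(rowSums(ha^2), rowSums(pb^2), "+") - 2 * ha %*% t(pb))
  if (sum(d <= 10) < 3)
    stop("binding-pair spec yields fewer than 3 interface pairs")

  ctr <- rep(box_side / 2, 3)
  init_a <- sweep(ha, 2, ctr - c(separation / 2, 0, 0), "+")
  init_b <- sweep(pb - matrix(colMeans(pb), nrow(pb), 3, byrow = TRUE), 2,
                  ctr + c(separation / 2, 0, 0), "+")
  df <- dplyr::bind_rows(.struct_df("A", ca, init_a),
                         .struct_df("B", cb, init_b))
  topo <- build_system(df, rigid_spec = list(A = "A", B = "B"),
                       box_side = box_side, params = params)
  topo <- set_mass_scaling(topo, "A", mass_scale)
  topo <- set_mass_scaling(topo, "B", mass_scale)
  reference <- structure(
    list(pos = bound, component = topo$beads$chain), class = "kh_reference")
  list(topology = topo, reference = reference, bound_positions = bound,
       dock_energy = best$e)
}

#' Rigid helical core with a flexible tail
#'
#' A rigid alpha-helix with a flexible bead-spring tail bonded at the
#' junction, mimicking folded domains carrying disordered linkers.
#'
#' @param core_length Rigid helix length (>= 4 residues).
#' @param tail_length Flexible tail length (>= 1).
#' @param tail_seq Tail sequence (default alternating Gly/Ser); recycled to
#'   `tail_length`.
#' @param core_seq Core sequence (default Leu/Ser pattern); recycled.
#' @param box_side Cubic box side, Angstrom.
#' @return A `kh_topology` with one rigid group ("core") and a flexible tail.
#' @export
make_tailed_domain <- function(core_length = 12, tail_length = 10,
                               tail_seq = NULL, core_seq = NULL,
                               box_side = 150) {
  stopifnot(core_length >= 4, tail_length >= 1)
  core <- if (is.null(core_seq)) rep_len(c("L", "S", "S", "A"), core_length)
          else rep_len(strsplit(core_seq, "")[[1]], core_length)
  tail <- if (is.null(tail_seq)) rep_len(c("G", "S"), tail_length)
          else rep_len(strsplit(tail_seq, "")[[1]], tail_length)
  hx <- make_alpha_helix(core)
  top <- hx[core_length, ]
  tail_xyz <- cbind(rep(top[1], tail_length), rep(top[2], tail_length),
                    top[3] + 3.6 * seq_len(tail_length))
  xyz <- rbind(hx, tail_xyz)
  xyz <- sweep(xyz, 2, colMeans(xyz) - box_side / 2, "-")
  df <- .struct_df("A", c(core, tail), xyz)
  build_system(df,
               rigid_spec = list(core = sprintf("A:1-%d", core_length)),
               flexible_spec = sprintf("A:%d-%d", core_length + 1,
                                       core_length + tail_length),
               box_side = box_side)
}

#' Filament-like stack of rigid subunits with flexible loops
#'
#' `n_subunits` copies of a rigid mini-domain stacked on a helix with fixed
#' rise and twist, all placed in ONE rigid group, each carrying one flexible
#' loop bonded at both ends into its subunit (the loop is inserted between
#' the two rigid halves of the chain, like a flexible surface loop in an
#' otherwise rigid subunit).
#'
#' @param n_subunits Number of subunits (>= 2).
#' @param loop_length Flexible loop length per subunit (default 12).
#' @param rise Axial rise per subunit, Angstrom (default 27.5).
#' @param twist Rotation per subunit, degrees (default -166.7).
#' @param box_side Cubic box side, Angstrom.
#' @return A `kh_topology` with one rigid group ("filament") and
#'   `n_subunits * loop_length` flexible beads.
#' @export
make_filament_stub <- function(n_subunits = 8, loop_length = 12,
                               rise = 27.5, twist = -166.7, box_side = 300) {
  stopifnot(n_subunits >= 2, loop_length >= 2)
  sub_seq <- strsplit("LVSKAELTAV", "")[[1]]       # 10 rigid residues
  loop_seq <- rep_len(c("G", "S"), loop_length)
  hx <- make_alpha_helix(sub_seq)
  hx <- sweep(hx, 2, colMeans(hx))
  hx[, 1] <- hx[, 1] + 12                           # radial offset from axis
  p5 <- hx[5, ]; p6 <- hx[6, ]
  mid <- (p5 + p6) / 2
  nhat <- c(mid[1], mid[2], 0)
  nhat <- nhat / sqrt(sum(nhat^2))
  half <- loop_length %/% 2
  loop <- matrix(NA_real_, loop_length, 3)
  for (j in seq_len(half)) loop[j, ] <- p5 + 3.5 * j * nhat
  for (j in (half + 1):loop_length)
    loop[j, ] <- p6 + 3.5 * (loop_length + 1 - j) * nhat
  sub_codes <- c(sub_seq[1:5], loop_seq, sub_seq[6:10])
  sub_xyz <- rbind(hx[1:5, ], loop, hx[6:10, ])
  dfs <- lapply(seq_len(n_subunits), function(s) {
    xyz <- sub_xyz %*% t(.rotz(twist * (s - 1)))
    xyz[, 3] <- xyz[, 3] + rise * (s - 1)
    .struct_df(LETTERS[s], sub_codes, xyz)
  })
  df <- dplyr::bind_rows(dfs)
  ctr <- c(0, 0, rise * (n_subunits - 1) / 2)
  df[, c("x", "y", "z")] <- sweep(as.matrix(df[, c("x", "y", "z")]), 2,
                                  ctr - box_side / 2, "-")
  rigid <- unlist(lapply(seq_len(n_subunits), function(s)
    c(sprintf("%s:1-5", LETTERS[s]),
      sprintf("%s:%d-%d", LETTERS[s], 6 + loop_length, 10 + loop_length))))
  flex <- vapply(seq_len(n_subunits), function(s)
    sprintf("%s:6-%d", LETTERS[s], 5 + loop_length), character(1))
  build_system(df, rigid_spec = list(filament = rigid), flexible_spec = flex,
               box_side = box_side)
}
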