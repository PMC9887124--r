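# Shared builders and independent (pure-R) oracles used across the suite.

kB <- khmd_constants()$kB

# two-bead fully flexible chain with the default backbone spring
flexible_dimer <- function(box = 50) {
  build_system(data.frame(chain = "A", resnum = 1:2, code = "A",
                          x = c(0, 3.81), y = 0, z = 0),
               flexible_spec = "A:1-2", box_side = box)
}

# single flexible bead tethered to a fixed bead at the origin by a spring
# with r0 = 0: an isotropic harmonic trap U = K r^2
harmonic_trap <- function(K = 1, box = 50) {
  topo <- build_system(data.frame(chain = "A", resnum = 1:2, code = "A",
                                  x = c(0, 0.01), y = 0, z = 0),
                       flexible_spec = "A:1-2", box_side = box)
  topo$bonds$r0 <- 0
  topo$bonds$k <- K
  topo$beads$fixed[1] <- TRUE
  topo
}

# random flexible system with minimum spacing, deterministic per seed
random_system <- function(n = 50, box = 40, seed = 1, min_sep = 3) {
  set.seed(seed)
  codes <- sample(residue_params()$code, n, replace = TRUE)
  pos <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    p <- runif(3, 0, box)
    if (k == 0 || min(sqrt(rowSums(sweep(pos[seq_len(k), , drop = FALSE],
                                         2, p)^2))) > min_sep) {
      k <- k + 1
      pos[k, ] <- p
    }
  }
  df <- data.frame(chain = "A", resnum = seq_len(n), code = codes,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3])
  build_system(df, flexible_spec = "A", box_side = box)
}

# independent direct-sum energy oracle: plain R loops over all pairs with
# minimum image, topology exclusions and both cutoffs; no neighbor list
r_energy_oracle <- function(topology, positions, forcefield = kh_forcefield()) {
  b <- topology$beads
  n <- nrow(b)
  L <- if (isTRUE(topology$box$periodic)) topology$box$side else Inf
  tab <- forcefield$table
  p <- forcefield$params
  gid <- rep(NA_character_, n)
  for (g in names(topology$groups)) gid[topology$groups[[g]]$members] <- g
  bonded <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds$i[r]; j <- topology$bonds$j[r]
    bonded[i, j] <- bonded[j, i] <- TRUE
  }
  mind <- function(d) if (is.finite(L)) d - L * round(d / L) else d
  vdw <- 0; elec <- 0; bond <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.na(gid[i]) && !is.na(gid[j]) && gid[i] == gid[j]) next
    if (b$fixed[i] && b$fixed[j]) next
    if (bonded[i, j]) next
    d <- sqrt(sum(mind(positions[i, ] - positions[j, ])^2))
    if (is.na(b$code[i]) || is.na(b$code[j])) {
      sig <- (b$sigma[i] + b$sigma[j]) / 2
      vdw <- vdw + pair_energy(d, topology$cap_eps, sig, p)
    } else {
      vdw <- vdw + pair_energy(d, tab$epsilon[b$code[i], b$code[j]],
                               (b$sigma[i] + b$sigma[j]) / 2, p)
      elec <- elec + electrostatic_energy(d, b$charge[i], b$charge[j], p)
    }
  }
  for (r in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds$i[r]; j <- topology$bonds$j[r]
    d <- sqrt(sum(mind(positions[i, ] - positions[j, ])^2))
    bond <- bond + bond_energy(d, p, r0 = topology$bonds$r0[r],
                               k = topology$bonds$k[r])
  }
  list(bond = bond, vdw = vdw, elec = elec, total = bond + vdw + elec)
}

# independent dRMS implementation (naive loop, no vectorisation)
r_drms_oracle <- function(positions, pairs, box = NULL) {
  acc <- 0
  for (r in seq_len(nrow(pairs))) {
    dv <- positions[pairs$i[r], ] - positions[pairs$j[r], ]
    if (!is.null(box)) dv <- dv - box * round(dv / box)
    acc <- acc + (sqrt(sum(dv^2)) - pairs$ref_dist[r])^2
  }
  sqrt(acc / nrow(pairs))
}

bond_lengths <- function(traj, i = 1, j = 2) {
  sqrt(colSums((traj$frames[i, , ] - traj$frames[j, , ])^2))
}
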