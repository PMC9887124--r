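# Kim-Hummer model A force field at C-alpha resolution: signed LJ-type pair
# potentials scaled from a 20x20 contact-energy matrix, Debye-Hueckel
# electrostatics, and harmonic backbone springs.

#' Force-field parameter set
#'
#' Global constants of the coarse-grained potential.  Defaults follow the
#' Kim-Hummer model A convention: contact energies \eqn{e_{ij}} scale to pair
#' strengths \eqn{\epsilon_{ij} = \lambda (e_{ij} - e_0)}; electrostatics are
#' Debye-Hueckel with a uniform dielectric of 80 and a 10 Angstrom screening
#' length (about 100 mM monovalent salt); LJ-like pair terms truncate at
#' \eqn{3\sigma} and electrostatics at 35 Angstrom; backbone springs have
#' equilibrium length 3.81 Angstrom and spring constant 189 kcal/(mol A^2).
#'
#' @param lambda_scale Dimensionless scale applied to shifted contact energies.
#' @param e0 Contact-energy reference point, kcal/mol.
#' @param dielectric Relative dielectric constant (dimensionless).
#' @param debye_length Electrostatic screening length, Angstrom.
#' @param elec_cutoff Electrostatic truncation distance, Angstrom.
#' @param lj_cutoff_factor LJ truncation in multiples of sigma; must be at
#'   least \eqn{2^{1/6}} so the attractive minimum lies inside the cutoff.
#' @param coulomb_constant Vacuum Coulomb constant, kcal A/(mol e^2).
#' @param bond_r0 Backbone spring equilibrium length, Angstrom.
#' @param bond_k Backbone spring constant, kcal/(mol A^2).
#' @param bond_half_convention If `FALSE` (default) the bond energy is
#'   \eqn{k (r - r_0)^2}, the convention of harmonic bond styles in common MD
#'   engines from which the printed constant is taken; if `TRUE`,
#'   \eqn{\frac{1}{2} k (r - r_0)^2}.
#'
#' @return An object of class `kh_params` (named list).
#' @export
#' @examples
#' p <- kh_params()
#' p$debye_length
kh_params <- function(lambda_scale = 0.159, e0 = -1.36,
                      dielectric = 80, debye_length = 10,
                      elec_cutoff = 35, lj_cutoff_factor = 3,
                      coulomb_constant = .coulomb_k,
                      bond_r0 = 3.81, bond_k = 189,
                      bond_half_convention = FALSE) {
  stopifnot(dielectric > 0, debye_length > 0, elec_cutoff > 0,
            bond_r0 > 0, bond_k > 0, coulomb_constant > 0)
  if (lj_cutoff_factor < 2^(1/6))
    stop("lj_cutoff_factor must be >= 2^(1/6) so the attractive minimum is inside the cutoff")
  structure(list(lambda_scale = lambda_scale, e0 = e0,
                 dielectric = dielectric, debye_length = debye_length,
                 elec_cutoff = elec_cutoff, lj_cutoff_factor = lj_cutoff_factor,
                 coulomb_constant = coulomb_constant,
                 bond_r0 = bond_r0, bond_k = bond_k,
                 bond_half_convention = bond_half_convention),
            class = "kh_params")
}

#' Per-residue bead parameters
#'
#' One bead per residue, carrying its van der Waals diameter (sigma, Angstrom),
#' side-chain-level charge (Asp/Glu -1, Lys/Arg +1, His +0.5, others 0) and
#' residue mass (amu).  Shipped as a plain-text table so it can be replaced.
#'
#' @param file Optional path to a replacement TSV with columns
#'   `code`, `sigma`, `charge`, `mass`.
#' @return A data frame with 20 rows, one per canonical amino acid.
#' @export
residue_params <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "residue_params.tsv", package = "khmd",
                        mustWork = TRUE)
  rp <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("code", "sigma", "charge", "mass") %in% names(rp)))
  if (nrow(rp) != 20 || anyDuplicated(rp$code))
    stop("residue parameter table must contain exactly the 20 canonical residues")
  if (any(rp$sigma <= 0)) stop("sigma values must be positive")
  if (!all(rp$charge %in% c(-1, 0, 0.5, 1)))
    stop("charges must be in {-1, 0, +0.5, +1}")
  rp
}

#' Load a 20x20 contact-energy matrix
#'
#' Reads a symmetric residue-residue contact-energy table (kcal/mol) with a
#' 1-letter-code header row and column.  The shipped default is the
#' Miyazawa-Jernigan upper-half contact-energy matrix.
#'
#' @param file Path to a TSV; default is the shipped matrix.
#' @return Symmetric 20x20 numeric matrix with residue-code dimnames.
#' @export
#' @examples
#' mj <- load_contact_matrix()
#' mj["L", "L"]
load_contact_matrix <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "mj1996_contact_energies.tsv",
                        package = "khmd", mustWork = TRUE)
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  .check_contact_matrix(m)
  m
}

.check_contact_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != 20 || ncol(m) != 20)
    stop("contact matrix must be 20x20 (got ",
         paste(dim(m), collapse = "x"), ")")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(sort(rownames(m)), sort(colnames(m))))
    stop("contact matrix needs matching residue-code dimnames")
  if (max(abs(m - t(m[colnames(m), rownames(m)]))) > 1e-9)
    stop("contact matrix must be symmetric")
  invisible(m)
}

#' Build the scaled pair-potential table
#'
#' Converts a contact-energy matrix \eqn{e_{ij}} into signed pair strengths
#' \eqn{\epsilon_{ij} = \lambda (e_{ij} - e_0)} (negative = attractive) and
#' pair diameters \eqn{\sigma_{ij} = (\sigma_i + \sigma_j)/2}.
#'
#' @param mj_matrix Symmetric 20x20 contact-energy matrix with residue-code
#'   dimnames (see [load_contact_matrix()]).
#' @param params A [kh_params()] object supplying `lambda_scale` and `e0`.
#' @param residues Residue parameter table (see [residue_params()]).
#' @return A `kh_pair_table`: list with `epsilon` and `sigma` 20x20 matrices
#'   (dimnames in `residues$code` order) and the `residues` table.
#' @export
#' @examples
#' tab <- build_pair_table(load_contact_matrix(), kh_params())
#' tab$epsilon["L", "L"]  # strongly attractive
build_pair_table <- function(mj_matrix, params = kh_params(),
                             residues = residue_params()) {
  .check_contact_matrix(mj_matrix)
  if (!all(residues$code %in% rownames(mj_matrix)))
    stop("contact matrix is missing residues: ",
         paste(setdiff(residues$code, rownames(mj_matrix)), collapse = ", "))
  ord <- residues$code
  eps <- params$lambda_scale * (mj_matrix[ord, ord] - params$e0)
  sig <- outer(residues$sigma, residues$sigma, function(a, b) (a + b) / 2)
  dimnames(sig) <- list(ord, ord)
  structure(list(epsilon = eps, sigma = sig, residues = residues),
            class = "kh_pair_table")
}

#' Side-chain-level residue charge
#'
#' @param code Character vector of 1-letter amino-acid codes.
#' @return Numeric charges in elementary units: Asp/Glu -1, Lys/Arg +1,
#'   His +0.5, all others 0.
#' @export
#' @examples
#' assign_charge(c("D", "E", "K", "R", "H", "G"))
assign_charge <- function(code) {
  rp <- residue_params()
  idx <- match(code, rp$code)
  if (anyNA(idx))
    stop("unknown amino-acid code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  rp$charge[idx]
}

#' Nonbonded pair energy (KH form)
#'
#' For an attractive pair (`eps < 0`) this is a plain Lennard-Jones well of
#' depth `|eps|`.  For a repulsive pair (`eps > 0`) the KH repulsive-only
#' form is used: the shifted LJ core below the minimum and the mirrored
#' (sign-flipped) tail beyond it, so the potential decays to zero from above
#' and is continuous at \eqn{2^{1/6}\sigma}.  Both branches truncate to
#' exactly zero at `lj_cutoff_factor * sigma` (plain truncation, no shift).
#'
#' @param r Distance(s), Angstrom; must be positive.
#' @param eps Signed pair strength, kcal/mol (negative = attractive).
#' @param sigma Pair diameter, Angstrom.
#' @param params A [kh_params()] object (supplies the cutoff factor).
#' @return Energy in kcal/mol, vectorised over `r`.
#' @export
#' @examples
#' pair_energy(2^(1/6) * 6.2, eps = -0.5, sigma = 6.2)  # -0.5 at the minimum
pair_energy <- function(r, eps, sigma, params = kh_params()) {
  if (any(r <= 0)) stop("pair_energy: r must be positive")
  sr6 <- (sigma / r)^6
  lj <- 4 * (sr6^2 - sr6)          # unit-eps LJ shape
  rmin <- 2^(1/6) * sigma
  u <- if (eps < 0) {
    abs(eps) * lj
  } else if (eps > 0) {
    ifelse(r < rmin, eps * lj + 2 * eps, -eps * lj)
  } else {
    rep(0, length(r))
  }
  u[r >= params$lj_cutoff_factor * sigma] <- 0
  u
}

#' Nonbonded pair force magnitude
#'
#' Analytic radial force \eqn{-du/dr} of [pair_energy()]; positive values
#' push the beads apart.  Zero at and beyond the cutoff.
#'
#' @inheritParams pair_energy
#' @return Force in kcal/(mol Angstrom), vectorised over `r`.
#' @export
pair_force <- function(r, eps, sigma, params = kh_params()) {
  if (any(r <= 0)) stop("pair_force: r must be positive")
  sr6 <- (sigma / r)^6
  dlj <- (24 * sr6 - 48 * sr6^2) / r   # d(lj)/dr for unit eps
  rmin <- 2^(1/6) * sigma
  f <- if (eps < 0) {
    -abs(eps) * dlj
  } else if (eps > 0) {
    ifelse(r < rmin, -eps * dlj, eps * dlj)
  } else {
    rep(0, length(r))
  }
  f[r >= params$lj_cutoff_factor * sigma] <- 0
  f
}

#' Debye-Hueckel electrostatic pair energy
#'
#' Screened Coulomb interaction
#' \eqn{u = C q_i q_j \exp(-r/\ell_D) / (D r)} truncated to exactly zero at
#' the electrostatic cutoff.
#'
#' @param r Distance(s), Angstrom; must be positive.
#' @param qi,qj Charges, elementary units.
#' @param params A [kh_params()] object.
#' @return Energy in kcal/mol, vectorised over `r`.
#' @export
#' @examples
#' electrostatic_energy(10, 1, 1)  # ~0.153 kcal/mol
electrostatic_energy <- function(r, qi, qj, params = kh_params()) {
  if (any(r <= 0)) stop("electrostatic_energy: r must be positive")
  u <- params$coulomb_constant * qi * qj /
    (params$dielectric * r) * exp(-r / params$debye_length)
  u[r >= params$elec_cutoff] <- 0
  u
}

#' Debye-Hueckel electrostatic force magnitude
#'
#' Analytic \eqn{-du/dr} of [electrostatic_energy()]; zero at and beyond the
#' cutoff.
#'
#' @inheritParams electrostatic_energy
#' @return Force in kcal/(mol Angstrom).
#' @export
electrostatic_force <- function(r, qi, qj, params = kh_params()) {
  if (any(r <= 0)) stop("electrostatic_force: r must be positive")
  pref <- params$coulomb_constant * qi * qj / params$dielectric
  f <- pref * exp(-r / params$debye_length) *
    (1 / r^2 + 1 / (r * params$debye_length))
  f[r >= params$elec_cutoff] <- 0
  f
}

#' Harmonic bond energy
#'
#' By default \eqn{u = k (r - r_0)^2}: the printed spring constant multiplies
#' the squared displacement directly, without the 1/2 factor (the convention
#' of the harmonic bond style in common MD engines).  Set
#' `bond_half_convention = TRUE` in [kh_params()] for the physics-text
#' \eqn{\frac{1}{2} k} form.
#'
#' @param r Distance(s), Angstrom; non-negative.
#' @param params A [kh_params()] object.
#' @param r0,k Optional per-bond overrides of the default spring.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' bond_energy(3.81)  # 0 at the equilibrium length
#' bond_energy(4.81)  # 189 kcal/mol, one Angstrom of stretch
bond_energy <- function(r, params = kh_params(),
                        r0 = params$bond_r0, k = params$bond_k) {
  if (any(r < 0)) stop("bond_energy: r must be non-negative")
  fac <- if (isTRUE(params$bond_half_convention)) 0.5 else 1
  fac * k * (r - r0)^2
}
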