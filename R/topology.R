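# System building: C-alpha structures -> beads, rigid groups, flexible
# segments, bonds, exclusions, plus reference conformations by superposition.

#' Read a C-alpha structure from a PDB file
#'
#' Extracts one bead per residue from its C-alpha atom.  Residues that appear
#' in ATOM records but lack a C-alpha are reported in `$missing`, never
#' silently dropped.  When alternate locations conflict, the first altloc is
#' kept with a warning.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @return A `calpha_structure`: list with `beads` (tibble: chain, resnum,
#'   icode, code, x, y, z) and `missing` (tibble of residues without C-alpha).
#' @export
read_calpha_structure <- function(pdb) {
  if (length(pdb) > 1 || grepl("\n", pdb) ||
      (!file.exists(pdb) && grepl("^ATOM", pdb[1]))) {
    tf <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb, "\n")), tf)
    pdb <- tf
    on.exit(unlink(tf))
  }
  p <- bio3d::read.pdb(pdb)
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found")
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  ca <- at[at$elety == "CA", , drop = FALSE]
  cakey <- paste(ca$chain, ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  if (anyDuplicated(cakey)) {
    warning("alternate locations for some C-alpha atoms; keeping the first")
    ca <- ca[!duplicated(cakey), , drop = FALSE]
    cakey <- cakey[!duplicated(cakey)]
  }
  beads <- tibble::tibble(
    chain = ca$chain, resnum = ca$resno,
    icode = ifelse(is.na(ca$insert), "", ca$insert),
    code = bio3d::aa321(ca$resid),
    x = ca$x, y = ca$y, z = ca$z)
  miss_key <- setdiff(unique(key), cakey)
  miss <- unique(at[match(miss_key, key), c("chain", "resno", "resid")])
  missing <- tibble::tibble(chain = miss$chain, resnum = miss$resno,
                            resid = miss$resid)
  structure(list(beads = beads, missing = missing),
            class = "calpha_structure")
}

# parse "A:3-12" / "A" range selectors into a logical mask over beads
.parse_ranges <- function(ranges, beads) {
  sel <- rep(FALSE, nrow(beads))
  for (r in ranges) {
    parts <- strsplit(r, ":", fixed = TRUE)[[1]]
    ch <- parts[1]
    if (!ch %in% beads$chain) stop("range '", r, "': no such chain '", ch, "'")
    if (length(parts) == 1) {
      sel <- sel | beads$chain == ch
    } else {
      lim <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
      if (length(lim) != 2 || anyNA(lim)) stop("bad range selector: ", r)
      sel <- sel | (beads$chain == ch & beads$resnum >= lim[1] &
                    beads$resnum <= lim[2])
    }
  }
  sel
}

#' Build a simulatable topology from a C-alpha structure
#'
#' Every residue must be assigned either to a named rigid group or to a
#' flexible segment, disjointly.  Bonds are created between consecutive
#' residues of a chain (residue numbers differing by one) unless both belong
#' to the same rigid group, so rigid-flexible junctions and flexible-flexible
#' neighbours are bonded with the default backbone spring.  Interactions
#' internal to a rigid group are excluded, as are bonded (1-2) pairs.
#'
#' @param structure A [read_calpha_structure()] result, or a data frame with
#'   columns chain, resnum, code, x, y, z.
#' @param rigid_spec Named list of range-selector vectors ("A:1-12" or "A"),
#'   one entry per rigid group.
#' @param flexible_spec Character vector of range selectors for flexible
#'   residues.
#' @param box_side Cubic box side, Angstrom.
#' @param periodic Use periodic boundaries with minimum image (default TRUE).
#' @param params [kh_params()] supplying default bond r0 and k.
#' @param residues Residue parameter table ([residue_params()]).
#' @return A `kh_topology`: beads tibble, named `groups` list (members,
#'   mass_scale, fixed), bonds tibble (i, j, r0, k), and box description.
#' @export
build_system <- function(structure, rigid_spec = list(), flexible_spec = character(),
                         box_side = 300, periodic = TRUE,
                         params = kh_params(), residues = residue_params()) {
  beads <- if (inherits(structure, "calpha_structure")) structure$beads
           else tibble::as_tibble(structure)
  stopifnot(all(c("chain", "resnum", "code", "x", "y", "z") %in% names(beads)))
  n <- nrow(beads)
  group_of <- rep(NA_character_, n)
  for (g in names(rigid_spec)) {
    sel <- .parse_ranges(rigid_spec[[g]], beads)
    clash <- sel & !is.na(group_of)
    if (any(clash))
      stop("rigid group '", g, "' overlaps earlier assignment at residues: ",
           paste(utils::head(beads$resnum[clash], 5), collapse = ", "))
    group_of[sel] <- g
  }
  flex <- if (length(flexible_spec)) .parse_ranges(flexible_spec, beads)
          else rep(FALSE, n)
  if (any(flex & !is.na(group_of)))
    stop("flexible spec overlaps rigid groups at residues: ",
         paste(utils::head(beads$resnum[flex & !is.na(group_of)], 5),
               collapse = ", "))
  uncovered <- is.na(group_of) & !flex
  if (any(uncovered))
    stop("residues covered by neither rigid nor flexible spec: ",
         paste(utils::head(paste0(beads$chain[uncovered], ":",
                                  beads$resnum[uncovered]), 8), collapse = ", "))

  idx <- match(beads$code, residues$code)
  if (anyNA(idx))
    stop("unknown residue code(s): ",
         paste(unique(beads$code[is.na(idx)]), collapse = ", "))
  beads$index <- seq_len(n)
  beads$mass <- residues$mass[idx]
  beads$charge <- residues$charge[idx]
  beads$sigma <- residues$sigma[idx]
  beads$group <- group_of
  beads$fixed <- FALSE

  groups <- lapply(names(rigid_spec), function(g) {
    mem <- which(group_of == g)
    if (length(mem) < 3)
      stop("rigid group '", g, "' needs >= 3 members")
    pos <- as.matrix(beads[mem, c("x", "y", "z")])
    sv <- svd(scale(pos, scale = FALSE))$d
    if (sv[2] < 1e-6)
      stop("rigid group '", g, "' is collinear; not orientable")
    list(members = mem, mass_scale = 1, fixed = FALSE)
  })
  names(groups) <- names(rigid_spec)

  bi <- integer(0); bj <- integer(0)
  for (ch in unique(beads$chain)) {
    rows <- which(beads$chain == ch)
    rows <- rows[order(beads$resnum[rows])]
    if (length(rows) < 2) next
    a <- rows[-length(rows)]; b <- rows[-1]
    consec <- beads$resnum[b] - beads$resnum[a] == 1L
    if (any(!consec))
      warning("chain ", ch, ": residue-number gaps; no bonds across gaps")
    same_rigid <- !is.na(group_of[a]) & !is.na(group_of[b]) &
      group_of[a] == group_of[b]
    keep <- consec & !same_rigid
    bi <- c(bi, a[keep]); bj <- c(bj, b[keep])
  }
  bonds <- tibble::tibble(i = bi, j = bj, r0 = params$bond_r0, k = params$bond_k)

  structure(list(beads = beads, groups = groups, bonds = bonds,
                 box = list(side = box_side, periodic = periodic),
                 cap_eps = 1.0),
            class = "kh_topology")
}

#' @export
print.kh_topology <- function(x, ...) {
  cat("kh_topology:", nrow(x$beads), "beads |", length(x$groups),
      "rigid group(s) |", sum(is.na(x$beads$group) & !x$beads$fixed),
      "flexible |", nrow(x$bonds), "bonds | box",
      x$box$side, "A", if (x$box$periodic) "(periodic)" else "(open)", "\n")
  invisible(x)
}

#' Bead coordinates of a topology
#'
#' @param topology A `kh_topology`.
#' @return n x 3 numeric matrix.
#' @export
bead_positions <- function(topology) {
  as.matrix(topology$beads[, c("x", "y", "z")])
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' corresponding points, via SVD of the covariance matrix with a determinant
#' correction so the rotation is never a reflection.
#'
#' @param mobile,target n x 3 coordinate matrices.
#' @param correspondence Optional 2-column integer matrix (mobile row, target
#'   row); default pairs rows 1:1.
#' @return A `kh_transform`: list with `rotation` (3x3, det +1),
#'   `translation` (length 3) and `rmsd` over the correspondence, such that
#'   `mobile %*% t(rotation) + translation` superposes onto `target`.
#' @export
kabsch_superpose <- function(mobile, target, correspondence = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!is.null(correspondence)) {
    mobile <- mobile[correspondence[, 1], , drop = FALSE]
    target <- target[correspondence[, 2], , drop = FALSE]
  }
  if (nrow(mobile) != nrow(target)) stop("correspondence sizes differ")
  if (nrow(mobile) < 3) stop("need >= 3 corresponding points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  Pm <- sweep(mobile, 2, cm); Pt <- sweep(target, 2, ct)
  if (svd(Pm)$d[2] < 1e-8) stop("mobile points are collinear")
  H <- t(Pm) %*% Pt
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.vector(R %*% cm)
  fitted <- mobile %*% t(R) + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "kh_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param x n x 3 matrix.
#' @param transform A `kh_transform` from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(x, transform) {
  as.matrix(x) %*% t(transform$rotation) +
    matrix(transform$translation, nrow(x), 3, byrow = TRUE)
}

#' Build a reference conformation of a complex
#'
#' Composes per-component rigid transforms (e.g. obtained by
#' [kabsch_superpose()] against an experimental complex) into a single
#' reference coordinate set with component labels, as needed for
#' interface-pair selection and dRMS.
#'
#' @param topology A `kh_topology`.
#' @param transforms Named list of `kh_transform` (or NULL entries for
#'   identity), keyed by component label.
#' @param components Per-bead component labels; defaults to the chain id.
#' @return A `kh_reference`: list with `pos` (n x 3) and `component`.
#' @export
make_reference <- function(topology, transforms = list(), components = NULL) {
  pos <- bead_positions(topology)
  if (is.null(components)) components <- topology$beads$chain
  stopifnot(length(components) == nrow(pos))
  for (lab in names(transforms)) {
    sel <- components == lab
    if (!any(sel)) stop("component '", lab, "' not present in topology")
    if (!is.null(transforms[[lab]]))
      pos[sel, ] <- apply_transform(pos[sel, , drop = FALSE], transforms[[lab]])
  }
  structure(list(pos = pos, component = components), class = "kh_reference")
}

#' Add immobile repulsive capping beads
#'
#' Appends extra-large, uncharged, purely repulsive and immobile beads, used
#' to block otherwise sticky surfaces (e.g. the open ends of a filament
#' segment).  They interact with all non-excluded beads through the repulsive
#' KH branch with pair strength `topology$cap_eps`.
#'
#' @param topology A `kh_topology`.
#' @param positions m x 3 matrix of cap positions; empty leaves the topology
#'   unchanged.
#' @param sigma_large Cap bead diameter, Angstrom (> 0).
#' @return The extended `kh_topology`.
#' @export
add_capping_beads <- function(topology, positions, sigma_large) {
  if (sigma_large <= 0) stop("sigma_large must be positive")
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) == 0) return(topology)
  if (any(!is.finite(positions))) stop("cap positions must be finite")
  n0 <- nrow(topology$beads)
  caps <- tibble::tibble(
    chain = "CAP", resnum = seq_len(nrow(positions)), icode = "",
    code = NA_character_, x = positions[, 1], y = positions[, 2],
    z = positions[, 3], index = n0 + seq_len(nrow(positions)),
    mass = 1000, charge = 0, sigma = sigma_large,
    group = NA_character_, fixed = TRUE)
  topology$beads <- dplyr::bind_rows(topology$beads, caps)
  topology
}

#' Scale the dynamical mass of a rigid group
#'
#' Divides the effective mass (and inertia) of a rigid group by `factor` for
#' the dynamics only -- a standard device to speed up the diffusion of fully
#' rigid objects.  The potential energy of any configuration is unaffected,
#' so equilibrium ensemble averages are unchanged.
#'
#' @param topology A `kh_topology`.
#' @param group Rigid-group name.
#' @param factor Positive divisor applied to the group's mass.
#' @return The modified `kh_topology`.
#' @export
set_mass_scaling <- function(topology, group, factor) {
  if (!group %in% names(topology$groups)) stop("unknown group: ", group)
  if (factor <= 0) stop("mass scaling factor must be positive")
  topology$groups[[group]]$mass_scale <- factor
  topology
}
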