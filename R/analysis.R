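# Binding-ensemble analysis: interface-pair dRMS against a reference complex,
# cross-group binding energies, 2D occupancy histograms, cold-rung extraction
# and hotspot summaries.

#' Select interface residue pairs from a reference complex
#'
#' All cross-component pairs whose distance in the reference conformation is
#' within the cutoff (inclusive boundary).  These pairs define the dRMS.
#'
#' @param reference A `kh_reference` ([make_reference()]).
#' @param comp_a,comp_b Component labels (must be disjoint).
#' @param cutoff Interface distance cutoff, Angstrom (default 10).
#' @return A `kh_pairset` tibble: i, j (bead indices), ref_dist.  Empty
#'   selections return zero rows with a warning (dRMS is then undefined).
#' @export
select_interface_pairs <- function(reference, comp_a, comp_b, cutoff = 10) {
  ia <- which(reference$component %in% comp_a)
  ib <- which(reference$component %in% comp_b)
  if (!length(ia) || !length(ib))
    stop("component labels not found in reference")
  if (length(intersect(ia, ib))) stop("components must be disjoint")
  pa <- reference$pos[ia, , drop = FALSE]
  pb <- reference$pos[ib, , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  out <- tibble::tibble(i = ia[hit[, 1]], j = ib[hit[, 2]],
                        ref_dist = d[hit])
  if (nrow(out) == 0)
    warning("no interface pairs within ", cutoff,
            " A; dRMS is undefined for this reference")
  class(out) <- c("kh_pairset", class(out))
  out
}

#' Distance RMS against the reference pair distances
#'
#' \eqn{dRMS = \sqrt{\frac{1}{N}\sum_{pairs}(d_{ij} - d_{ij}^{ref})^2}} --
#' invariant to any rigid motion of the whole frame.
#'
#' @param positions n x 3 frame coordinates (full bead index space of the
#'   pair set).
#' @param pairs A `kh_pairset` from [select_interface_pairs()].
#' @param box Cubic box side for minimum-image pair distances (Angstrom), or
#'   NULL for plain Euclidean distances.  Frames from periodic simulations
#'   should pass the box side, since molecules may associate through a
#'   periodic image.
#' @return dRMS in Angstrom.
#' @export
drms <- function(positions, pairs, box = NULL) {
  if (nrow(pairs) == 0) stop("empty interface pair set: dRMS undefined")
  positions <- as.matrix(positions)
  dv <- positions[pairs$i, , drop = FALSE] - positions[pairs$j, , drop = FALSE]
  if (!is.null(box)) dv <- dv - box * round(dv / box)
  d <- sqrt(rowSums(dv^2))
  sqrt(mean((d - pairs$ref_dist)^2))
}

#' dRMS over the frames of a trajectory or frame array
#'
#' @param frames A `kh_trajectory`, or an n x 3 x nframes array.
#' @param pairs A `kh_pairset`.
#' @param every Compute every `every`-th frame (default 1).
#' @param box Cubic box side for minimum image, or NULL; a `kh_trajectory`
#'   supplies its own periodic box automatically.
#' @return Tibble with frame index and dRMS (Angstrom).
#' @export
drms_series <- function(frames, pairs, every = 1, box = NULL) {
  if (inherits(frames, "kh_trajectory")) {
    if (is.null(box) && isTRUE(frames$topology$box$periodic))
      box <- frames$topology$box$side
    frames <- frames$frames
  }
  nf <- dim(frames)[3]
  idx <- seq(1, nf, by = every)
  tibble::tibble(frame = idx,
                 drms = vapply(idx, function(f) drms(frames[, , f], pairs, box),
                               numeric(1)))
}

#' Nonbonded binding energy between two bead groups
#'
#' Sum of KH pair and screened electrostatic energies over cross pairs only,
#' honouring both cutoffs and topology exclusions.  Additive over partitions
#' of either group, and symmetric in its arguments.
#'
#' @param topology A `kh_topology`.
#' @param positions n x 3 frame coordinates.
#' @param group_a,group_b Bead index vectors, rigid-group names, or chain
#'   ids; must be disjoint.
#' @param forcefield A [kh_forcefield()].
#' @return Tibble with vdw, elec and total (kcal/mol).
#' @export
binding_energy <- function(topology, positions, group_a, group_b,
                           forcefield = kh_forcefield()) {
  ga <- .resolve_beads(topology, group_a)
  gb <- .resolve_beads(topology, group_b)
  if (length(intersect(ga, gb))) stop("groups overlap; binding energy undefined")
  out <- cpp_cross_energy(as.matrix(positions),
                          .pack_system(topology, forcefield),
                          as.integer(ga), as.integer(gb))
  tibble::tibble(vdw = out$vdw, elec = out$elec, total = out$total)
}

.resolve_beads <- function(topology, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  if (all(sel %in% names(topology$groups)))
    return(unlist(lapply(sel, function(g) topology$groups[[g]]$members)))
  if (all(sel %in% topology$beads$chain))
    return(which(topology$beads$chain %in% sel))
  stop("cannot resolve bead selection: ", paste(sel, collapse = ", "))
}

#' 2D occupancy histogram
#'
#' Half-open bins `[origin + k w, origin + (k+1) w)`: samples exactly on a
#' bin edge fall in the upper bin.  Out-of-range samples are counted
#' separately, so in-range counts always sum to the number of in-range
#' samples.
#'
#' @param xs,ys Equal-length numeric samples.
#' @param widths Bin widths c(wx, wy); both positive.
#' @param origin Bin origins c(x0, y0).  Default 0 on both axes; pass
#'   `floor(min(ys)/w)*w` style origins for signed quantities like energies.
#' @param nbins Optional c(nx, ny); default spans the data.
#' @return A `kh_hist2d`: counts matrix plus axis metadata.
#' @export
hist2d <- function(xs, ys, widths, origin = c(0, 0), nbins = NULL) {
  stopifnot(length(xs) == length(ys))
  if (any(widths <= 0)) stop("bin widths must be positive")
  origin <- rep_len(origin, 2)
  kx <- floor((xs - origin[1]) / widths[1])
  ky <- floor((ys - origin[2]) / widths[2])
  if (is.null(nbins)) {
    ok0 <- kx >= 0 & ky >= 0 & is.finite(kx) & is.finite(ky)
    if (!any(ok0)) stop("no samples at or above the histogram origin")
    nbins <- c(max(kx[ok0]) + 1, max(ky[ok0]) + 1)
  }
  ok <- kx >= 0 & kx < nbins[1] & ky >= 0 & ky < nbins[2]
  counts <- matrix(0L, nbins[1], nbins[2])
  if (any(ok)) {
    tab <- table(factor(kx[ok], levels = 0:(nbins[1] - 1)),
                 factor(ky[ok], levels = 0:(nbins[2] - 1)))
    counts <- matrix(as.integer(tab), nbins[1], nbins[2])
  }
  structure(list(counts = counts, widths = widths, origin = origin,
                 n_in = sum(ok), n_out = sum(!ok)),
            class = "kh_hist2d")
}

#' Bin centres of a 2D histogram
#'
#' @param h A `kh_hist2d`.
#' @return List with `x` and `y` centre vectors.
#' @export
hist2d_centers <- function(h) {
  list(x = h$origin[1] + (seq_len(nrow(h$counts)) - 0.5) * h$widths[1],
       y = h$origin[2] + (seq_len(ncol(h$counts)) - 0.5) * h$widths[2])
}

#' Write a histogram as a plain-text grid with axis metadata
#'
#' @param h A `kh_hist2d`.
#' @param file Output path.
#' @export
write_hist2d <- function(h, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# origin %g %g widths %g %g n_in %d n_out %d",
                     h$origin[1], h$origin[2], h$widths[1], h$widths[2],
                     h$n_in, h$n_out), con)
  utils::write.table(h$counts, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Frames recorded at one temperature rung of a REMD run
#'
#' Concatenates, in time order, the frames recorded while any replica
#' occupied the requested rung, keeping replica provenance.
#'
#' @param remd A `kh_remd` from [run_remd()].
#' @param rung Rung index (1 = coldest, the default).
#' @return List with `frames` (n x 3 x nsel array), `provenance` tibble
#'   (sweep, replica, temperature).
#' @export
cold_ensemble <- function(remd, rung = 1) {
  if (rung < 1 || rung > length(remd$ladder)) stop("no such rung")
  target <- remd$ladder[rung]
  hit <- which(remd$frame_temp == target, arr.ind = TRUE)
  hit <- hit[order(hit[, 1]), , drop = FALSE]
  n <- dim(remd$frames)[1]
  frames <- array(NA_real_, c(n, 3, nrow(hit)))
  for (k in seq_len(nrow(hit)))
    frames[, , k] <- remd$frames[, , hit[k, 1], hit[k, 2]]
  list(frames = frames,
       provenance = tibble::tibble(sweep = hit[, 1], replica = hit[, 2],
                                   temperature = target))
}

#' Hotspot summary of a 2D histogram
#'
#' Bins whose occupancy exceeds `threshold` times the maximum bin count,
#' listed with their centres and fractional occupancy (count / in-range
#' samples), sorted by occupancy descending; ties broken by (x, y) bin index.
#'
#' @param h A `kh_hist2d`.
#' @param threshold Fraction of the maximum count (default 0.5).
#' @return Tibble: x, y (bin centres), count, occupancy.
#' @export
hotspot_summary <- function(h, threshold = 0.5) {
  if (sum(h$counts) == 0) stop("empty histogram")
  cmax <- max(h$counts)
  hit <- which(h$counts >= threshold * cmax & h$counts > 0, arr.ind = TRUE)
  ctr <- hist2d_centers(h)
  out <- tibble::tibble(x = ctr$x[hit[, 1]], y = ctr$y[hit[, 2]],
                        count = h$counts[hit],
                        occupancy = h$counts[hit] / h$n_in,
                        .ix = hit[, 1], .iy = hit[, 2])
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$.ix, .data$.iy)
  out$.ix <- NULL; out$.iy <- NULL
  out
}
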