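# one A bead at the origin and one B bead per requested cross distance
toy_reference <- function(dists = c(5, 8, 9.999, 10.001)) {
  pos <- rbind(c(0, 0, 0),
               do.call(rbind, lapply(dists, function(d) c(d, 0, 0))))
  structure(list(pos = pos,
                 component = c("A", rep("B", length(dists)))),
            class = "kh_reference")
}

test_that("interface-pair selection uses an inclusive 10 A cross-component rule", {
  # one A bead against B beads at 5, 8, 9.999, 10.001 A: three pairs survive
  ref <- toy_reference()
  pr <- select_interface_pairs(ref, "A", "B", cutoff = 10)
  expect_equal(nrow(pr), 3)
  expect_true(all(pr$ref_dist <= 10))
  expect_true(any(abs(pr$ref_dist - 9.999) < 1e-9))  # boundary is inclusive-ish
  pr10 <- select_interface_pairs(toy_reference(c(3, 10)), "A", "B")
  expect_equal(nrow(pr10), 2)                        # exactly 10 A included

  # distant components: empty set with a warning
  far <- toy_reference(c(100, 120))
  expect_warning(pr0 <- select_interface_pairs(far, "A", "B"), "undefined")
  expect_equal(nrow(pr0), 0)

  expect_error(select_interface_pairs(ref, "A", "A"), "disjoint")
  expect_error(select_interface_pairs(ref, "A", "Z"), "not found")
})

test_that("dRMS has the root-mean-square form and rigid-motion invariance", {
  ref <- toy_reference(c(5, 8))
  pr <- select_interface_pairs(ref, "A", "B")
  expect_equal(drms(ref$pos, pr), 0)

  # stretch the two pair distances to 6 and 10: sqrt((1 + 4)/2)
  pos <- ref$pos
  pos[2, 1] <- 6
  pos[3, 1] <- 10
  expect_equal(drms(pos, pr), sqrt(2.5), tolerance = 1e-12)

  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- pos %*% t(R) + matrix(c(7, -4, 11), nrow(pos), 3, byrow = TRUE)
  expect_equal(drms(moved, pr), drms(pos, pr), tolerance = 1e-12)

  expect_error(drms(pos, pr[0, ]), "empty")
})

test_that("dRMS matches an independent implementation to 1e-12 on random frames", {
  bp <- make_binding_pair()
  pr <- select_interface_pairs(bp$reference, "A", "B")
  set.seed(31)
  for (rep in 1:20) {
    pos <- bp$reference$pos + matrix(rnorm(nrow(bp$reference$pos) * 3, sd = 3),
                                     ncol = 3)
    expect_equal(drms(pos, pr), r_drms_oracle(pos, pr), tolerance = 1e-12)
    expect_equal(drms(pos, pr, box = 100), r_drms_oracle(pos, pr, box = 100),
                 tolerance = 1e-12)
  }
})

test_that("dRMS grows monotonically as one component is displaced", {
  bp <- make_binding_pair()
  pr <- select_interface_pairs(bp$reference, "A", "B")
  iB <- which(bp$reference$component == "B")
  vals <- vapply(seq(0, 10, by = 0.5), function(s) {
    pos <- bp$reference$pos
    pos[iB, 1] <- pos[iB, 1] + s
    drms(pos, pr)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[1], 0)
})

test_that("binding energy is a symmetric, additive cross-group direct sum", {
  ff <- kh_forcefield()
  df <- data.frame(chain = c("A", "A", "B", "B"), resnum = c(1, 2, 1, 2),
                   code = c("L", "K", "L", "E"),
                   x = c(0, 3.8, 7, 10.8), y = c(0, 0.4, 0.2, 0),
                   z = c(0, 0, 0.3, 0))
  topo <- build_system(df, flexible_spec = c("A", "B"), box_side = 60)
  pos <- bead_positions(topo)

  got <- binding_energy(topo, pos, "A", "B", ff)
  # oracle: only the four cross pairs, direct evaluation
  tab <- ff$table
  cross <- expand.grid(i = 1:2, j = 3:4)
  want <- 0
  for (r in seq_len(nrow(cross))) {
    i <- cross$i[r]; j <- cross$j[r]
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    want <- want +
      pair_energy(d, tab$epsilon[df$code[i], df$code[j]],
                  (topo$beads$sigma[i] + topo$beads$sigma[j]) / 2) +
      electrostatic_energy(d, topo$beads$charge[i], topo$beads$charge[j])
  }
  expect_equal(got$total, want, tolerance = 1e-10)

  expect_equal(binding_energy(topo, pos, "B", "A", ff)$total, got$total,
               tolerance = 1e-12)

  # additive over a partition of group B
  e1 <- binding_energy(topo, pos, c(1, 2), 3, ff)$total
  e2 <- binding_energy(topo, pos, c(1, 2), 4, ff)$total
  expect_equal(e1 + e2, got$total, tolerance = 1e-12)

  # beyond all cutoffs: exactly zero
  pos2 <- pos; pos2[3:4, 1] <- pos2[3:4, 1] + 50
  topo2 <- build_system(df, flexible_spec = c("A", "B"), box_side = 300)
  expect_identical(binding_energy(topo2, pos2, "A", "B", ff)$total, 0)

  expect_error(binding_energy(topo, pos, c(1, 2), c(2, 3), ff), "overlap")
})

test_that("2D histogram uses half-open bins with out-of-range accounting", {
  h1 <- hist2d(3.2, 1.7, widths = c(0.5, 0.5))
  expect_equal(sum(h1$counts), 1)
  expect_equal(h1$counts[7, 4], 1L)   # [3.0,3.5) x [1.5,2.0)

  # samples exactly on an edge fall in the upper bin
  he <- hist2d(c(0.5, 0.5), c(0, 0.5), widths = c(0.5, 0.5), nbins = c(3, 3))
  expect_equal(he$counts[2, 1], 1L)
  expect_equal(he$counts[2, 2], 1L)

  set.seed(37)
  xs <- runif(1000, 0, 10 - 1e-9)
  h <- hist2d(xs, xs, widths = c(0.5, 0.5))
  expect_equal(nrow(h$counts), 20)
  expect_equal(sum(h$counts), 1000)
  expect_equal(h$n_out, 0)

  ho <- hist2d(c(1, -2), c(1, 1), widths = c(0.5, 0.5), nbins = c(4, 4))
  expect_equal(ho$n_out, 1)
  expect_equal(ho$n_in, 1)

  expect_error(hist2d(1, 1, widths = c(0, 0.5)), "positive")
})

test_that("cold-ensemble extraction respects rung temperature and dwell bookkeeping", {
  topo <- flexible_dimer()
  lad <- geometric_ladder(180, 540, 4)
  rx <- run_remd(topo, nsweeps = 40, ladder = lad, exchange_interval = 20,
                 seed = 41)
  expect_equal(rx$ladder[1], 180)

  for (rung in c(1, 4)) {
    ce <- cold_ensemble(rx, rung)
    dw <- dwell_time_distribution(rx)
    expect_equal(dim(ce$frames)[3],
                 sum(dw$dwell[dw$rung == rung]))
    expect_true(all(ce$provenance$temperature == lad[rung]))
    expect_true(!is.unsorted(ce$provenance$sweep))
  }
  expect_error(cold_ensemble(rx, 9), "no such rung")
})

test_that("hotspot summary ranks occupancy with the stated tie-break", {
  h1 <- hist2d(1.2, 3.3, widths = c(0.5, 0.5))
  hs <- hotspot_summary(h1)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$occupancy, 1)

  # two exactly equal peaks: both reported, ordered by bin index
  h2 <- hist2d(c(1.1, 1.1, 5.1, 5.1), c(1.1, 1.1, 5.1, 5.1),
               widths = c(1, 1))
  hs2 <- hotspot_summary(h2, threshold = 0.5)
  expect_equal(nrow(hs2), 2)
  expect_true(hs2$x[1] < hs2$x[2])

  # bimodal 70/30 synthetic sample
  set.seed(43)
  xs <- c(rnorm(7000, 2.5, 0.05), rnorm(3000, 8.5, 0.05))
  h3 <- hist2d(xs, rep(0.5, length(xs)), widths = c(1, 1))
  hs3 <- hotspot_summary(h3, threshold = 0.25)
  expect_equal(nrow(hs3), 2)
  expect_equal(hs3$occupancy[1], 0.7, tolerance = 0.02)
  expect_equal(hs3$occupancy[2], 0.3, tolerance = 0.02)
  expect_error(hotspot_summary(hist2d(numeric(0), numeric(0),
                                      widths = c(1, 1), nbins = c(2, 2))),
               "empty")
})
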