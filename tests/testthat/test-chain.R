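test_that("expanding a walk gives one bead per visit on a linear path", {
  # single forward step: 2 beads, 1 bond, no overlaps
  p <- walk_params(1.15, 2, rc = 300, seed = 1)
  ch <- expand_overlaps(generate_walk(p))
  expect_equal(nrow(ch$positions), 2)
  expect_equal(length(ch$rest_lengths), 1)
  expect_equal(count_overlaps(ch), 0)

  # a star of 7 jump+return pairs expands to 15 linearly connected beads
  star <- generate_walk(walk_params(1.15, 15, rc = 1e5, seed = 1),
                        returns_enabled = FALSE, confine = FALSE)
  star$is_return <- rep(c(FALSE, TRUE), 7)
  star$step_lengths <- rep(star$step_lengths[1], 14)
  pos <- matrix(0, 15, 3)
  tips <- star$positions[2, ] # re-use one jump vector for every branch
  for (k in seq(2, 14, by = 2)) pos[k, ] <- tips
  star$positions <- pos
  star$site_id <- as.integer(c(0, rbind(seq(1, 7), 0)))
  star$site_multiplicity <- c(8L, rep(1L, 7))
  ch <- expand_overlaps(star)
  expect_equal(nrow(ch$positions), 15)
  expect_equal(length(ch$rest_lengths), 14)
  expect_gt(count_overlaps(ch), 0)

  # no returns -> no coincident beads
  w <- generate_walk(walk_params(1.2, 500, rc = 1e5, seed = 2),
                     returns_enabled = FALSE, confine = FALSE)
  ch <- expand_overlaps(w)
  expect_equal(nrow(unique(round(ch$positions, 6))), 500)
})

test_that("overlap counting matches brute force", {
  two <- function(d) make_chain(rbind(c(0,0,0), c(d,0,0)))
  expect_equal(count_overlaps(two(9.8)), 0)   # boundary is non-overlapping
  expect_equal(count_overlaps(two(9.0)), 1)
  # k near-coincident beads -> k(k-1)/2 pairs (brute-force count)
  for (k in c(3, 7, 12)) {
    set.seed(k)
    pos <- matrix(rnorm(3 * k, sd = 0.1), ncol = 3)
    d <- as.matrix(dist(pos))
    brute <- sum(d[upper.tri(d)] < 9.8)
    expect_equal(count_overlaps(make_chain(pos)), brute)
    expect_equal(brute, k * (k - 1) / 2)
  }
  # cross-check the cell list against dist() on a random cloud
  set.seed(11)
  pos <- matrix(runif(3 * 300, 0, 60), ncol = 3)
  d <- as.matrix(dist(pos))
  expect_equal(count_overlaps(make_chain(pos)),
               sum(d[upper.tri(d)] < 9.8))
})

test_that("relaxation resolves all overlaps and preserves the chain", {
  w <- generate_walk(walk_params(1.15, 1000, rc = rc_for_phi(0.16, 1000),
                                 seed = 21))
  set.seed(21)
  ch0 <- expand_overlaps(w)
  expect_gt(count_overlaps(ch0), 0)
  ch <- relax_chain(ch0)
  expect_equal(count_overlaps(ch), 0)
  expect_gte(min_pair_distance_cpp(ch$positions, 2 * ch$ro + 1), 2 * ch$ro)
  # bead count and bond topology conserved
  expect_equal(nrow(ch$positions), nrow(ch0$positions))
  expect_equal(length(bond_lengths(ch)), 999)
  # all beads essentially inside the confinement sphere
  expect_lte(max(sqrt(rowSums(ch$positions^2))), ch$rc + 2 * ch$ro)
  # structure preserved: radius of gyration changes by < 50 %
  expect_lt(abs(radius_of_gyration(ch) / radius_of_gyration(ch0) - 1), 0.5)
})

test_that("relaxation is idempotent on an overlap-free chain", {
  pos <- 30 * as.matrix(expand.grid(0:3, 0:3, 0:3))
  dimnames(pos) <- NULL
  ch <- make_chain(pos, rc = 1e4)
  out <- relax_chain(ch)
  expect_equal(out$relax_iterations, 0)
  expect_identical(out$positions, ch$positions)
})

test_that("zero-temperature relaxation descends the energy", {
  w <- generate_walk(walk_params(1.15, 500, rc = rc_for_phi(0.16, 500),
                                 seed = 31))
  set.seed(31)
  ch <- expand_overlaps(w)
  # small step to stay in the strict-descent regime
  out <- relax_chain(ch, relax_config(gamma = 0.02, max_iter = 60000L,
                                      method = "descent"))
  tr <- out$energy_trace
  expect_gt(length(tr), 10)
  expect_true(all(diff(tr) <= 1e-9 * tr[1]))
})

test_that("crowding stretches bonds at fixed alpha", {
  mean_bond <- function(phi) {
    ch <- sr_ev_chain(1.15, n_beads = 3000, rc = rc_for_phi(phi, 3000),
                      seed = 77)
    mean(bond_lengths(ch))
  }
  lo <- mean_bond(0.08)
  hi <- mean_bond(0.20)
  expect_gt(hi, lo)
})

test_that("volume fraction arithmetic matches the published bead counts", {
  expect_equal(volume_fraction(373483, 4.9, 650), 0.16, tolerance = 1e-5)
  expect_equal(volume_fraction(186741, 4.9, 650), 0.08, tolerance = 1e-5)
  expect_equal(volume_fraction(0), 0)
  expect_equal(beads_for_phi(0.16, 650, 4.9), 373484L, tolerance = 2)
  expect_equal(volume_fraction(5e4, 4.9, rc_for_phi(0.16, 5e4)), 0.16,
               tolerance = 1e-12)
})
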