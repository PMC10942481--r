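test_that("coordination numbers match constructed geometries", {
  # isolated bead
  expect_equal(coordination_numbers(make_chain(rbind(c(0,0,0)))), 0L)
  # pair just inside the coordination radius
  two <- make_chain(rbind(c(0,0,0), c(11.4,0,0)))
  expect_equal(coordination_numbers(two), c(1L, 1L))
  expect_equal(coordination_numbers(make_chain(rbind(c(0,0,0), c(11.6,0,0)))),
               c(0L, 0L))
  # FCC shell at contact distance: the central bead coordinates 12
  fcc <- make_chain(fcc_cluster())
  cn <- coordination_numbers(fcc, radius = 11.5)
  expect_equal(cn[1], 12L)
  # brute-force cross-check on a random cloud
  set.seed(4)
  pos <- matrix(runif(3 * 200, 0, 50), ncol = 3)
  d <- as.matrix(dist(pos)); diag(d) <- Inf
  expect_equal(coordination_numbers(make_chain(pos)),
               as.integer(rowSums(d < 11.5)))
})

test_that("CVC grid counts bead volume per probing cube", {
  # single bead in one cube of a 2x2x2 grid of 120 nm cubes
  ch <- make_chain(rbind(c(60, 60, 60)), rc = 650)
  v <- cvc_grid(ch, cube_edge = 120, grid = 2)
  expect_equal(length(v), 8)
  expect_equal(sum(v > 0), 1)
  expect_equal(max(v), (4 / 3) * pi * 4.9^3 / 120^3)
  # empty cubes are zero
  expect_equal(sum(v == 0), 7)
  # ensemble support: relaxed chain stays within the jamming ballpark
  ch2 <- cached_chain()
  g <- max(1, floor(2 * ch2$rc / (120 * sqrt(3))))
  v2 <- cvc_grid(ch2, cube_edge = 120, grid = g)
  expect_true(all(v2 >= 0 & v2 <= 0.74))
})

test_that("pair correlation is flat for an ideal gas and excluded at core", {
  gas <- uniform_sphere_chain(20000, rc = 200, seed = 8)
  g <- pair_correlation(gas, dr = 4, r_max = 80)
  mid_range <- g$mid > 20
  expect_equal(mean(g$value[mid_range]), 1, tolerance = 0.05)
  # hard-core chain: g = 0 below the contact distance
  ch <- cached_chain()
  g2 <- pair_correlation(ch, dr = 2, r_max = 60)
  expect_true(all(g2$value[g2$mid < 9] == 0))
  expect_gt(max(g2$value[g2$mid > 9 & g2$mid < 14]), 1)  # contact peak
})

test_that("cumulative G integrates g and recovers closed forms", {
  r <- seq(1, 200, by = 1)
  gu <- curve_table(r, rep(1, length(r)), rep(1, length(r)))
  G <- cumulative_G(gu)
  expect_equal(G$value, (4 / 3) * pi * G$mid^3, tolerance = 1e-3)
  expect_true(all(diff(G$value) >= 0))
  # zero below the core -> flat G there
  gz <- curve_table(r, ifelse(r < 9.8, 0, 1), rep(1, length(r)))
  Gz <- cumulative_G(gz)
  expect_true(all(Gz$value[Gz$mid < 9] == 0))
  # exact power law recovery through the fit
  Gp <- curve_table(r, 0.37 * r^2.5, rep(1, length(r)))
  expect_equal(fit_packing_D(Gp, window = c(40, 120)), 2.5, tolerance = 1e-6)
})

test_that("uniform density gives a packing parameter of 3", {
  gas <- uniform_sphere_chain(30000, rc = 400, seed = 9)
  out <- local_D_phi(gas, radius = 240, r_max = 130)
  expect_equal(out$D, 3, tolerance = 0.05)
  expect_equal(out$phi, sum(rowSums(sweep(gas$positions, 2,
    colMeans(gas$positions))^2) <= 240^2) * (4.9 / 240)^3, tolerance = 1e-12)
})

test_that("slab rendering conserves mass and normalises to one", {
  ch <- make_chain(rbind(c(0, 0, 0)), rc = 60)
  img <- render_slab_density(ch, thickness = 100, pixel = 2, half_width = 60,
                             normalize = FALSE)
  expect_equal(sum(img$data), 1, tolerance = 1e-4)      # one bead mass
  expect_equal(dim(img$data), c(60, 60))
  # two beads at the same (x, y): one blob of double mass
  ch2 <- make_chain(rbind(c(0, 0, -10), c(0, 0, 10)), rc = 60)
  img2 <- render_slab_density(ch2, thickness = 100, pixel = 2,
                              half_width = 60, normalize = FALSE)
  expect_equal(sum(img2$data), 2, tolerance = 1e-4)
  expect_equal(img2$data / max(img2$data), img$data / max(img$data),
               tolerance = 1e-9)
  # normalisation
  img3 <- render_slab_density(ch2, thickness = 100, pixel = 2, half_width = 60)
  expect_equal(max(img3$data), 1)
  # beads outside the slab are excluded
  ch4 <- make_chain(rbind(c(0, 0, 0), c(0, 0, 200)), rc = 300)
  img4 <- render_slab_density(ch4, thickness = 100, pixel = 4,
                              half_width = 100, center_z = 0,
                              normalize = FALSE)
  expect_equal(sum(img4$data), 1, tolerance = 1e-4)
})

test_that("volume rendering conserves mass and projects to the slab image", {
  set.seed(11)
  pos <- matrix(rnorm(3 * 50, sd = 30), ncol = 3)
  ch <- make_chain(pos, rc = 120)
  vol <- render_volume(ch, voxel = 4)
  expect_equal(sum(vol$data), 50, tolerance = 0.01 * 50)  # within 1 %
  proj <- apply(vol$data, c(1, 2), sum)
  slab <- render_slab_density(ch, thickness = Inf, pixel = 4,
                              half_width = 120 + 4 * ch$ro, center_z = 0,
                              normalize = FALSE)
  expect_equal(dim(proj), dim(slab$data))
  expect_equal(proj, slab$data, tolerance = 1e-3)
})
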