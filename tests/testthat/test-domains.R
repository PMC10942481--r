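test_that("preprocessing is shape-preserving and bounded", {
  # constant image stays constant (up to rescale)
  flat <- blob_image(cbind(120, 120), 20)
  flat$data[] <- 0.5
  out <- suppressWarnings(preprocess_density(flat))
  expect_true(all(out$data >= 0 & out$data <= 1))
  # a delta spike widens but its peak stays put (symmetric filter)
  spike <- flat
  spike$data[] <- 0
  spike$data[120, 80] <- 1
  out2 <- suppressWarnings(preprocess_density(spike))
  peak <- which(out2$data == max(out2$data), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(peak - c(120, 80))), 6)
  expect_gt(sum(out2$data > 0.5 * max(out2$data)), 1)
})

test_that("domain centers recover isolated blobs", {
  one <- blob_image(cbind(120, 120), 10)
  c1 <- find_domain_centers(suppressWarnings(preprocess_density(one)))
  expect_equal(nrow(c1), 1)
  expect_lt(max(abs(c1 - c(120, 120))), 4)
  two <- blob_image(rbind(c(70, 70), c(170, 170)), 10)
  c2 <- find_domain_centers(suppressWarnings(preprocess_density(two)))
  expect_equal(nrow(c2), 2)
  # flat image has no maxima
  flat <- one
  flat$data[] <- 0.3
  expect_equal(nrow(find_domain_centers(flat)), 0)
})

test_that("translating the image translates the centers", {
  img <- blob_image(rbind(c(80, 100), c(160, 60)), 8)
  shift <- img
  shift$data <- rbind(matrix(0, 20, ncol(img$data)),
                      img$data[1:(nrow(img$data) - 20), ])
  c0 <- find_domain_centers(suppressWarnings(preprocess_density(img)))
  c1 <- find_domain_centers(suppressWarnings(preprocess_density(shift)))
  c0 <- c0[order(c0[, 1]), , drop = FALSE]
  c1 <- c1[order(c1[, 1]), , drop = FALSE]
  expect_equal(nrow(c0), nrow(c1))
  expect_lt(max(abs((c0[, 1] + 20) - c1[, 1])), 3)
  expect_lt(max(abs(c0[, 2] - c1[, 2])), 3)
})

test_that("mass scaling of a uniform field is quadratic in radius", {
  img <- blob_image(cbind(120, 120), 10)
  img$data[] <- 0.7  # uniform density
  M <- mass_scaling_curve(img, c(120, 120), r_max = 100)
  expect_true(all(diff(M$value) >= 0))       # monotone non-decreasing
  slope <- fit_loglog(M, window = c(20, 90))
  expect_equal(slope, 2, tolerance = 0.05)   # M(r) = rho pi r^2
  # absolute level matches the closed form within discretisation error
  k40 <- which.min(abs(M$mid - 40))
  expect_equal(M$value[k40], 0.7 * pi * (40 / img$pixel)^2,
               tolerance = 0.05)
})

test_that("mass-scaling exponent of a blob decays from 2 toward 0", {
  img <- blob_image(cbind(120, 120), 15)
  M <- mass_scaling_curve(img, c(120, 120), r_max = 140)
  h <- 2
  ks <- (h + 1):(nrow(M) - h)
  slope <- (log(M$value[ks + h]) - log(M$value[ks - h])) /
    (log(M$mid[ks + h]) - log(M$mid[ks - h]))
  expect_gt(slope[2], 1.7)                  # core is nearly uniform
  expect_lt(tail(slope, 1), 0.3)            # tail saturates
})

test_that("domain radius fires on the correct stopping criterion", {
  r <- seq(2, 150, by = 2)
  n <- rep(121, length(r))
  flat_cvc <- curve_table(r, rep(0.3, length(r)), n)
  # exact power law with monotone CVC: nothing fires, radius undefined
  M_pow <- curve_table(r, 0.2 * r^2.6, n)
  expect_true(is.na(domain_radius(M_pow, flat_cvc)))
  # power law that flattens past r0: deviation criterion fires just past r0
  r0 <- 80
  M_bend <- curve_table(r, 0.2 * pmin(r, r0)^2.6, n)
  rd <- domain_radius(M_bend, flat_cvc)
  expect_gt(rd, r0 - 2)
  expect_lt(rd, r0 + 16)
  # CVC minimum before the bend wins the minimum rule
  cvc_min <- curve_table(r, 0.3 + 0.001 * (r - 50)^2, n)
  rd2 <- domain_radius(M_bend, cvc_min)
  expect_equal(rd2, 50, tolerance = 2.1)
  expect_lt(rd2, rd)
  # local exponent reaching 3 fires criterion (ii)
  M_steep <- curve_table(r, 0.2 * r^(2 + r / 100), n)
  rd3 <- domain_radius(M_steep, flat_cvc)
  expect_false(is.na(rd3))
})

test_that("the full pipeline finds k domains and recovers their size order", {
  # parabolic density domes: power-law core, so the stopping criteria
  # are well posed; radii must track the seeded dome size
  centers <- rbind(c(75, 75), c(75, 225), c(225, 75), c(225, 225))
  img <- dome_image(centers, rep(45, 4), size = 300)
  dom <- find_domains(img, min_separation = 10, threshold = 0.15)
  expect_equal(nrow(dom), 4)
  # each found center near a seeded dome
  dmin <- apply(dom[, c("x", "y")], 1, function(p)
    min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)))
  expect_lt(max(dmin), 6)
  expect_true(all(dom$radius_nm > 0 & dom$radius_nm <= 300))
  # wider domes give larger recovered radii
  img_wide <- dome_image(centers, rep(70, 4), size = 300)
  dom_wide <- find_domains(img_wide, min_separation = 10, threshold = 0.15)
  expect_equal(nrow(dom_wide), 4)
  expect_gt(mean(dom_wide$radius_nm), mean(dom$radius_nm))
  # pooled statistics
  st <- domain_stats(list(dom, dom_wide))
  expect_equal(st$counts, c(4L, 4L))
  expect_equal(st$mean_radius,
               mean(c(dom$radius_nm, dom_wide$radius_nm)))
})
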