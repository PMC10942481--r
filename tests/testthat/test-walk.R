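test_that("return probability follows the power-law return rule", {
  # u0 = 1 leaves only the 1/alpha factor
  expect_equal(return_probability(1, 1.15), 1 / 1.15, tolerance = 1e-12)
  # direct evaluation: 2^(-1.1)/1.1
  expect_equal(return_probability(2, 1.10), 2^(-1.1) / 1.1, tolerance = 1e-12)
  expect_equal(round(return_probability(2, 1.10), 4), 0.4241)
  # power-law decay limit
  expect_lt(return_probability(1e8, 1.10), 1e-8)
  expect_error(return_probability(0.5, 1.2))
  expect_error(return_probability(2, 1.0))
})

test_that("jump-length sampler matches the analytic law", {
  # closed-form inverse CDF at the bounds and the median
  expect_equal(jump_length_quantile(0, 1.1), 1)
  expect_equal(jump_length_quantile(0.5, 1.10), 2^(1 / 2.1), tolerance = 1e-12)
  set.seed(1)
  u <- sample_jump_length(1e5, alpha = 1.10, u_max = Inf)
  # analytic mean (alpha+1)/alpha = 1.909...; MC error ~ sd/sqrt(n)
  expect_equal(mean(u), 2.1 / 1.1, tolerance = 0.02)
  # KS agreement with the analytic CDF
  ks <- suppressWarnings(ks.test(u, function(q) jump_length_cdf(q, 1.10)))
  expect_gt(ks$p.value, 0.01)
  # truncated draws respect the support
  set.seed(2)
  ut <- sample_jump_length(1e4, alpha = 1.10, u_max = 5)
  expect_true(all(ut >= 1 & ut <= 5))
})

test_that("walk obeys stack discipline and confinement", {
  params <- walk_params(1.15, 5000, rc = 200, seed = 3)
  w <- generate_walk(params)
  expect_equal(nrow(w$positions), 5000)
  expect_false(w$is_return[1])             # first step must be forward
  expect_true(all(w$step_lengths >= 1 & w$step_lengths <= params$u_max))
  # replay kinds against a stack: never pops empty
  depth <- 0
  for (r in w$is_return) {
    depth <- depth + ifelse(r, -1, 1)
    expect_gte(depth, 0)
  }
  # a return exactly reverses the matching forward step (spot check)
  ret1 <- which(w$is_return)[1]
  expect_equal(w$positions[ret1 + 1, ], w$positions[ret1 - 1, ],
               tolerance = 1e-12)
  # confinement: nodes within rc + u_max of the final COM is implied by
  # the generation-time contract; check the far weaker global envelope
  com <- colMeans(w$positions)
  d <- sqrt(rowSums(sweep(w$positions, 2, com)^2))
  expect_lt(max(d) * params$unit_length, params$rc + params$u_max * params$unit_length)
  # site multiplicities account for every bead
  expect_equal(sum(w$site_multiplicity), nrow(w$positions))
})

test_that("walks are deterministic given the seed", {
  p <- walk_params(1.2, 2000, rc = 300, seed = 99)
  w1 <- generate_walk(p)
  w2 <- generate_walk(p)
  expect_identical(w1$positions, w2$positions)
  expect_identical(w1$is_return, w2$is_return)
})

test_that("disabling returns yields a plain random flight", {
  p <- walk_params(1.15, 3000, rc = 1e6, seed = 5)
  w <- generate_walk(p, returns_enabled = FALSE, confine = FALSE)
  expect_false(any(w$is_return))
  expect_true(all(w$site_multiplicity == 1))
  expect_error(return_fraction(structure(list(is_return = logical(0)),
                                         class = "srev_walk")))
  # mean squared end-to-end distance grows linearly in step count
  n <- nrow(w$positions)
  lags <- c(50, 200, 800)
  msd <- vapply(lags, function(L) {
    i <- seq(1, n - L, by = 23)
    mean(rowSums((w$positions[i + L, , drop = FALSE] -
                  w$positions[i, , drop = FALSE])^2))
  }, numeric(1))
  slope <- coef(lm(log(msd) ~ log(lags)))[2]
  expect_equal(unname(slope), 1, tolerance = 0.12)
})

test_that("return fraction counts steps and decreases with alpha", {
  w3 <- list(is_return = c(FALSE, TRUE, FALSE))
  class(w3) <- "srev_walk"
  expect_equal(return_fraction(w3), 1 / 3)
  fr <- vapply(c(1.10, 1.15, 1.20), function(a) {
    return_fraction(generate_walk(walk_params(a, 1e5, rc = 650, seed = 17)))
  }, numeric(1))
  expect_true(all(fr > 0.45 & fr < 0.50))
  expect_true(all(diff(fr) < 0))
})

test_that("parameter validation rejects out-of-contract input", {
  expect_error(walk_params(1.0, 100))
  expect_error(walk_params(1.1, 1))
  expect_error(walk_params(1.1, 100, rc = 5))
  expect_error(walk_params(1.1, 100, u_max = 1))
  expect_error(sample_jump_length(10, alpha = 0.9))
})
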