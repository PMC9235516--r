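test_that("joint_integral evaluates the Beta integral exactly", {
  expect_equal(joint_integral(0, 0), 1)
  expect_equal(joint_integral(1, 1), 1 / 6)
  expect_equal(joint_integral(2, 2), 1 / 30)
  # numeric quadrature cross-check on a grid
  for (a in 0:2) {
    for (b in 0:5) {
      q <- integrate(function(x) x^a * (1 - x)^b, 0, 1)$value
      expect_equal(joint_integral(a, b), q, tolerance = 1e-8)
    }
  }
  expect_error(joint_integral(-1, 0), "non-negative")
})

test_that("charge_pattern encodes the boundary and interior sign patterns", {
  # boundary index: no below clause
  cp <- charge_pattern(-1, 2, 4, 20)
  expect_true(cp$boundary)
  expect_length(cp$below, 0)
  expect_setdiff_empty <- setdiff(cp$above, c(0, 1, 3))
  expect_length(expect_setdiff_empty, 0)
  # interior index joins the below set
  cp2 <- charge_pattern(6, 8, 4, 20)
  expect_false(cp2$boundary)
  expect_equal(cp2$below, 6L)
  expect_false(8 %in% cp2$above)
  expect_error(charge_pattern(8, 8, 4, 20), "legal charging range")
  # pattern probabilities over all legal i sum to Pr[p is a minimizer]
  for (w in 2:5) {
    L <- 20; p <- 9
    tot <- sum(vapply(max(-1, p - w):min(p - 1, L - w - 1),
                      function(i) charge_pattern(i, p, w, L)$prob, numeric(1)))
    expect_equal(tot, 2 / (w + 1))
  }
})

test_that("C reproduces the worked per-shared-k-mer enumerations", {
  iso <- layout_isolated()
  # isolated shared k-mer at w = 2: joint probability 64/120 each, two of them
  expect_equal(expected_intersection(iso$A, iso$B, 2), 2 * 64 / 120)
  adj <- layout_adjacent()
  # shared window neighbour raises it to 14/24
  expect_equal(expected_intersection(adj$A, adj$B, 2), 2 * 14 / 24)
  # layout sensitivity with identical I, U (the crux of the bias):
  expect_false(isTRUE(all.equal(expected_intersection(iso$A, iso$B, 2),
                                expected_intersection(adj$A, adj$B, 2))))
  # empty matching kills every term
  expect_equal(
    expected_intersection(abstract_seq(1:8), abstract_seq(11:18), 3), 0)
})

test_that("C is symmetric and bounded by 2L/(w+1)", {
  set.seed(55)
  for (r in 1:20) {
    pr <- tiny_random_pair(n = 9, L = 7)
    w <- sample(2:3, 1)
    mAB <- expected_intersection(pr$A, pr$B, w)
    mBA <- expected_intersection(pr$B, pr$A, w)
    expect_equal(mAB, mBA, tolerance = 1e-12)
    expect_lte(mAB, 2 * 7 / (w + 1) + 1e-12)
  }
})

test_that("C brackets the exact expected sketch intersection", {
  set.seed(56)
  for (r in 1:30) {
    pr <- tiny_random_pair(n = 8, L = 6)
    w <- sample(2:3, 1)
    C <- expected_intersection(pr$A, pr$B, w)
    e <- exact_expectations(pr$A, pr$B, w)
    expect_lte(C, e$E_I + 1e-9)
    expect_lte(e$E_I, C + 2 + 1e-9)
  }
})

test_that("bias_estimate assembles B = C/(dL - C) - J with its guards", {
  # J = 0 gives B = 0
  b0 <- bias_estimate(abstract_seq(1:40), abstract_seq(101:140), 3)
  expect_equal(b0$B, 0)
  expect_equal(b0$C, 0)
  # padded pair with J > 0 has B < 0
  set.seed(57)
  sp <- sparsely_matched_pair(600, 8, 10, 5)
  br <- bias_estimate(sp$A, sp$B, 5)
  expect_lt(br$B, 0)
  expect_equal(br$U_approx, 4 * 600 / 6 - br$C)
  # warns below the guaranteed regime
  expect_warning(bias_estimate(abstract_seq(1:20), abstract_seq(1:20), 4),
                 "7\\(w\\+1\\)")
  # report round-trips through the tidiers
  td <- generics::tidy(br)
  expect_equal(td$B, br$B)
  expect_equal(nrow(td), 1)
})

test_that("epsilon_bound evaluates 15 w^2 / L^(1/3)", {
  expect_equal(epsilon_bound(2, 1e12), 0.006)
  expect_gt(epsilon_bound(20, 1e4), 1)   # vacuous at practical scales
  expect_true(all(diff(epsilon_bound(2:10, 1e6)) > 0))
  expect_true(all(diff(epsilon_bound(5, 10^(3:9))) < 0))
  expect_equal(epsilon_bound(2, 1e12, constant = 100), 0.04)
})

test_that("sparse-matching ratio and bias bounds evaluate exactly", {
  expect_equal(sparse_ratio_bound(2), 12 / 30)
  expect_equal(sparse_ratio_bound(20), 1938 / 3198)
  expect_equal(round(100 * sparse_ratio_bound(20)), 61)
  expect_equal(sparse_ratio_bound(1e8), 5 / 8, tolerance = 1e-6)
  expect_error(sparse_ratio_bound(1), ">= 2")

  expect_equal(sparse_bias_bound(0, 5), 0)
  expect_equal(sparse_bias_bound(1, 2), -6 / 30)
  expect_error(sparse_bias_bound(1.2, 3), "\\[0, 1\\]")
})

test_that("the bias of sparsely matched pairs obeys its upper bound", {
  set.seed(58)
  for (w in c(2, 5, 10, 20)) {
    for (r in 1:5) {
      sp <- sparsely_matched_pair(40 * (w + 1), 25, 12, w)
      expect_true(is_sparsely_matched(sp$A, sp$B, w))
      br <- suppressWarnings(bias_estimate(sp$A, sp$B, w))
      expect_lte(br$B, sparse_bias_bound(br$J, w) + 1e-9)
    }
  }
})

test_that("harmonic numbers and the gap closed form are exact", {
  expect_equal(harmonic(1), 1)
  expect_equal(harmonic(4) - harmonic(2), 7 / 12)
  h <- sketchbias:::gap_h(10)
  expect_equal(h, 11 * (1 - 2 * (harmonic(20) - harmonic(10))) / 2)
  expect_lt(h, 0)  # negative for w >= 2, which makes B < 0

  g <- gap_layout_bias(232, 43, 15, 10)
  expect_equal(g$L, 9991)
  expect_equal(g$I, 9991 - 233 * 15)
  expect_equal(g$J, g$I / g$U)
  expect_lt(g$B, 0)
  # the quoted instances: ~10% and ~4% relative bias
  expect_equal(100 * g$relative_bias, 9.52, tolerance = 0.01)
  g2 <- gap_layout_bias(100, 100, 15, 10)
  expect_equal(100 * g2$relative_bias, 3.73, tolerance = 0.01)
  expect_error(gap_layout_bias(10, 30, 15, 10), "g > w")
  expect_error(gap_layout_bias(10, 200, 15, 16), "w < k")
})

test_that("gap closed form agrees with the configuration computation", {
  set.seed(59)
  # small instance: construct the layout and run the C machinery on it
  gp <- deterministic_gap_pair(3, 22, 5, w = 3)
  br <- suppressWarnings(bias_estimate(gp$A, gp$B, 3))
  cf <- gap_layout_bias(3, 22, 5, 3)
  expect_equal(br$B, cf$B, tolerance = 0.1)
  expect_equal(br$J, cf$J)
})

test_that("mash divergence conversions invert and agree to first order", {
  k <- 16
  expect_equal(mash_divergence(1, k, "binomial"), 0)
  expect_equal(mash_divergence(1, k, "poisson"), 0)
  expect_equal(mash_divergence(0, k, "binomial"), 1) # sentinel
  # binomial mode inverts the forward map d -> J = t/(2-t), t = (1-d)^k
  d <- seq(0.001, 0.5, by = 0.007)
  t <- (1 - d)^k
  J <- t / (2 - t)
  expect_equal(mash_divergence(J, k, "binomial"), d, tolerance = 1e-12)
  # first-order agreement as divergence -> 0
  dd <- 10^seq(-6, -2, by = 1)
  JJ <- (1 - dd)^k / (2 - (1 - dd)^k)
  ratio <- mash_divergence(JJ, k, "poisson") / mash_divergence(JJ, k, "binomial")
  expect_lt(abs(ratio[1] - 1), 1e-4)
  expect_true(all(abs(ratio - 1) < 0.1))
})
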