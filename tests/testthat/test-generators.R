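test_that("random_duplicate_free honours its postcondition across a grid", {
  set.seed(81)
  grid <- expand.grid(L = c(4, 50, 200), k = c(4, 8, 12))
  for (i in seq_len(nrow(grid))) {
    ks <- random_duplicate_free(grid$L[i], grid$k[i])
    expect_true(ks$duplicate_free)
    expect_equal(ks$L, grid$L[i])
    expect_equal(nchar(ks$source), grid$L[i] + grid$k[i] - 1)
  }
  # L = 4, k = 8: four distinct 8-mers from a length-11 string
  ks <- random_duplicate_free(4, 8)
  expect_equal(nchar(ks$source), 11)
  expect_error(random_duplicate_free(5, 1), "k must be")
  expect_error(random_duplicate_free(300, 4), "exceeds 4\\^k")
})

test_that("dense draws near the 4^k ceiling stay duplicate-free", {
  set.seed(82)
  # ~95% of all 6-mers; handled by the Eulerian-circuit path
  L <- floor(0.95 * 4^6)
  ks <- random_duplicate_free(L, 6)
  expect_true(ks$duplicate_free)
  expect_equal(ks$L, L)
  ks2 <- random_duplicate_free(L, 6, method = "euler")
  expect_true(ks2$duplicate_free)
})

test_that("generators are reproducible under set.seed", {
  set.seed(83); a <- random_duplicate_free(200, 8)
  set.seed(83); b <- random_duplicate_free(200, 8)
  expect_identical(a$source, b$source)
  set.seed(84); p1 <- sparsely_matched_pair(300, 5, 10, 4)
  set.seed(84); p2 <- sparsely_matched_pair(300, 5, 10, 4)
  expect_identical(p1$A$kmers, p2$A$kmers)
  expect_identical(p1$B$kmers, p2$B$kmers)
})

test_that("unrelated_pair sizes L for the target Jaccard and concentrates", {
  set.seed(85)
  expect_equal(unrelated_pair(0.5, 4)$L, 170)  # floor(2*0.5*256/1.5)
  for (r in 1:5) {
    pr <- unrelated_pair(0.9, 8)
    expect_true(pr$A$duplicate_free && pr$B$duplicate_free)
    expect_lt(abs(pr$J - 0.9), 0.01)
  }
  pr <- unrelated_pair(0.9, 8, j_tol = 0.005)
  expect_lte(abs(pr$J - 0.9), 0.005)
  expect_error(unrelated_pair(0, 8), "in \\(0, 1\\]")
})

test_that("related_pair mutates at rate r1 while staying duplicate-free", {
  set.seed(86)
  base <- random_duplicate_free(2000, 12)
  r0 <- related_pair(base, 0)
  expect_identical(r0$B$kmers, base$kmers)
  expect_equal(true_jaccard(r0$A, r0$B), 1)

  r1 <- related_pair(base, 1)
  expect_true(r1$B$duplicate_free)
  expect_lt(true_jaccard(r1$A, r1$B), 0.05)
  expect_gt(r1$n_mutated, 1500)

  # calibration: r1 = 0.01, k = 16, L = 1e4 lands near J = 0.74
  base16 <- random_duplicate_free(10000, 16)
  js <- vapply(1:3, function(i) {
    rp <- related_pair(base16, 0.01)
    expect_true(rp$B$duplicate_free)
    true_jaccard(rp$A, rp$B)
  }, numeric(1))
  expect_lt(abs(mean(js) - 0.74), 0.05)
})

test_that("deterministic_gap_pair realizes the periodic-mutation layout", {
  set.seed(87)
  # single gap at minimal legal spacing
  k <- 6; w <- 3; g <- w + 2 * k + 1
  gp <- deterministic_gap_pair(1, g, k, w = w)
  expect_equal(gp$L, g + k)
  expect_equal(gp$I, gp$L - 2 * k)  # two mutations, k destroyed matches each
  m <- kmer_matching(gp$A, gp$B)
  expect_equal(m$I, gp$I)
  # the matching is identity on the surviving runs
  expect_true(all(m$pairs$p == m$pairs$q))
  # exact Jaccard from the isolation count
  ell <- 3
  gp3 <- deterministic_gap_pair(ell, 25, 7, w = 4)
  expect_equal(gp3$J,
               (gp3$L - (ell + 1) * 7) / (gp3$L + (ell + 1) * 7))
  # mutated nucleotide positions are k - 1 + i g
  expect_equal(gp3$positions, 7 - 1 + (0:3) * 25)
  expect_error(deterministic_gap_pair(2, 10, 6, w = 3), "g > w")
})

test_that("sparsely_matched_pair places exactly n_shared isolated matches", {
  set.seed(88)
  sp <- sparsely_matched_pair(500, 7, 10, 6)
  m <- kmer_matching(sp$A, sp$B)
  expect_equal(m$I, 7)
  expect_equal(sort(m$pairs$p), sort(sp$p))
  expect_true(is_padded(sp$A, sp$B, 6))
  expect_true(is_sparsely_matched(sp$A, sp$B, 6))
  expect_equal(sp$J, 7 / (1000 - 7))
  # n_shared = 0: disjoint spectra, zero Jaccard and zero bias
  sp0 <- sparsely_matched_pair(300, 0, 10, 4)
  expect_equal(true_jaccard(sp0$A, sp0$B), 0)
  b0 <- bias_estimate(sp0$A, sp0$B, 4)
  expect_equal(b0$B, 0)
  expect_error(sparsely_matched_pair(50, 20, 10, 5), "infeasible packing")
})
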