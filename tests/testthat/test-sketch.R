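test_that("minimizer selection follows the argmin-per-window definition", {
  L <- 30
  ks <- abstract_seq(1:L)

  # strictly increasing hashes: the leftmost element is every window's min
  for (w in c(2, 5, 10)) {
    ms <- minimizer_sketch(ks, w, hashes = seq(0.01, 0.99, length.out = L))
    expect_equal(ms$positions, 0:(L - w))
  }

  # strictly decreasing hashes: each window's min is its last element
  ms <- minimizer_sketch(ks, 5, hashes = seq(0.99, 0.01, length.out = L))
  expect_equal(ms$positions, 4:(L - 1))

  # w = 1: every position is its own window
  ms1 <- minimizer_sketch(ks, 1, hashes = runif(L))
  expect_equal(ms1$positions, 0:(L - 1))

  expect_error(minimizer_sketch(abstract_seq(1:3), 5), "fewer than w")
})

test_that("every window of w consecutive positions contains a minimizer", {
  set.seed(101)
  for (r in 1:25) {
    L <- sample(10:60, 1)
    w <- sample(2:min(8, L), 1)
    ms <- minimizer_sketch(abstract_seq(1:L), w, hashes = runif(L))
    sel <- rep(FALSE, L)
    sel[ms$positions + 1] <- TRUE
    covered <- vapply(0:(L - w), function(s) any(sel[(s + 1):(s + w)]),
                      logical(1))
    expect_true(all(covered))
  }
})

test_that("expected minimizer density approaches 2/(w+1)", {
  set.seed(7)
  L <- 10000; w <- 20
  dens <- vapply(1:50, function(i) {
    ms <- minimizer_sketch(abstract_seq(1:L), w, seed = i)
    length(ms$positions) / L
  }, numeric(1))
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 2 / (w + 1)), 3 * se + 1e-4)
})

test_that("a position charges an index iff it is a minimizer, uniquely", {
  set.seed(202)
  for (r in 1:200) {
    L <- 40
    w <- sample(2:6, 1)
    h <- runif(L)
    ms <- minimizer_sketch(abstract_seq(1:L), w, hashes = h)
    sel <- 0:(L - 1) %in% ms$positions
    for (p in 0:(L - 1)) {
      hits <- sketchbias:::charges_all(p, h, w)
      expect_equal(length(hits), as.integer(sel[p + 1]))
      expect_identical(charges(p, h, w),
                       if (length(hits)) hits[1] else NA_integer_)
      if (length(hits)) expect_true(hits[1] >= -1 && hits[1] <= L - w - 1)
    }
  }
})

test_that("charging agrees with a hand-evaluated case", {
  # w = 2, L = 3, hashes (0.2, 0.1, 0.3): p = 1 is the global min, it is a
  # minimizer and charges the boundary index -1
  h <- c(0.2, 0.1, 0.3)
  expect_identical(charges(1, h, 2), -1L)
  expect_identical(length(sketchbias:::charges_all(1, h, 2)), 1L)
  # p = 2 is min of no window
  expect_identical(charges(2, h, 2), NA_integer_)
})

test_that("sketches depend on k-mer content, not sequence identity", {
  set.seed(3)
  km <- sprintf("K%04d", sample(1:500, 40))
  s1 <- minimizer_sketch(kmer_seq(km), 5, seed = 11)
  s2 <- minimizer_sketch(kmer_seq(km), 5, seed = 11)
  expect_identical(s1$positions, s2$positions)
  expect_identical(sort(s1$members), sort(s2$members))
})

test_that("jaccard_estimate hits the trivial endpoints", {
  set.seed(4)
  A <- abstract_seq(1:40)
  expect_equal(jaccard_estimate(A, A, 5, seed = 99), 1)
  B <- abstract_seq(101:140)
  expect_equal(jaccard_estimate(A, B, 5, seed = 99), 0)
  expect_error(jaccard_estimate(A, kmer_seq(c("AAA", "CCC", "GGG")), 2),
               "different k")
})

test_that("sketch_table exposes position, kmer and hash value", {
  ks <- abstract_seq(1:20)
  ms <- minimizer_sketch(ks, 4, seed = 5)
  tab <- sketch_table(ms)
  expect_named(tab, c("position", "kmer", "hash_value"))
  expect_equal(nrow(tab), length(ms$positions))
  expect_identical(tab$kmer, ks$kmers[tab$position + 1])
})
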