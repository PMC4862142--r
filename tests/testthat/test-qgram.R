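test_that("q-gram profiles count overlapping occurrences", {
  p <- qgram_profile("GGAGTCTA", 3)
  expect_equal(sort(names(p)), sort(c("GGA", "GAG", "AGT", "GTC", "TCT", "CTA")))
  expect_true(all(p == 1L))
  expect_false("AAA" %in% names(p))  # zero-count grams are absent from the map
  p2 <- qgram_profile("TTCTAGCG", 3)
  expect_setequal(names(p2), c("TTC", "TCT", "CTA", "TAG", "AGC", "GCG"))
  expect_equal(unname(qgram_profile("AAAA", 2)), 3L)
  expect_length(qgram_profile("ACG", 5), 0L)  # q > length: empty, no error
  expect_error(qgram_profile("ACG", 0), "positive")
})

test_that("profile mass is conserved", {
  set.seed(1)
  for (k in 1:20) {
    s <- random_dna(sample(5:30, 1))
    q <- sample(1:4, 1)
    expect_equal(sum(qgram_profile(s, q)), max(nchar(s) - q + 1L, 0L))
  }
})

test_that("q-gram distance reproduces the worked example and the exhaustive oracle", {
  expect_identical(qgram_distance("GGAGTCTA", "TTCTAGCG", 3), 8L)
  expect_identical(qgram_distance("GGAGTCTA", "GGAGTCTA", 3), 0L)
  set.seed(42)
  for (k in 1:200) {
    x <- random_dna(sample(4:12, 1))
    y <- random_dna(sample(4:12, 1))
    q <- sample(1:4, 1)
    expect_identical(as.integer(qgram_distance(x, y, q)),
                     as.integer(oracle_qgram_distance(x, y, q)))
  }
})

test_that("q-gram distance is a pseudo-metric with the stated bounds", {
  set.seed(7)
  for (k in 1:60) {
    q <- sample(2:3, 1)
    x <- random_dna(sample((q + 1):15, 1))
    y <- random_dna(sample((q + 1):15, 1))
    z <- random_dna(sample((q + 1):15, 1))
    dxy <- qgram_distance(x, y, q)
    expect_gte(dxy, 0)
    expect_identical(dxy, qgram_distance(y, x, q))
    expect_lte(dxy, qgram_distance(x, z, q) + qgram_distance(z, y, q))
    expect_gte(dxy, abs(nchar(x) - nchar(y)))
    expect_lte(dxy, nchar(x) + nchar(y) - 2 * q + 2)
  }
})

test_that("concatenation bound holds on randomized splits", {
  set.seed(8)
  for (k in 1:40) {
    q <- 3
    x1 <- random_dna(sample(q:10, 1)); x2 <- random_dna(sample(q:10, 1))
    y1 <- random_dna(sample(q:10, 1)); y2 <- random_dna(sample(q:10, 1))
    expect_lte(
      qgram_distance(paste0(x1, x2), paste0(y1, y2), q),
      qgram_distance(x1, y1, q) + qgram_distance(x2, y2, q) + 2 * (q - 1))
  }
})

test_that("block partition follows the floor rule", {
  expect_identical(block_partition(8, 2), c(0L, 4L, 8L))
  expect_identical(block_partition(10, 3), c(0L, 3L, 6L, 10L))
  expect_identical(block_partition(7, 1), c(0L, 7L))
  expect_error(block_partition(3, 4), "exceed")
  set.seed(3)
  for (k in 1:20) {
    L <- sample(5:40, 1); b <- sample(1:min(L, 6), 1)
    cuts <- block_partition(L, b)
    sizes <- diff(cuts)
    expect_identical(cuts[1], 0L)
    expect_identical(cuts[b + 1], as.integer(L))
    expect_lte(max(sizes) - min(sizes), 1L)
  }
})

test_that("blockwise distance matches Table-style example and brute force", {
  expect_identical(blockwise_qgram_distance("GGAGTCTA", "TTCTAGCG", 2, 3), 8L)
  set.seed(9)
  for (k in 1:50) {
    q <- sample(2:3, 1)
    beta <- sample(1:4, 1)
    x <- random_dna(sample((beta * q):(beta * q + 20), 1))
    y <- random_dna(sample((beta * q):(beta * q + 20), 1))
    expect_identical(as.integer(blockwise_qgram_distance(x, y, beta, q)),
                     as.integer(oracle_blockwise(x, y, beta, q)))
    if (beta == 1) {
      expect_identical(blockwise_qgram_distance(x, y, 1, q),
                       qgram_distance(x, y, q))
    }
  }
})

test_that("blockwise distance rejects blocks shorter than q", {
  expect_error(blockwise_qgram_distance("ACGTACGT", "ACGTACGTACGT", 4, 3),
               "blocks of x too short")
  expect_error(blockwise_qgram_distance("ACGTACGTACGT", "ACGTACGT", 4, 3),
               "blocks of y too short")
})

test_that("Parikh vectors count letters over an explicit alphabet", {
  expect_identical(parikh_vector("", DNA), c(A = 0L, C = 0L, G = 0L, T = 0L))
  expect_identical(parikh_vector("GAG", DNA), c(A = 1L, C = 0L, G = 2L, T = 0L))
  expect_error(parikh_vector("GAX", DNA), "not in alphabet")
  set.seed(4)
  for (k in 1:10) {
    w <- random_dna(sample(1:30, 1))
    expect_equal(sum(parikh_vector(w, DNA)), nchar(w))
  }
})

test_that("rotation follows the circular-string convention", {
  expect_identical(rotate_seq("GAGTCTA", 0), "GAGTCTA")
  expect_identical(rotate_seq("GAGTCTA", 3), "TCTAGAG")
  s <- "ACGGTT"
  for (r in 0:5) {
    expect_identical(rotate_seq(rotate_seq(s, r), (6 - r) %% 6), s)
  }
})
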