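# The worked pair used throughout: x = GAGTCTA vs y = TCTAGCG, q = 3,
# one block. Its exact rotation-distance profile is 6 4 4 4 6 8 8.

test_that("sliding-window initialisation reproduces the worked states", {
  rs <- rank_qgrams("GAGTCTA", "TCTAGCG", 3)
  st <- csc_init_window(rs, 1)
  # after Step 1: diff = Parikh vector of y' (ranks 1..3 once each,
  # a_y twice, a_x zero) and the accumulator is its total mass
  expect_identical(st$delta0_step1, 5)
  # after Step 2 (window 0 consumed): signed diff and delta_0 = 6
  expect_identical(st$delta0, 6)
  expect_identical(st$diff[, 1L],
                   c(0L, 1L, 0L, -3L, 2L))  # ranks 1,2,3 then a_x, a_y
})

test_that("sliding one window position applies the two rules in order", {
  rs <- rank_qgrams("GAGTCTA", "TCTAGCG", 3)
  st <- csc_init_window(rs, 1)
  for (i in 0:2) st <- csc_slide_window(st, i)
  # state at window start 3: diff(a_x) = -2, diff(a_y) = 2, shared 0
  expect_identical(st$diff[, 1L], c(0L, 0L, 0L, -2L, 2L))
  expect_identical(sum(st$delta_j), 4)
})

test_that("the exact solver reproduces the worked example end to end", {
  fit <- sacsc("GAGTCTA", "TCTAGCG", q = 3, beta = 1)
  expect_equal(fit$delta, c(6, 4, 4, 4, 6, 8, 8))
  expect_identical(fit$best_index, 3L)
  expect_equal(fit$best_distance, 4)
  expect_identical(fit$rotated, "TCTAGAG")
  # naive solver agrees bit-exactly (same tie rule)
  ref <- ncsc("GAGTCTA", "TCTAGCG", q = 3, beta = 1)
  expect_equal(ref$delta, fit$delta)
  expect_identical(ref$best_index, fit$best_index)
})

test_that("saCSC equals nCSC and the per-rotation oracle on random instances", {
  set.seed(31)
  for (k in 1:40) {
    q <- sample(2:3, 1)
    beta <- sample(c(1L, 2L, 4L), 1)
    m <- sample((beta * q + 1):32, 1)
    n <- sample(m:48, 1)
    x <- random_dna(m); y <- random_dna(n)
    if (floor(n / beta) < q) next
    ex <- sacsc(x, y, q, beta)
    nv <- ncsc(x, y, q, beta)
    expect_equal(ex$delta, nv$delta)
    expect_equal(ex$delta, oracle_delta_profile(x, y, beta, q))
    expect_identical(ex$best_index, nv$best_index)
  }
})

test_that("the heuristic never beats the exact optimum and matches it at beta = 1", {
  h <- hcsc("GAGTCTA", "TCTAGCG", q = 3, beta = 1)  # degenerates to a full scan
  expect_identical(h$best_index, 3L)
  expect_equal(h$best_distance, 4)
  set.seed(32)
  n_eq <- 0L
  for (k in 1:50) {
    beta <- sample(c(1L, 2L, 3L), 1)
    q <- 2L
    m <- sample((3 * beta * q):40, 1)
    n <- sample(m:52, 1)
    x <- random_dna(m); y <- random_dna(n)
    hv <- hcsc(x, y, q, beta)
    ev <- sacsc(x, y, q, beta)
    expect_gte(hv$best_distance, ev$best_distance)
    # the heuristic's reported distance is honest
    expect_equal(hv$best_distance,
                 blockwise_qgram_distance(rotate_seq(x, hv$best_index), y, beta, q))
    if (hv$best_distance == ev$best_distance) n_eq <- n_eq + 1L
  }
  expect_gte(n_eq, 1L)  # equality does occur (frequency tracked, not fixed)
})

test_that("delta never drops below the a_y occupancy and is conserved on a full circle", {
  set.seed(33)
  for (k in 1:20) {
    q <- 2L
    m <- sample(6:20, 1)
    x <- random_dna(m); y <- random_dna(sample(m:24, 1))
    rs <- rank_qgrams(x, y, q)
    ay_count <- sum(rs$yr == rs$ay)
    fit <- sacsc(x, y, q, 1)
    expect_true(all(fit$delta >= ay_count))
    # incremental state matches a from-scratch recomputation at each slide
    st <- csc_init_window(rs, 1)
    for (i in 0:(m - 2)) {
      st <- csc_slide_window(st, i)
      expect_identical(sum(abs(st$diff[, 1L])) , as.integer(sum(st$delta_j)))
    }
  }
  # full circle on x == y returns to the initial state
  w <- random_dna(12)
  rs <- rank_qgrams(w, w, 2)
  st0 <- csc_init_window(rs, 1)
  st <- st0
  for (i in 0:(nchar(w) - 1)) st <- csc_slide_window(st, i)
  # window m coincides with window 0 (second copy of w in ww)
  expect_identical(st$diff, st0$diff)
  expect_identical(sum(st$delta_j), st0$delta0)
})

test_that("planted rotations are recovered exactly", {
  set.seed(34)
  for (k in 1:20) {
    m <- sample(10:40, 1)
    x <- random_dna(m)
    r <- sample(0:(m - 1), 1)
    y <- rotate_seq(x, r)
    fit <- sacsc(x, y, q = 3, beta = 1)
    expect_equal(fit$best_distance, 0)
    expect_equal(qgram_distance(rotate_seq(x, fit$best_index), y, 3), 0L)
    # primitive (aperiodic) strings pin the offset itself
    periods <- which(vapply(1:(m - 1), function(p) {
      identical(rotate_seq(x, p), x)
    }, logical(1)))
    if (length(periods) == 0L && sum(fit$delta == 0) == 1L) {
      expect_identical(fit$best_index, as.integer(r))
    }
  }
})

test_that("the front-end dispatches, defaults, and validates", {
  fit <- csc("GAGTCTA", "TCTAGCG", method = "sacsc", q = 3, beta = 1)
  expect_s3_class(fit, "csc")
  expect_identical(fit$best_index, 3L)
  # ell parameterisation: ell = floor(m / beta)
  f2 <- csc("GAGTCTAA", "TCTAGCGA", q = 3, ell = 4)  # beta = 2
  expect_identical(f2$beta, 2L)
  expect_error(csc("GAGTCTA", "TCTAGCG", q = 3, beta = 1, ell = 7), "exactly one")
  expect_error(csc("ACGTACGT", "ACG", q = 2), "swap")
  expect_error(csc("ACGT", "ACGTACGT", q = 4), "smaller than")
  # default parameters follow beta = ceiling(sqrt(m)), q = ceiling(log_sigma(m))
  x <- random_dna(100); y <- random_dna(120)
  f3 <- csc(x, y)
  expect_identical(f3$beta, 10L)
  expect_identical(f3$q, as.integer(ceiling(log(100, 4))))
  expect_output(print(fit), "best rotation index: 3")
  expect_output(summary(fit), "tie")
})
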