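test_that("self-alignment is perfect and a forced deletion costs one gap", {
  a <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(a$similarity, 100)
  expect_equal(a$identity, 100)
  expect_identical(a$gaps, 0L)
  b <- global_align("ACGT", "AGT")
  expect_identical(b$gaps, 1L)
  expect_identical(gsub("-", "", b$aligned[1]), "ACGT")
  expect_identical(gsub("-", "", b$aligned[2]), "AGT")
})

test_that("affine scores equal exhaustive enumeration on tiny pairs", {
  lets <- c("A", "C", "G", "T")
  mat <- matrix(-2, 4, 4, dimnames = list(lets, lets)); diag(mat) <- 3
  par <- align_params(matrix = mat, gap_open = 2.5, gap_extend = 1,
                      endweight = TRUE)
  set.seed(51)
  for (k in 1:15) {
    a <- random_dna(sample(2:6, 1)); b <- random_dna(sample(2:6, 1))
    expect_equal(global_align(a, b, par)$score,
                 oracle_global_score(a, b, mat, 2.5, 1))
  }
})

test_that("scores agree with Biostrings under EMBOSS-default parameters", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(52)
  for (k in 1:15) {
    a <- random_dna(sample(10:80, 1)); b <- random_dna(sample(10:80, 1))
    for (ew in c(TRUE, FALSE)) {
      par <- align_params(matrix = mat, gap_open = 10, gap_extend = 0.5,
                          endweight = ew)
      ref <- Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
        type = if (ew) "global" else "overlap")
      expect_equal(global_align(a, b, par)$score, Biostrings::score(ref))
    }
  }
})

test_that("affine scorer agrees with the non-affine special case and is symmetric", {
  lets <- c("A", "C", "G", "T")
  mat <- matrix(-1, 4, 4, dimnames = list(lets, lets)); diag(mat) <- 2
  # open = 0 makes every gap position cost `extend`: plain linear gaps
  par_lin <- align_params(matrix = mat, gap_open = 0, gap_extend = 1.5,
                          endweight = TRUE)
  set.seed(53)
  for (k in 1:10) {
    a <- random_dna(sample(3:7, 1)); b <- random_dna(sample(3:7, 1))
    expect_equal(global_align(a, b, par_lin)$score,
                 oracle_global_score(a, b, mat, 0, 1.5))
    s_ab <- global_align(a, b)
    s_ba <- global_align(b, a)
    expect_equal(s_ab$similarity, s_ba$similarity)
    expect_equal(s_ab$score, s_ba$score)
  }
})

test_that("bundled matrices parse and match their canonical values", {
  edna <- read_scoring_matrix(system.file("extdata", "EDNAFULL",
                                          package = "circsc"))
  expect_equal(edna["A", "A"], 5)
  expect_equal(edna["A", "T"], -4)
  expect_equal(edna["A", "R"], 1)
  expect_equal(edna["N", "N"], -1)
  expect_equal(edna, t(edna))
  blos <- read_scoring_matrix(system.file("extdata", "EBLOSUM62",
                                          package = "circsc"))
  ref <- local({ data("BLOSUM62", package = "Biostrings", envir = environment())
                 BLOSUM62 })
  expect_equal(blos[rownames(ref), colnames(ref)], ref)
  expect_error(global_align("ACGT", "AC!T"), "absent from scoring matrix")
})

test_that("all-rotations alignment finds planted rotations and dominates rotation 0", {
  set.seed(54)
  x <- random_dna(70)
  r <- 23L
  fit <- cnw(x, rotate_seq(x, r))
  expect_identical(fit$best_index, r)
  expect_equal(fit$alignment$similarity, 100)
  # definitional check: the chosen score dominates every rotation
  y <- random_dna(80)
  fit2 <- cnw(substr(x, 1, 40), y)
  expect_true(all(fit2$score >= fit2$delta))
  expect_gte(fit2$score, fit2$delta[1])  # at least as good as unrotated
})

test_that("the local-alignment anchor recovers clean rotations but can be fooled by repeats", {
  set.seed(55)
  x <- random_dna(90)
  r <- 31L
  fit <- hsw(x, rotate_seq(x, r))
  expect_identical(fit$best_index, r)
  expect_equal(global_align(fit$rotated, rotate_seq(x, r))$similarity, 100)
  # low mutation: anchor lands near the planted rotation
  fam <- simulate_family(alpha = 2, gamma = 200, theta = 0.02, seed = 56)
  x <- fam$rotated[[1]]; y <- fam$rotated[[2]]
  if (nchar(x) > nchar(y)) { tmp <- x; x <- y; y <- tmp }
  h <- hsw(x, y)
  e <- sacsc(x, y, q = 4, beta = 1)
  # the anchor rotation aligns essentially as well as the q-gram one
  # (indices may differ by a few positions when indels shift the arc)
  s_h <- global_align(h$rotated, y)$similarity
  s_e <- global_align(e$rotated, y)$similarity
  expect_gte(s_h, s_e - 2)
  # adversarial repeat: a long duplicated arc can anchor the rotation
  # in the wrong copy, giving a worse alignment than the exact solver
  core <- random_dna(30)
  xa <- paste0(core, random_dna(40), core, random_dna(10))
  ya <- rotate_seq(xa, 55)
  ha <- hsw(xa, ya)
  ca <- cnw(xa, ya)
  expect_lte(global_align(ha$rotated, ya)$similarity,
             ca$alignment$similarity)
})
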