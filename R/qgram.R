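#' q-gram profile of a string
#'
#' Counts the overlapping occurrences of every substring of length `q`
#' ("q-gram") in `s`. The profile is sparse: grams that do not occur are
#' absent from the returned vector, but are conceptually zero.
#'
#' @param s Character scalar (the sequence; case-sensitive, typically
#'   upper-case DNA/RNA/protein).
#' @param q Gram length, a positive integer.
#' @return A named integer vector mapping each occurring q-gram to its
#'   count. If `nchar(s) < q` the profile is empty (length-0 vector).
#'   The counts always sum to `max(nchar(s) - q + 1, 0)`.
#' @examples
#' qgram_profile("GGAGTCTA", 3)
#' @export
qgram_profile <- function(s, q) {
  check_seq(s)
  check_q(q)
  L <- nchar(s)
  if (L < q) {
    return(structure(integer(0), names = character(0)))
  }
  starts <- seq_len(L - q + 1L)
  grams <- substring(s, starts, starts + q - 1L)
  tab <- table(grams)
  structure(as.integer(tab), names = names(tab))
}

#' q-gram distance between two strings
#'
#' The L1 distance between the q-gram profiles of `x` and `y`:
#' \deqn{D_q(x, y) = \sum_v | G_q(x)[v] - G_q(y)[v] |}
#' summed over all grams `v`. This is a pseudo-metric: it is symmetric,
#' satisfies the triangle inequality, and can be 0 for distinct strings
#' with identical profiles.
#'
#' @inheritParams qgram_profile
#' @param x,y Character scalars.
#' @return Non-negative integer distance.
#' @examples
#' qgram_distance("GGAGTCTA", "TTCTAGCG", 3)  # 8
#' @export
qgram_distance <- function(x, y, q) {
  profile_l1(qgram_profile(x, q), qgram_profile(y, q))
}

# L1 distance between two sparse named count vectors.
profile_l1 <- function(gx, gy) {
  keys <- union(names(gx), names(gy))
  if (length(keys) == 0L) return(0L)
  cx <- integer(length(keys))
  cy <- integer(length(keys))
  cx[match(names(gx), keys)] <- gx
  cy[match(names(gy), keys)] <- gy
  sum(abs(cx - cy))
}

#' Even block partition of a length
#'
#' Cut positions splitting a sequence of `length` letters into `beta`
#' contiguous blocks "as evenly as possible": boundary `j` sits at
#' `floor(j * length / beta)`, so block sizes differ by at most one and
#' when `beta` divides `length` all blocks have `length/beta` letters.
#'
#' @param length Sequence length (positive integer).
#' @param beta Number of blocks, `1 <= beta <= length`.
#' @return Integer vector of `beta + 1` 0-based cut positions; block `j`
#'   (1-based) spans 0-based letter positions
#'   `boundaries[j] .. boundaries[j+1] - 1`.
#' @examples
#' block_partition(8, 2)   # 0 4 8
#' block_partition(10, 3)  # 0 3 6 10
#' @export
block_partition <- function(length, beta) {
  if (!is.numeric(length) || length(length) != 1L || length < 1L) {
    stop("`length` must be a positive integer")
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1L || beta != as.integer(beta)) {
    stop("`beta` must be a positive integer")
  }
  if (beta > length) {
    stop("`beta` (", beta, ") must not exceed the sequence length (", length, ")")
  }
  as.integer(floor((0:beta) * length / beta))
}

#' Blockwise q-gram distance
#'
#' The beta-blockwise q-gram distance: both strings are partitioned into
#' `beta` blocks as evenly as possible (independently, by the same floor
#' rule; see [block_partition()]), and the q-gram distances of
#' corresponding block pairs are summed. `beta = 1` recovers the plain
#' q-gram distance. The blockwise form enforces locality: grams must
#' match within the corresponding block, not merely anywhere.
#'
#' Every block of either string must contain at least `q` letters
#' (i.e. `floor(m/beta) >= q` and `floor(n/beta) >= q`); shorter blocks
#' would have empty profiles and silently degrade the measure.
#'
#' @inheritParams qgram_distance
#' @param beta Number of blocks.
#' @return Non-negative integer distance.
#' @examples
#' blockwise_qgram_distance("GGAGTCTA", "TTCTAGCG", beta = 2, q = 3)  # 8
#' @export
blockwise_qgram_distance <- function(x, y, beta, q) {
  check_seq(x); check_seq(y)
  check_q(q)
  m <- nchar(x); n <- nchar(y)
  check_blocks(m, n, beta, q)
  bx <- block_partition(m, beta)
  by <- block_partition(n, beta)
  total <- 0L
  for (j in seq_len(beta)) {
    xb <- substr(x, bx[j] + 1L, bx[j + 1L])
    yb <- substr(y, by[j] + 1L, by[j + 1L])
    total <- total + qgram_distance(xb, yb, q)
  }
  total
}

#' Parikh vector of a string
#'
#' Per-letter occurrence counts of `w` over an explicit alphabet.
#'
#' @param w Character scalar (may be empty).
#' @param alphabet Character vector of single letters.
#' @return Named integer vector, one entry per alphabet letter, summing
#'   to `nchar(w)`.
#' @examples
#' parikh_vector("GAG", c("A", "C", "G", "T"))
#' @export
parikh_vector <- function(w, alphabet) {
  if (!is.character(w) || length(w) != 1L || is.na(w)) {
    stop("`w` must be a character scalar")
  }
  if (any(nchar(alphabet) != 1L)) stop("`alphabet` must contain single letters")
  letters_w <- strsplit(w, "", fixed = TRUE)[[1L]]
  hit <- match(letters_w, alphabet)
  if (anyNA(hit)) {
    stop("letter(s) not in alphabet: ", paste(unique(letters_w[is.na(hit)]), collapse = ", "))
  }
  counts <- tabulate(hit, nbins = length(alphabet))
  structure(as.integer(counts), names = alphabet)
}

# ---- shared validation helpers ----

check_seq <- function(s) {
  nm <- deparse(substitute(s))
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) < 1L) {
    stop("`", nm, "` must be a non-empty character scalar")
  }
  invisible(s)
}

check_q <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || q < 1L || q != as.integer(q)) {
    stop("`q` must be a positive integer")
  }
  invisible(as.integer(q))
}

# Blockwise preconditions: every block of both strings holds >= q letters.
check_blocks <- function(m, n, beta, q) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1L || beta != as.integer(beta)) {
    stop("`beta` must be a positive integer")
  }
  if (floor(m / beta) < q) {
    stop("blocks of x too short: floor(", m, "/", beta, ") = ",
         floor(m / beta), " < q = ", q)
  }
  if (floor(n / beta) < q) {
    stop("blocks of y too short: floor(", n, "/", beta, ") = ",
         floor(n / beta), " < q = ", q)
  }
  invisible(TRUE)
}

#' Rotate a sequence
#'
#' The `i`th rotation of `s`: `s[i..m-1] s[0..i-1]` with a 0-based
#' offset, so `rotate_seq(s, 0)` is `s` itself.
#'
#' @param s Character scalar.
#' @param i Rotation offset, `0 <= i < nchar(s)` (reduced mod length).
#' @return The rotated string.
#' @examples
#' rotate_seq("GAGTCTA", 3)  # "TCTAGAG"
#' @export
rotate_seq <- function(s, i) {
  check_seq(s)
  m <- nchar(s)
  i <- as.integer(i %% m)
  if (i == 0L) return(s)
  paste0(substr(s, i + 1L, m), substr(s, 1L, i))
}
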