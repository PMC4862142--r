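# Independent brute-force oracles used across the suite. These never
# call the code paths they check.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n, alphabet = DNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# q-gram distance by explicit summation over every gram of Sigma^q.
oracle_qgram_distance <- function(x, y, q, alphabet = DNA) {
  grams <- apply(do.call(expand.grid, rep(list(alphabet), q)), 1L,
                 paste, collapse = "")
  count_in <- function(s) {
    L <- nchar(s)
    if (L < q) return(integer(length(grams)))
    starts <- seq_len(L - q + 1L)
    occ <- substring(s, starts, starts + q - 1L)
    tabulate(match(occ, grams), nbins = length(grams))
  }
  sum(abs(count_in(x) - count_in(y)))
}

# Blockwise distance from explicitly constructed block substrings.
oracle_blockwise <- function(x, y, beta, q, alphabet = DNA) {
  cuts <- function(L) floor((0:beta) * L / beta)
  bx <- cuts(nchar(x)); by <- cuts(nchar(y))
  total <- 0L
  for (j in seq_len(beta)) {
    total <- total + oracle_qgram_distance(
      substr(x, bx[j] + 1L, bx[j + 1L]),
      substr(y, by[j] + 1L, by[j + 1L]), q, alphabet)
  }
  total
}

# Full rotation-distance profile, one explicit rotation at a time.
oracle_delta_profile <- function(x, y, beta, q, alphabet = DNA) {
  m <- nchar(x)
  vapply(0:(m - 1L), function(i) {
    xi <- paste0(substr(x, i + 1L, m), substr(x, 1L, i))
    oracle_blockwise(xi, y, beta, q, alphabet)
  }, numeric(1))
}

# Suffix array by explicit sort of suffix strings.
oracle_suffix_array <- function(z) {
  n <- nchar(z)
  sufs <- substring(z, seq_len(n), n)
  order(sufs, method = "radix") - 1L
}

oracle_lcp <- function(z, sa) {
  n <- nchar(z)
  lets <- strsplit(z, "", fixed = TRUE)[[1L]]
  lcp <- integer(n)
  for (r in 2:n) {
    a <- lets[(sa[r - 1L] + 1L):n]
    b <- lets[(sa[r] + 1L):n]
    k <- 0L
    while (k < length(a) && k < length(b) && a[k + 1L] == b[k + 1L]) k <- k + 1L
    lcp[r] <- k
  }
  lcp
}

# Optimal global alignment score by exhaustive recursion (tiny inputs
# only); affine gap of length L costs open + L * extend, end gaps
# charged.
oracle_global_score <- function(a, b, sub, open, extend) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- -Inf
  rec <- function(i, j, state, acc) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, acc); return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1L, j + 1L, 0L, acc + sub[av[i], bv[j]])
    }
    if (i <= length(av)) {
      rec(i + 1L, j, 1L, acc - (if (state == 1L) extend else open + extend))
    }
    if (j <= length(bv)) {
      rec(i, j + 1L, 2L, acc - (if (state == 2L) extend else open + extend))
    }
  }
  rec(1L, 1L, -1L, 0)
  best
}
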