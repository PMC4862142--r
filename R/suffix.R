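#' Suffix array, inverse, and LCP array of a string
#'
#' Builds the lexicographic suffix array `SA` (0-based starting
#' positions), its inverse `iSA`, and the longest-common-prefix array
#' `LCP` (`LCP[r]` = lcp of the suffixes at sorted ranks `r-1` and `r`,
#' with `LCP[0] = 0`). Construction is by prefix doubling
#' (O(n log n), vectorised) followed by Kasai's O(n) LCP scan.
#'
#' @param z Character scalar, length >= 1.
#' @return A list of class `suffix_structures` with components `text`,
#'   `SA`, `iSA`, `LCP` (all arrays 0-based in value; `SA`/`iSA`/`LCP`
#'   are plain integer vectors indexed 1..n in R).
#' @examples
#' suffix_structures("AAA")  # SA = 2 1 0, LCP = 0 1 2
#' @export
suffix_structures <- function(z) {
  check_seq(z)
  codes <- utf8ToInt(z)
  n <- length(codes)
  rk <- match(codes, sort(unique(codes)))
  if (n > 1L) {
    k <- 1L
    while (max(rk) < n) {
      second <- c(rk[-seq_len(min(k, n))], rep.int(0L, min(k, n)))
      o <- order(rk, second, method = "radix")
      newr <- integer(n)
      changed <- c(TRUE, rk[o[-1L]] != rk[o[-n]] | second[o[-1L]] != second[o[-n]])
      newr[o] <- cumsum(changed)
      rk <- newr
      k <- k * 2L
    }
  }
  sa <- integer(n)
  sa[rk] <- seq_len(n) - 1L   # 0-based positions in rank order
  lcp <- kasai_lcp(codes, sa, rk)
  structure(
    list(text = z, SA = sa, iSA = rk - 1L, LCP = lcp),
    class = "suffix_structures"
  )
}

# Kasai's algorithm; codes integer letters, sa 0-based, rk 1-based inverse.
kasai_lcp <- function(codes, sa, rk) {
  n <- length(codes)
  lcp <- integer(n)
  h <- 0L
  for (i in 0:(n - 1L)) {
    r <- rk[i + 1L]              # 1-based rank of suffix i
    if (r > 1L) {
      j <- sa[r - 1L]            # previous suffix in sorted order
      while (i + h < n && j + h < n && codes[i + h + 1L] == codes[j + h + 1L]) {
        h <- h + 1L
      }
      lcp[r] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

#' q-gram rank reduction of a sequence pair
#'
#' Substrate of the exact rotation search: builds the suffix array of
#' the concatenation `xxy` and assigns a rank to the q-length prefix of
#' every suffix of length at least `q`, so that equal q-grams (detected
#' through LCP >= q between adjacent sorted suffixes) share a rank.
#' The grams of `xx` (positions 0..2m-q) become the integer string `xr`
#' and the grams of `y` become `yr`; grams that straddle the xx/y
#' junction are never read. Ranks are then renumbered: grams occurring
#' in both `xx` and `y` get 1..sigma in lexicographic order, grams
#' private to `xx` collapse to the sentinel rank `ax = sigma + 1`, and
#' grams private to `y` collapse to `ay = sigma + 2`. The reduced
#' alphabet therefore has at most `min(n - q + 1, m) + 2 <= m + 2`
#' distinct values.
#'
#' @param x,y Character scalars with `q < nchar(x)` and
#'   `nchar(x) <= nchar(y)`.
#' @param q Gram length.
#' @return A list of class `rank_strings` with components `xr` (length
#'   `2m - q + 1`), `yr` (length `n - q + 1`), `ax`, `ay`, `sigma`.
#' @examples
#' rank_qgrams("GAGTCTA", "TCTAGCG", 3)
#' @export
rank_qgrams <- function(x, y, q) {
  check_seq(x); check_seq(y)
  q <- check_q(q)
  m <- nchar(x); n <- nchar(y)
  if (q >= m) stop("`q` must be smaller than nchar(x)")
  if (m > n) stop("require nchar(x) <= nchar(y)")
  z <- paste0(x, x, y)
  ss <- suffix_structures(z)
  N <- 2L * m + n

  # Raw rank per eligible suffix (length >= q), walking the SA in order.
  # The lcp between consecutive *eligible* suffixes is the min of the
  # LCP entries spanning any skipped short suffixes.
  raw <- rep.int(NA_integer_, N)
  cur <- 0L
  pending_min <- Inf
  for (r in seq_len(N)) {
    pending_min <- min(pending_min, ss$LCP[r])
    pos <- ss$SA[r]
    if (N - pos >= q) {
      if (cur == 0L || pending_min < q) cur <- cur + 1L
      raw[pos + 1L] <- cur
      pending_min <- Inf
    }
  }

  xr_raw <- raw[seq_len(2L * m - q + 1L)]
  yr_raw <- raw[(2L * m + 1L):(2L * m + n - q + 1L)]

  shared <- sort(intersect(unique(xr_raw), unique(yr_raw)))
  sigma <- length(shared)
  ax <- sigma + 1L
  ay <- sigma + 2L
  xr <- match(xr_raw, shared)
  xr[is.na(xr)] <- ax
  yr <- match(yr_raw, shared)
  yr[is.na(yr)] <- ay

  structure(
    list(xr = xr, yr = yr, ax = ax, ay = ay, sigma = sigma, m = m, n = n, q = q),
    class = "rank_strings"
  )
}
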