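#' Build dollar-padded end-block strings for refinement
#'
#' For pad length `L`, the padded string is
#' `prefix_L + "$"^L + suffix_L`: the first `L` letters of the
#' sequence, then `L` copies of the neutral pad letter `$` (not in the
#' sequence alphabet), then the last `L` letters. Rotating the padded
#' form of `x^i` against the padded form of `y` moves material across
#' the original junction while the neutral pad absorbs the middle.
#'
#' @param xi Character scalar (typically the rotation `x^i` reported by
#'   [sacsc()]).
#' @param y Character scalar; padded with the same `L` (error if
#'   `nchar(y) < 2L`).
#' @param L Pad length (`L = floor(p * m / beta)` in [sacscr()]).
#' @return List with `x2`, `y2` (both of length `3L`) and `L`.
#' @export
build_padded <- function(xi, y, L) {
  check_seq(xi); check_seq(y)
  m <- nchar(xi); n <- nchar(y)
  if (L < 1L) stop("`L` must be >= 1")
  if (2L * L > m) stop("pad length L = ", L, " too large for nchar(x) = ", m)
  if (2L * L > n) stop("pad length L = ", L, " too large for nchar(y) = ", n)
  if (grepl("$", xi, fixed = TRUE) || grepl("$", y, fixed = TRUE)) {
    stop("sequences must not contain the pad letter '$'")
  }
  pad <- strrep("$", L)
  list(
    x2 = paste0(substr(xi, 1L, L), pad, substr(xi, m - L + 1L, m)),
    y2 = paste0(substr(y, 1L, L), pad, substr(y, n - L + 1L, n)),
    L = as.integer(L)
  )
}

#' Scan rotations of a padded string against another
#'
#' Every rotation of `x2` that does not start with the pad letter `$`
#' is globally aligned against `y2` under a pad-neutral scoring scheme
#' (defaults: match +1, mismatch -1, each gap position -1, any column
#' involving `$` scores 0). Rotations starting in the prefix region
#' (`r < L`) correspond to forward shifts `s = r`; rotations starting
#' in the suffix region (`r >= 2L`) to backward shifts `s = r - 3L`.
#' The scan runs over `s = 0..L-1` then `s = -L..-1` and keeps the
#' first maximum, so ties favour the smallest forward shift (and no
#' shift at all).
#'
#' @param x2,y2 Padded strings from [build_padded()].
#' @param match,mismatch,gap Scoring constants (signs as stated; `gap`
#'   is the per-position linear gap penalty).
#' @return List with `shift` (signed), `score`, and `scores` (named by
#'   signed shift).
#' @export
scan_rotations <- function(x2, y2, match = 1, mismatch = -1, gap = 1) {
  L <- nchar(x2) / 3L
  if (L != as.integer(L)) stop("`x2` length must be 3L")
  L <- as.integer(L)
  lets <- sort(unique(strsplit(paste0(x2, y2), "", fixed = TRUE)[[1L]]))
  lets <- setdiff(lets, "$")
  mat <- matrix(mismatch, length(lets), length(lets), dimnames = list(lets, lets))
  diag(mat) <- match
  par <- align_params(matrix = mat, gap_open = 0, gap_extend = gap,
                      endweight = TRUE)
  offsets <- c(0:(L - 1L), (2L * L):(3L * L - 1L))
  shifts <- ifelse(offsets < L, offsets, offsets - 3L * L)
  scores <- vapply(offsets, function(r) {
    global_align_score(rotate_seq(x2, r), y2, par, dollar = "$")
  }, numeric(1))
  best <- which.max(scores)  # first max in scan order
  list(shift = as.integer(shifts[best]), score = scores[best],
       scores = stats::setNames(scores, shifts))
}

#' Exact rotation search with alignment-based refinement
#'
#' Runs [sacsc()] and then polishes the reported rotation: the first
#' and last `p` blocks of the rotated string and of `y` are extracted,
#' joined by a run of `L = floor(p * m / beta)` neutral `$` letters
#' ([build_padded()]), and the padded strings are rotation-scanned
#' under a pad-neutral global alignment ([scan_rotations()]). The
#' winning signed shift `s` (always `|s| < L`) gives the refined
#' rotation `i' = (i + s) mod m`. `p = 0` disables refinement and
#' reproduces [sacsc()] exactly.
#'
#' @inheritParams ncsc
#' @param p Number of end blocks to refine over, `0 <= p <= beta / 3`.
#' @param align Unused by the q-gram stage; kept so [csc()] can pass
#'   a single parameter set through (the refinement uses its own
#'   pad-neutral scoring per the scheme above).
#' @return A `"csc"` object; `best_index` is the refined index,
#'   `best_distance` its blockwise q-gram distance (read off the exact
#'   delta profile), and `refinement` records the unrefined index, the
#'   shift, and the scan score.
#' @export
sacscr <- function(x, y, q, beta, p = 1L, align = align_params()) {
  if (!is.numeric(p) || length(p) != 1L || p < 0L || p != as.integer(p)) {
    stop("`p` must be a non-negative integer")
  }
  base <- sacsc(x, y, q, beta)
  if (p == 0L) {
    base$method <- "sacscr"
    return(base)
  }
  if (p > beta / 3) stop("require p <= beta/3 (p = ", p, ", beta = ", beta, ")")
  m <- nchar(x)
  L <- as.integer(floor(p * m / beta))
  pads <- build_padded(base$rotated, y, L)
  scan <- scan_rotations(pads$x2, pads$y2)
  i2 <- (base$best_index + scan$shift) %% m
  new_csc(x, y, "sacscr", q, beta, i2,
          delta = base$delta,
          best_distance = base$delta[i2 + 1L],
          extra = list(refinement = list(
            unrefined_index = base$best_index,
            unrefined_distance = base$best_distance,
            shift = scan$shift, L = L, p = as.integer(p),
            scan_score = scan$score
          )))
}
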