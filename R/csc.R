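#' Circular sequence comparison under the blockwise q-gram distance
#'
#' Finds the rotation `x^i` of `x` minimising the beta-blockwise q-gram
#' distance to `y` (or, for the alignment baselines, maximising global
#' alignment score). This is the package front-end; the individual
#' solvers are also exported ([ncsc()], [hcsc()], [sacsc()],
#' [sacscr()], [cnw()], [hsw()]).
#'
#' Methods:
#' \describe{
#'   \item{`sacsc`}{Exact suffix-array sliding-window algorithm,
#'     O(beta*m + n) time and space. Default.}
#'   \item{`ncsc`}{Naive exact algorithm, O(m(m+n)); same answer as
#'     `sacsc`, kept as a cross-check and reference.}
#'   \item{`hcsc`}{Block-anchored heuristic: evaluates block-aligned
#'     window starts, then rescans the neighbourhood of the best one.
#'     Its distance is never below the exact optimum.}
#'   \item{`sacscr`}{`sacsc` followed by an alignment-based refinement
#'     of the rotation using dollar-padded end blocks (parameter `p`).}
#'   \item{`cnw`}{All-rotations global alignment (slow, exact under the
#'     alignment score).}
#'   \item{`hsw`}{Local-alignment anchor heuristic.}
#' }
#'
#' When ties occur between rotations (the distance is a pseudo-metric,
#' so ties are common), all q-gram solvers deterministically return the
#' last minimising index of the left-to-right scan over `i = 0..m-1`.
#'
#' @param x,y Character scalars (sequences), `nchar(x) <= nchar(y)`.
#' @param method One of `"sacsc"`, `"ncsc"`, `"hcsc"`, `"sacscr"`,
#'   `"cnw"`, `"hsw"`.
#' @param q Gram length; default `ceiling(log(m, base = alphabet size))`
#'   with the alphabet read off the sequences.
#' @param beta Number of blocks; default `ceiling(sqrt(m))`. Mutually
#'   exclusive with `ell`.
#' @param ell Block length; converted to `beta = floor(m / ell)`.
#' @param p Number of end blocks used by the `sacscr` refinement
#'   (`0 <= p <= beta/3`); `p = 0` disables refinement.
#' @param align Alignment parameters from [align_params()], used by the
#'   refinement and the alignment baselines.
#' @return An object of class `"csc"`: a list with `best_index`
#'   (0-based rotation), `best_distance` (blockwise q-gram distance of
#'   the reported rotation; `NA` for pure alignment methods), `delta`
#'   (full rotation-distance profile where the method computes one),
#'   `rotated` (the rotated sequence), `method`, `params`, and
#'   method-specific extras (e.g. `refinement`, `score`).
#' @examples
#' fit <- csc("GAGTCTA", "TCTAGCG", method = "sacsc", q = 3, beta = 1)
#' fit$best_index   # 3
#' fit$best_distance  # 4
#' @export
csc <- function(x, y, method = c("sacsc", "ncsc", "hcsc", "sacscr", "cnw", "hsw"),
                q = NULL, beta = NULL, ell = NULL, p = 0L,
                align = align_params()) {
  method <- match.arg(method)
  check_seq(x); check_seq(y)
  if (nchar(x) > nchar(y)) stop("require nchar(x) <= nchar(y); swap the inputs")
  par <- csc_params(x, y, q = q, beta = beta, ell = ell)
  res <- switch(method,
    sacsc  = sacsc(x, y, q = par$q, beta = par$beta),
    ncsc   = ncsc(x, y, q = par$q, beta = par$beta),
    hcsc   = hcsc(x, y, q = par$q, beta = par$beta),
    sacscr = sacscr(x, y, q = par$q, beta = par$beta, p = p, align = align),
    cnw    = cnw(x, y, align = align),
    hsw    = hsw(x, y, align = align)
  )
  res
}

# Resolve q/beta/ell defaults against the input pair.
csc_params <- function(x, y, q = NULL, beta = NULL, ell = NULL) {
  m <- nchar(x); n <- nchar(y)
  if (!is.null(beta) && !is.null(ell)) {
    stop("give exactly one of `beta` or `ell`")
  }
  if (!is.null(ell)) {
    if (ell < 1L || ell > m) stop("`ell` must be in 1..nchar(x)")
    beta <- max(1L, as.integer(floor(m / ell)))
  }
  if (is.null(beta)) beta <- as.integer(ceiling(sqrt(m)))
  if (is.null(q)) {
    sig <- length(unique(strsplit(paste0(x, y), "", fixed = TRUE)[[1L]]))
    sig <- max(sig, 2L)
    q <- as.integer(ceiling(log(m, base = sig)))
    q <- max(q, 1L)
  }
  q <- check_q(q)
  if (q >= m) stop("`q` must be smaller than nchar(x)")
  check_blocks(m, n, beta, q)
  list(q = q, beta = as.integer(beta))
}

new_csc <- function(x, y, method, q = NULL, beta = NULL, best_index, delta = NULL,
                    best_distance = NA_integer_, extra = list()) {
  out <- c(list(
    x = x, y = y, method = method, q = q, beta = beta,
    best_index = as.integer(best_index),
    best_distance = best_distance,
    delta = delta,
    rotated = rotate_seq(x, best_index)
  ), extra)
  class(out) <- "csc"
  out
}

# Last minimising index of a left-to-right scan (0-based); reproduces a
# "<=" running-minimum update, the deterministic tie rule used by every
# q-gram solver in this package.
argmin_last <- function(delta) {
  max(which(delta == min(delta))) - 1L
}

#' Naive exact rotation search
#'
#' Evaluates the blockwise q-gram distance of every window of length
#' `m` over `xx` against `y`, independently from scratch; O(m(m+n)).
#' Exact reference for [sacsc()].
#'
#' @inheritParams csc
#' @param q,beta Gram length and block count (required here; the
#'   [csc()] front-end supplies defaults).
#' @return A `"csc"` object (see [csc()]) with the full `delta` profile.
#' @export
ncsc <- function(x, y, q, beta) {
  check_seq(x); check_seq(y)
  q <- check_q(q)
  m <- nchar(x); n <- nchar(y)
  if (q >= m) stop("`q` must be smaller than nchar(x)")
  check_blocks(m, n, beta, q)
  xx <- paste0(x, x)
  delta <- vapply(0:(m - 1L), function(i) {
    blockwise_qgram_distance(substr(xx, i + 1L, i + m), y, beta, q)
  }, integer(1))
  i <- argmin_last(delta)
  new_csc(x, y, "ncsc", q, beta, i, delta = delta, best_distance = delta[i + 1L])
}

#' Heuristic block-anchored rotation search
#'
#' Step 1 splits `xx` into `2*beta` blocks and `y` into `beta` blocks;
#' Step 2 evaluates the blockwise distance at the `beta + 1`
#' block-aligned window starts `floor(j*m/beta)`, `j = 0..beta` (start
#' `m` duplicates rotation 0 and is kept); Step 3 rescans all window
#' starts in `(best - floor(m/beta), best + floor(m/beta) - 1]`
#' (reduced mod `m`) and reports the best. The result is an upper bound
#' on the exact optimum; it equals it whenever the exact argmin falls
#' inside the rescanned neighbourhood.
#'
#' @inheritParams ncsc
#' @return A `"csc"` object; `delta` holds the distances of the window
#'   starts actually evaluated (named by rotation index), not a full
#'   profile.
#' @export
hcsc <- function(x, y, q, beta) {
  check_seq(x); check_seq(y)
  q <- check_q(q)
  m <- nchar(x); n <- nchar(y)
  if (q >= m) stop("`q` must be smaller than nchar(x)")
  check_blocks(m, n, beta, q)
  xx <- paste0(x, x)
  dist_at <- function(i) {  # window start i in 0..m (xx has 2m letters)
    blockwise_qgram_distance(substr(xx, i + 1L, i + m), y, beta, q)
  }
  # Step 2: block-aligned starts
  starts <- as.integer(floor((0:beta) * m / beta))
  d2 <- vapply(starts, dist_at, integer(1))
  jb <- starts[max(which(d2 == min(d2)))]
  # Step 3: neighbourhood rescan, 2*floor(m/beta) - 1 starts
  mb <- as.integer(floor(m / beta))
  cand <- (jb - mb + 1L):(jb + mb - 1L)
  cand_rot <- cand %% m
  d3 <- vapply(cand_rot, dist_at, integer(1))
  ib <- cand_rot[max(which(d3 == min(d3)))]
  evaluated <- c(stats::setNames(d2, starts %% m), stats::setNames(d3, cand_rot))
  new_csc(x, y, "hcsc", q, beta, ib, delta = evaluated,
          best_distance = min(d3))
}

#' Exact suffix-array rotation search
#'
#' The exact O(beta*m + n) algorithm: reduce the q-grams of `xx` and
#' `y` to integer ranks over a shared alphabet of size at most `m + 2`
#' ([rank_qgrams()]), then slide a window of `m` letters over `xx`
#' maintaining, per block, a signed difference vector between the
#' Parikh vector of the corresponding block of `y`'s rank string and
#' the window block's gram counts. Each one-position shift updates each
#' block's difference vector and distance in O(1), so the full
#' rotation-distance profile `delta[i] = D_{beta,q}(x^i, y)` comes out
#' in one pass.
#'
#' @inheritParams ncsc
#' @return A `"csc"` object with the full `delta` profile.
#' @examples
#' sacsc("GAGTCTA", "TCTAGCG", q = 3, beta = 1)$delta  # 6 4 4 4 6 8 8
#' @export
sacsc <- function(x, y, q, beta) {
  check_seq(x); check_seq(y)
  q <- check_q(q)
  m <- nchar(x); n <- nchar(y)
  if (q >= m) stop("`q` must be smaller than nchar(x)")
  check_blocks(m, n, beta, q)
  rs <- rank_qgrams(x, y, q)
  st <- csc_init_window(rs, beta)
  delta <- integer(m)
  delta[1L] <- st$delta0
  if (m > 1L) {
    for (i in 0:(m - 2L)) {
      st <- csc_slide_window(st, i)
      delta[i + 2L] <- sum(st$delta_j)
    }
  }
  i <- argmin_last(delta)
  new_csc(x, y, "sacsc", q, beta, i, delta = delta, best_distance = delta[i + 1L])
}

#' Initialise the sliding-window state (Steps 1-2)
#'
#' Step 1 builds, for each block `j`, the Parikh vector of block `j` of
#' `y`'s rank string; the initial accumulator is the total gram count
#' of `y'` (for `beta = 1`, `n - q + 1`). Step 2 then consumes the
#' grams of window 0: for each rank `r` read, `diff[r]` is decremented
#' and the block distance decreases by 1 if `diff[r]` stays
#' non-negative (the gram was still owed by `y`), else increases by 1.
#' Block `j` of a window owns exactly the grams starting inside it and
#' fully contained in it; the `q - 1` grams straddling each block
#' boundary belong to no block.
#'
#' Mostly an internal of [sacsc()], exported for inspection and tests.
#'
#' @param rs A `rank_strings` object from [rank_qgrams()].
#' @param beta Number of blocks.
#' @return A list with `diff` (matrix `(sigma+2) x beta` of signed
#'   counts), `delta_j` (per-block distances of rotation 0), `delta0`
#'   (their sum), `delta0_step1` (the accumulator right after Step 1),
#'   `bx`, `out_idx`, `in_idx` (per-block gram offsets used by
#'   [csc_slide_window()]), and the rank strings.
#' @export
csc_init_window <- function(rs, beta) {
  m <- rs$m; n <- rs$n; q <- rs$q
  check_blocks(m, n, beta, q)
  K <- rs$sigma + 2L
  bx <- block_partition(m, beta)
  by <- block_partition(n, beta)
  diff <- matrix(0L, nrow = K, ncol = beta)
  for (j in seq_len(beta)) {
    idx <- by[j]:(by[j + 1L] - q)          # 0-based gram starts in y block j
    diff[, j] <- tabulate(rs$yr[idx + 1L], nbins = K)
  }
  delta_j <- colSums(diff)
  delta0_step1 <- sum(delta_j)
  # Step 2: consume the grams of window 0, block by block
  for (j in seq_len(beta)) {
    for (pos in bx[j]:(bx[j + 1L] - q)) {
      r <- rs$xr[pos + 1L]
      diff[r, j] <- diff[r, j] - 1L
      delta_j[j] <- delta_j[j] + (if (diff[r, j] >= 0L) -1L else 1L)
    }
  }
  list(
    diff = diff, delta_j = delta_j, delta0 = sum(delta_j),
    delta0_step1 = delta0_step1,
    bx = bx,
    out_idx = bx[seq_len(beta)],                    # departing gram offsets
    in_idx = bx[2L:(beta + 1L)] - q + 1L,           # arriving gram offsets
    rs = rs, beta = beta
  )
}

#' Slide the window one position (Step 3)
#'
#' Shifts the window from start `i` to `i + 1` (0-based). For each
#' block `j`, the departing gram rank `xr[i + b_j]` is re-added to the
#' difference vector (distance -1 if the updated entry is <= 0, else
#' +1) and the arriving gram rank `xr[i + b_{j+1} - q + 1]` is consumed
#' (distance -1 if the updated entry is >= 0, else +1), the two rules
#' applied sequentially in this order. The arriving index uses the
#' `- q + 1` correction so that a window of `m` letters always owns
#' `m - q + 1` grams (for `beta = 1`).
#'
#' Mostly an internal of [sacsc()], exported for inspection and tests.
#'
#' @param state State list from [csc_init_window()] or a previous call.
#' @param i Current window start, `0 <= i < m - 1`.
#' @return Updated state; `sum(state$delta_j)` is `delta[i + 1]`.
#' @export
csc_slide_window <- function(state, i) {
  beta <- state$beta
  xr <- state$rs$xr
  ro <- xr[i + state$out_idx + 1L]
  ij <- cbind(ro, seq_len(beta))
  state$diff[ij] <- state$diff[ij] + 1L
  state$delta_j <- state$delta_j + ifelse(state$diff[ij] <= 0L, -1L, 1L)
  ri <- xr[i + state$in_idx + 1L]
  ij2 <- cbind(ri, seq_len(beta))
  state$diff[ij2] <- state$diff[ij2] - 1L
  state$delta_j <- state$delta_j + ifelse(state$diff[ij2] >= 0L, -1L, 1L)
  state
}

#' @export
print.csc <- function(x, ...) {
  cat("Circular sequence comparison (", x$method, ")\n", sep = "")
  cat("  m = ", nchar(x$x), ", n = ", nchar(x$y), sep = "")
  if (!is.null(x$q)) cat(", q = ", x$q, ", beta = ", x$beta, sep = "")
  cat("\n")
  cat("  best rotation index: ", x$best_index, " (0-based)\n", sep = "")
  if (!is.na(x$best_distance)) {
    cat("  blockwise q-gram distance: ", x$best_distance, "\n", sep = "")
  }
  if (!is.null(x$score)) cat("  alignment score: ", x$score, "\n", sep = "")
  if (!is.null(x$refinement)) {
    cat("  refinement shift: ", x$refinement$shift,
        " (from index ", x$refinement$unrefined_index, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.csc <- function(object, ...) {
  print(object)
  if (!is.null(object$delta) && length(object$delta) > 1L) {
    cat("  rotation-distance profile: min ", min(object$delta),
        ", median ", stats::median(object$delta),
        ", max ", max(object$delta), "\n", sep = "")
    ties <- sum(object$delta == min(object$delta))
    if (ties > 1L) cat("  (", ties, " rotations tie at the minimum)\n", sep = "")
  }
  invisible(object)
}

#' Plot the rotation-distance profile
#'
#' @param x A `"csc"` object whose method produced a full `delta`
#'   profile (`sacsc`, `ncsc`, `sacscr`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.csc <- function(x, ...) {
  if (is.null(x$delta)) stop("no rotation-distance profile in this object")
  graphics::plot(seq_along(x$delta) - 1L, x$delta, type = "l",
                 xlab = "rotation index i",
                 ylab = "blockwise q-gram distance", ...)
  graphics::abline(v = x$best_index, lty = 2)
  invisible(x)
}
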