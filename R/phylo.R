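#' All-vs-all rotation + alignment similarity matrix
#'
#' For every unordered pair of sequences, finds the best rotation of
#' the shorter onto the longer by the chosen method, aligns the
#' re-rotated pair with the EMBOSS-default global aligner, and stores
#' the similarity percentage symmetrically. `rotate = "none"` skips the
#' rotation stage (the reference pipeline for already-aligned /
#' original sequences).
#'
#' @param seqs Named character vector of N >= 3 sequences.
#' @param rotate One of `"sacscr"`, `"sacsc"`, `"hcsc"`, `"cnw"`,
#'   `"hsw"`, `"none"`.
#' @param q,beta,p Parameters for the q-gram methods (defaults as in
#'   [csc()]: `beta = ceiling(sqrt(m))`, `q` from the alphabet size).
#' @param align [align_params()] used for scoring (and for `cnw`/`hsw`
#'   rotation search).
#' @param value `"similarity"` (percent) or `"score"` (raw alignment
#'   score).
#' @return Symmetric N x N numeric matrix with 100 (or the self-score)
#'   on the diagonal and sequence names as dimnames.
#' @export
pairwise_matrix <- function(seqs, rotate = c("sacscr", "sacsc", "hcsc", "cnw", "hsw", "none"),
                            q = NULL, beta = NULL, p = 1L,
                            align = align_params(), value = c("similarity", "score")) {
  rotate <- match.arg(rotate)
  value <- match.arg(value)
  if (length(seqs) < 3L) stop("need at least 3 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("`seqs` must have unique names")
  }
  N <- length(seqs)
  S <- matrix(NA_real_, N, N, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      a <- seqs[[i]]; b <- seqs[[j]]
      swapped <- nchar(a) > nchar(b)
      if (swapped) { tmp <- a; a <- b; b <- tmp }
      ar <- if (rotate == "none") a else {
        fit <- csc(a, b, method = rotate, q = q, beta = beta, p = p, align = align)
        fit$rotated
      }
      aln <- global_align(ar, b, align)
      S[i, j] <- S[j, i] <- if (value == "similarity") aln$similarity else aln$score
    }
  }
  diag(S) <- if (value == "similarity") 100 else {
    vapply(seqs, function(s) global_align(s, s, align)$score, numeric(1))
  }
  S
}

#' Convert a similarity matrix to a distance matrix
#'
#' Each similarity is expressed relative to the maximum of the matrix:
#' `d[i, j] = 1 - s[i, j] / max(S)` off the diagonal, 0 on it. A
#' monotone transform, so pair rankings are preserved.
#'
#' @param S Symmetric numeric similarity matrix with a positive
#'   maximum.
#' @return Distance matrix of the same shape.
#' @export
similarity_to_distance <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("`S` must be square")
  mx <- max(S, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("similarity maximum must be positive")
  D <- 1 - S / mx
  diag(D) <- 0
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbour joining (via \pkg{ape}), returning an
#' unrooted tree with the matrix labels as tips.
#'
#' @param D Symmetric distance matrix with zero diagonal and dimnames.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("`D` must be square")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("`D` must be symmetric")
  }
  ape::nj(stats::as.dist(D))
}

#' Robinson-Foulds distance between two trees
#'
#' The number of bipartitions present in exactly one of the two trees
#' (unnormalised; 0 for topologically identical trees on the same leaf
#' set).
#'
#' @param t1,t2 [ape::phylo] trees with identical tip labels.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must share the same leaf set")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Distance-based phylogeny pipeline
#'
#' The full application pipeline: all-vs-all rotation + alignment
#' similarity matrix ([pairwise_matrix()]), conversion to distances
#' ([similarity_to_distance()]), and neighbour joining ([nj_tree()]).
#'
#' @inheritParams pairwise_matrix
#' @return List with `similarity`, `distance`, `tree`.
#' @export
run_phylo <- function(seqs, rotate = "sacscr", q = NULL, beta = NULL, p = 1L,
                      align = align_params()) {
  S <- pairwise_matrix(seqs, rotate = rotate, q = q, beta = beta, p = p,
                       align = align)
  D <- similarity_to_distance(S)
  list(similarity = S, distance = D, tree = nj_tree(D))
}
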