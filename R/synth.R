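#' Simulate a diverged family of circular-like sequences
#'
#' Generates a random root sequence of length `gamma` and evolves
#' `alpha` descendants from it along a random ultrametric coalescent
#' guide tree scaled to unit height, so every tip sits at total branch
#' length 1 from the root. Along an edge of length `b`, each site is
#' substituted with probability `theta * b` under a
#' Jukes-Cantor-style model (an equal chance of each alternative
#' letter), and single-letter insertions and deletions occur per site
#' with probabilities `kappa * theta * b` and `omega * theta * b`
#' (`kappa`, `omega` are rates relative to a substitution rate of 1).
#' Each tip therefore accumulates divergence `theta` from the root in
#' expectation, while pairs of tips diverge in proportion to twice
#' their distance to the most recent common ancestor — giving the
#' family a resolvable phylogenetic structure. `tree = "star"`
#' suppresses the guide tree and evolves every descendant
#' independently from the root.
#'
#' Defaults match the validation regime used throughout the package:
#' 12 sequences of 2500 bp with theta in \{0.05, 0.20, 0.35\},
#' kappa = 0.06, omega = 0.04.
#'
#' With `multi_hit = TRUE`, branch substitution probabilities use the
#' Jukes-Cantor transform `3/4 * (1 - exp(-4 * theta * b / 3))`,
#' allowing for multiple hits.
#'
#' Draws come from R's RNG; call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @param alpha Number of descendant sequences (>= 2).
#' @param gamma Root length (>= 1).
#' @param theta Substitution rate per site (root-to-tip).
#' @param kappa,omega Insertion / deletion rates relative to
#'   substitution rate 1.
#' @param alphabet Letters to draw from (default DNA).
#' @param seed Optional integer; if given, `set.seed(seed)` is called
#'   first.
#' @param root Optional root sequence (character scalar over
#'   `alphabet`); when given, `gamma` is ignored and descendants are
#'   evolved from it. Lets callers chain families into deeper
#'   histories.
#' @param rotate If `TRUE`, each descendant is additionally rotated by
#'   a uniform random offset ([random_rotation()]) and the offsets are
#'   recorded.
#' @param multi_hit See Details.
#' @param tree `"coalescent"` (default) for a random ultrametric guide
#'   tree, `"star"` for independent descendants, or an [ape::phylo]
#'   object with `alpha` tips (its branch lengths are rescaled to unit
#'   height).
#' @return A list of class `sim_family`: `root`, `originals` (named
#'   character vector `seq_1..seq_alpha`), `rotated`, `offsets`
#'   (0-based true rotation offsets; zeros when `rotate = FALSE`),
#'   `tree` (the guide tree with tips renamed to match, or `NULL` for
#'   a star), and `params`.
#' @examples
#' fam <- simulate_family(alpha = 3, gamma = 200, theta = 0.05, seed = 1)
#' nchar(fam$originals)
#' @export
simulate_family <- function(alpha = 12L, gamma = 2500L, theta = 0.05,
                            kappa = 0.06, omega = 0.04,
                            alphabet = c("A", "C", "G", "T"),
                            seed = NULL, rotate = TRUE, multi_hit = FALSE,
                            root = NULL, tree = "coalescent") {
  if (alpha < 2L) stop("`alpha` must be >= 2")
  if (gamma < 1L) stop("`gamma` must be >= 1")
  if (theta < 0 || kappa < 0 || omega < 0) stop("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(root)) {
    root_letters <- sample(alphabet, gamma, replace = TRUE)
  } else {
    check_seq(root)
    root_letters <- strsplit(root, "", fixed = TRUE)[[1L]]
    if (!all(root_letters %in% alphabet)) stop("`root` has letters outside `alphabet`")
    gamma <- length(root_letters)
  }
  k <- length(alphabet)

  # one mutation pass over a letter vector, for a branch of length b
  mutate_letters <- function(s, b) {
    p_sub <- if (multi_hit) 3 / 4 * (1 - exp(-4 * theta * b / 3)) else theta * b
    p_ins <- kappa * theta * b
    p_del <- omega * theta * b
    hit <- stats::runif(length(s)) < p_sub
    if (any(hit)) {
      shift <- sample.int(k - 1L, sum(hit), replace = TRUE)
      s[hit] <- alphabet[((match(s[hit], alphabet) - 1L + shift) %% k) + 1L]
    }
    del <- stats::runif(length(s)) < p_del
    s <- s[!del]
    ins <- stats::runif(length(s)) < p_ins
    if (any(ins)) {
      pieces <- s
      pieces[ins] <- paste0(s[ins], sample(alphabet, sum(ins), replace = TRUE))
      s <- strsplit(paste(pieces, collapse = ""), "", fixed = TRUE)[[1L]]
    }
    s
  }

  guide <- NULL
  if (is.character(tree) && identical(tree, "star")) {
    tips <- lapply(seq_len(alpha), function(i) mutate_letters(root_letters, 1))
  } else {
    if (is.character(tree) && identical(tree, "coalescent")) {
      guide <- ape::rcoal(alpha)
    } else if (inherits(tree, "phylo")) {
      if (length(tree$tip.label) != alpha) stop("`tree` must have `alpha` tips")
      guide <- tree
    } else {
      stop("`tree` must be \"coalescent\", \"star\", or a phylo object")
    }
    depths <- ape::node.depth.edgelength(guide)
    guide$edge.length <- guide$edge.length / max(depths)
    guide <- stats::reorder(guide, "cladewise")  # edges in preorder
    node_seq <- vector("list", alpha + guide$Nnode)
    node_seq[[alpha + 1L]] <- root_letters      # root node
    for (e in seq_len(nrow(guide$edge))) {
      par <- guide$edge[e, 1L]; ch <- guide$edge[e, 2L]
      node_seq[[ch]] <- mutate_letters(node_seq[[par]], guide$edge.length[e])
    }
    tips <- node_seq[seq_len(alpha)]
    guide$tip.label <- paste0("seq_", seq_len(alpha))
  }

  originals <- vapply(tips, paste, "", collapse = "")
  names(originals) <- paste0("seq_", seq_len(alpha))
  offsets <- integer(alpha)
  rotated <- originals
  if (rotate) {
    for (i in seq_len(alpha)) {
      r <- random_rotation(originals[[i]])
      rotated[[i]] <- r$rotated
      offsets[[i]] <- r$offset
    }
  }
  structure(list(
    root = paste(root_letters, collapse = ""),
    originals = originals, rotated = rotated, offsets = offsets,
    tree = guide,
    params = list(alpha = alpha, gamma = gamma, theta = theta,
                  kappa = kappa, omega = omega, multi_hit = multi_hit)
  ), class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  p <- x$params
  cat("Simulated sequence family: alpha = ", p$alpha,
      ", gamma = ", p$gamma, ", theta = ", p$theta,
      ", kappa = ", p$kappa, ", omega = ", p$omega, "\n",
      "  guide tree: ", if (is.null(x$tree)) "star" else "coalescent",
      "; lengths ", min(nchar(x$originals)), "..", max(nchar(x$originals)),
      "; rotations recorded: ", any(x$offsets > 0L), "\n", sep = "")
  invisible(x)
}

#' Uniform random rotation of a sequence
#'
#' Draws an offset uniformly from `0..nchar(s)-1` and returns the
#' corresponding rotation.
#'
#' @param s Character scalar.
#' @return List with `rotated` and `offset` (0-based).
#' @export
random_rotation <- function(s) {
  check_seq(s)
  offset <- sample.int(nchar(s), 1L) - 1L
  list(rotated = rotate_seq(s, offset), offset = offset)
}
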