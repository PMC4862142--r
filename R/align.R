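#' Alignment parameters
#'
#' Bundles a substitution matrix and affine gap penalties. Defaults are
#' the EMBOSS Needle defaults: EDNAFULL with gap open 10 / extend 0.5
#' for nucleotides (EBLOSUM62 with the same penalties for proteins). A
#' gap of length L costs `gap_open + L * gap_extend`. With
#' `endweight = FALSE` (the EMBOSS default) leading and trailing gaps
#' are not penalised, though they appear in (and are counted over) the
#' reported alignment.
#'
#' @param matrix `"EDNAFULL"`, `"EBLOSUM62"`, or a numeric matrix with
#'   letter row/column names (see [read_scoring_matrix()]).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param endweight Logical; penalise end gaps?
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "EDNAFULL", gap_open = 10, gap_extend = 0.5,
                         endweight = FALSE) {
  if (is.character(matrix)) {
    matrix <- scoring_matrix(matrix)
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix))) {
    stop("`matrix` must be a named square scoring matrix or a known matrix name")
  }
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, endweight = isTRUE(endweight)),
            class = "align_params")
}

#' Read an EMBOSS/NCBI-format scoring matrix
#'
#' Parses the plain-text substitution matrix format used by EMBOSS and
#' NCBI tools: `#` comment lines, a header row of letters, then one row
#' per letter.
#'
#' @param path File path.
#' @return Numeric matrix with letter dimnames.
#' @export
read_scoring_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  lab <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  dimnames(vals) <- list(lab, header)
  vals[header, , drop = FALSE]  # enforce symmetric ordering
}

# Bundled matrices, cached per session.
scoring_matrix <- local({
  cache <- list()
  function(name = c("EDNAFULL", "EBLOSUM62")) {
    name <- match.arg(name)
    if (is.null(cache[[name]])) {
      path <- system.file("extdata", name, package = "circsc", mustWork = TRUE)
      cache[[name]] <<- read_scoring_matrix(path)
    }
    cache[[name]]
  }
})

# Map a sequence to 1-based indices into the matrix alphabet.
encode_for_matrix <- function(s, mat) {
  letters_s <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- match(letters_s, rownames(mat))
  if (anyNA(idx)) {
    stop("letter(s) absent from scoring matrix: ",
         paste(unique(letters_s[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch / Gotoh global alignment with a substitution matrix
#' and affine gap penalties; EMBOSS-Needle-compatible defaults and
#' statistics. Identity is the percentage of alignment columns with
#' equal letters; similarity is the EMBOSS convention, the percentage
#' of columns whose substitution score is positive (gap columns count
#' in the denominator); `gaps` counts gap characters over both rows.
#'
#' @param a,b Character scalars.
#' @param params [align_params()].
#' @param dollar Optional neutral pad letter (a single character, e.g.
#'   `"$"`): columns involving it — substitutions against it and gaps
#'   consuming it — score exactly 0. Used by the rotation refinement.
#' @return List of class `alignment`: `score`, `aligned` (two gapped
#'   strings), `length`, `identity`, `similarity` (percentages),
#'   `gaps`.
#' @examples
#' global_align("ACGT", "AGT")
#' @export
global_align <- function(a, b, params = align_params(), dollar = NULL) {
  check_seq(a); check_seq(b)
  mat <- params$matrix
  if (!is.null(dollar)) {
    stopifnot(nchar(dollar) == 1L)
    if (!dollar %in% rownames(mat)) {
      mat <- rbind(cbind(mat, 0), 0)
      rownames(mat)[nrow(mat)] <- dollar
      colnames(mat)[ncol(mat)] <- dollar
    }
    dollar_idx <- match(dollar, rownames(mat))
  } else {
    dollar_idx <- 0L
  }
  ia <- encode_for_matrix(a, mat)
  ib <- encode_for_matrix(b, mat)
  res <- cpp_nw_align(ia, ib, mat, params$gap_open, params$gap_extend,
                      params$endweight, dollar_idx)
  lets <- rownames(mat)
  dec <- function(v) paste(ifelse(v == 0L, "-", lets[pmax(v, 1L)]), collapse = "")
  av <- res$a; bv <- res$b
  len <- length(av)
  both <- av > 0L & bv > 0L
  ident <- sum(both & lets[pmax(av, 1L)] == lets[pmax(bv, 1L)])
  simil <- sum(both & mat[cbind(pmax(av, 1L), pmax(bv, 1L))] > 0)
  structure(list(
    score = res$score,
    aligned = c(dec(av), dec(bv)),
    length = len,
    identity = 100 * ident / len,
    similarity = 100 * simil / len,
    gaps = sum(av == 0L) + sum(bv == 0L)
  ), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Global alignment: score ", format(x$score), ", length ", x$length,
      "\n  identity ", sprintf("%.1f%%", x$identity),
      ", similarity ", sprintf("%.1f%%", x$similarity),
      ", gaps ", x$gaps, "\n", sep = "")
  invisible(x)
}

# Score-only global alignment (used by rotation scans).
global_align_score <- function(a, b, params = align_params(), dollar = NULL) {
  mat <- params$matrix
  if (!is.null(dollar)) {
    if (!dollar %in% rownames(mat)) {
      mat <- rbind(cbind(mat, 0), 0)
      rownames(mat)[nrow(mat)] <- dollar
      colnames(mat)[ncol(mat)] <- dollar
    }
    dollar_idx <- match(dollar, rownames(mat))
  } else {
    dollar_idx <- 0L
  }
  cpp_nw_score(encode_for_matrix(a, mat), encode_for_matrix(b, mat), mat,
               params$gap_open, params$gap_extend, params$endweight, dollar_idx)
}

#' All-rotations global alignment baseline
#'
#' Aligns every rotation of `x` against `y` and reports the rotation
#' with the highest alignment score (smallest index on ties). Exact
#' under the alignment objective but O(m) alignments, hence slow;
#' used as the accuracy reference.
#'
#' @inheritParams global_align
#' @param x,y Character scalars.
#' @param params [align_params()].
#' @return A `"csc"` object with `score` and `alignment` extras;
#'   `best_distance` is `NA` (no q-gram distance involved).
#' @export
cnw <- function(x, y, params = align_params()) {
  check_seq(x); check_seq(y)
  m <- nchar(x)
  scores <- vapply(0:(m - 1L), function(i) {
    global_align_score(rotate_seq(x, i), y, params)
  }, numeric(1))
  i <- which.max(scores) - 1L  # smallest index on ties
  aln <- global_align(rotate_seq(x, i), y, params)
  new_csc(x, y, "cnw", best_index = i,
          delta = scores, best_distance = NA_integer_,
          extra = list(score = scores[i + 1L], alignment = aln))
}

#' Local-alignment anchor heuristic
#'
#' Runs Smith-Waterman local alignment of `x` vs `y`, takes the column
#' at the midpoint of the optimal local alignment path (ties to the
#' earlier column), and rotates `x` so that its letter in that column
#' lands at the position aligning it with `y`'s letter. If the local
#' alignment is empty (all scores non-positive) rotation 0 is returned
#' with a warning.
#'
#' @inheritParams cnw
#' @return A `"csc"` object with `score` (the local alignment score).
#' @export
hsw <- function(x, y, params = align_params()) {
  check_seq(x); check_seq(y)
  mat <- params$matrix
  res <- cpp_sw_local(encode_for_matrix(x, mat), encode_for_matrix(y, mat),
                      mat, params$gap_open, params$gap_extend)
  m <- nchar(x)
  if (length(res$a_pos) == 0L) {
    warning("empty local alignment; falling back to rotation 0")
    return(new_csc(x, y, "hsw", best_index = 0L, best_distance = NA_integer_,
                   extra = list(score = res$score)))
  }
  # central match column: nearest column to the path midpoint where
  # both sequences contribute a letter
  both <- which(res$a_pos > 0L & res$b_pos > 0L)
  mid <- (length(res$a_pos) + 1L) %/% 2L
  anchor <- both[which.min(abs(both - mid))]
  ai <- res$a_pos[anchor] - 1L   # 0-based position in x
  bj <- res$b_pos[anchor] - 1L   # 0-based position in y
  rot <- (ai - bj) %% m
  new_csc(x, y, "hsw", best_index = rot, best_distance = NA_integer_,
          extra = list(score = res$score))
}
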