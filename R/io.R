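#' Read a (Multi)FASTA file
#'
#' Wraps \pkg{Biostrings}: wrapped lines are joined, letters are
#' upper-cased (U is kept distinct from T), and ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path Readable FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("empty FASTA record in ", path)
  bad <- grepl("[^A-Z*]", seqs)
  if (any(bad)) {
    stop("illegal characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs))) stop("`seqs` must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param D Square numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(D, path) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("`D` must be square")
  lab <- rownames(D)
  lines <- c(
    sprintf("%5d", nrow(D)),
    vapply(seq_len(nrow(D)), function(i) {
      paste0(formatC(lab[i], width = -10L),
             paste(sprintf("%.6f", D[i, ]), collapse = " "))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Run a pairwise circular comparison and report
#'
#' Convenience wrapper for script use: compares the first sequence of a
#' FASTA file (or vector) against the second, prints a small report,
#' and optionally writes the rotated sequence and the full
#' rotation-distance profile.
#'
#' @param seqs Named character vector of exactly two sequences, or a
#'   FASTA path.
#' @param method,q,beta,ell,p See [csc()].
#' @param out_prefix If non-`NULL`, writes `<prefix>.fasta` (the
#'   rotated first sequence) and, when available, `<prefix>.delta.tsv`
#'   (the profile).
#' @param quiet Suppress the printed report.
#' @return The `"csc"` object, invisibly.
#' @export
run_pair <- function(seqs, method = "sacsc", q = NULL, beta = NULL, ell = NULL,
                     p = 0L, out_prefix = NULL, quiet = FALSE) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    seqs <- read_fasta(seqs)
  }
  if (length(seqs) != 2L) stop("need exactly two sequences")
  x <- seqs[[1L]]; y <- seqs[[2L]]
  swapped <- nchar(x) > nchar(y)
  if (swapped) { tmp <- x; x <- y; y <- tmp }
  fit <- csc(x, y, method = method, q = q, beta = beta, ell = ell, p = p)
  if (!quiet) print(fit)
  if (!is.null(out_prefix)) {
    write_fasta(stats::setNames(fit$rotated,
                                paste0(names(seqs)[if (swapped) 2L else 1L],
                                       "_rot", fit$best_index)),
                paste0(out_prefix, ".fasta"))
    if (!is.null(fit$delta)) {
      utils::write.table(
        data.frame(rotation = seq_along(fit$delta) - 1L, delta = fit$delta),
        paste0(out_prefix, ".delta.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(fit)
}
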