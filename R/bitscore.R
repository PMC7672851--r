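#' Sparse symmetric table of BLAST bit scores
#'
#' Stores sequence-similarity bit scores for pairs of proteins. Lookups are
#' symmetric, missing pairs read as 0, and when the same unordered pair is
#' supplied twice (reciprocal BLAST hits usually differ) the larger score is
#' kept, which is the conservative choice for a similarity.
#'
#' @param u,v character vectors of protein identifiers.
#' @param score numeric vector of non-negative raw bit scores.
#' @return An object of class `bit_score_table`.
#' @examples
#' b <- bit_score_table(c("a", "b"), c("b", "a"), c(50, 70))
#' bit_score(b, "a", "b")  # 70: max of the two reciprocal rows
#' bit_score(b, "a", "z")  # 0: absent pair
#' @export
bit_score_table <- function(u, v, score) {
  u <- as.character(u)
  v <- as.character(v)
  score <- as.numeric(score)
  stopifnot(length(u) == length(v), length(u) == length(score))
  if (anyNA(score)) stop("bit scores must be numeric")
  if (any(score < 0)) stop("bit scores must be non-negative")
  a <- pmin(u, v)
  b <- pmax(u, v)
  key <- pair_key(u, v)
  # max-merge duplicated unordered pairs: sort by key then decreasing score,
  # keep the first occurrence of each key
  o <- order(key, -score)
  keep <- !duplicated(key[o])
  structure(
    list(
      u = a[o][keep],
      v = b[o][keep],
      score = score[o][keep],
      key = key[o][keep]
    ),
    normalized = FALSE,
    class = "bit_score_table"
  )
}

#' @export
print.bit_score_table <- function(x, ...) {
  cat(sprintf("bit score table: %d pairs, %s, max score %.4g\n",
              length(x$score),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw",
              if (length(x$score)) max(x$score) else NA_real_))
  invisible(x)
}

#' Read bit scores from a three-column table
#'
#' Expects tab- or whitespace-separated rows `protein protein score`; `#`
#' comment lines are skipped.
#'
#' @param path input path.
#' @return A [bit_score_table].
#' @export
read_bit_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                         colClasses = c("character", "character", "numeric"),
                         col.names = c("u", "v", "score"))
  bit_score_table(d$u, d$v, d$score)
}

#' Write a bit-score table as three-column TSV
#' @param x a [bit_score_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bit_scores <- function(x, path) {
  stopifnot(inherits(x, "bit_score_table"))
  utils::write.table(data.frame(x$u, x$v, x$score), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Rescale a bit-score table to the unit interval
#'
#' Divides every stored score by the table's maximum, so that normalized
#' scores `B(u,v)` lie in `[0,1]` and at least one pair attains 1. Each table
#' (within either network, or cross-network) is normalized independently.
#'
#' @param x a [bit_score_table].
#' @return The normalized table.
#' @export
normalize_bit_scores <- function(x) {
  stopifnot(inherits(x, "bit_score_table"))
  if (isTRUE(attr(x, "normalized"))) return(x)
  if (length(x$score) == 0L) stop("cannot normalize an empty bit-score table")
  m <- max(x$score)
  if (m <= 0) stop("cannot normalize an all-zero bit-score table")
  x$score <- x$score / m
  attr(x, "normalized") <- TRUE
  x
}

#' Look up bit scores
#'
#' Vectorized symmetric lookup; unknown pairs return 0.
#'
#' @param x a [bit_score_table].
#' @param u,v protein identifiers (recycled to a common length).
#' @return Numeric vector of scores.
#' @export
bit_score <- function(x, u, v) {
  stopifnot(inherits(x, "bit_score_table"))
  i <- match(pair_key(as.character(u), as.character(v)), x$key)
  out <- x$score[i]
  out[is.na(out)] <- 0
  out
}

# Dense score matrix over given row/column node sets; used where every pair
# within a network (or across the two) is consulted.
bit_score_dense <- function(x, rows, cols) {
  stopifnot(inherits(x, "bit_score_table"))
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  place <- function(a, b) {
    i <- match(a, rows)
    j <- match(b, cols)
    ok <- !is.na(i) & !is.na(j)
    m[cbind(i[ok], j[ok])] <<- pmax(m[cbind(i[ok], j[ok])], x$score[ok])
  }
  place(x$u, x$v)
  place(x$v, x$u)
  m
}
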