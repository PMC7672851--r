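#' GO annotation table
#'
#' Maps each protein to its set of Gene Ontology term identifiers. Proteins
#' absent from the table are treated as unannotated (empty term set).
#'
#' @param protein,term character vectors: one row per (protein, term)
#'   assignment; repeated rows accumulate into a set.
#' @return A named list of class `annotation_table`, protein -> sorted
#'   character vector of unique terms.
#' @export
annotation_table <- function(protein, term) {
  protein <- as.character(protein)
  term <- as.character(term)
  stopifnot(length(protein) == length(term))
  out <- lapply(split(term, protein), function(x) sort(unique(x)))
  structure(out[order(names(out))], class = "annotation_table")
}

#' Read a two-column protein/term annotation table
#' @param path input path (TSV, `#` comments skipped).
#' @return An [annotation_table].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                         colClasses = "character",
                         col.names = c("protein", "term"))
  annotation_table(d$protein, d$term)
}

#' Write an annotation table as two-column TSV
#' @param x an [annotation_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  stopifnot(inherits(x, "annotation_table"))
  d <- data.frame(protein = rep(names(x), lengths(x)),
                  term = unlist(x, use.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Term set of one protein
#' @param x an [annotation_table].
#' @param protein protein identifier.
#' @return Character vector of terms; empty for unannotated proteins.
#' @export
go_terms <- function(x, protein) {
  stopifnot(inherits(x, "annotation_table"))
  x[[protein]] %||% character(0)
}

#' Protein-complex catalog with functional labels
#'
#' @param complex,protein,label character vectors, one row per (complex,
#'   member, function label) assignment; rows accumulate. Each complex must
#'   end up with at least one member.
#' @return A list of class `complex_catalog`; each element has `id`,
#'   `members` and `labels`.
#' @export
complex_catalog <- function(complex, protein, label) {
  complex <- as.character(complex)
  protein <- as.character(protein)
  label <- as.character(label)
  stopifnot(length(complex) == length(protein), length(complex) == length(label))
  ids <- sort(unique(complex))
  out <- lapply(ids, function(id) {
    sel <- complex == id
    members <- sort(unique(protein[sel]))
    if (length(members) == 0L) stop("complex '", id, "' has no members")
    list(id = id, members = members, labels = sort(unique(label[sel])))
  })
  names(out) <- ids
  structure(out, class = "complex_catalog")
}

#' Read a three-column complex catalog (complex id, protein, function label)
#' @param path input path.
#' @return A [complex_catalog].
#' @export
read_complex_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                         colClasses = "character",
                         col.names = c("complex", "protein", "label"))
  complex_catalog(d$complex, d$protein, d$label)
}

#' Read a one-column list of essential proteins
#' @param path input path.
#' @return Sorted character vector of unique identifiers.
#' @export
read_essential_proteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  sort(unique(lines[!grepl("^(#|$)", lines)]))
}
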