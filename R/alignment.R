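#' Construct a multiple sequence alignment object
#'
#' Rows are equal-length strings over the 21-letter alphabet (20 amino acids
#' plus \code{"-"} for gap/unknown). Row 1 is the query.
#'
#' @param sequences character vector of aligned rows (uppercase, gaps as "-").
#' @param ids character vector of record ids (recycled header text is kept
#'   only as ids).
#' @return An object of class \code{"msa"} with fields \code{sequences},
#'   \code{ids}, \code{query_id}, \code{depth} and \code{length}.
#' @export
msa <- function(sequences, ids = paste0("seq", seq_along(sequences))) {
  stopifnot(length(sequences) >= 1, length(ids) == length(sequences))
  sequences <- unname(sequences); ids <- unname(ids)
  L <- nchar(sequences[1])
  bad <- which(nchar(sequences) != L)
  if (length(bad)) {
    stop(sprintf("alignment row %d ('%s') has length %d, expected %d",
                 bad[1], ids[bad[1]], nchar(sequences[bad[1]]), L))
  }
  structure(list(sequences = toupper(sequences), ids = ids,
                 query_id = ids[1], depth = length(sequences), length = L),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns (query: %s)\n",
              x$depth, x$length, x$query_id))
  invisible(x)
}

#' Read an a3m or aligned-FASTA multiple sequence alignment
#'
#' Applies the a3m convention: lowercase letters mark insertions relative to
#' the query and are deleted; \code{"."} is treated as a gap; unknown letters
#' map to the shared gap/unknown symbol on encoding. After insertion removal
#' every row must have the query length.
#'
#' @param path path to an a3m or aligned FASTA file.
#' @return An \code{\link{msa}} object.
#' @export
read_a3m <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty alignment file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("not FASTA/a3m (first record lacks '>'): ", path)
  rec <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- vapply(strsplit(ids, "[ \t]"), `[`, "", 1)
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 paste, "", collapse = "")
  if (length(seqs) != length(ids)) stop("record without sequence in ", path)
  # a3m: drop lowercase insertion columns, '.' -> '-'
  seqs <- gsub("[a-z]", "", seqs)
  seqs <- gsub("\\.", "-", seqs)
  L <- nchar(seqs[1])
  bad <- which(nchar(seqs) != L)
  if (length(bad)) {
    stop(sprintf(
      "row '%s' has length %d after insertion removal, expected %d (query '%s')",
      ids[bad[1]], nchar(seqs[bad[1]]), L, ids[1]))
  }
  msa(seqs, ids)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an \code{\link{msa}} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  out <- character(2L * aln$depth)
  out[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  out[c(FALSE, TRUE)] <- aln$sequences
  writeLines(out, path)
  invisible(path)
}

#' Encode an alignment as an integer matrix
#'
#' @param aln an \code{\link{msa}} object.
#' @return depth x L integer matrix of states in 1..21.
#' @export
msa_matrix <- function(aln) {
  m <- t(vapply(aln$sequences, encode_sequence,
                integer(aln$length), USE.NAMES = FALSE))
  dim(m) <- c(aln$depth, aln$length)
  m
}
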