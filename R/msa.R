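#' Multiple sequence alignment container
#'
#' A minimal aligned amino-acid alignment: equal-length rows over the 20
#' standard residues plus `-` (gap) and `X` (unknown). This is the input to
#' [build_profile()] and the output of [align_marker()] / [trim_alignment()].
#'
#' @param sequences character vector of aligned rows (equal length).
#' @param labels sequence identifiers; defaults to names of `sequences` or
#'   `seq1`, `seq2`, ...
#' @return An object of class `msa` with elements `sequences` and `labels`.
#' @examples
#' m <- msa(c(a = "AC-D", b = "ACAD"))
#' msa_width(m)
#' @export
msa <- function(sequences, labels = NULL) {
  if (is.null(labels)) {
    labels <- names(sequences) %||% paste0("seq", seq_along(sequences))
  }
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 2) {
    stop("an alignment needs at least 2 rows")
  }
  w <- unique(nchar(sequences))
  if (length(w) != 1) {
    stop("alignment rows differ in length")
  }
  if (w == 0) {
    stop("alignment has zero columns")
  }
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X-]"),
               sequences)
  if (any(bad)) {
    stop("alignment rows contain symbols outside the amino-acid alphabet: ",
         paste(labels[bad], collapse = ", "))
  }
  structure(list(sequences = unname(sequences), labels = as.character(labels)),
            class = "msa")
}

#' @rdname msa
#' @param x an `msa` object.
#' @export
msa_width <- function(x) nchar(x$sequences[1])

#' @rdname msa
#' @export
msa_nrow <- function(x) length(x$sequences)

# alignment as a character matrix (rows x columns)
msa_matrix <- function(x) {
  do.call(rbind, strsplit(x$sequences, "", fixed = TRUE))
}

#' Remove gaps from every alignment row
#'
#' @param x an `msa` object.
#' @return named character vector of ungapped sequences.
#' @export
msa_ungap <- function(x) {
  setNames(gsub("-", "", x$sequences, fixed = TRUE), x$labels)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows x %d columns\n", msa_nrow(x), msa_width(x)))
  invisible(x)
}

#' Read an aligned FASTA file into an `msa`
#'
#' @param path FASTA file of equal-length aligned amino-acid sequences.
#' @return an `msa` object.
#' @export
read_msa_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  msa(as.character(set), labels = names(set))
}

#' Majority-rule consensus over the match columns of an alignment
#'
#' Columns with gap fraction >= 0.5 are skipped (they do not form match
#' states); at each remaining column the most frequent residue wins, ties
#' broken alphabetically.
#'
#' @param x an `msa` object.
#' @return a single ungapped consensus sequence.
#' @export
msa_consensus <- function(x) {
  m <- msa_matrix(x)
  keep <- colMeans(m == "-") < 0.5
  cons <- vapply(which(keep), function(j) {
    col <- m[, j]
    col <- col[col %in% AA_ALPHABET]
    if (length(col) == 0) return("X")
    tab <- table(col)
    names(tab)[which.max(tab)]  # ties: first alphabetically (table is sorted)
  }, character(1))
  paste(cons, collapse = "")
}
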