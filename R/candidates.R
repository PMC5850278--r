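# Candidate gene regions: the unit scored against lineage profiles.
# Candidates are kept in a plain data.frame with columns
#   id, aa, source_seq, strand (+/-/NA), nt_from, nt_to, frame (0-2/NA).
# Nucleotide coordinates are 1-based inclusive on the forward strand of the
# source record and include the terminating stop codon when one is present.

empty_candidates <- function() {
  data.frame(id = character(0), aa = character(0), source_seq = character(0),
             strand = character(0), nt_from = integer(0), nt_to = integer(0),
             frame = integer(0), stringsAsFactors = FALSE)
}

#' Candidates from an amino-acid FASTA (protein mode)
#'
#' One candidate per record; terminal `*` stop symbols are stripped. Records
#' with internal `*` are kept verbatim with a warning (they are not split).
#'
#' @param x an `AAStringSet` or named character vector of protein sequences.
#' @return Candidate data.frame (nucleotide coordinates are `NA` in protein
#'   mode).
#' @export
extract_candidates_protein <- function(x) {
  if (methods::is(x, "AAStringSet")) x <- setNames(as.character(x), names(x))
  if (length(x) == 0) return(empty_candidates())
  ids <- names(x)
  if (is.null(ids) || anyNA(ids)) stop("protein records must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(x) == 0) return(empty_candidates())
  aa <- toupper(unname(x))
  aa <- sub("\\*+$", "", aa)
  internal <- grepl("*", aa, fixed = TRUE)
  if (any(internal)) {
    warning("internal stop symbol in record(s) ",
            paste(ids[internal], collapse = ", "), "; kept verbatim")
  }
  data.frame(id = ids, aa = aa, source_seq = ids,
             strand = NA_character_, nt_from = NA_integer_,
             nt_to = NA_integer_, frame = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Six-frame ORF extraction from one nucleotide record
#'
#' Translates all six reading frames with the standard genetic code
#' (ambiguous codons become `X`) and reports every stop-free stretch
#' (stop-to-stop or to the sequence end; an initial Met is not required) of
#' at least `min_aa` residues. Coordinates are 1-based inclusive on the
#' forward strand of the source record and include the terminating stop
#' codon when present; reverse-strand ORFs carry strand `-`.
#'
#' @param record a `DNAString` or single character string.
#' @param id source record identifier.
#' @param min_aa minimum ORF length in residues; the pipeline defaults are
#'   50 (genome) and 30 (transcriptome).
#' @return Candidate data.frame (possibly zero rows).
#' @export
six_frame_orfs <- function(record, id, min_aa = 50) {
  if (!is.numeric(min_aa) || min_aa < 1) stop("min_aa must be >= 1")
  dna <- if (methods::is(record, "DNAString")) record else
    Biostrings::DNAString(toupper(as.character(record)))
  L <- length(dna)
  if (L < 3 * min_aa) return(empty_candidates())
  plain <- sum(Biostrings::letterFrequency(dna, c("A", "C", "G", "T", "N")))
  if (plain < 0.9 * L) {
    warning(sprintf("record '%s': more than 10%% of symbols outside ACGTN", id))
  }
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else Biostrings::reverseComplement(dna)
    for (f in 0:2) {
      w <- ((L - f) %/% 3) * 3
      if (w < 3 * min_aa) next
      pep <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::subseq(s, start = f + 1, width = w),
                              if.fuzzy.codon = "X", no.init.codon = TRUE)))
      runs <- gregexpr("[^*]+", pep)[[1]]
      if (runs[1] == -1) next
      lens <- attr(runs, "match.length")
      keep <- lens >= min_aa
      for (r in which(keep)) {
        a <- runs[r]
        b <- a + lens[r] - 1
        aa <- substr(pep, a, b)
        stop_after <- b < nchar(pep)
        from_s <- f + 3 * (a - 1) + 1
        to_s <- f + 3 * b + if (stop_after) 3 else 0
        if (strand == "+") {
          nt_from <- from_s; nt_to <- to_s
        } else {
          nt_from <- L - to_s + 1; nt_to <- L - from_s + 1
        }
        out[[length(out) + 1]] <- data.frame(
          id = sprintf("%s:%d-%d:%s:f%d", id, nt_from, nt_to, strand, f),
          aa = aa, source_seq = id, strand = strand,
          nt_from = as.integer(nt_from), nt_to = as.integer(nt_to),
          frame = as.integer(f), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_candidates())
  do.call(rbind, out)
}

#' @rdname six_frame_orfs
#' @param records a `DNAStringSet` or named character vector; ORFs are
#'   extracted per record and concatenated.
#' @export
extract_candidates_nucleotide <- function(records, min_aa = 50) {
  if (!methods::is(records, "DNAStringSet")) {
    records <- Biostrings::DNAStringSet(
      setNames(toupper(as.character(records)), names(records)))
  }
  if (is.null(names(records))) stop("nucleotide records must be named")
  res <- lapply(seq_along(records), function(i) {
    six_frame_orfs(records[[i]], names(records)[i], min_aa = min_aa)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty_candidates() else out
}

#' Re-translate a genomic region into its peptide
#'
#' Extracts `nt_from..nt_to` from the forward strand of the source record,
#' reverse-complements when strand is `-`, translates, and strips a trailing
#' stop. Used to verify that reported coordinates reproduce the scored
#' peptide.
#'
#' @param record source `DNAString` or character string.
#' @param nt_from,nt_to 1-based inclusive forward-strand coordinates.
#' @param strand `"+"` or `"-"`.
#' @return amino-acid sequence (character).
#' @export
translate_region <- function(record, nt_from, nt_to, strand = "+") {
  dna <- if (methods::is(record, "DNAString")) record else
    Biostrings::DNAString(toupper(as.character(record)))
  sub <- Biostrings::subseq(dna, start = nt_from, end = nt_to)
  if (strand == "-") sub <- Biostrings::reverseComplement(sub)
  pep <- as.character(suppressWarnings(
    Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE)))
  sub("\\*$", "", pep)
}

# TRUE when a sequence set looks nucleotide (>90% ACGTN)
looks_nucleotide <- function(seqs) {
  s <- paste(toupper(as.character(seqs)), collapse = "")
  if (nchar(s) == 0) return(FALSE)
  n_plain <- nchar(gsub("[^ACGTN]", "", s))
  n_plain > 0.9 * nchar(s)
}
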