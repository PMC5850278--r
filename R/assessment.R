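# Classification engine: score candidates against every lineage profile,
# assign each candidate to its best ortholog, and grade every ortholog in
# the set as complete_single / complete_duplicated / fragmented / missing.

BUSCO_STATUSES <- c("complete_single", "complete_duplicated",
                    "fragmented", "missing")

#' Score candidates against every profile of a lineage dataset
#'
#' Each (ortholog, candidate) pair is scored with the local Viterbi
#' algorithm; matches with non-positive bit scores are discarded. A length
#' pre-filter skips candidates shorter than 0.2x or longer than 5x the
#' ortholog's expected length (these cannot reach complete grade and
#' essentially never carry signal).
#'
#' @param candidates candidate data.frame (see
#'   [extract_candidates_protein()] / [six_frame_orfs()]).
#' @param ds a `lineage_dataset`.
#' @param prefilter apply the length pre-filter (default TRUE).
#' @return Match data.frame: one row per retained (busco, candidate) pair
#'   with columns busco_id, candidate id/aa/coordinates, `bits`,
#'   `ali_from`, `ali_to`, `matched_states` and `ungapped_len` (the length
#'   of the profile-aligned target region).
#' @export
search <- function(candidates, ds, prefilter = TRUE) {
  stopifnot(inherits(ds, "lineage_dataset"))
  if (ds$n_buscos == 0) stop("empty lineage dataset")
  out <- list()
  if (nrow(candidates) > 0) {
    lens <- nchar(candidates$aa)
    codes <- lapply(candidates$aa, aa_codes)
    for (i in seq_len(ds$n_buscos)) {
      id <- ds$cutoffs$busco_id[i]
      lm <- ds$cutoffs$length_mean[i]
      keep <- if (prefilter) which(lens >= 0.2 * lm & lens <= 5 * lm) else
        seq_along(lens)
      if (length(keep) == 0) next
      tab <- hmm_log_tables(ds$profiles[[id]])
      for (ci in keep) {
        sc <- .viterbi_dp(tab$lmatch, tab$ltrans, codes[[ci]], FALSE)
        if (sc$bits <= 0) next
        row <- candidates[ci, , drop = FALSE]
        out[[length(out) + 1]] <- data.frame(
          busco_id = id, candidate_id = row$id, aa = row$aa,
          source_seq = row$source_seq, strand = row$strand,
          nt_from = row$nt_from, nt_to = row$nt_to, frame = row$frame,
          bits = sc$bits, ali_from = sc$ali_from, ali_to = sc$ali_to,
          matched_states = sc$matched_states,
          ungapped_len = sc$ali_to - sc$ali_from + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_matches())
  m <- do.call(rbind, out)
  rownames(m) <- NULL
  m
}

empty_matches <- function() {
  data.frame(busco_id = character(0), candidate_id = character(0),
             aa = character(0), source_seq = character(0),
             strand = character(0), nt_from = integer(0), nt_to = integer(0),
             frame = integer(0), bits = numeric(0), ali_from = integer(0),
             ali_to = integer(0), matched_states = integer(0),
             ungapped_len = integer(0), stringsAsFactors = FALSE)
}

# distinct-locus test: different source records are always distinct; on the
# same record, loci are distinct when nucleotide overlap is < 50% of the
# shorter span. Protein-mode matches on the same record share the locus.
same_locus <- function(a, b) {
  if (a$source_seq != b$source_seq) return(FALSE)
  if (is.na(a$nt_from) || is.na(b$nt_from)) return(TRUE)
  ov <- min(a$nt_to, b$nt_to) - max(a$nt_from, b$nt_from) + 1
  if (ov <= 0) return(FALSE)
  ov >= 0.5 * min(a$nt_to - a$nt_from + 1, b$nt_to - b$nt_from + 1)
}

# count distinct loci among complete-grade matches (greedy clustering)
n_distinct_loci <- function(m) {
  if (nrow(m) == 0) return(0L)
  reps <- list(m[1, , drop = FALSE])
  for (i in seq_len(nrow(m))[-1]) {
    row <- m[i, , drop = FALSE]
    if (!any(vapply(reps, function(r) same_locus(r, row), logical(1)))) {
      reps[[length(reps) + 1]] <- row
    }
  }
  length(reps)
}

#' Classify every ortholog of a lineage dataset from its matches
#'
#' Each candidate is consumed by at most one ortholog: when a candidate
#' matches several profiles it is assigned to the highest-scoring pairing
#' (ties broken by ortholog id, then candidate id). Per ortholog, a match is
#' complete-grade when its bits reach the score cutoff and its aligned
#' length falls inside the expected length window (mean +/- max(2 sigma,
#' 0.15 mean), boundaries inclusive), and fragment-grade when the score
#' passes but the length falls outside. Status: `complete_duplicated` with
#' >= 2 complete-grade matches on distinct loci, `complete_single` with
#' exactly 1, `fragmented` with fragment-grade evidence only, else
#' `missing`.
#'
#' @param matches match data.frame from [search()].
#' @param ds the `lineage_dataset` the matches were scored against.
#' @return A `classification_set`: named list (one entry per ortholog of
#'   `ds`, sorted by id) of lists with `busco_id`, `status` and `matches`
#'   (the cutoff-passing matches; empty exactly when missing).
#' @export
classify <- function(matches, ds) {
  stopifnot(inherits(ds, "lineage_dataset"))
  ids <- ds$cutoffs$busco_id
  if (nrow(matches) > 0) {
    unknown <- setdiff(unique(matches$busco_id), ids)
    if (length(unknown) > 0) {
      stop("match references ortholog id(s) absent from the dataset: ",
           paste(unknown, collapse = ", "))
    }
    # greedy one-candidate-one-ortholog assignment by descending bits
    ord <- order(-matches$bits, matches$busco_id, matches$candidate_id)
    matches <- matches[ord, , drop = FALSE]
    matches <- matches[!duplicated(matches$candidate_id), , drop = FALSE]
  }
  results <- vector("list", length(ids))
  names(results) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    co <- ds$cutoffs[i, ]
    m <- matches[matches$busco_id == id, , drop = FALSE]
    m <- m[m$bits >= co$score_cutoff, , drop = FALSE]
    if (nrow(m) == 0) {
      results[[i]] <- list(busco_id = id, status = "missing",
                           matches = empty_matches())
      next
    }
    rng <- length_range(co$length_mean, co$length_sigma)
    complete <- m$ungapped_len >= rng[1] & m$ungapped_len <= rng[2]
    cm <- m[complete, , drop = FALSE]
    cm <- cm[order(-cm$bits, cm$candidate_id), , drop = FALSE]
    status <- if (nrow(cm) >= 2 && n_distinct_loci(cm) >= 2) {
      "complete_duplicated"
    } else if (nrow(cm) >= 1) {
      "complete_single"
    } else {
      "fragmented"
    }
    keep <- if (status == "fragmented") m else cm
    rownames(keep) <- NULL
    results[[i]] <- list(busco_id = id, status = status, matches = keep)
  }
  structure(results, class = "classification_set")
}

#' @export
print.classification_set <- function(x, ...) {
  st <- vapply(x, `[[`, character(1), "status")
  cat(sprintf("classification_set: %d orthologs (%s)\n", length(x),
              paste(sprintf("%s=%d", BUSCO_STATUSES,
                            as.integer(table(factor(st, BUSCO_STATUSES)))),
                    collapse = ", ")))
  invisible(x)
}

#' Summarize a classification into C/S/D/F/M counts and percentages
#'
#' Percentages are one-decimal, rounded half away from zero. The one-line
#' summary string follows the familiar
#' `C:..%[S:..%,D:..%],F:..%,M:..%,n:..` style.
#'
#' @param results a `classification_set`.
#' @return A `busco_summary`: list with counts `C`, `S`, `D`, `F`, `M`, `n`,
#'   percentages `pC`, `pS`, `pD`, `pF`, `pM` and `one_line` (the summary
#'   string).
#' @export
summarize_assessment <- function(results) {
  stopifnot(inherits(results, "classification_set"))
  n <- length(results)
  if (n == 0) stop("no orthologs to summarize")
  st <- vapply(results, `[[`, character(1), "status")
  S <- sum(st == "complete_single")
  D <- sum(st == "complete_duplicated")
  F_ <- sum(st == "fragmented")
  M <- sum(st == "missing")
  pct <- function(k) round_half_away(100 * k / n, 1)
  s <- list(C = S + D, S = S, D = D, F = F_, M = M, n = n,
            pC = pct(S + D), pS = pct(S), pD = pct(D), pF = pct(F_),
            pM = pct(M))
  s$one_line <- sprintf("C:%.1f%%[S:%.1f%%,D:%.1f%%],F:%.1f%%,M:%.1f%%,n:%d",
                        s$pC, s$pS, s$pD, s$pF, s$pM, s$n)
  structure(s, class = "busco_summary")
}

#' @export
print.busco_summary <- function(x, ...) {
  cat(x$one_line, "\n")
  invisible(x)
}

#' Run a complete assessment
#'
#' Genome mode extracts six-frame ORFs from every record; transcriptome
#' mode does the same but keeps only each transcript's best-scoring
#' candidate per ortholog; protein mode takes records verbatim. Candidates
#' are then scored against the lineage profiles, classified, and
#' summarized. When `out_dir` is given, `full_table.tsv`,
#' `short_summary.txt` and per-status FASTA files are written.
#'
#' Note on genome mode: genes are recovered from unspliced reading frames,
#' so intron-containing genes surface as fragments; the mode is exact for
#' intronless gene structures.
#'
#' @param input FASTA path, or a named character vector /
#'   `XStringSet` of sequences.
#' @param mode `"genome"`, `"proteins"` or `"transcriptome"`.
#' @param ds a `lineage_dataset` or dataset directory path.
#' @param out_dir output directory (optional; no files written when NULL).
#' @param min_aa minimum ORF length for nucleotide modes; defaults to 50
#'   (genome) or 30 (transcriptome).
#' @return A `busco_run`: list with `mode`, `dataset` (name), `results`
#'   (a `classification_set`), `summary` (a `busco_summary`), `candidates`
#'   and `sources` (the input sequences, nucleotide modes only).
#' @export
run_assessment <- function(input, mode = c("genome", "proteins",
                                           "transcriptome"),
                           ds, out_dir = NULL, min_aa = NULL) {
  mode <- match.arg(mode)
  if (is.character(ds) && length(ds) == 1) ds <- read_dataset(ds)
  stopifnot(inherits(ds, "lineage_dataset"))
  seqs <- load_sequences(input, mode)
  if (length(seqs) == 0) stop("no sequences in input")
  if (mode == "proteins" && looks_nucleotide(seqs)) {
    stop("input looks like nucleotide sequence; use mode = 'genome' or 'transcriptome'")
  }
  if (mode != "proteins" && !looks_nucleotide(seqs)) {
    stop("input does not look like nucleotide sequence; use mode = 'proteins'")
  }
  if (is.null(min_aa)) min_aa <- if (mode == "transcriptome") 30 else 50

  if (mode == "proteins") {
    cands <- extract_candidates_protein(seqs)
    matches <- search(cands, ds)
  } else {
    cands <- extract_candidates_nucleotide(seqs, min_aa = min_aa)
    matches <- search(cands, ds)
    if (mode == "transcriptome" && nrow(matches) > 0) {
      # one candidate per (transcript, ortholog): keep the best-scoring one
      key <- paste(matches$source_seq, matches$busco_id, sep = "\r")
      ord <- order(-matches$bits, matches$candidate_id)
      matches <- matches[ord, , drop = FALSE]
      matches <- matches[!duplicated(key[ord]), , drop = FALSE]
    }
  }
  results <- classify(matches, ds)
  summary <- summarize_assessment(results)
  run <- structure(list(mode = mode, dataset = ds$name, results = results,
                        summary = summary, candidates = cands,
                        sources = if (mode == "proteins") NULL else seqs),
                   class = "busco_run")
  if (!is.null(out_dir)) write_run_outputs(run, ds, out_dir)
  run
}

#' @export
print.busco_run <- function(x, ...) {
  cat(sprintf("busco_run (%s mode, dataset '%s')\n", x$mode, x$dataset))
  cat(" ", x$summary$one_line, "\n")
  invisible(x)
}

load_sequences <- function(input, mode) {
  if (is.character(input) && length(input) == 1 && file.exists(input)) {
    set <- if (mode == "proteins") Biostrings::readAAStringSet(input) else
      Biostrings::readDNAStringSet(input)
    return(setNames(as.character(set), sub("\\s.*$", "", names(set))))
  }
  if (methods::is(input, "XStringSet")) {
    return(setNames(as.character(input), names(input)))
  }
  if (is.character(input)) return(input)
  stop("input must be a FASTA path, an XStringSet or a named character vector")
}

#' Full-table rows of an assessment
#'
#' @param run a `busco_run`.
#' @return data.frame with one row per retained match (plus one row per
#'   missing ortholog): busco_id, status, sequence, start, end, strand,
#'   score_bits, length.
#' @export
full_table <- function(run) {
  stopifnot(inherits(run, "busco_run"))
  rows <- lapply(run$results, function(r) {
    if (r$status == "missing" || nrow(r$matches) == 0) {
      return(data.frame(busco_id = r$busco_id, status = r$status,
                        sequence = "", start = NA_integer_, end = NA_integer_,
                        strand = "", score_bits = NA_real_,
                        length = NA_integer_, stringsAsFactors = FALSE))
    }
    m <- r$matches
    data.frame(busco_id = r$busco_id, status = r$status,
               sequence = m$source_seq, start = m$nt_from, end = m$nt_to,
               strand = ifelse(is.na(m$strand), "", m$strand),
               score_bits = m$bits, length = m$ungapped_len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_run_outputs <- function(run, ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ft <- full_table(run)
  con <- file(file.path(out_dir, "full_table.tsv"), "w")
  writeLines(c(sprintf("# microbusco full table, dataset '%s', n = %d",
                       ds$name, ds$n_buscos),
               paste(colnames(ft), collapse = "\t")), con)
  # deterministic score formatting
  ft2 <- ft
  ft2$score_bits <- ifelse(is.na(ft$score_bits), "",
                           sprintf("%.4f", ft$score_bits))
  body <- do.call(paste, c(lapply(ft2, function(col) {
    col[is.na(col)] <- ""
    as.character(col)
  }), sep = "\t"))
  writeLines(body, con)
  close(con)

  s <- run$summary
  writeLines(c(sprintf("# microbusco short summary, dataset '%s', mode %s",
                       ds$name, run$mode),
               s$one_line,
               sprintf("\t%d\tComplete BUSCOs (C)", s$C),
               sprintf("\t%d\tComplete and single-copy BUSCOs (S)", s$S),
               sprintf("\t%d\tComplete and duplicated BUSCOs (D)", s$D),
               sprintf("\t%d\tFragmented BUSCOs (F)", s$F),
               sprintf("\t%d\tMissing BUSCOs (M)", s$M),
               sprintf("\t%d\tTotal BUSCO groups searched", s$n),
               "# note: duplicated orthologs can reflect uncollapsed heterozygous alleles rather than true duplications"),
             file.path(out_dir, "short_summary.txt"))

  # per-status sequence FASTAs
  by_status <- list(single_copy = "complete_single",
                    duplicated = "complete_duplicated",
                    fragmented = "fragmented")
  for (nm in names(by_status)) {
    recs <- character(0)
    for (r in run$results) {
      if (r$status != by_status[[nm]] || nrow(r$matches) == 0) next
      m <- r$matches
      recs <- c(recs, setNames(m$aa, paste0(r$busco_id, "|", m$candidate_id)))
    }
    if (length(recs) > 0) {
      Biostrings::writeXStringSet(Biostrings::AAStringSet(recs),
                                  file.path(out_dir, paste0(nm, ".faa")))
    }
  }
  invisible(out_dir)
}

# GFF3 attribute escaping (reserved characters percent-encoded)
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

#' Export complete gene models for gene-predictor training
#'
#' Writes the gene models of orthologs identified as complete (single-copy
#' or duplicated) in a genome-mode run as GFF3, a GenBank-flavored flat
#' file, and a nucleotide FASTA, the inputs expected by ab initio gene
#' predictor training pipelines. Coordinates are 1-based inclusive on the
#' forward strand; each exported region re-translates to its matched
#' peptide.
#'
#' @param run a genome-mode `busco_run`.
#' @param out_dir output directory.
#' @return data.frame of exported models (busco_id, sequence, start, end,
#'   strand), invisibly.
#' @export
export_training_models <- function(run, out_dir) {
  stopifnot(inherits(run, "busco_run"))
  if (run$mode != "genome") stop("training-model export requires a genome-mode run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (r in run$results) {
    if (!r$status %in% c("complete_single", "complete_duplicated")) next
    m <- r$matches
    for (i in seq_len(nrow(m))) {
      rows[[length(rows) + 1]] <- cbind(busco_id = r$busco_id,
                                        m[i, , drop = FALSE])
    }
  }
  gff_path <- file.path(out_dir, "training_models.gff3")
  gbk_path <- file.path(out_dir, "training_models.gbk")
  fna_path <- file.path(out_dir, "training_models.fna")
  if (length(rows) == 0) {
    warning("no complete orthologs; writing empty training files")
    writeLines("##gff-version 3", gff_path)
    writeLines(character(0), gbk_path)
    writeLines(character(0), fna_path)
    return(invisible(data.frame()))
  }
  tab <- do.call(rbind, rows)
  tab$busco_id <- as.character(tab$busco_id)

  gff <- c("##gff-version 3",
           sprintf("%s\tmicrobusco\tgene\t%d\t%d\t%.4f\t%s\t.\tID=%s;Name=%s",
                   tab$source_seq, tab$nt_from, tab$nt_to, tab$bits,
                   tab$strand, gff3_escape(paste0(tab$busco_id, "_",
                                                  seq_len(nrow(tab)))),
                   gff3_escape(tab$busco_id)))
  writeLines(gff, gff_path)

  gbk <- character(0)
  fna <- character(0)
  fna_names <- character(0)
  for (i in seq_len(nrow(tab))) {
    nt <- as.character(Biostrings::subseq(
      Biostrings::DNAString(run$sources[[tab$source_seq[i]]]),
      start = tab$nt_from[i], end = tab$nt_to[i]))
    len <- nchar(nt)
    loc <- sprintf("%d..%d", 1L, len)
    if (tab$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    origin <- vapply(seq(1, len, by = 60), function(s) {
      chunk <- substr(nt, s, min(s + 59, len))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      sprintf("%9d %s", s, paste(tolower(blocks), collapse = " "))
    }, character(1))
    coding <- if (tab$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    } else nt
    gbk <- c(gbk,
             sprintf("LOCUS       %s_%d %d bp    DNA", tab$busco_id[i], i, len),
             sprintf("DEFINITION  %s gene model from %s:%d-%d(%s)",
                     tab$busco_id[i], tab$source_seq[i], tab$nt_from[i],
                     tab$nt_to[i], tab$strand[i]),
             "FEATURES             Location/Qualifiers",
             sprintf("     gene            %s", loc),
             sprintf("                     /gene=\"%s\"", tab$busco_id[i]),
             "ORIGIN", origin, "//")
    fna <- c(fna, coding)   # coding orientation: re-translates to the peptide
    fna_names <- c(fna_names, sprintf("%s|%s:%d-%d:%s", tab$busco_id[i],
                                      tab$source_seq[i], tab$nt_from[i],
                                      tab$nt_to[i], tab$strand[i]))
  }
  writeLines(gbk, gbk_path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(fna, fna_names)), fna_path)
  invisible(data.frame(busco_id = tab$busco_id, sequence = tab$source_seq,
                       start = tab$nt_from, end = tab$nt_to,
                       strand = tab$strand, stringsAsFactors = FALSE))
}
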