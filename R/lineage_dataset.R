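#' Read an orthology table
#'
#' Rows are ortholog groups, columns are species, cells are gene-copy
#' counts. Tab-separated, `#` comment lines allowed, first column holds the
#' group identifier.
#'
#' @param path TSV file.
#' @return An `orthology_table`: list with `species` (character) and
#'   `counts` (integer matrix, rownames = group ids).
#' @export
read_orthology_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   row.names = 1, check.names = FALSE)
  orthology_table(as.matrix(df))
}

#' @rdname read_orthology_table
#' @param counts integer matrix of copy counts (rows = groups,
#'   columns = species, dimnames required).
#' @export
orthology_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("orthology table needs group and species names")
  }
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("copy counts must be nonnegative integers (a count is required for every species)")
  }
  structure(list(species = colnames(counts), counts = counts),
            class = "orthology_table")
}

#' Delineate near-universal single-copy ortholog groups
#'
#' A group qualifies when the fraction of species carrying it in exactly one
#' copy is at least `universality`. Raising `universality` can only shrink
#' the selection.
#'
#' @param table an `orthology_table`.
#' @param universality required single-copy fraction in (0, 1]; default 0.9.
#' @return Sorted character vector of qualifying group ids.
#' @export
delineate <- function(table, universality = 0.9) {
  stopifnot(inherits(table, "orthology_table"))
  if (!is.numeric(universality) || universality <= 0 || universality > 1) {
    stop("universality must be in (0, 1]")
  }
  if (nrow(table$counts) == 0) return(character(0))
  frac <- rowMeans(table$counts == 1L)
  sort(rownames(table$counts)[frac >= universality])
}

#' Derive score and length cutoffs for one ortholog group
#'
#' Every member sequence (the ungapped orthologs of the group) is scored
#' against the group's profile in local mode; the score cutoff is a fixed
#' fraction (default one quarter) of the mean member score, so truncated
#' copies of a true ortholog still clear it while unrelated sequences stay
#' far below. Expected length is summarized by the mean and the n-1 standard
#' deviation of the ungapped member lengths.
#'
#' @param hmm the group's `profile_hmm`.
#' @param member_sequences character vector of >= 2 ungapped amino-acid
#'   member sequences.
#' @param score_fraction fraction of the mean member score used as the
#'   score cutoff; default 0.25.
#' @return A `busco_cutoffs`: list with `score_cutoff` (bits), `length_mean`
#'   and `length_sigma` (residues).
#' @export
derive_cutoffs <- function(hmm, member_sequences, score_fraction = 0.25) {
  stopifnot(inherits(hmm, "profile_hmm"))
  member_sequences <- as.character(member_sequences)
  if (length(member_sequences) < 2) {
    stop("need at least 2 member sequences to derive cutoffs")
  }
  scores <- vapply(member_sequences,
                   function(s) viterbi_score(hmm, s, mode = "local")$bits,
                   numeric(1), USE.NAMES = FALSE)
  mean_score <- mean(scores)
  cutoff <- score_fraction * mean_score
  if (!is.finite(cutoff) || cutoff <= 0) {
    stop("member sequences do not score positively against the profile")
  }
  lens <- nchar(member_sequences)
  structure(list(score_cutoff = cutoff,
                 length_mean = mean(lens),
                 length_sigma = sd(lens)),
            class = "busco_cutoffs")
}

# accepted length window: mean +/- max(2*sigma, 0.15*mean)
length_range <- function(length_mean, length_sigma) {
  hw <- max(2 * length_sigma, 0.15 * length_mean)
  c(length_mean - hw, length_mean + hw)
}

#' Build a lineage dataset from an orthology table and per-group alignments
#'
#' Delineates the near-universal single-copy groups, builds one profile HMM
#' per group from its alignment, and derives score/length cutoffs from the
#' alignment's ungapped rows.
#'
#' @param table an `orthology_table`.
#' @param msas named list of [msa] objects, one per group id (at least the
#'   delineated ones).
#' @param universality single-copy fraction threshold; default 0.9.
#' @param name dataset name.
#' @param pseudocount_weight passed to [build_profile()].
#' @return A `lineage_dataset`: list with `name`, `profiles` (named list of
#'   `profile_hmm`), `cutoffs` (data.frame busco_id / score_cutoff /
#'   length_mean / length_sigma), `n_species`, `n_buscos`.
#' @export
build_dataset <- function(table, msas, universality = 0.9,
                          name = "lineage", pseudocount_weight = 1) {
  stopifnot(inherits(table, "orthology_table"))
  ids <- delineate(table, universality)
  missing_msa <- setdiff(ids, names(msas))
  if (length(missing_msa) > 0) {
    stop("missing MSA for delineated group(s): ",
         paste(missing_msa, collapse = ", "))
  }
  profiles <- list()
  cut_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    hmm <- build_profile(msas[[id]], pseudocount_weight = pseudocount_weight,
                         busco_id = id)
    co <- derive_cutoffs(hmm, msa_ungap(msas[[id]]))
    profiles[[id]] <- hmm
    cut_rows[[i]] <- data.frame(busco_id = id,
                                score_cutoff = co$score_cutoff,
                                length_mean = co$length_mean,
                                length_sigma = co$length_sigma,
                                stringsAsFactors = FALSE)
  }
  cutoffs <- if (length(cut_rows)) do.call(rbind, cut_rows) else
    data.frame(busco_id = character(0), score_cutoff = numeric(0),
               length_mean = numeric(0), length_sigma = numeric(0))
  lineage_dataset(name, profiles, cutoffs, n_species = length(table$species))
}

#' @rdname build_dataset
#' @param profiles named list of `profile_hmm` objects.
#' @param cutoffs data.frame with columns busco_id, score_cutoff,
#'   length_mean, length_sigma.
#' @param n_species number of species the set was delineated from.
#' @export
lineage_dataset <- function(name, profiles, cutoffs, n_species) {
  if (!setequal(names(profiles), cutoffs$busco_id)) {
    stop("profiles and cutoffs must cover the same ortholog ids")
  }
  ord <- order(cutoffs$busco_id)
  cutoffs <- cutoffs[ord, , drop = FALSE]
  rownames(cutoffs) <- NULL
  profiles <- profiles[cutoffs$busco_id]
  if (any(cutoffs$score_cutoff <= 0) || any(cutoffs$length_mean <= 0) ||
      any(cutoffs$length_sigma < 0)) {
    stop("invalid cutoffs (score_cutoff > 0, length_mean > 0, length_sigma >= 0 required)")
  }
  structure(list(name = as.character(name), profiles = profiles,
                 cutoffs = cutoffs, n_species = as.integer(n_species),
                 n_buscos = length(profiles)),
            class = "lineage_dataset")
}

#' @export
print.lineage_dataset <- function(x, ...) {
  cat(sprintf("lineage_dataset '%s': %d BUSCOs from %d species\n",
              x$name, x$n_buscos, x$n_species))
  invisible(x)
}

#' Write / read a lineage dataset directory
#'
#' Layout: `dataset.cfg` (name, n_species, n_buscos), `scores_cutoff.tsv`,
#' `lengths_cutoff.tsv`, and `profiles/<busco_id>.prf` (one serialized
#' profile per ortholog). The round trip preserves every numeric field to
#' 1e-9.
#'
#' @param ds a `lineage_dataset`.
#' @param directory dataset directory (created if needed).
#' @return `write_dataset`: the directory, invisibly. `read_dataset`: a
#'   `lineage_dataset`.
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "lineage_dataset"))
  dir.create(file.path(directory, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  writeLines(c(paste0("name=", ds$name),
               paste0("n_species=", ds$n_species),
               paste0("n_buscos=", ds$n_buscos)),
             file.path(directory, "dataset.cfg"))
  co <- ds$cutoffs
  writeLines(c("# busco_id\tscore_cutoff",
               sprintf("%s\t%.12g", co$busco_id, co$score_cutoff)),
             file.path(directory, "scores_cutoff.tsv"))
  writeLines(c("# busco_id\tlength_mean\tlength_sigma",
               sprintf("%s\t%.12g\t%.12g", co$busco_id, co$length_mean,
                       co$length_sigma)),
             file.path(directory, "lengths_cutoff.tsv"))
  for (id in names(ds$profiles)) {
    cat(serialize_profile(ds$profiles[[id]]),
        file = file.path(directory, "profiles", paste0(id, ".prf")))
  }
  invisible(directory)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  cfg_path <- file.path(directory, "dataset.cfg")
  if (!file.exists(cfg_path)) stop("not a lineage dataset: missing dataset.cfg")
  cfg <- strsplit(readLines(cfg_path), "=", fixed = TRUE)
  cfg <- setNames(vapply(cfg, `[`, character(1), 2),
                  vapply(cfg, `[`, character(1), 1))
  sc_path <- file.path(directory, "scores_cutoff.tsv")
  ln_path <- file.path(directory, "lengths_cutoff.tsv")
  if (!file.exists(sc_path) || !file.exists(ln_path)) {
    stop("missing cutoffs (scores_cutoff.tsv / lengths_cutoff.tsv)")
  }
  sc <- read.table(sc_path, sep = "\t", comment.char = "#",
                   col.names = c("busco_id", "score_cutoff"),
                   stringsAsFactors = FALSE)
  ln <- read.table(ln_path, sep = "\t", comment.char = "#",
                   col.names = c("busco_id", "length_mean", "length_sigma"),
                   stringsAsFactors = FALSE)
  cutoffs <- merge(sc, ln, by = "busco_id")
  prf_files <- list.files(file.path(directory, "profiles"),
                          pattern = "\\.prf$", full.names = TRUE)
  profiles <- lapply(prf_files, function(p) parse_profile(readLines(p)))
  names(profiles) <- vapply(profiles, `[[`, character(1), "busco_id")
  miss <- setdiff(names(profiles), cutoffs$busco_id)
  if (length(miss) > 0) {
    stop("missing cutoff entry for profile(s): ", paste(miss, collapse = ", "))
  }
  ds <- lineage_dataset(cfg[["name"]], profiles, cutoffs,
                        n_species = as.integer(cfg[["n_species"]]))
  if (ds$n_buscos != as.integer(cfg[["n_buscos"]])) {
    stop(sprintf("dataset.cfg declares %s BUSCOs but %d profiles found",
                 cfg[["n_buscos"]], ds$n_buscos))
  }
  ds
}
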