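# Phylogenomic marker extraction: orthologs found complete and single-copy
# in every assessed species are aligned, trimmed, and concatenated into a
# partitioned supermatrix; a neighbor-joining guide tree can be derived
# from p-distances.

#' Select orthologs complete and single-copy in every species
#'
#' @param runs named list (species -> `busco_run`), all assessed against the
#'   same lineage dataset.
#' @return A `marker_set`: list with `busco_ids`, `species` and `sequences`
#'   (per ortholog, a named character vector of the matched peptide in each
#'   species), orthologs sorted by id. Warns when no ortholog is shared.
#' @export
select_universal_markers <- function(runs) {
  if (length(runs) < 3 || is.null(names(runs))) {
    stop("need >= 3 named species runs")
  }
  stopifnot(all(vapply(runs, inherits, logical(1), "busco_run")))
  dsn <- unique(vapply(runs, `[[`, character(1), "dataset"))
  if (length(dsn) != 1) {
    stop("runs used different lineage datasets: ", paste(dsn, collapse = ", "))
  }
  species <- names(runs)
  ids <- sort(names(runs[[1]]$results))
  keep <- ids[vapply(ids, function(id) {
    all(vapply(runs, function(r) {
      res <- r$results[[id]]
      !is.null(res) && res$status == "complete_single"
    }, logical(1)))
  }, logical(1))]
  if (length(keep) == 0) {
    warning("no ortholog is complete single-copy in all species")
  }
  sequences <- lapply(keep, function(id) {
    vapply(species, function(sp) runs[[sp]]$results[[id]]$matches$aa[1],
           character(1))
  })
  names(sequences) <- keep
  structure(list(busco_ids = keep, species = species, sequences = sequences),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d universal single-copy markers x %d species\n",
              length(x$busco_ids), length(x$species)))
  invisible(x)
}

# pairwise global alignment (BLOSUM62, affine gaps open -10 / extend -1)
pairwise_global <- function(a, b) {
  Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                Biostrings::AAString(b),
                                substitutionMatrix = "BLOSUM62",
                                gapOpening = 10, gapExtension = 1,
                                type = "global")
}

#' Align one marker across species (center-star)
#'
#' Progressive center-star alignment: the center is the sequence with the
#' highest summed pairwise global-alignment score (BLOSUM62, affine gap
#' open -10 / extend -1); every other sequence is aligned to the center and
#' the pairwise alignments are merged ("once a gap, always a gap").
#' Removing the gaps from any output row returns the corresponding input.
#'
#' @param sequences named character vector (>= 2 ungapped amino-acid
#'   sequences).
#' @return an [msa] with rows in input order.
#' @export
align_marker <- function(sequences) {
  sequences <- unlist(sequences)
  labels <- names(sequences) %||% paste0("seq", seq_along(sequences))
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n < 2) stop("need >= 2 sequences to align")
  if (any(nchar(sequences) == 0)) stop("empty sequence")

  if (length(unique(sequences)) == 1) {
    return(msa(sequences, labels = labels))
  }
  score_sum <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sc <- Biostrings::score(pairwise_global(sequences[i], sequences[j]))
      score_sum[i] <- score_sum[i] + sc
      score_sum[j] <- score_sum[j] + sc
    }
  }
  ci <- which.max(score_sum)
  center <- sequences[ci]
  Lc <- nchar(center)
  others <- setdiff(seq_len(n), ci)

  # per sequence: insertion runs between center residues (slot r holds
  # residues placed before center residue r), and the character aligned to
  # each center residue
  ins <- vector("list", n)
  ali <- vector("list", n)
  for (i in others) {
    pa <- pairwise_global(center, sequences[i])
    pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    ps <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ins_i <- vector("list", Lc + 1)
    ali_i <- character(Lc)
    r <- 0L
    for (c in seq_along(pc)) {
      if (pc[c] == "-") {
        ins_i[[r + 1L]] <- c(ins_i[[r + 1L]], ps[c])
      } else {
        r <- r + 1L
        ali_i[r] <- ps[c]
      }
    }
    ins[[i]] <- ins_i
    ali[[i]] <- ali_i
  }
  ins[[ci]] <- rep(list(character(0)), Lc + 1)
  ali[[ci]] <- strsplit(center, "")[[1]]

  max_ins <- vapply(seq_len(Lc + 1), function(s) {
    max(vapply(ins, function(x) length(x[[s]]), integer(1)))
  }, integer(1))
  rows <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (s in seq_len(Lc + 1)) {
      run <- ins[[i]][[s]]
      parts <- c(parts, run, rep("-", max_ins[s] - length(run)))
      if (s <= Lc) parts <- c(parts, ali[[i]][s])
    }
    paste(parts, collapse = "")
  }, character(1))
  msa(rows, labels = labels)
}

#' Drop gap-rich alignment columns
#'
#' Retains exactly the columns whose gap fraction is at most
#' `max_gap_fraction` (so a 50% gappy column survives the default), in
#' their original order. Idempotent.
#'
#' @param msa an [msa].
#' @param max_gap_fraction maximum tolerated gap fraction per column;
#'   default 0.5.
#' @return the trimmed [msa]; if every column is removed, a zero-column
#'   `msa` is returned with a warning.
#' @export
trim_alignment <- function(msa, max_gap_fraction = 0.5) {
  stopifnot(inherits(msa, "msa"))
  m <- msa_matrix(msa)
  keep <- colMeans(m == "-") <= max_gap_fraction
  if (!any(keep)) {
    warning("all alignment columns removed")
    return(structure(list(sequences = rep("", msa_nrow(msa)),
                          labels = msa$labels), class = "msa"))
  }
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  structure(list(sequences = unname(rows), labels = msa$labels),
            class = "msa")
}

#' Concatenate per-marker alignments into a supermatrix
#'
#' Markers are concatenated in sorted ortholog-id order; the partition
#' table records each marker's 1-based inclusive column range, and the
#' partitions tile the full supermatrix length.
#'
#' @param aligned named list (busco_id -> [msa]); all alignments must carry
#'   the same species labels.
#' @return A `supermatrix`: list with `species`, `matrix` (named character
#'   vector of concatenated rows) and `partitions` (data.frame busco_id /
#'   start / end).
#' @export
concatenate_markers <- function(aligned) {
  if (length(aligned) == 0 || is.null(names(aligned))) {
    stop("need a named list of alignments")
  }
  ids <- sort(names(aligned))
  species <- sort(aligned[[ids[1]]]$labels)
  rows <- setNames(rep("", length(species)), species)
  parts <- vector("list", length(ids))
  pos <- 0L
  for (i in seq_along(ids)) {
    m <- aligned[[ids[i]]]
    if (!setequal(m$labels, species)) {
      stop("species set mismatch in marker ", ids[i])
    }
    seqs <- setNames(m$sequences, m$labels)[species]
    w <- nchar(seqs[[1]])
    rows <- paste0(rows, seqs)
    parts[[i]] <- data.frame(busco_id = ids[i], start = pos + 1L,
                             end = pos + w, stringsAsFactors = FALSE)
    pos <- pos + w
  }
  names(rows) <- species
  structure(list(species = species, matrix = rows,
                 partitions = do.call(rbind, parts)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d species x %d columns, %d partitions\n",
              length(x$species), nchar(x$matrix[[1]]), nrow(x$partitions)))
  invisible(x)
}

#' Pairwise p-distances between supermatrix rows
#'
#' Fraction of differing positions among columns where neither row carries
#' a gap or `X`.
#'
#' @param sm a `supermatrix` (or any named character vector of equal-length
#'   aligned rows).
#' @return symmetric distance matrix.
#' @export
p_distance <- function(sm) {
  rows <- if (inherits(sm, "supermatrix")) sm$matrix else sm
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ok <- matrix(mat %in% AA_ALPHABET, nrow = nrow(mat))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) {
        stop(sprintf("no comparable positions between '%s' and '%s'",
                     names(rows)[i], names(rows)[j]))
      }
      d[i, j] <- d[j, i] <- mean(mat[i, comp] != mat[j, comp])
    }
  }
  d
}

#' Neighbor-joining guide tree from a supermatrix
#'
#' Neighbor-joining on p-distances; negative branch lengths are clamped to
#' zero. This is a guide tree for inspecting marker signal, not a
#' substitute for maximum-likelihood inference (the emitted partition file
#' lets users run ML externally).
#'
#' @param sm a `supermatrix` with >= 3 species.
#' @return Newick string (single character, terminated by `;`).
#' @export
nj_tree <- function(sm) {
  stopifnot(inherits(sm, "supermatrix"))
  if (length(sm$species) < 3) stop("need >= 3 species for a tree")
  d <- p_distance(sm)
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  ape::write.tree(tr)
}

#' Build a trimmed supermatrix from a marker set
#'
#' Convenience wrapper: center-star aligns every marker, trims gap-rich
#' columns, and concatenates.
#'
#' @param markers a `marker_set` from [select_universal_markers()].
#' @param max_gap_fraction column trimming threshold; default 0.5.
#' @return a `supermatrix`.
#' @export
build_supermatrix <- function(markers, max_gap_fraction = 0.5) {
  stopifnot(inherits(markers, "marker_set"))
  if (length(markers$busco_ids) == 0) stop("empty marker set")
  aligned <- lapply(markers$sequences, function(s) {
    trim_alignment(align_marker(s), max_gap_fraction)
  })
  concatenate_markers(aligned)
}

#' Write supermatrix artifacts
#'
#' Writes the supermatrix as relaxed PHYLIP (`supermatrix.phy`) and aligned
#' FASTA (`supermatrix.faa`), the partition table in RAxML style
#' (`partitions.txt`, `WAG, <busco_id> = start-end`), and, with >= 3
#' species, the NJ guide tree (`nj_tree.nwk`).
#'
#' @param sm a `supermatrix`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_supermatrix <- function(sm, out_dir) {
  stopifnot(inherits(sm, "supermatrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  len <- nchar(sm$matrix[[1]])
  writeLines(c(sprintf("%d %d", length(sm$species), len),
               sprintf("%s  %s", sm$species, sm$matrix)),
             file.path(out_dir, "supermatrix.phy"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sm$matrix),
                              file.path(out_dir, "supermatrix.faa"))
  writeLines(sprintf("WAG, %s = %d-%d", sm$partitions$busco_id,
                     sm$partitions$start, sm$partitions$end),
             file.path(out_dir, "partitions.txt"))
  if (length(sm$species) >= 3) {
    writeLines(nj_tree(sm), file.path(out_dir, "nj_tree.nwk"))
  }
  invisible(out_dir)
}
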