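# Seeded synthetic lineages and target data sets with planted ground truth.
# Ortholog families are simulated over a star or species tree by per-site
# substitution; targets plant each ortholog per its assigned status
# (complete single-copy, duplicated copies, an N-terminal fragment, or
# absent) so every pipeline stage can be checked against known truth.

#' Specify a synthetic fixture
#'
#' @param n_buscos number of ortholog groups.
#' @param n_species number of species in the simulated lineage.
#' @param divergence per-site substitution probability from the ancestral
#'   protein (star model) in `[0, 0.95]`.
#' @param seed RNG seed; all outputs are byte-deterministic given the spec.
#' @param planted named character vector busco_id -> status (statuses
#'   `complete_single`, `complete_duplicated`, `fragmented`, `missing`),
#'   covering every ortholog exactly once. Defaults to all
#'   `complete_single`. See [planted_statuses()].
#' @param gene_length_range ancestral protein length range in residues.
#' @param genome_mode plant targets as nucleotide contigs (genes embedded
#'   intronless in random intergenic background) instead of proteins.
#' @param tree optional `ape` phylo whose tip labels name the species;
#'   sequences then evolve along its branches with per-site substitution
#'   probability equal to the branch length, instead of the star model.
#' @param dup_copies copies planted for duplicated orthologs (default 2).
#' @param frag_fraction N-terminal fraction kept for fragmented orthologs
#'   (default 0.4).
#' @param indel_rate per-site gap probability added to lineage alignments
#'   (default 0: alignments are gapless and trivially exact).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_buscos, n_species, divergence = 0.1, seed = 1,
                         planted = NULL,
                         gene_length_range = c(150, 250),
                         genome_mode = FALSE, tree = NULL,
                         dup_copies = 2, frag_fraction = 0.4,
                         indel_rate = 0) {
  if (divergence < 0) stop("divergence must be nonnegative")
  if (divergence > 0.95) stop("divergence > 0.95: substitution saturation")
  ids <- sprintf("busco%03d", seq_len(n_buscos))
  if (is.null(planted)) {
    planted <- setNames(rep("complete_single", n_buscos), ids)
  }
  if (!setequal(names(planted), ids) || length(planted) != n_buscos) {
    stop("planted statuses must cover every ortholog exactly once")
  }
  if (!all(planted %in% BUSCO_STATUSES)) {
    stop("unknown planted status: ",
         paste(setdiff(planted, BUSCO_STATUSES), collapse = ", "))
  }
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
    if (length(tree$tip.label) != n_species) {
      stop("tree tip count must equal n_species")
    }
  }
  structure(list(n_buscos = n_buscos, n_species = n_species,
                 divergence = divergence, seed = as.integer(seed),
                 planted = planted[ids],
                 gene_length_range = gene_length_range,
                 genome_mode = genome_mode, tree = tree,
                 dup_copies = dup_copies, frag_fraction = frag_fraction,
                 indel_rate = indel_rate),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @param n_single,n_dup,n_frag,n_missing category sizes; statuses are
#'   assigned to `busco001..` in this order.
#' @export
planted_statuses <- function(n_single, n_dup = 0, n_frag = 0, n_missing = 0) {
  n <- n_single + n_dup + n_frag + n_missing
  setNames(rep(c("complete_single", "complete_duplicated", "fragmented",
                 "missing"),
               c(n_single, n_dup, n_frag, n_missing)),
           sprintf("busco%03d", seq_len(n)))
}

# substitute each residue independently with probability p (uniform choice
# among the 19 alternatives)
mutate_protein <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  }
  chars
}

#' Simulate an ortholog lineage
#'
#' Draws one random ancestral protein per ortholog group (uniform residues,
#' leading Met, length uniform in `gene_length_range`) and evolves one copy
#' per species: independently per site with probability `divergence` under
#' the star model, or along `spec$tree` branch by branch. With the default
#' `indel_rate = 0` the per-group alignments are the trivially aligned
#' copies (gapless), so profile lengths are exact.
#'
#' @param spec a [fixture_spec()].
#' @return list with `table` (an `orthology_table`, all single-copy),
#'   `msas` (named list of [msa]), `ancestors` (named character) and
#'   `species`.
#' @export
simulate_lineage <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  species <- if (!is.null(spec$tree)) spec$tree$tip.label else
    sprintf("sp%02d", seq_len(spec$n_species))
  ids <- names(spec$planted)
  ancestors <- character(length(ids))
  msas <- vector("list", length(ids))
  names(msas) <- ids
  for (b in seq_along(ids)) {
    len <- sample(seq(spec$gene_length_range[1], spec$gene_length_range[2]), 1)
    anc <- c("M", sample(AA_ALPHABET, len - 1, replace = TRUE))
    ancestors[b] <- paste(anc, collapse = "")
    copies <- if (is.null(spec$tree)) {
      lapply(species, function(sp) mutate_protein(anc, spec$divergence))
    } else {
      evolve_along_tree(anc, spec$tree)[species]
    }
    rows <- vapply(copies, paste, character(1), collapse = "")
    if (spec$indel_rate > 0) {
      rows <- vapply(rows, function(r) {
        ch <- strsplit(r, "")[[1]]
        ch[stats::runif(length(ch)) < spec$indel_rate] <- "-"
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    msas[[b]] <- msa(rows, labels = species)
  }
  names(ancestors) <- ids
  counts <- matrix(1L, nrow = length(ids), ncol = length(species),
                   dimnames = list(ids, species))
  list(table = orthology_table(counts), msas = msas, ancestors = ancestors,
       species = species)
}

# evolve a root sequence down an ape tree; per-branch per-site substitution
# probability = branch length; returns named list of tip sequences (chars)
evolve_along_tree <- function(root_chars, tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- root_chars
  done <- rep(FALSE, nrow(tree$edge))
  while (!all(done)) {
    progressed <- FALSE
    for (e in which(!done)) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      if (!is.null(seqs[[parent]])) {
        seqs[[child]] <- mutate_protein(seqs[[parent]], tree$edge.length[e])
        done[e] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("tree edges do not descend from the root")
  }
  setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

# encode a peptide as nucleotides with uniformly drawn synonymous codons
encode_codons <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  ch <- strsplit(peptide, "")[[1]]
  paste(vapply(ch, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant target sequences with known statuses
#'
#' Builds the target data set matching `spec$planted`: complete single-copy
#' orthologs get one freshly diverged full-length copy, duplicated ones get
#' `dup_copies` copies on distinct records, fragmented ones keep only the
#' N-terminal `frag_fraction`, and missing ones are omitted. In genome mode
#' each copy is codon-encoded (random synonymous codons, terminal stop) and
#' embedded intronless, on a random strand, in a random-nucleotide contig of
#' its own, with its true coordinates recorded.
#'
#' @param spec a [fixture_spec()].
#' @param lineage output of [simulate_lineage()] on the same spec.
#' @param out_dir optional directory; when given, `targets.fasta` and
#'   `truth.tsv` are written.
#' @return list with `targets` (named character; proteins, or contigs in
#'   genome mode), `truth` (data.frame busco_id / planted_status / records /
#'   start / end / strand), `peptides` (per ortholog, the planted peptide
#'   copies) and `mode` (`"proteins"` or `"genome"`).
#' @export
plant_targets <- function(spec, lineage, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 10007L)
  lens <- vapply(lineage$msas, function(m) mean(nchar(msa_ungap(m))),
                 numeric(1))
  sigmas <- vapply(lineage$msas, function(m) sd(nchar(msa_ungap(m))),
                   numeric(1))
  targets <- character(0)
  truth <- list()
  peptides <- list()
  for (id in names(spec$planted)) {
    status <- spec$planted[[id]]
    anc <- strsplit(lineage$ancestors[[id]], "")[[1]]
    n_copies <- switch(status, complete_single = 1L, fragmented = 1L,
                       complete_duplicated = as.integer(spec$dup_copies),
                       missing = 0L)
    if (status == "fragmented") {
      rng <- length_range(lens[[id]], sigmas[[id]])
      if (spec$frag_fraction * length(anc) >= rng[1]) {
        stop(sprintf("fragment would classify complete for %s (fraction %.2f >= %.2f)",
                     id, spec$frag_fraction, rng[1] / length(anc)))
      }
    }
    recs <- character(0)
    starts <- integer(0); ends <- integer(0); strands <- character(0)
    for (i in seq_len(n_copies)) {
      pep <- mutate_protein(anc, spec$divergence)
      if (status == "fragmented") {
        pep <- pep[seq_len(max(1, round(spec$frag_fraction * length(pep))))]
      }
      pep <- paste(pep, collapse = "")
      peptides[[id]] <- c(peptides[[id]], pep)
      if (!spec$genome_mode) {
        nm <- sprintf("t_%s_%d", id, i)
        targets[nm] <- pep
        recs <- c(recs, nm)
        starts <- c(starts, NA_integer_); ends <- c(ends, NA_integer_)
        strands <- c(strands, NA_character_)
      } else {
        gene <- paste0(encode_codons(pep), "TAA")
        strand <- sample(c("+", "-"), 1)
        fl1 <- random_dna(sample(200:400, 1))
        fl2 <- random_dna(sample(200:400, 1))
        insert <- if (strand == "+") gene else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene)))
        contig <- paste0(fl1, insert, fl2)
        nm <- sprintf("contig_%s_%d", id, i)
        targets[nm] <- contig
        recs <- c(recs, nm)
        starts <- c(starts, nchar(fl1) + 1L)
        ends <- c(ends, nchar(fl1) + nchar(gene))
        strands <- c(strands, strand)
      }
    }
    truth[[id]] <- data.frame(
      busco_id = id, planted_status = status,
      records = paste(recs, collapse = ","),
      start = paste(starts, collapse = ","),
      end = paste(ends, collapse = ","),
      strand = paste(strands, collapse = ","),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  mode <- if (spec$genome_mode) "genome" else "proteins"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    set <- if (spec$genome_mode) Biostrings::DNAStringSet(targets) else
      Biostrings::AAStringSet(targets)
    Biostrings::writeXStringSet(set, file.path(out_dir, "targets.fasta"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(targets = targets, truth = truth, peptides = peptides, mode = mode)
}

#' Fraction of orthologs recovered at their planted status
#'
#' @param run a `busco_run` on the planted targets.
#' @param truth truth table from [plant_targets()].
#' @return named list with `agreement` (fraction in `[0, 1]`) and `table`
#'   (per-ortholog planted vs observed status).
#' @export
evaluate_recovery <- function(run, truth) {
  stopifnot(inherits(run, "busco_run"))
  obs <- vapply(run$results, `[[`, character(1), "status")
  tab <- data.frame(busco_id = truth$busco_id,
                    planted = truth$planted_status,
                    observed = unname(obs[truth$busco_id]),
                    stringsAsFactors = FALSE)
  list(agreement = mean(tab$planted == tab$observed), table = tab)
}
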