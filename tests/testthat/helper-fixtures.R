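# Shared miniature fixtures: small, fast lineages used across test files.

# lineage + dataset + planted targets in one call
mini_fixture <- function(n_buscos = 6, n_species = 4, divergence = 0.08,
                         seed = 1, planted = NULL,
                         gene_length_range = c(60, 100),
                         genome_mode = FALSE, tree = NULL) {
  spec <- fixture_spec(n_buscos, n_species, divergence = divergence,
                       seed = seed, planted = planted,
                       gene_length_range = gene_length_range,
                       genome_mode = genome_mode, tree = tree)
  lineage <- simulate_lineage(spec)
  ds <- build_dataset(lineage$table, lineage$msas,
                      name = sprintf("mini_s%d", seed))
  targets <- plant_targets(spec, lineage)
  list(spec = spec, lineage = lineage, ds = ds, targets = targets)
}

# per-species proteome assessments over one simulated lineage (each
# species' input is its own ungapped ortholog copies)
species_runs <- function(lineage, ds, drop = list()) {
  runs <- lapply(lineage$species, function(sp) {
    seqs <- vapply(lineage$msas, function(m) msa_ungap(m)[[sp]], character(1))
    names(seqs) <- paste0(sp, "|", names(lineage$msas))
    omit <- drop[[sp]]
    if (!is.null(omit)) seqs <- seqs[!names(seqs) %in% paste0(sp, "|", omit)]
    run_assessment(seqs, mode = "proteins", ds = ds)
  })
  names(runs) <- lineage$species
  runs
}

# random aligned block with gaps, for trimming / alignment properties
random_msa <- function(n_rows = 4, n_cols = 20, gap_p = 0.2) {
  rows <- replicate(n_rows, {
    ch <- sample(c("A", "C", "D", "E", "F", "G", "H", "K"), n_cols,
                 replace = TRUE)
    ch[stats::runif(n_cols) < gap_p] <- "-"
    paste(ch, collapse = "")
  })
  # guard: msa() forbids nothing here, but keep at least one residue per row
  rows <- vapply(rows, function(r) {
    if (gsub("-", "", r) == "") sub("-", "A", r) else r
  }, character(1), USE.NAMES = FALSE)
  msa(rows)
}
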