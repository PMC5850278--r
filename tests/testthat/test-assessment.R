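# a tiny dataset plus hand-crafted match rows for the classifier
fake_match <- function(busco_id, candidate_id, bits, len,
                       source_seq = candidate_id, nt_from = NA_integer_,
                       nt_to = NA_integer_, strand = NA_character_) {
  data.frame(busco_id = busco_id, candidate_id = candidate_id,
             aa = strrep("A", len), source_seq = source_seq,
             strand = strand, nt_from = nt_from, nt_to = nt_to,
             frame = NA_integer_, bits = bits, ali_from = 1L,
             ali_to = as.integer(len), matched_states = as.integer(len),
             ungapped_len = as.integer(len), stringsAsFactors = FALSE)
}

test_that("search finds planted orthologs above their cutoffs", {
  fix <- mini_fixture(n_buscos = 4, n_species = 4, seed = 12)
  cands <- extract_candidates_protein(fix$targets$targets)
  matches <- search(cands, fix$ds)
  for (id in names(fix$ds$profiles)) {
    co <- fix$ds$cutoffs[fix$ds$cutoffs$busco_id == id, ]
    own <- matches[matches$busco_id == id &
                     grepl(id, matches$candidate_id, fixed = TRUE), ]
    expect_gte(nrow(own), 1)
    expect_true(any(own$bits >= co$score_cutoff))
  }
  expect_equal(nrow(search(microbusco:::empty_candidates(), fix$ds)), 0)
})

test_that("unrelated random sequences rarely reach any cutoff", {
  fix <- mini_fixture(n_buscos = 2, n_species = 4, seed = 13)
  set.seed(13)
  n_above <- 0L
  for (i in 1:200) {
    len <- sample(60:100, 1)
    cand <- data.frame(id = "r", aa = paste(sample(microbusco:::AA_ALPHABET,
                                                   len, TRUE), collapse = ""),
                       source_seq = "r", strand = NA_character_,
                       nt_from = NA_integer_, nt_to = NA_integer_,
                       frame = NA_integer_, stringsAsFactors = FALSE)
    m <- search(cand, fix$ds)
    if (nrow(m) > 0) {
      co <- setNames(fix$ds$cutoffs$score_cutoff, fix$ds$cutoffs$busco_id)
      if (any(m$bits >= co[m$busco_id])) n_above <- n_above + 1L
    }
  }
  expect_lte(n_above / 200, 0.01)
})

test_that("classification follows the score-cutoff and length-window rules", {
  fix <- mini_fixture(n_buscos = 2, n_species = 3, seed = 14,
                      gene_length_range = c(80, 90))
  ds <- fix$ds
  co <- ds$cutoffs[1, ]
  id <- co$busco_id
  other <- ds$cutoffs$busco_id[2]
  lm <- round(co$length_mean)

  # boundary inclusive: bits == cutoff, length == mean -> complete_single
  r <- classify(fake_match(id, "c1", co$score_cutoff, lm), ds)
  expect_equal(r[[id]]$status, "complete_single")
  expect_equal(r[[other]]$status, "missing")
  expect_equal(nrow(r[[other]]$matches), 0)

  # two complete-grade matches on different records -> complete_duplicated
  r2 <- classify(rbind(fake_match(id, "c1", co$score_cutoff + 5, lm),
                       fake_match(id, "c2", co$score_cutoff + 3, lm)), ds)
  expect_equal(r2[[id]]$status, "complete_duplicated")

  # passing score but 0.3x expected length -> fragmented
  r3 <- classify(fake_match(id, "c1", co$score_cutoff + 1,
                            round(0.3 * co$length_mean)), ds)
  expect_equal(r3[[id]]$status, "fragmented")

  # sub-cutoff evidence is not evidence
  r4 <- classify(fake_match(id, "c1", co$score_cutoff * 0.5, lm), ds)
  expect_equal(r4[[id]]$status, "missing")

  expect_error(classify(fake_match("nope", "c1", 10, lm), ds),
               "absent from the dataset")
})

test_that("same-record loci are merged unless overlap is below half", {
  fix <- mini_fixture(n_buscos = 2, n_species = 3, seed = 15,
                      gene_length_range = c(80, 90))
  ds <- fix$ds
  co <- ds$cutoffs[1, ]
  id <- co$busco_id
  lm <- round(co$length_mean)
  b <- co$score_cutoff + 2
  # nearly identical spans on one contig: one locus -> complete_single
  r <- classify(rbind(
    fake_match(id, "c1", b, lm, source_seq = "ctg", nt_from = 1L,
               nt_to = 300L, strand = "+"),
    fake_match(id, "c2", b - 1, lm, source_seq = "ctg", nt_from = 31L,
               nt_to = 330L, strand = "+")), ds)
  expect_equal(r[[id]]$status, "complete_single")
  # disjoint spans on one contig: two loci -> complete_duplicated
  r2 <- classify(rbind(
    fake_match(id, "c1", b, lm, source_seq = "ctg", nt_from = 1L,
               nt_to = 300L, strand = "+"),
    fake_match(id, "c2", b - 1, lm, source_seq = "ctg", nt_from = 501L,
               nt_to = 800L, strand = "+")), ds)
  expect_equal(r2[[id]]$status, "complete_duplicated")
})

test_that("each candidate is consumed by its best-scoring ortholog only", {
  fix <- mini_fixture(n_buscos = 2, n_species = 3, seed = 16,
                      gene_length_range = c(80, 90))
  ds <- fix$ds
  ids <- ds$cutoffs$busco_id
  lm1 <- round(ds$cutoffs$length_mean[1])
  lm2 <- round(ds$cutoffs$length_mean[2])
  b1 <- ds$cutoffs$score_cutoff[1]
  b2 <- ds$cutoffs$score_cutoff[2]
  # one candidate passing both cutoffs goes to the higher-bits pairing
  m <- rbind(fake_match(ids[1], "c1", b1 + 10, lm1),
             fake_match(ids[2], "c1", b2 + 1, lm2))
  r <- classify(m, ds)
  expect_equal(r[[ids[1]]]$status, "complete_single")
  expect_equal(r[[ids[2]]]$status, "missing")
})

test_that("summaries conserve counts and format percentages", {
  fix <- mini_fixture(n_buscos = 5, n_species = 3, seed = 17,
                      planted = planted_statuses(2, 1, 1, 1))
  run <- run_assessment(fix$targets$targets, mode = "proteins", ds = fix$ds)
  s <- run$summary
  expect_equal(s$C, s$S + s$D)
  expect_equal(s$C + s$F + s$M, s$n)
  expect_equal(c(s$S, s$D, s$F, s$M), c(2, 1, 1, 1))
  expect_equal(s$pC, 60.0)
  expect_equal(s$pS, 40.0)
  expect_equal(s$one_line,
               "C:60.0%[S:40.0%,D:20.0%],F:20.0%,M:20.0%,n:5")

  all_single <- mini_fixture(n_buscos = 3, n_species = 3, seed = 18)
  r2 <- run_assessment(all_single$targets$targets, "proteins",
                       ds = all_single$ds)
  expect_equal(r2$summary$one_line,
               "C:100.0%[S:100.0%,D:0.0%],F:0.0%,M:0.0%,n:3")
})

test_that("assessment runs are deterministic and validate their inputs", {
  fix <- mini_fixture(n_buscos = 3, n_species = 3, seed = 19)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_assessment(fix$targets$targets, "proteins", ds = fix$ds, out_dir = d1)
  run_assessment(fix$targets$targets, "proteins", ds = fix$ds, out_dir = d2)
  expect_identical(readLines(file.path(d1, "full_table.tsv")),
                   readLines(file.path(d2, "full_table.tsv")))
  expect_true(file.exists(file.path(d1, "short_summary.txt")))
  expect_true(file.exists(file.path(d1, "single_copy.faa")))

  expect_error(run_assessment(character(0), "proteins", ds = fix$ds),
               "no sequences")
  expect_error(run_assessment(c(x = "ACGTACGTACGTACGTACGT"), "proteins",
                              ds = fix$ds),
               "genome|transcriptome")
})

test_that("duplicating the input maps every single-copy ortholog to duplicated", {
  fix <- mini_fixture(n_buscos = 4, n_species = 3, seed = 20,
                      planted = planted_statuses(2, 0, 1, 1))
  tg <- fix$targets$targets
  run1 <- run_assessment(tg, "proteins", ds = fix$ds)
  doubled <- c(tg, setNames(tg, paste0(names(tg), "_dup")))
  run2 <- run_assessment(doubled, "proteins", ds = fix$ds)
  st1 <- vapply(run1$results, `[[`, character(1), "status")
  st2 <- vapply(run2$results, `[[`, character(1), "status")
  expect_true(all(st2[st1 == "complete_single"] == "complete_duplicated"))
  expect_identical(names(which(st1 == "missing")),
                   names(which(st2 == "missing")))
})

test_that("transcriptome mode keeps one candidate per transcript and ortholog", {
  fix <- mini_fixture(n_buscos = 3, n_species = 3, seed = 22,
                      gene_length_range = c(70, 90))
  set.seed(22)
  peps <- vapply(fix$targets$peptides, `[`, character(1), 1)
  tx <- setNames(vapply(peps, function(p) {
    paste0(microbusco:::encode_codons(p), "TAA")
  }, character(1)), paste0("tx_", names(peps)))
  run <- run_assessment(tx, "transcriptome", ds = fix$ds)
  st <- vapply(run$results, `[[`, character(1), "status")
  expect_true(all(st == "complete_single"))
})

test_that("training-model export emits consistent GFF3 and re-translatable FASTA", {
  fix <- mini_fixture(n_buscos = 4, n_species = 3, seed = 23,
                      planted = planted_statuses(3, 0, 0, 1),
                      genome_mode = TRUE, gene_length_range = c(100, 140))
  run <- run_assessment(fix$targets$targets, "genome", ds = fix$ds)
  out <- withr::local_tempdir()
  tab <- export_training_models(run, out)
  expect_gte(nrow(tab), 3)
  gff <- readLines(file.path(out, "training_models.gff3"))
  expect_equal(gff[1], "##gff-version 3")
  body <- read.table(text = gff[-1], sep = "\t", stringsAsFactors = FALSE)
  expect_true(all(body$V4 <= body$V5))           # start <= end, both strands
  expect_true(all(body$V7 %in% c("+", "-")))

  fna <- Biostrings::readDNAStringSet(file.path(out, "training_models.fna"))
  peps <- unlist(lapply(run$results, function(r) {
    if (r$status == "complete_single") r$matches$aa else character(0)
  }))
  for (i in seq_along(fna)) {
    pep <- sub("\\*$", "", as.character(suppressWarnings(
      Biostrings::translate(fna[[i]], if.fuzzy.codon = "X", no.init.codon = TRUE))))
    expect_true(pep %in% peps)
  }

  # protein-mode runs cannot export gene models
  pfix <- mini_fixture(n_buscos = 2, n_species = 3, seed = 24)
  prun <- run_assessment(pfix$targets$targets, "proteins", ds = pfix$ds)
  expect_error(export_training_models(prun, out), "genome-mode")
})
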