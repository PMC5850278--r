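test_that("center-star alignment preserves inputs and handles indels", {
  # identical inputs align gapless
  a <- align_marker(c(s1 = "MACDEF", s2 = "MACDEF", s3 = "MACDEF"))
  expect_equal(a$sequences, rep("MACDEF", 3))

  # a deletion gets one gap and the alignment spans the longer sequence
  a2 <- align_marker(c(x = "ACD", y = "AD"))
  expect_equal(msa_width(a2), 3)
  expect_equal(sum(strsplit(a2$sequences[2], "")[[1]] == "-"), 1)

  # gap-strip round trip on random triples with indels
  set.seed(41)
  for (i in 1:30) {
    base <- sample(microbusco:::AA_ALPHABET, 40, TRUE)
    seqs <- vapply(1:3, function(j) {
      ch <- base
      if (runif(1) < 0.8) ch <- ch[-sample(40, sample(1:5, 1))]
      paste(ch, collapse = "")
    }, character(1))
    names(seqs) <- paste0("s", 1:3)
    al <- align_marker(seqs)
    expect_equal(unname(msa_ungap(al)), unname(seqs))
  }

  expect_error(align_marker(c(a = "ACD", b = "")), "empty sequence")
})

test_that("column trimming keeps exactly the gap-poor columns and is idempotent", {
  m <- msa(c("A-CD", "A-CD", "AAC-", "A-C-"))   # gap fractions 0,.75,0,.5
  tr <- trim_alignment(m, 0.5)
  expect_equal(msa_width(tr), 3)                # the 50% column survives
  tr2 <- trim_alignment(msa(c("A-CD", "A-CD", "AACD", "A-CD")), 0.5)
  expect_equal(msa_width(tr2), 3)               # 75% gap column removed
  g <- msa(c("ACD", "ACD"))
  expect_equal(trim_alignment(g, 0.5)$sequences, g$sequences)

  set.seed(42)
  for (i in 1:25) {
    m <- random_msa(4, 30, gap_p = 0.3)
    t1 <- trim_alignment(m, 0.5)
    expect_identical(trim_alignment(t1, 0.5)$sequences, t1$sequences)
  }

  expect_warning(out <- trim_alignment(msa(c("A-", "-A", "A-", "-A")), 0.3),
                 "all alignment columns removed")
  expect_equal(nchar(out$sequences[1]), 0)
})

test_that("concatenation records partitions that tile the supermatrix", {
  m1 <- msa(c(a = "ACDEF", b = "ACDEF", c = "ACDEF"))
  m2 <- msa(c(a = "GHIKLMN", b = "GHIKLMN", c = "GHIKLMN"))
  sm <- concatenate_markers(list(m1 = m1, m2 = m2))
  expect_equal(nchar(sm$matrix[[1]]), 12)
  expect_equal(sm$partitions$start, c(1L, 6L))
  expect_equal(sm$partitions$end, c(5L, 12L))

  # single marker: supermatrix equals the alignment
  sm1 <- concatenate_markers(list(m1 = m1))
  expect_equal(unname(sm1$matrix), m1$sequences)

  # input order does not matter (markers are sorted by id)
  sm_rev <- concatenate_markers(list(m2 = m2, m1 = m1))
  expect_identical(sm_rev$matrix, sm$matrix)
  expect_identical(sm_rev$partitions, sm$partitions)

  m3 <- msa(c(a = "AC", b = "AC", z = "AC"))
  expect_error(concatenate_markers(list(m1 = m1, m3 = m3)),
               "species set mismatch in marker m3")
})

test_that("neighbor joining recovers hand-built additive distances", {
  # disjoint mutated blocks make p-distances exactly additive:
  # ((a,b),(c,d)) with internal branch from sites 11-20
  set.seed(43)
  base <- sample(c("A", "C", "D", "E"), 100, TRUE)
  flip <- function(ch, idx) {
    ch[idx] <- vapply(ch[idx], function(x) {
      sample(setdiff(c("F", "G", "H", "K"), x), 1)
    }, character(1))
    ch
  }
  a <- base
  b <- flip(base, 1:10)
  cd_anc <- flip(base, 11:20)        # shared internal-branch changes
  cc <- flip(cd_anc, 21:30)
  d <- flip(cd_anc, 31:40)
  rows <- vapply(list(a = a, b = b, c = cc, d = d), paste, character(1),
                 collapse = "")
  sm <- concatenate_markers(list(g1 = msa(rows, labels = names(rows))))
  dmat <- p_distance(sm)
  expect_equal(dmat["a", "b"], 0.10)
  expect_equal(dmat["c", "d"], 0.20)
  expect_equal(dmat["b", "c"], 0.30)
  tr <- ape::read.tree(text = nj_tree(sm))
  expected <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(expected))[1], 0)
  expect_true(all(tr$edge.length >= 0))

  # three identical rows: a zero-length star
  sm3 <- concatenate_markers(list(g = msa(c(x = "ACDE", y = "ACDE",
                                            z = "ACDE"))))
  tr3 <- ape::read.tree(text = nj_tree(sm3))
  expect_equal(ape::Ntip(tr3), 3)
  expect_true(all(abs(tr3$edge.length) < 1e-12))
  expect_setequal(tr3$tip.label, c("x", "y", "z"))
})

test_that("universal markers require complete single-copy status everywhere", {
  fix <- mini_fixture(n_buscos = 4, n_species = 3, seed = 44)
  runs <- species_runs(fix$lineage, fix$ds)
  mk <- select_universal_markers(runs)
  expect_equal(mk$busco_ids, sort(names(fix$ds$profiles)))

  # duplicating one ortholog in one species excludes it
  sp <- fix$lineage$species[1]
  seqs <- vapply(fix$lineage$msas, function(m) msa_ungap(m)[[sp]],
                 character(1))
  names(seqs) <- paste0(sp, "|", names(fix$lineage$msas))
  seqs <- c(seqs, setNames(seqs[1], paste0(names(seqs)[1], "_copy")))
  runs2 <- runs
  runs2[[sp]] <- run_assessment(seqs, "proteins", ds = fix$ds)
  mk2 <- select_universal_markers(runs2)
  expect_false("busco001" %in% mk2$busco_ids)
  expect_equal(length(mk2$busco_ids), 3)

  runs3 <- runs
  runs3[[1]]$dataset <- "other"
  expect_error(select_universal_markers(runs3), "different lineage datasets")
  expect_error(select_universal_markers(runs[1:2]), ">= 3")
})

test_that("restricting to fewer species never loses universal markers", {
  fix <- mini_fixture(n_buscos = 6, n_species = 5, seed = 45)
  # drop random orthologs from some species so statuses vary
  set.seed(45)
  drop <- list()
  for (sp in fix$lineage$species[1:3]) {
    drop[[sp]] <- sample(names(fix$ds$profiles), 1)
  }
  runs <- species_runs(fix$lineage, fix$ds, drop = drop)
  n_all <- length(select_universal_markers(runs)$busco_ids)
  n_sub <- length(select_universal_markers(runs[c(1, 4, 5)])$busco_ids)
  expect_gte(n_sub, n_all)
})

test_that("supermatrix artifacts are written in the declared formats", {
  fix <- mini_fixture(n_buscos = 3, n_species = 4, seed = 46)
  runs <- species_runs(fix$lineage, fix$ds)
  sm <- build_supermatrix(select_universal_markers(runs))
  expect_equal(nrow(sm$partitions), 3)
  expect_equal(sm$partitions$start[1], 1L)
  expect_equal(sm$partitions$end[nrow(sm$partitions)],
               nchar(sm$matrix[[1]]))

  out <- withr::local_tempdir()
  write_supermatrix(sm, out)
  phy <- readLines(file.path(out, "supermatrix.phy"))
  expect_equal(strsplit(phy[1], " ")[[1]],
               c("4", as.character(nchar(sm$matrix[[1]]))))
  parts <- readLines(file.path(out, "partitions.txt"))
  expect_true(all(grepl("^WAG, busco[0-9]+ = [0-9]+-[0-9]+$", parts)))
  tr <- ape::read.tree(file.path(out, "nj_tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(sm$species))
})
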