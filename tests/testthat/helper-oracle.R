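# Independent scoring oracle: exhaustive enumeration of every legal state
# path through a small profile HMM, scored directly from the model's
# probabilities. Shares no code with the dynamic-programming kernel.

# Enumerate complete paths for a model with k match states and a target of
# length L. Each path records its transition triples (from-position,
# from-state, to-state) and its match emissions (model position, consumed
# target index). Global paths start at the begin state (position 0) and
# must end at position k with the whole target consumed; local paths start
# and end at a match state (free entry/exit) and may consume any number of
# residues, the flanks being free.
enum_paths <- function(k, L, mode) {
  paths <- list()
  add_path <- function(trans, ems, consumed) {
    paths[[length(paths) + 1]] <<- list(trans = trans, ems = ems,
                                        consumed = consumed)
  }
  rec <- function(pos, state, consumed, trans, ems) {
    if (mode == "global") {
      if (pos == k && consumed == L) add_path(trans, ems, consumed)
    } else {
      if (state == "M") add_path(trans, ems, consumed)
    }
    if (consumed < L) {                      # insert at current position
      rec(pos, "I", consumed + 1,
          rbind(trans, c(pos, state, "I")), ems)
    }
    if (pos < k) {
      if (consumed < L) {                    # match at next position
        rec(pos + 1, "M", consumed + 1,
            rbind(trans, c(pos, state, "M")),
            rbind(ems, c(pos + 1, consumed + 1)))
      }
      rec(pos + 1, "D", consumed,            # delete at next position
          rbind(trans, c(pos, state, "D")), ems)
    }
  }
  if (mode == "global") {
    rec(0, "M", 0, NULL, NULL)
  } else {
    for (a in seq_len(k)) {
      rec(a, "M", 1, NULL, matrix(c(a, 1), nrow = 1))
    }
  }
  paths
}

# Score every target (rows of integer code matrix `tmat`, codes = columns
# of the emission matrix) against `hmm` by taking the maximum over all
# enumerated paths. Insert emissions equal background, so only transitions
# and match emissions contribute.
oracle_scores <- function(hmm, tmat, mode, paths = NULL) {
  k <- hmm$match_count
  L <- ncol(tmat)
  if (is.null(paths)) paths <- enum_paths(k, L, mode)
  lmatch <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  ltr <- log2(hmm$transitions)
  best <- rep(-Inf, nrow(tmat))
  for (p in paths) {
    const <- 0
    if (!is.null(p$trans)) {
      for (r in seq_len(nrow(p$trans))) {
        const <- const + ltr[as.integer(p$trans[r, 1]) + 1L,
                             p$trans[r, 2], p$trans[r, 3]]
      }
    }
    if (mode == "global") {
      sc <- rep(const, nrow(tmat))
      if (!is.null(p$ems)) {
        for (r in seq_len(nrow(p$ems))) {
          sc <- sc + lmatch[p$ems[r, 1], tmat[, p$ems[r, 2]]]
        }
      }
      best <- pmax(best, sc)
    } else {
      for (s in 0:(L - p$consumed)) {        # free flank offset
        sc <- rep(const, nrow(tmat))
        for (r in seq_len(nrow(p$ems))) {
          sc <- sc + lmatch[p$ems[r, 1], tmat[, p$ems[r, 2] + s]]
        }
        best <- pmax(best, sc)
      }
    }
  }
  best
}

# all targets of length L over an alphabet given as emission-column indices
all_targets <- function(L, codes = 1:3) {
  as.matrix(expand.grid(rep(list(codes), L)))
}

# random small profile over the {A, C, D} sub-alphabet, built through the
# package's own builder from a random gappy alignment with exactly k match
# columns (insert columns are 3/4 gaps)
gen_test_profile <- function(k, seed) {
  set.seed(seed)
  n <- 4
  cols <- list()
  for (j in seq_len(k)) {
    if (j > 1 && stats::runif(1) < 0.5) {    # insert column before j
      ins <- rep("-", n)
      ins[sample(n, 1)] <- sample(c("A", "C", "D"), 1)
      cols[[length(cols) + 1]] <- ins
    }
    col <- sample(c("A", "C", "D"), n, replace = TRUE)
    if (stats::runif(1) < 0.5) col[sample(n, 1)] <- "-"   # 25% gaps < 0.5
    cols[[length(cols) + 1]] <- col
  }
  m <- do.call(cbind, cols)
  rows <- apply(m, 1, paste, collapse = "")
  build_profile(msa(rows), busco_id = sprintf("test_k%d_s%d", k, seed))
}
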