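#' Build a profile HMM from an ortholog alignment
#'
#' Alignment columns with a gap fraction below 0.5 become match states;
#' the remaining columns are treated as insertions. Match emissions are the
#' observed residue frequencies mixed with the alignment-wide background via
#' a pseudocount, `(counts + w * background) / (n + w)`, so every residue
#' keeps positive probability. Transitions among match/insert/delete states
#' are counted from each row's path through the alignment with +1 Laplace
#' smoothing (delete-to-delete is allowed). Insert states emit the
#' background, so inserted residues are score-neutral.
#'
#' @param msa an [msa] object (amino acids, gaps as `-`).
#' @param pseudocount_weight positive pseudocount mass `w` added to the
#'   emission counts as `w * background`. Default 1.
#' @param busco_id identifier stored with the profile.
#' @return A `profile_hmm` object with elements `busco_id`, `match_count`,
#'   `match_emissions` (match_count x 20), `insert_emissions`, `background`
#'   (length-20, floored at 1e-4 and renormalized) and `transitions`
#'   (array `(match_count + 1) x 3 x 3`, positions 0..match_count; position 0
#'   is the begin state, the last row feeds the terminal insert state).
#' @examples
#' m <- msa(c("ACD", "ACD", "ACD", "ACD"))
#' h <- build_profile(m, busco_id = "b1")
#' h$match_count
#' @export
build_profile <- function(msa, pseudocount_weight = 1, busco_id = "profile") {
  stopifnot(inherits(msa, "msa"))
  if (!is.numeric(pseudocount_weight) || length(pseudocount_weight) != 1 ||
      pseudocount_weight <= 0) {
    stop("pseudocount_weight must be a single positive number")
  }
  m <- msa_matrix(msa)
  gap_frac <- colMeans(m == "-")
  is_match <- gap_frac < 0.5
  k <- sum(is_match)
  if (k == 0) stop("no match columns")

  # background: pooled residue frequency, floored and renormalized
  res <- m[m %in% AA_ALPHABET]
  counts <- table(factor(res, levels = AA_ALPHABET))
  bg <- as.numeric(counts) / max(1, sum(counts))
  bg <- pmax(bg, 1e-4)
  bg <- bg / sum(bg)
  names(bg) <- AA_ALPHABET

  w <- pseudocount_weight
  match_cols <- which(is_match)
  em <- matrix(0, nrow = k, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(k)) {
    col <- m[, match_cols[j]]
    cnt <- as.numeric(table(factor(col[col %in% AA_ALPHABET],
                                   levels = AA_ALPHABET)))
    em[j, ] <- (cnt + w * bg) / (sum(cnt) + w)
  }

  # transition counts from each row's path through the alignment
  states <- c("M", "I", "D")
  trans <- array(1, dim = c(k + 1, 3, 3),
                 dimnames = list(NULL, states, states))  # +1 Laplace
  col_pos <- cumsum(is_match)          # model position of each match column
  for (r in seq_len(nrow(m))) {
    prev_pos <- 0L; prev_state <- 1L   # begin acts as a match at position 0
    for (cc in seq_len(ncol(m))) {
      ch <- m[r, cc]
      if (is_match[cc]) {
        st <- if (ch == "-") 3L else 1L
        pos <- col_pos[cc]
      } else {
        if (ch == "-") next
        st <- 2L
        pos <- col_pos[cc]             # inserts belong to the position before
      }
      trans[prev_pos + 1L, prev_state, st] <- trans[prev_pos + 1L, prev_state, st] + 1
      prev_pos <- pos; prev_state <- st
    }
  }
  for (p in seq_len(k + 1)) {
    for (s in 1:3) trans[p, s, ] <- trans[p, s, ] / sum(trans[p, s, ])
  }

  structure(list(busco_id = as.character(busco_id),
                 match_count = as.integer(k),
                 match_emissions = em,
                 insert_emissions = bg,
                 background = bg,
                 transitions = trans),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': %d match states\n",
              x$busco_id, x$match_count))
  invisible(x)
}

# log2 score tables consumed by the C++ Viterbi kernel
hmm_log_tables <- function(hmm) {
  lmatch <- cbind(log2(sweep(hmm$match_emissions, 2, hmm$background, "/")), 0)
  k <- hmm$match_count
  lt <- matrix(0, nrow = k + 1, ncol = 9)
  for (p in seq_len(k + 1)) {
    lt[p, ] <- log2(as.numeric(t(hmm$transitions[p, , ])))
  }
  list(lmatch = lmatch, ltrans = lt)
}

#' Score a sequence against a profile HMM (Viterbi)
#'
#' Computes the maximum log2-odds (profile versus background) alignment
#' score over all admissible state paths. In `"global"` mode the whole model
#' must be traversed and the whole target consumed (insert states absorb
#' extra residues). In `"local"` mode entry and exit are free at any match
#' state and flanking target residues cost nothing, so the score reflects
#' the best-matching region. Residues outside the 20-letter alphabet emit
#' the background (log-odds contribution zero).
#'
#' @param hmm a `profile_hmm`.
#' @param target amino-acid sequence (single string), length >= 1.
#' @param mode `"local"` (default) or `"global"` (global on the model).
#' @return An `hmm_score`: list with `bits`, `ali_from`, `ali_to` (1-based
#'   inclusive coordinates of the match-aligned region on the target) and
#'   `matched_states`.
#' @export
viterbi_score <- function(hmm, target, mode = c("local", "global")) {
  stopifnot(inherits(hmm, "profile_hmm"))
  mode <- match.arg(mode)
  target <- as.character(target)
  if (length(target) != 1 || is.na(target) || nchar(target) == 0) {
    stop("empty target")
  }
  tab <- hmm_log_tables(hmm)
  res <- .viterbi_dp(tab$lmatch, tab$ltrans, aa_codes(target),
                     mode == "global")
  structure(res, class = "hmm_score")
}

#' @export
print.hmm_score <- function(x, ...) {
  cat(sprintf("hmm_score: %.3f bits, target %d-%d, %d match states\n",
              x$bits, x$ali_from, x$ali_to, x$matched_states))
  invisible(x)
}

#' Serialize / parse a profile HMM as a text block
#'
#' The format is line-oriented and tab-separated: a versioned header, the
#' `busco_id` and `match_count`, one `background` row, one `match` emission
#' row per match state, and a `trans` row per (position, from-state). All
#' probability rows must sum to 1. `parse_profile(serialize_profile(h))`
#' reproduces `h` to within 1e-9 on every probability.
#'
#' @param hmm a `profile_hmm`.
#' @return `serialize_profile`: a single character string.
#' @export
serialize_profile <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"))
  num <- function(x) paste(sprintf("%.12g", x), collapse = "\t")
  k <- hmm$match_count
  lines <- c("microbusco_profile\t1",
             paste0("busco_id\t", hmm$busco_id),
             paste0("match_count\t", k),
             paste0("background\t", num(hmm$background)))
  for (j in seq_len(k)) {
    lines <- c(lines, paste0("match\t", j, "\t", num(hmm$match_emissions[j, ])))
  }
  for (p in 0:k) {
    for (s in c("M", "I", "D")) {
      lines <- c(lines, paste0("trans\t", p, "\t", s, "\t",
                               num(hmm$transitions[p + 1, s, ])))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname serialize_profile
#' @param text character: serialized profile (single string or lines).
#' @return `parse_profile`: a `profile_hmm`.
#' @export
parse_profile <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(lines)]
  if (length(lines) < 4 || lines[1] != "microbusco_profile\t1") {
    stop("malformed header (line 1)")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- function(i, key, n_min) {
    f <- fields[[i]]
    if (f[1] != key || length(f) < n_min) {
      stop(sprintf("malformed '%s' record (line %d)", key, i))
    }
    f
  }
  check_norm <- function(x, i) {
    if (abs(sum(x) - 1) > 1e-6) stop(sprintf("row not normalized (line %d)", i))
    x
  }
  busco_id <- need(2, "busco_id", 2)[2]
  k <- as.integer(need(3, "match_count", 2)[2])
  if (is.na(k) || k < 1) stop("malformed 'match_count' record (line 3)")
  bg <- check_norm(as.numeric(need(4, "background", 21)[-1]), 4)
  names(bg) <- AA_ALPHABET

  em <- matrix(0, nrow = k, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(k)) {
    i <- 4 + j
    f <- need(i, "match", 22)
    if (as.integer(f[2]) != j) stop(sprintf("match rows out of order (line %d)", i))
    em[j, ] <- check_norm(as.numeric(f[-(1:2)]), i)
  }
  states <- c("M", "I", "D")
  trans <- array(0, dim = c(k + 1, 3, 3),
                 dimnames = list(NULL, states, states))
  i <- 4 + k
  for (p in 0:k) {
    for (s in states) {
      i <- i + 1
      if (i > length(lines)) stop("truncated transition block")
      f <- need(i, "trans", 6)
      if (as.integer(f[2]) != p || f[3] != s) {
        stop(sprintf("transition rows out of order (line %d)", i))
      }
      trans[p + 1, s, ] <- check_norm(as.numeric(f[-(1:3)]), i)
    }
  }
  structure(list(busco_id = busco_id, match_count = k, match_emissions = em,
                 insert_emissions = bg, background = bg, transitions = trans),
            class = "profile_hmm")
}
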