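# Reporting utilities: plot-ready category tables, the gene-prediction
# coverage score, and assembly contiguity metrics.

#' Plot-ready category table from one or more assessment summaries
#'
#' One row per (run, category) in the fixed category order S, D, F, M.
#'
#' @param summaries named list (run label -> `busco_summary`).
#' @param out_tsv optional path; when given the table is written as TSV.
#' @return data.frame with columns run_label, category, percent.
#' @export
make_plot_table <- function(summaries, out_tsv = NULL) {
  cats <- c("S", "D", "F", "M")
  rows <- lapply(names(summaries), function(lbl) {
    s <- summaries[[lbl]]
    data.frame(run_label = lbl, category = cats,
               percent = c(s$pS, s$pD, s$pF, s$pM),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run_label = character(0), category = character(0),
               percent = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(out_tsv)) {
    write.table(out, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Stacked completeness bar chart (optional)
#'
#' Thin ggplot2 layer over [make_plot_table()]; the TSV table is the tested
#' surface, the figure is a convenience.
#'
#' @param plot_table data.frame from [make_plot_table()].
#' @return a ggplot object.
#' @export
plot_busco_bars <- function(plot_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  pal <- c(S = "#56B4E9", D = "#3492C7", F = "#F0E442", M = "#F04442")
  plot_table$category <- factor(plot_table$category, levels = c("M", "F", "D", "S"))
  ggplot2::ggplot(plot_table,
                  ggplot2::aes(x = run_label, y = percent,
                               fill = category)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_fill_manual(values = pal, breaks = c("S", "D", "F", "M")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% BUSCOs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Coverage score of a predicted protein against its reference
#'
#' Globally aligns the predicted against the reference protein (BLOSUM62,
#' affine gap open -10 / extend -1) and reports
#' `100 * identical aligned positions / reference length`: 100 means every
#' reference residue is recovered with no insertions, deletions, or
#' substitutions.
#'
#' @param predicted,reference amino-acid sequences (nonempty).
#' @return percent in `[0, 100]`.
#' @export
coverage_score <- function(predicted, reference) {
  predicted <- toupper(as.character(predicted))
  reference <- toupper(as.character(reference))
  if (nchar(reference) == 0) stop("empty reference")
  if (nchar(predicted) == 0) stop("empty predicted sequence")
  pa <- pairwise_global(predicted, reference)
  100 * Biostrings::nmatch(pa) / nchar(reference)
}

#' Assembly contiguity metrics
#'
#' N50 is the length of the shortest sequence in the minimal set of longest
#' sequences jointly covering at least half the total assembly length.
#'
#' @param x a `DNAStringSet`, named character vector of sequences, or a
#'   numeric vector of sequence lengths.
#' @param gene_count optional annotated gene count carried through.
#' @return list with `n_seqs`, `total_len`, `n50` and `gene_count`.
#' @export
assembly_metrics <- function(x, gene_count = NULL) {
  lens <- if (is.numeric(x)) as.numeric(x) else
    nchar(as.character(if (methods::is(x, "XStringSet")) as.character(x) else x))
  if (length(lens) == 0) stop("no sequences")
  lens <- sort(lens, decreasing = TRUE)
  cum <- cumsum(lens)
  n50 <- lens[which(cum >= sum(lens) / 2)[1]]
  list(n_seqs = length(lens), total_len = sum(lens), n50 = n50,
       gene_count = gene_count)
}
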