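#' Per-gene windowed binding scores
#'
#' Each gene body is subdivided into consecutive `window_bp` windows (10 bp
#' by default), the log2(ChIP/input) ratio is averaged within each window,
#' and the gene's binding score is the sum of window values divided by the
#' number of windows analysed (windows with no covered bases are not
#' analysed). Genes with zero covered bases get a missing score and are
#' excluded from ranking.
#'
#' @param track a log2-ratio signal track.
#' @param genes non-empty named `GRanges` of gene bodies.
#' @param window_bp window width in bp.
#' @return a `data.frame` (gene, average_log2, n_windows, rank, bound);
#'   rank/bound are filled by [classify_bound_top_fraction()].
#' @export
gene_binding_scores <- function(track, genes, window_bp = 10L) {
  if (length(genes) == 0L) stop("empty gene set")
  check_same_layout(track, genes)
  ids <- if (is.null(names(genes))) as.character(seq_along(genes))
         else names(genes)
  win <- GenomicRanges::slidingWindows(genes, width = as.integer(window_bp),
                                       step = as.integer(window_bp))
  per_gene <- rep(seq_along(genes), lengths(win))
  m <- interval_means(track, unlist(win, use.names = FALSE))$mean
  score <- tapply(m, per_gene, function(x) mean(x, na.rm = TRUE))
  nwin <- tapply(m, per_gene, function(x) sum(!is.na(x)))
  out <- data.frame(gene = ids,
                    average_log2 = as.numeric(score),
                    n_windows = as.integer(nwin),
                    rank = NA_integer_, bound = NA,
                    stringsAsFactors = FALSE)
  out$average_log2[is.nan(out$average_log2)] <- NA_real_
  out
}

#' Classify the top fraction of genes as bound
#'
#' Ranks scored genes by descending binding score and flags the top
#' `fraction` (default the top 10%) as bound: exactly
#' `max(1, floor(fraction * n_scored))` genes, ties broken deterministically
#' by (score descending, gene id ascending). The minimum score among bound
#' genes is recorded as attribute `min_bound_score`.
#'
#' @param table output of [gene_binding_scores()].
#' @param fraction fraction of scored genes to flag, in (0, 1).
#' @return the table with `rank` (dense rank by descending score, scored
#'   genes only) and `bound` filled in.
#' @export
classify_bound_top_fraction <- function(table, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  scored <- !is.na(table$average_log2)
  n <- sum(scored)
  if (n == 0L) stop("no gene has a binding score")
  n_bound <- max(1L, floor(fraction * n))
  ord <- order(-table$average_log2[scored],
               as.character(table$gene)[scored])
  idx <- which(scored)[ord]
  table$bound <- FALSE
  table$bound[idx[seq_len(n_bound)]] <- TRUE
  s <- table$average_log2[scored]
  dense <- match(table$average_log2[scored],
                 sort(unique(s), decreasing = TRUE))
  table$rank <- NA_integer_
  table$rank[scored] <- dense
  attr(table, "min_bound_score") <- min(table$average_log2[table$bound])
  attr(table, "n_bound") <- n_bound
  table
}
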