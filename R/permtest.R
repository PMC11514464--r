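#' Randomize a region set across the genome, preserving lengths
#'
#' Draws one randomized counterpart of a region set: every region keeps its
#' length and is re-placed uniformly over all feasible genomic positions
#' (the chromosome is chosen with probability proportional to its number of
#' valid start positions for that length, then the start uniformly among
#' them). Randomized regions may overlap one another. This is the
#' null-model generator of the overlap permutation test.
#'
#' @param regions a `GRanges`.
#' @param layout a `Seqinfo`; defaults to the regions' own layout.
#' @return a `GRanges` with the same multiset of lengths.
#' @export
randomize_regions <- function(regions, layout = GenomeInfoDb::seqinfo(regions)) {
  lens <- layout_lengths(layout)
  L <- GenomicRanges::width(regions)
  n <- length(L)
  if (n == 0L) return(GenomicRanges::GRanges(seqinfo = layout))
  ## valid starts per (chromosome, region): lens - L + 1, floored at 0
  v <- outer(lens, L, function(cl, rl) pmax(cl - rl + 1, 0))
  tot <- colSums(v)
  if (any(tot == 0))
    stop("region longer than every chromosome (length ",
         max(L[tot == 0]), ")")
  cum <- matrix(apply(v, 2L, cumsum), nrow = length(lens))
  u <- stats::runif(n) * tot
  chrom_idx <- colSums(cum < rep(u, each = length(lens))) + 1L
  nvalid <- v[cbind(chrom_idx, seq_len(n))]
  start <- floor(stats::runif(n) * nvalid) + 1
  GenomicRanges::GRanges(
    seqnames = factor(names(lens)[chrom_idx], levels = names(lens)),
    ranges = IRanges::IRanges(start = start, width = L),
    seqinfo = layout)
}

#' Count genes overlapping a region set
#'
#' Number of genes sharing at least 1 bp with the merged region set -- the
#' element-count overlap statistic of the permutation test.
#'
#' @param genes,regions `GRanges` on one layout.
#' @return integer count.
#' @export
count_gene_overlaps <- function(genes, regions) {
  if (length(regions) == 0L) return(0L)
  check_same_layout(genes, regions)
  sum(IRanges::overlapsAny(genes, regions, ignore.strand = TRUE))
}

#' Region-randomization overlap permutation test
#'
#' Tests whether the number of genes overlapping a region set is higher or
#' lower than expected by chance: the regions are randomized `n_perm` times
#' (lengths preserved, uniform genome-wide placement) and the observed
#' gene-overlap count is compared with the permuted distribution. Reports
#' the Z-score `(observed - mean) / sd`, the empirical p-value with the +1
#' pseudocount convention `(#{at least as extreme} + 1) / (n_perm + 1)`,
#' and the one-sided `alpha` critical value of the permuted distribution
#' (the "red line" of permutation histograms).
#'
#' @param genes,regions `GRanges` on one layout.
#' @param n_perm number of randomizations (>= 1); 1000 by default.
#' @param alternative "auto" picks the direction of the observed deviation
#'   from the permuted mean; or force "greater"/"less".
#' @param alpha significance level for the critical value.
#' @param seed optional integer; when given, results are reproducible.
#' @return object of class `permutation_overlap_test`: list with `observed`,
#'   `permuted`, `n_perm`, `mean_perm`, `sd_perm`, `z_score`, `p_value`,
#'   `alternative`, `alpha`, `critical`, `significant`, `seed`.
#' @export
permutation_overlap_test <- function(genes, regions, n_perm = 1000L,
                                     alternative = c("auto", "greater",
                                                     "less"),
                                     alpha = 0.05, seed = NULL) {
  alternative <- match.arg(alternative)
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  check_same_layout(genes, regions)
  layout <- GenomeInfoDb::seqinfo(regions)
  ## the permutation loop runs on plain numeric arrays: it draws the same
  ## placements as randomize_regions but skips GRanges construction
  lens <- layout_lengths(layout)
  gc <- as.integer(GenomicRanges::seqnames(genes))
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  L <- GenomicRanges::width(regions)
  nreg <- length(L)
  v <- outer(lens, L, function(cl, rl) pmax(cl - rl + 1, 0))
  tot <- colSums(v)
  if (nreg > 0 && any(tot == 0))
    stop("region longer than every chromosome (length ",
         max(L[tot == 0]), ")")
  cum <- matrix(apply(v, 2L, cumsum), nrow = length(lens))
  one_perm <- function() {
    if (nreg == 0L) return(0L)
    u <- stats::runif(nreg) * tot
    ci <- colSums(matrix(cum < rep(u, each = length(lens)),
                         nrow = length(lens))) + 1L
    st <- floor(stats::runif(nreg) * v[cbind(ci, seq_len(nreg))]) + 1
    en <- st + L - 1
    hit <- logical(length(gs))
    for (j in seq_len(nreg))
      hit <- hit | (gc == ci[j] & gs <= en[j] & ge >= st[j])
    sum(hit)
  }
  run <- function() {
    observed <- count_gene_overlaps(genes, regions)
    permuted <- vapply(seq_len(n_perm), function(i) one_perm(), integer(1))
    list(observed = observed, permuted = permuted)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  observed <- res$observed; permuted <- res$permuted
  m <- mean(permuted); s <- stats::sd(permuted)
  if (alternative == "auto")
    alternative <- if (observed >= m) "greater" else "less"
  extreme <- if (alternative == "greater") sum(permuted >= observed)
             else sum(permuted <= observed)
  p <- (extreme + 1) / (n_perm + 1)
  z <- if (is.na(s) || s == 0) {
    warning("permuted distribution is degenerate; Z-score undefined")
    NA_real_
  } else (observed - m) / s
  critical <- if (alternative == "greater")
    stats::quantile(permuted, 1 - alpha, names = FALSE)
  else stats::quantile(permuted, alpha, names = FALSE)
  structure(list(observed = observed, permuted = permuted,
                 n_perm = as.integer(n_perm), mean_perm = m, sd_perm = s,
                 z_score = z, p_value = p, alternative = alternative,
                 alpha = alpha, critical = critical,
                 significant = if (alternative == "greater")
                   observed > critical else observed < critical,
                 seed = seed),
            class = "permutation_overlap_test")
}

#' @export
print.permutation_overlap_test <- function(x, ...) {
  cat("Region-randomization overlap permutation test\n")
  cat(sprintf("  observed overlap: %d genes\n", x$observed))
  cat(sprintf("  permuted: mean %.2f, sd %.2f (n_perm = %d)\n",
              x$mean_perm, x$sd_perm, x$n_perm))
  cat(sprintf("  Z-score = %.3f, P value = %.3g (alternative: %s)\n",
              x$z_score, x$p_value, x$alternative))
  cat(sprintf("  alpha = %.2f critical value: %.1f (%ssignificant)\n",
              x$alpha, x$critical, if (x$significant) "" else "not "))
  invisible(x)
}
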