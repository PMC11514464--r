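#' Drop genes with low expected counts
#'
#' Keeps genes whose expected count is strictly greater than `min_count` in
#' every library (the "more than 5 in all 3 libraries" rule; a count of
#' exactly 5 is dropped).
#'
#' @param table data.frame with a `gene` column and one column per library.
#' @param count_cols names of the count columns; defaults to every column
#'   starting with "count".
#' @param min_count strict lower bound.
#' @return the filtered table.
#' @export
filter_low_counts <- function(table, count_cols = NULL, min_count = 5) {
  if (is.null(count_cols))
    count_cols <- grep("^count", names(table), value = TRUE)
  if (length(count_cols) == 0L) stop("no count columns")
  if (nrow(table) == 0L) return(table)
  keep <- apply(as.matrix(table[count_cols]) > min_count, 1L, all)
  table[keep, , drop = FALSE]
}

#' Flag expressed genes by FPKM
#'
#' A gene is expressed when its FPKM is at least `fpkm_min` in every
#' replicate (inclusive: exactly 0.5 qualifies).
#'
#' @param table data.frame with per-replicate FPKM columns.
#' @param fpkm_cols names of the FPKM columns; defaults to every column
#'   starting with "fpkm".
#' @param fpkm_min inclusive lower bound.
#' @return logical vector along rows.
#' @export
flag_expressed <- function(table, fpkm_cols = NULL, fpkm_min = 0.5) {
  if (is.null(fpkm_cols))
    fpkm_cols <- grep("^fpkm", names(table), value = TRUE)
  if (length(fpkm_cols) == 0L) stop("no FPKM columns")
  if (nrow(table) == 0L) return(logical(0))
  apply(as.matrix(table[fpkm_cols]) >= fpkm_min, 1L, all)
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when it reaches `min_cpm` counts per million in at least
#' one library of the comparison (inclusive), its absolute log2 fold change
#' is strictly larger than `abs_lfc`, and its p-value is strictly below
#' `p_max`. Direction is the sign of the fold change.
#'
#' @param results data.frame with columns `gene`, `log2fc`, `p_value` and
#'   per-library CPM columns.
#' @param cpm_cols names of the CPM columns; defaults to every column
#'   starting with "cpm".
#' @param min_cpm,abs_lfc,p_max the three thresholds.
#' @return `results` with added `deg` (logical) and `direction`
#'   ("up"/"down", NA for non-DEGs).
#' @export
select_degs <- function(results, cpm_cols = NULL, min_cpm = 10,
                        abs_lfc = 1.5, p_max = 0.05) {
  need <- c("gene", "log2fc", "p_value")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(cpm_cols))
    cpm_cols <- grep("^cpm", names(results), value = TRUE)
  if (length(cpm_cols) == 0L) stop("no CPM columns")
  bad <- which(is.na(results$log2fc) | is.na(results$p_value))
  if (length(bad))
    stop("missing log2FC or p-value for gene ", results$gene[bad[1L]])
  max_cpm <- apply(as.matrix(results[cpm_cols]), 1L, max)
  results$deg <- max_cpm >= min_cpm &
    abs(results$log2fc) > abs_lfc &
    results$p_value < p_max
  results$direction <- ifelse(results$deg,
                              ifelse(results$log2fc > 0, "up", "down"),
                              NA_character_)
  results
}

#' Cross-classify DEGs by peak membership, stage and LAD class
#'
#' For every differentially expressed gene, membership in each stage's peak
#' set is decided by the 1 bp overlap rule; genes are then cross-classified
#' by direction (up/down), stage pattern of peak membership (both stages /
#' each single stage / outside), and cLAD class (inside/outside, "IL"/"OL").
#'
#' @param genes named `GRanges` of gene bodies (names = gene ids).
#' @param degs data.frame from [select_degs()] (only `deg` rows are used).
#' @param peaks_by_stage named list of `GRanges` peak sets, one per stage
#'   (e.g. `list(Prol = ..., D2 = ...)`).
#' @param clads optional `GRanges` of constitutive lamina-associated
#'   domains; when `NULL` every gene is classed "OL".
#' @return long data.frame (direction, stage_class, lad_class, count,
#'   fraction); fractions sum to 1 within each direction.
#' @export
summarize_gene_classes <- function(genes, degs, peaks_by_stage,
                                   clads = NULL) {
  if (is.null(names(genes))) stop("'genes' must be named by gene id")
  deg <- degs[which(degs$deg), , drop = FALSE]
  unknown <- setdiff(deg$gene, names(genes))
  if (length(unknown)) stop("unknown gene id: ", unknown[1L])
  g <- genes[deg$gene]
  stages <- names(peaks_by_stage)
  if (is.null(stages)) stop("'peaks_by_stage' must be a named list")
  inpk <- vapply(peaks_by_stage, function(p) overlaps_regions(g, p),
                 logical(length(g)))
  inpk <- matrix(inpk, nrow = length(g), ncol = length(stages),
                 dimnames = list(NULL, stages))
  stage_class <- apply(inpk, 1L, function(r) {
    if (all(r)) "both" else if (!any(r)) "outside"
    else paste(stages[r], collapse = "&")
  })
  lad_class <- if (is.null(clads)) rep("OL", length(g))
               else ifelse(overlaps_regions(g, clads), "IL", "OL")
  tab <- as.data.frame(table(direction = deg$direction,
                             stage_class = stage_class,
                             lad_class = lad_class),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  totals <- tapply(tab$count, tab$direction, sum)
  tab$fraction <- tab$count / as.numeric(totals[tab$direction])
  tab$fraction[is.nan(tab$fraction)] <- 0
  tab
}
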