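#' Normalize ChIP-qPCR percent-input values per locus and replicate
#'
#' Removes batch-to-batch variability: each %input value is divided by the
#' mean %input of its locus across all samples of the same biological
#' replicate. After normalization the per-(locus, replicate) mean is exactly
#' 1, and rescaling a whole batch leaves the values unchanged.
#'
#' When the table has an `antibody` column, IgG control rows are excluded
#' from the group mean by default (but are themselves divided by it), so the
#' normalizer reflects the specific ChIPs only; set `include_igg = TRUE` to
#' average over all rows.
#'
#' @param table data.frame with columns `locus`, `replicate`,
#'   `percent_input`, and optionally `sample` and `antibody`
#'   ("specific"/"IgG").
#' @param include_igg include IgG rows in the group mean.
#' @return the table with an added `normalized` column.
#' @export
normalize_percent_input <- function(table, include_igg = FALSE) {
  need <- c("locus", "replicate", "percent_input")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(table$percent_input < 0)) stop("percent_input must be >= 0")
  key <- interaction(table$locus, table$replicate, drop = TRUE)
  in_mean <- if (!include_igg && "antibody" %in% names(table))
    table$antibody != "IgG" else rep(TRUE, nrow(table))
  gmean <- tapply(table$percent_input[in_mean], key[in_mean], mean)
  denom <- as.numeric(gmean[as.character(key)])
  zero <- which(is.na(denom) | denom == 0)
  if (length(zero))
    stop("zero mean percent input for locus ", table$locus[zero[1L]],
         ", replicate ", table$replicate[zero[1L]])
  table$normalized <- table$percent_input / denom
  table
}

#' Fold enrichment of specific ChIP over IgG
#'
#' For every (locus, sample), pairs each technical replicate's specific
#' measurement with its matched IgG control, takes the ratio, and reports
#' mean and standard deviation (n - 1 denominator) across technical
#' replicates.
#'
#' @param table data.frame with columns `locus`, `sample`, `replicate`
#'   (technical replicate id), `antibody` ("specific"/"IgG") and `value`
#'   (%input, raw or normalized).
#' @return data.frame (locus, sample, n, mean_fold, sd_fold).
#' @export
fold_enrichment <- function(table) {
  need <- c("locus", "sample", "replicate", "antibody", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  sp <- table[table$antibody != "IgG", , drop = FALSE]
  ig <- table[table$antibody == "IgG", , drop = FALSE]
  key <- function(d) paste(d$locus, d$sample, d$replicate, sep = "\r")
  idx <- match(key(sp), key(ig))
  if (anyNA(idx)) {
    m <- which(is.na(idx))[1L]
    stop("no matched IgG measurement for locus ", sp$locus[m],
         ", sample ", sp$sample[m], ", replicate ", sp$replicate[m])
  }
  igv <- ig$value[idx]
  if (any(igv == 0)) stop("IgG value of 0 for locus ",
                          sp$locus[which(igv == 0)[1L]])
  sp$fold <- sp$value / igv
  grp <- interaction(sp$locus, sp$sample, drop = TRUE)
  out <- data.frame(
    locus = tapply(sp$locus, grp, `[`, 1L),
    sample = tapply(sp$sample, grp, `[`, 1L),
    n = as.integer(tapply(sp$fold, grp, length)),
    mean_fold = as.numeric(tapply(sp$fold, grp, mean)),
    sd_fold = as.numeric(tapply(sp$fold, grp, stats::sd)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Two-sample t-test on normalized qPCR values
#'
#' Thin reporting helper: two-tailed, two-sample, equal-variance Student's
#' t-test comparing normalized %input values between two conditions (e.g.
#' wildtype vs knockout) at one locus.
#'
#' @param x,y numeric vectors of normalized values.
#' @return list (t_statistic, df, p_value, mean_x, mean_y).
#' @export
qpcr_t_test <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}
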