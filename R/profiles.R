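## Split `len` bases into `nbins` consecutive widths; remainder bases go to
## the leftmost bins. Widths may be 0 when len < nbins.
#' @noRd
bin_breaks <- function(len, nbins) {
  base <- len %/% nbins
  rem <- len %% nbins
  base + (seq_len(nbins) <= rem)
}

## Assemble a ProfileMatrix from a long table of candidate bins.
## bins: data.frame(row, col, chrom, start, end) in 1-based closed coords,
## possibly out of chromosome bounds; clipped bases count as missing.
#' @noRd
fill_profile <- function(track, bins, n_row, n_col, layout, missing_policy) {
  lens <- layout_lengths(layout)
  start <- pmax(bins$start, 1)
  end <- pmin(bins$end, lens[bins$chrom])
  ok <- !is.na(bins$start) & start <= end
  mat <- matrix(NA_real_, n_row, n_col)
  covered <- matrix(0, n_row, n_col)
  if (any(ok)) {
    gr <- GenomicRanges::GRanges(
      seqnames = factor(bins$chrom[ok], levels = names(lens)),
      ranges = IRanges::IRanges(start = start[ok], end = end[ok]),
      seqinfo = layout)
    im <- interval_means(track, gr, missing_policy)
    idx <- cbind(bins$row[ok], bins$col[ok])
    mat[idx] <- im$mean
    covered[idx] <- im$covered
  }
  list(values = mat, covered = covered)
}

#' Scaled meta-region signal profile
#'
#' Rescales each region body to a common percentage axis: the body is split
#' into `body_bins` equal-length sub-intervals (remainder bases to the
#' leftmost bins) and each flank spans exactly one region-length, split into
#' `flank_bins` sub-intervals -- the layout used for plots where the full
#' region length is 100% and one region-length is shown up- and downstream.
#' Minus-strand regions are reversed so columns always read 5' to 3'.
#' Flanks are clipped at chromosome ends; clipped bases count as missing.
#'
#' @param track a signal track.
#' @param regions non-empty `GRanges` on the track's layout.
#' @param body_bins,flank_bins number of bins for the body and each flank
#'   (default 100, i.e. 1% of the region per body bin).
#' @param missing_policy see [mean_over_interval()].
#' @return a `profile_matrix`: rows = regions, columns =
#'   upstream flank / body / downstream flank bins; attribute `covered`
#'   holds per-cell covered-base counts.
#' @export
scaled_region_profile <- function(track, regions, body_bins = 100L,
                                  flank_bins = 100L,
                                  missing_policy = c("exclude_missing",
                                                     "zero_fill")) {
  if (length(regions) == 0L) stop("empty region set")
  stopifnot(body_bins >= 1L, flank_bins >= 1L)
  check_same_layout(track, regions)
  missing_policy <- match.arg(missing_policy)
  layout <- GenomeInfoDb::seqinfo(regions)
  n_col <- 2L * flank_bins + body_bins
  rows <- lapply(seq_along(regions), function(i) {
    s <- GenomicRanges::start(regions)[i]
    e <- GenomicRanges::end(regions)[i]
    L <- e - s + 1L
    chrom <- as.character(GenomicRanges::seqnames(regions))[i]
    wf <- bin_breaks(L, flank_bins)
    wb <- bin_breaks(L, body_bins)
    w <- c(wf, wb, wf)
    starts <- (s - L) + cumsum(c(0, w[-length(w)]))
    df <- data.frame(row = i, col = seq_len(n_col), chrom = chrom,
                     start = starts, end = starts + w - 1)
    df$start[w == 0L] <- NA  # degenerate bin when region shorter than bins
    if (as.character(GenomicRanges::strand(regions))[i] == "-")
      df$col <- rev(df$col)
    df
  })
  bins <- do.call(rbind, rows)
  out <- fill_profile(track, bins, length(regions), n_col, layout,
                      missing_policy)
  mat <- out$values
  colnames(mat) <- c(paste0("U", seq_len(flank_bins)),
                     paste0("B", seq_len(body_bins)),
                     paste0("D", seq_len(flank_bins)))
  rownames(mat) <- names(regions)
  structure(mat, covered = out$covered, kind = "scaled",
            body_bins = body_bins, flank_bins = flank_bins,
            class = c("profile_matrix", "matrix", "array"))
}

#' Anchor-centred signal profile
#'
#' Fixed-width profile matrix centred on single positions -- typically
#' strand-aware transcription start sites -- with `flank_bp` bases on each
#' side cut into `bin_bp` bins. Minus-strand anchors are flipped so columns
#' read 5' to 3'; bins beyond chromosome ends are missing.
#'
#' @param track a signal track.
#' @param anchors a `GRanges`; the anchor of each range is its strand-aware
#'   5' end (start for "+" or "*", end for "-").
#' @param flank_bp half-width of the profile in bp; must be a multiple of
#'   `bin_bp`.
#' @param bin_bp bin width in bp.
#' @inheritParams scaled_region_profile
#' @return a `profile_matrix` with `2 * flank_bp / bin_bp` columns named by
#'   the bin's left offset from the anchor.
#' @export
anchored_profile <- function(track, anchors, flank_bp = 50000L,
                             bin_bp = 1000L,
                             missing_policy = c("exclude_missing",
                                                "zero_fill")) {
  if (length(anchors) == 0L) stop("empty anchor set")
  if (flank_bp %% bin_bp != 0L)
    stop("'flank_bp' must be a multiple of 'bin_bp'")
  check_same_layout(track, anchors)
  missing_policy <- match.arg(missing_policy)
  layout <- GenomeInfoDb::seqinfo(anchors)
  n_col <- as.integer(2L * flank_bp / bin_bp)
  minus <- as.character(GenomicRanges::strand(anchors)) == "-"
  pos <- ifelse(minus, GenomicRanges::end(anchors),
                GenomicRanges::start(anchors))
  offsets <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  rows <- lapply(seq_along(anchors), function(i) {
    starts <- pos[i] + offsets
    df <- data.frame(row = i, col = seq_len(n_col),
                     chrom = as.character(
                       GenomicRanges::seqnames(anchors))[i],
                     start = starts, end = starts + bin_bp - 1)
    if (minus[i]) df$col <- rev(df$col)
    df
  })
  bins <- do.call(rbind, rows)
  out <- fill_profile(track, bins, length(anchors), n_col, layout,
                      missing_policy)
  mat <- out$values
  colnames(mat) <- as.character(offsets)
  rownames(mat) <- names(anchors)
  structure(mat, covered = out$covered, kind = "anchored",
            bin_bp = bin_bp, flank_bp = flank_bp,
            class = c("profile_matrix", "matrix", "array"))
}

#' Aggregate a profile matrix across regions
#'
#' Per-bin mean or median over the non-missing rows, the summary drawn above
#' profile heatmaps.
#'
#' @param mat a `profile_matrix`.
#' @param statistic "mean" or "median".
#' @return named numeric vector (one value per bin; `NA` where every row is
#'   missing) with attribute `statistic`.
#' @export
aggregate_profile <- function(mat, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (nrow(mat) == 0L) stop("empty profile matrix")
  fun <- if (statistic == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) stats::median(x, na.rm = TRUE)
  }
  v <- apply(unclass(mat), 2L, fun)
  v[!is.finite(v)] <- NA_real_
  structure(v, statistic = statistic)
}

#' Write a profile matrix (or aggregate) as TSV
#'
#' The first line is a comment recording the bin structure.
#'
#' @param mat a `profile_matrix`.
#' @param path output path.
#' @export
write_profile <- function(mat, path) {
  hdr <- if (attr(mat, "kind") == "scaled") {
    sprintf("# scaled profile: flank_bins=%d body_bins=%d flank_bins=%d",
            attr(mat, "flank_bins"), attr(mat, "body_bins"),
            attr(mat, "flank_bins"))
  } else {
    sprintf("# anchored profile: flank_bp=%d bin_bp=%d",
            attr(mat, "flank_bp"), attr(mat, "bin_bp"))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(unclass(mat)), con, sep = "\t",
                     quote = FALSE, row.names = !is.null(rownames(mat)),
                     col.names = TRUE)
  invisible(path)
}
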