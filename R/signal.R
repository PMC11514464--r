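#' Construct a signal track
#'
#' A signal track is a set of sorted, non-overlapping genomic steps each
#' carrying one numeric value -- the in-memory form of a bedGraph, holding
#' log2(ChIP/input) ratios or coverage. Bases covered by no step are
#' "missing" and are excluded from (or zero-filled into) downstream means
#' according to the caller's missing policy.
#'
#' @param steps a `GRanges` with a numeric `score` column, on a layout.
#' @param value_kind "log2_ratio" or "coverage".
#' @return the validated, sorted `GRanges`; `metadata()$value_kind` set.
#' @export
signal_track <- function(steps, value_kind = c("log2_ratio", "coverage")) {
  value_kind <- match.arg(value_kind)
  check_has_layout(steps, "signal track")
  v <- S4Vectors::mcols(steps)$score
  if (is.null(v) || !is.numeric(v))
    stop("signal track needs a numeric 'score' column")
  if (any(!is.finite(v))) stop("signal values must be finite")
  steps <- GenomicRanges::sort(steps, ignore.strand = TRUE)
  if (!GenomicRanges::isDisjoint(steps, ignore.strand = TRUE))
    stop("signal track has overlapping steps")
  S4Vectors::metadata(steps)$value_kind <- value_kind
  steps
}

#' Read a bedGraph file into a signal track
#'
#' @param path 4-column bedGraph (chrom, start, end, value; 0-based
#'   half-open). Steps may be unsorted; overlapping steps are rejected.
#' @param layout a `Seqinfo` layout.
#' @inheritParams signal_track
#' @export
read_bedgraph <- function(path, layout,
                          value_kind = c("log2_ratio", "coverage")) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(track|browser|#)", lines))
  if (length(keep) == 0L)
    return(signal_track(GenomicRanges::GRanges(score = numeric(0),
                                               seqinfo = layout),
                        match.arg(value_kind)))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed bedGraph line ", keep[which(nf < 4L)[1L]],
         ": fewer than 4 fields")
  num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  start <- num(2L); end <- num(3L); value <- num(4L)
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad))
    stop("malformed bedGraph line ", keep[bad[1L]], ": non-numeric field")
  gr <- interval_set(vapply(fields, `[[`, "", 1L), start, end, layout)
  S4Vectors::mcols(gr)$score <- value
  signal_track(gr, match.arg(value_kind))
}

#' Write a signal track as bedGraph
#'
#' @param track a signal track.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = format(GenomicRanges::start(track) - 1L, scientific = FALSE,
                   trim = TRUE),
    end = format(GenomicRanges::end(track), scientific = FALSE, trim = TRUE),
    value = format(S4Vectors::mcols(track)$score, scientific = FALSE,
                   trim = TRUE, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Base-weighted mean of track values over each of several intervals.
## Returns list(mean =, covered =): covered = bases of the interval under
## some step. Zero-width "intervals" (width0 marker allowed by callers that
## construct degenerate bins) yield covered 0.
#' @noRd
interval_means <- function(track, regions,
                           missing_policy = c("exclude_missing",
                                              "zero_fill")) {
  missing_policy <- match.arg(missing_policy)
  n <- length(regions)
  hits <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- pmin(GenomicRanges::end(regions)[qh],
            GenomicRanges::end(track)[sh]) -
    pmax(GenomicRanges::start(regions)[qh],
         GenomicRanges::start(track)[sh]) + 1
  v <- S4Vectors::mcols(track)$score[sh]
  num <- rep(0, n); cov <- rep(0, n)
  if (length(qh)) {
    aggn <- rowsum(w * v, qh); aggc <- rowsum(w, qh)
    idx <- as.integer(rownames(aggn))
    num[idx] <- aggn[, 1L]; cov[idx] <- aggc[, 1L]
  }
  if (missing_policy == "exclude_missing") {
    m <- ifelse(cov > 0, num / cov, NA_real_)
  } else {
    wid <- GenomicRanges::width(regions)
    m <- ifelse(wid > 0, num / wid, NA_real_)
  }
  list(mean = m, covered = cov)
}

#' Mean signal over one interval
#'
#' Base-weighted mean of step values over the bases of the interval that are
#' covered by the track. Under `"exclude_missing"` uncovered bases are
#' dropped (an interval with zero covered bases yields `NA`); under
#' `"zero_fill"` uncovered bases contribute 0 and the denominator is the
#' full interval width.
#'
#' @param track a signal track.
#' @param interval a length-1 `GRanges`.
#' @param missing_policy "exclude_missing" (default) or "zero_fill".
#' @return a single numeric value, `NA` if missing.
#' @export
mean_over_interval <- function(track, interval,
                               missing_policy = c("exclude_missing",
                                                  "zero_fill")) {
  stopifnot(length(interval) == 1L)
  interval_means(track, interval, missing_policy)$mean
}

#' Mean signal in consecutive windows tiling an interval
#'
#' The interval is subdivided left to right into windows of `width` bp; the
#' final partial window (shorter than `width`) is retained. This is the
#' primitive behind the per-gene binding score, which uses 10 bp windows.
#'
#' @inheritParams mean_over_interval
#' @param width window width in bp (>= 1).
#' @return numeric vector of window means (`NA` where a window has no
#'   covered bases).
#' @export
window_means <- function(track, interval, width = 10L,
                         missing_policy = c("exclude_missing",
                                            "zero_fill")) {
  stopifnot(length(interval) == 1L, width >= 1L)
  win <- GenomicRanges::slidingWindows(interval, width = as.integer(width),
                                       step = as.integer(width))[[1L]]
  interval_means(track, win, missing_policy)$mean
}
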