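#' Build an interval set on a genome layout
#'
#' Interval sets (peak sets, gene sets, lamina-associated domains) are plain
#' `GRanges` objects whose `seqinfo` carries the layout. Coordinates follow
#' the BED convention externally (0-based half-open) and the GRanges
#' convention internally (1-based closed); conversion happens only at I/O.
#'
#' @param chrom,start,end vectors of chromosome label and BED (0-based
#'   half-open) coordinates.
#' @param layout a `Seqinfo` from [genome_layout()].
#' @param name optional interval labels.
#' @param strand optional strand ("+", "-" or "*"); overlap and distance
#'   operations ignore it, profiles honour it.
#' @return a `GRanges` on `layout`.
#' @export
interval_set <- function(chrom, start, end, layout, name = NULL,
                         strand = NULL) {
  chrom <- as.character(chrom)
  known <- GenomeInfoDb::seqnames(layout)
  bad <- setdiff(unique(chrom), known)
  if (length(bad))
    stop("unknown chromosome: ", paste(bad, collapse = ", "))
  if (any(start < 0) || any(end <= start))
    stop("invalid coordinates: require 0 <= start < end")
  lens <- layout_lengths(layout)
  over <- end > lens[chrom]
  if (any(over))
    stop("interval beyond chromosome end on ",
         paste(unique(chrom[over]), collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = known),
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = if (is.null(strand)) rep("*", length(chrom))
             else rep_len(as.character(strand), length(chrom)),
    seqinfo = layout)
  if (!is.null(name)) names(gr) <- name
  gr
}

#' Read a BED3/BED6 file into an interval set
#'
#' Parses tab- (or space-) separated BED lines, validates every interval
#' against the layout, and reports malformed lines by line number.
#' `track`/`browser` header lines and blank lines are skipped.
#'
#' @inheritParams interval_set
#' @param path path to the BED file.
#' @return a `GRanges` on `layout`; empty file yields an empty set.
#' @export
read_bed <- function(path, layout) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(track|browser|#)", lines))
  if (length(keep) == 0L)
    return(GenomicRanges::GRanges(seqinfo = layout))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", keep[which(nf < 3L)[1L]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", keep[bad[1L]], ": non-numeric coordinates")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  ""), NA_character_)
  strand <- ifelse(nf >= 6L,
                   vapply(fields, function(f) f[min(6L, length(f))], ""),
                   "*")
  strand[!strand %in% c("+", "-")] <- "*"
  interval_set(chrom, start, end, layout,
               name = if (all(is.na(name))) NULL else name,
               strand = strand)
}

#' Write an interval set as BED
#'
#' @param x a `GRanges`.
#' @param path output path.
#' @param score numeric score column (defaults to 0).
#' @export
write_bed <- function(x, path, score = NULL) {
  n <- length(x)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = format(GenomicRanges::start(x) - 1L, scientific = FALSE,
                   trim = TRUE),
    end = format(GenomicRanges::end(x), scientific = FALSE, trim = TRUE))
  nm <- names(x)
  if (!is.null(nm) || !is.null(score)) {
    df$name <- if (is.null(nm)) rep(".", n) else nm
    df$score <- if (is.null(score)) rep(0, n) else score
    df$strand <- as.character(GenomicRanges::strand(x))
    df$strand[df$strand == "*"] <- "."
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge an interval set
#'
#' Collapses overlapping and book-ended intervals into their union
#' (strand-blind), as `bedtools merge` does. Base-pair totals over the set
#' are unchanged.
#'
#' @param x a `GRanges`.
#' @return a sorted, disjoint `GRanges`; `metadata(x)$merged` is `TRUE`.
#' @export
merge_intervals <- function(x) {
  check_has_layout(x)
  out <- GenomicRanges::reduce(x, ignore.strand = TRUE)
  S4Vectors::metadata(out)$merged <- TRUE
  out
}

#' Total genomic bases covered by an interval set
#'
#' @param x a `GRanges` (merged internally).
#' @return covered bases (bp).
#' @export
covered_bases <- function(x) sum(GenomicRanges::width(merge_intervals(x)))

#' Base pairs shared by two interval sets
#'
#' Total bases covered by both sets (the `bedtools intersect` total),
#' symmetric in its arguments; both sets are merged internally.
#'
#' @param a,b `GRanges` on one layout.
#' @return shared bases (bp).
#' @export
intersect_length <- function(a, b) {
  check_same_layout(a, b)
  sum(GenomicRanges::width(
    GenomicRanges::intersect(merge_intervals(a), merge_intervals(b),
                             ignore.strand = TRUE)))
}

#' Base-pair Venn partition of two or three interval sets
#'
#' Splits the union of k = 2 or 3 merged interval sets into its 2^k - 1
#' disjoint membership classes and reports the total genomic length of each
#' class, the quantity plotted as area-proportional Venn diagrams of broad
#' ChIP domains.
#'
#' @param sets a named list of 2 or 3 `GRanges` on one layout.
#' @return a data.frame with one logical membership column per set plus
#'   `class` (label like "A&B"), `bp` and `mb`; classes are disjoint and
#'   their `bp` sums to the merged union length.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (!k %in% c(2L, 3L))
    stop("venn_partition requires 2 or 3 interval sets, got ", k)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- LETTERS[seq_len(k)]
  for (i in seq_len(k - 1L)) check_same_layout(sets[[i]], sets[[i + 1L]])
  red <- lapply(sets, merge_intervals)
  pooled <- do.call(c, unname(lapply(red, function(g) {
    S4Vectors::metadata(g) <- list(); g
  })))
  dj <- GenomicRanges::disjoin(pooled, ignore.strand = TRUE)
  member <- vapply(red, function(s)
    IRanges::overlapsAny(dj, s, ignore.strand = TRUE),
    logical(length(dj)))
  member <- matrix(member, nrow = length(dj), ncol = k,
                   dimnames = list(NULL, names(sets)))
  ## enumerate all 2^k - 1 non-empty membership classes
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  key <- function(m) apply(m, 1L, function(r) paste(as.integer(r),
                                                    collapse = ""))
  dj_key <- key(member)
  combo_key <- key(as.matrix(combos))
  bp <- vapply(combo_key, function(kk)
    sum(GenomicRanges::width(dj)[dj_key == kk]), numeric(1))
  out <- data.frame(combos,
                    class = apply(combos, 1L, function(r)
                      paste(names(sets)[as.logical(r)], collapse = "&")),
                    bp = unname(bp),
                    row.names = NULL, check.names = FALSE)
  out$mb <- out$bp / 1e6
  out
}

#' Flag query intervals overlapping a region set
#'
#' A query is flagged when it shares at least `min_bp` bases with the merged
#' region set -- the 1 bp rule used to call genes inside or outside
#' lamina-associated domains.
#'
#' @param queries,regions `GRanges` on one layout.
#' @param min_bp minimum shared bases (>= 1).
#' @return logical vector along `queries`.
#' @export
overlaps_regions <- function(queries, regions, min_bp = 1L) {
  check_same_layout(queries, regions)
  if (min_bp < 1L) stop("'min_bp' must be >= 1")
  red <- merge_intervals(regions)
  hits <- GenomicRanges::findOverlaps(queries, red, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(queries)[qh], GenomicRanges::end(red)[sh]) -
    pmax(GenomicRanges::start(queries)[qh],
         GenomicRanges::start(red)[sh]) + 1L
  per <- rep(0, length(queries))
  if (length(qh)) {
    agg <- rowsum(ov, qh)
    per[as.integer(rownames(agg))] <- agg[, 1L]
  }
  per >= min_bp
}

#' Distance from each query to its closest reference interval
#'
#' Unsigned edge-to-edge gap in bp, scanning both chromosomal directions;
#' 0 when the query overlaps (or exactly abuts) a reference interval.
#' Queries on chromosomes carrying no reference interval get `NA`
#' ("no neighbour") and are reported via an attribute rather than a
#' pseudo-distance.
#'
#' @param queries,reference `GRanges` on one layout; `reference` non-empty.
#' @return numeric vector along `queries` (NA = no neighbour on that
#'   chromosome), with attribute `n_no_neighbor`.
#' @export
closest_distance <- function(queries, reference) {
  check_same_layout(queries, reference)
  if (length(reference) == 0L) stop("reference set is empty")
  ref <- merge_intervals(reference)
  hits <- GenomicRanges::distanceToNearest(queries, ref,
                                           ignore.strand = TRUE)
  d <- rep(NA_real_, length(queries))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  attr(d, "n_no_neighbor") <- sum(is.na(d))
  d
}
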