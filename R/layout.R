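#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths that
#' every interval set and signal track in an analysis is validated against.
#' It is represented as a [GenomeInfoDb::Seqinfo] object so that layouts plug
#' directly into `GRanges` containers.
#'
#' @param chrom_lengths named numeric vector; names are unique chromosome
#'   labels, values are lengths in base pairs (all > 0).
#' @return a `Seqinfo` object.
#' @examples
#' genome_layout(c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7))
#' @export
genome_layout <- function(chrom_lengths) {
  if (!is.numeric(chrom_lengths) || length(chrom_lengths) == 0L)
    stop("'chrom_lengths' must be a non-empty named numeric vector")
  nm <- names(chrom_lengths)
  if (is.null(nm) || any(!nzchar(nm)) || anyNA(nm))
    stop("every chromosome must be named")
  if (anyDuplicated(nm))
    stop("duplicated chromosome name: ", nm[duplicated(nm)][1L])
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be finite and > 0")
  GenomeInfoDb::Seqinfo(seqnames = nm,
                        seqlengths = as.integer(chrom_lengths))
}

#' Read a two-column chrom-sizes file into a genome layout
#'
#' @param path path to a tab-separated file with columns chromosome name and
#'   length in bp (the UCSC `chrom.sizes` convention).
#' @return a `Seqinfo` layout.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) == 0L) stop("empty chrom-sizes file: ", path)
  genome_layout(stats::setNames(df$length, df$chrom))
}

#' @noRd
layout_lengths <- function(layout) {
  stats::setNames(as.numeric(GenomeInfoDb::seqlengths(layout)),
                  GenomeInfoDb::seqnames(layout))
}

## Total genome size in bp.
#' @noRd
layout_size <- function(layout) sum(layout_lengths(layout))

## Every interval operation requires both operands to live on one layout.
#' @noRd
check_same_layout <- function(a, b) {
  sa <- GenomeInfoDb::seqinfo(a); sb <- GenomeInfoDb::seqinfo(b)
  if (!identical(GenomeInfoDb::seqnames(sa), GenomeInfoDb::seqnames(sb)) ||
      !identical(GenomeInfoDb::seqlengths(sa), GenomeInfoDb::seqlengths(sb)))
    stop("interval sets are defined on different genome layouts")
  invisible(TRUE)
}

#' @noRd
check_has_layout <- function(gr, what = "interval set") {
  if (anyNA(GenomeInfoDb::seqlengths(gr)))
    stop(what, " has no genome layout (missing seqlengths)")
  invisible(TRUE)
}
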