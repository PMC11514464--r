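#' Bin closest distances into distance classes
#'
#' The first class holds exactly-zero distances (query overlaps a region);
#' subsequent classes are half-open `(lo, hi]` between consecutive edges,
#' with a final open-ended class beyond the last edge. `NA` distances
#' ("no neighbour on the chromosome") are excluded and counted separately.
#'
#' @param distances numeric vector from [closest_distance()] (>= 0 or NA).
#' @param bin_edges strictly increasing bp thresholds starting at 0;
#'   defaults to 0, 10 kb, 100 kb, 1 Mb.
#' @param label optional label of the gene class.
#' @return data.frame (bin, count) with attributes `n_no_neighbor` and
#'   `label`; counts sum to the number of queries with a neighbour.
#' @export
bin_distances <- function(distances, bin_edges = c(0, 1e4, 1e5, 1e6),
                          label = NULL) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("'bin_edges' must be strictly increasing")
  if (bin_edges[1L] != 0) stop("'bin_edges' must start at 0")
  if (any(distances < 0, na.rm = TRUE)) stop("distances must be >= 0")
  n_na <- sum(is.na(distances))
  d <- distances[!is.na(distances)]
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  inner <- if (length(bin_edges) > 1L) {
    paste0("(", fmt(bin_edges[-length(bin_edges)]), "-",
           fmt(bin_edges[-1L]), "]")
  } else character(0)
  labs <- c("0 (overlap)", inner,
            paste0(">", fmt(bin_edges[length(bin_edges)])))
  edges <- c(bin_edges, Inf)
  counts <- integer(length(labs))
  counts[1L] <- sum(d == 0)
  for (i in 2:length(counts))
    counts[i] <- sum(d > edges[i - 1L] & d <= edges[i])
  out <- data.frame(bin = labs, count = counts, stringsAsFactors = FALSE)
  attr(out, "n_no_neighbor") <- n_na
  attr(out, "label") <- label
  out
}

## Two-sample KS statistic: sup |ECDF_a - ECDF_b|.
#' @noRd
ks_statistic <- function(a, b) {
  w <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(w) - stats::ecdf(b)(w)))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two raw (unbinned) distance samples. `method = "asymptotic"`
#' uses the standard asymptotic two-sided p-value; `method = "exact"`
#' enumerates every assignment of the pooled values to the two groups and
#' reports the proportion with a KS statistic at least as large as observed
#' -- exact under ties, feasible for small samples (the enumeration is
#' capped at 500000 assignments).
#'
#' @param a,b non-empty numeric samples.
#' @param method "asymptotic" (default) or "exact".
#' @return list of class `ks_result`: `d_statistic`, `p_value`,
#'   `p_adjusted` (NA until adjusted), `n_a`, `n_b`, `method`.
#' @export
ks_compare <- function(a, b, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  d <- ks_statistic(a, b)
  p <- if (method == "asymptotic") {
    suppressWarnings(stats::ks.test(a, b, exact = FALSE)$p.value)
  } else {
    pooled <- c(a, b)
    n <- length(a); m <- length(b)
    if (choose(n + m, n) > 5e5)
      stop("exact enumeration infeasible for these sample sizes")
    combos <- utils::combn(n + m, n)
    hits <- 0L
    for (j in seq_len(ncol(combos))) {
      ia <- combos[, j]
      if (ks_statistic(pooled[ia], pooled[-ia]) >= d - 1e-12)
        hits <- hits + 1L
    }
    hits / ncol(combos)
  }
  structure(list(d_statistic = d, p_value = p, p_adjusted = NA_real_,
                 n_a = length(a), n_b = length(b), method = method),
            class = "ks_result")
}

#' Hochberg step-up multiple-testing adjustment
#'
#' Adjusts a family of p-values (here: all relevant KS tests) with the
#' Hochberg step-up procedure, controlling family-wise error.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, original order.
#' @export
hochberg_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "hochberg")
}

#' Run a family of KS comparisons with Hochberg correction
#'
#' @param samples named list of numeric distance samples.
#' @param pairs optional 2-column character matrix of sample names to
#'   compare; defaults to all pairs.
#' @param method passed to [ks_compare()].
#' @return data.frame (sample_a, sample_b, n_a, n_b, d_statistic, p_value,
#'   p_adjusted), adjusted across the whole family.
#' @export
ks_family <- function(samples, pairs = NULL,
                      method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  nm <- names(samples)
  if (is.null(pairs)) pairs <- t(utils::combn(nm, 2L))
  res <- apply(pairs, 1L, function(pr)
    ks_compare(samples[[pr[1L]]], samples[[pr[2L]]], method = method))
  out <- data.frame(sample_a = pairs[, 1L], sample_b = pairs[, 2L],
                    n_a = vapply(res, `[[`, 0L, "n_a"),
                    n_b = vapply(res, `[[`, 0L, "n_b"),
                    d_statistic = vapply(res, `[[`, 0, "d_statistic"),
                    p_value = vapply(res, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE)
  out$p_adjusted <- hochberg_adjust(out$p_value)
  out
}
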