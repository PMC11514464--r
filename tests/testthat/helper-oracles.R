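# Per-base brute-force oracles and random-instance generators. Everything
# here works on explicit base vectors (genomes <= 1 Mb), independent of the
# interval arithmetic under test.

rand_layout <- function(n_chrom = 2L, min_len = 2000, max_len = 10000) {
  lens <- sample(min_len:max_len, n_chrom, replace = TRUE)
  genome_layout(stats::setNames(lens, paste0("chr", seq_len(n_chrom))))
}

# random interval set in BED coordinates
rand_intervals <- function(layout, n, max_w = 500) {
  lens <- GenomeInfoDb::seqlengths(layout)
  chrom <- sample(names(lens), n, replace = TRUE)
  w <- sample(max_w, n, replace = TRUE)
  start <- floor(runif(n) * (lens[chrom] - w))
  interval_set(chrom, start, start + w, layout)
}

# logical coverage mask per chromosome (index i = base i-1 in BED coords)
mask_of <- function(gr, layout) {
  lens <- GenomeInfoDb::seqlengths(layout)
  masks <- lapply(lens, function(l) logical(l))
  for (i in seq_along(gr)) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    masks[[ch]][GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  }
  masks
}

oracle_intersect_length <- function(a, b, layout) {
  ma <- mask_of(a, layout); mb <- mask_of(b, layout)
  sum(mapply(function(x, y) sum(x & y), ma, mb))
}

oracle_union_length <- function(sets, layout) {
  ms <- lapply(sets, mask_of, layout = layout)
  sum(vapply(seq_along(ms[[1]]), function(ci)
    sum(Reduce(`|`, lapply(ms, `[[`, ci))), numeric(1)))
}

# bp per membership class, keyed like "101" (in A, not B, in C)
oracle_venn <- function(sets, layout) {
  ms <- lapply(sets, mask_of, layout = layout)
  out <- new.env()
  for (ci in seq_along(ms[[1]])) {
    mem <- sapply(ms, `[[`, ci)   # bases x sets
    key <- apply(mem, 1L, function(r) paste(as.integer(r), collapse = ""))
    tab <- table(key[rowSums(mem) > 0])
    for (k in names(tab))
      assign(k, (if (exists(k, out)) get(k, out) else 0) + tab[[k]], out)
  }
  as.list(out)
}

# per-query overlap bases with a region set
oracle_overlap_bp <- function(queries, regions, layout) {
  mr <- mask_of(regions, layout)
  vapply(seq_along(queries), function(i) {
    ch <- as.character(GenomicRanges::seqnames(queries))[i]
    sum(mr[[ch]][GenomicRanges::start(queries)[i]:
                   GenomicRanges::end(queries)[i]])
  }, numeric(1))
}

# exhaustive all-pairs minimum edge-to-edge gap (0 on overlap or adjacency)
oracle_closest <- function(queries, reference) {
  qs <- GenomicRanges::start(queries); qe <- GenomicRanges::end(queries)
  rs <- GenomicRanges::start(reference); re <- GenomicRanges::end(reference)
  qc <- as.character(GenomicRanges::seqnames(queries))
  rc <- as.character(GenomicRanges::seqnames(reference))
  vapply(seq_along(queries), function(i) {
    j <- which(rc == qc[i])
    if (!length(j)) return(NA_real_)
    min(pmax(0, pmax(rs[j] - qe[i] - 1, qs[i] - re[j] - 1)))
  }, numeric(1))
}

# expand a signal track to one value per base (NA where missing)
expand_track <- function(track, layout) {
  lens <- GenomeInfoDb::seqlengths(layout)
  vecs <- lapply(lens, function(l) rep(NA_real_, l))
  v <- S4Vectors::mcols(track)$score
  for (i in seq_along(track)) {
    ch <- as.character(GenomicRanges::seqnames(track))[i]
    vecs[[ch]][GenomicRanges::start(track)[i]:
                 GenomicRanges::end(track)[i]] <- v[i]
  }
  vecs
}

# mean over 1-based closed [s, e] of a base vector under a missing policy
oracle_base_mean <- function(vec, s, e, policy = "exclude_missing") {
  if (e < s) return(NA_real_)
  x <- vec[s:e]
  if (policy == "exclude_missing") {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    sum(x, na.rm = TRUE) / length(x)
  }
}

oracle_window_means <- function(track, interval, width, layout,
                                policy = "exclude_missing") {
  vec <- expand_track(track, layout)[[
    as.character(GenomicRanges::seqnames(interval))]]
  s <- GenomicRanges::start(interval); e <- GenomicRanges::end(interval)
  starts <- seq(s, e, by = width)
  vapply(starts, function(ws)
    oracle_base_mean(vec, ws, min(ws + width - 1, e), policy), numeric(1))
}

# random disjoint step track over a layout
rand_track <- function(layout, n_steps = 30L, gap_prob = 0.3) {
  lens <- GenomeInfoDb::seqlengths(layout)
  parts <- lapply(names(lens), function(ch) {
    bk <- sort(sample(0:lens[[ch]], min(n_steps, lens[[ch]] - 1)))
    bk <- unique(c(0, bk, lens[[ch]]))
    s <- bk[-length(bk)]; e <- bk[-1]
    keep <- runif(length(s)) > gap_prob & e > s
    if (!any(keep)) keep[1] <- TRUE
    g <- interval_set(rep(ch, sum(keep)), s[keep], e[keep], layout)
    S4Vectors::mcols(g)$score <- round(rnorm(sum(keep)), 3)
    g
  })
  signal_track(do.call(c, parts))
}

# direct Hochberg step-up formula
oracle_hochberg <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min((m - (i:m) + 1) * ps[i:m]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive two-sample KS permutation p-value (independent coding)
oracle_ks_exact <- function(a, b) {
  ksd <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t),
                   numeric(1))))
  }
  d0 <- ksd(a, b)
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  mean(apply(idx, 2L, function(ia)
    ksd(pooled[ia], pooled[-ia]) >= d0 - 1e-12))
}

# small shared fixture config for desk-scale module tests
small_config <- function(seed = 1L, n_genes = 60L, n_up = 10L,
                         n_down = 15L, step_bp = 200L, ...) {
  sim_config(seed = seed,
             chrom_lengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
             n_genes = n_genes, n_up = n_up, n_down = n_down,
             gene_length_range = c(1e3, 5e3),
             domain_length_range = c(5e4, 1.5e5),
             clad_length_range = c(3e4, 1e5),
             n_narrow_peaks = 30L, step_bp = step_bp, ...)
}
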