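lay <- genome_layout(c(chrA = 1000, chrB = 500))

const_track <- function(value, layout = lay) {
  lens <- GenomeInfoDb::seqlengths(layout)
  g <- interval_set(names(lens), rep(0, length(lens)), lens, layout)
  S4Vectors::mcols(g)$score <- value
  signal_track(g)
}

step_track <- function(starts, ends, values, chrom = "chrA",
                       layout = lay) {
  g <- interval_set(rep(chrom, length(starts)), starts, ends, layout)
  S4Vectors::mcols(g)$score <- values
  signal_track(g)
}

test_that("read_bedgraph parses, rejects overlap, and round-trips", {
  f <- withr::local_tempfile()
  writeLines("chrA\t0\t100\t1.5", f)
  tr <- read_bedgraph(f, lay)
  expect_length(tr, 1L)
  expect_equal(S4Vectors::mcols(tr)$score, 1.5)
  expect_equal(S4Vectors::metadata(tr)$value_kind, "log2_ratio")

  writeLines(c("chrA\t0\t100\t1.5", "chrA\t50\t150\t2"), f)
  expect_error(read_bedgraph(f, lay), "overlapping")
  writeLines("chrA\t0\t100\tNaNope", f)
  expect_error(read_bedgraph(f, lay), "line 1")

  tr0 <- step_track(c(0, 50, 400), c(50, 100, 600), c(-1.25, 2, 0.5))
  write_bedgraph(tr0, f)
  back <- read_bedgraph(f, lay)
  expect_equal(GenomicRanges::ranges(back), GenomicRanges::ranges(tr0),
               ignore_attr = TRUE)
  expect_equal(S4Vectors::mcols(back)$score, S4Vectors::mcols(tr0)$score)
})

test_that("mean_over_interval: constants, forced arithmetic, policies", {
  ct <- const_track(3.25)
  expect_equal(mean_over_interval(ct, interval_set("chrA", 17, 830, lay)),
               3.25)
  tr <- step_track(c(0, 50), c(50, 100), c(0, 2))
  iv <- interval_set("chrA", 0, 100, lay)
  expect_equal(mean_over_interval(tr, iv), 1.0)
  gap <- interval_set("chrA", 200, 300, lay)
  expect_true(is.na(mean_over_interval(tr, gap)))
  expect_equal(mean_over_interval(tr, gap, "zero_fill"), 0)
  part <- interval_set("chrA", 50, 200, lay)   # 50 bases at 2, 100 missing
  expect_equal(mean_over_interval(tr, part), 2)
  expect_equal(mean_over_interval(tr, part, "zero_fill"), 100 / 150)
})

test_that("window_means tiles left to right keeping the partial window", {
  ct <- const_track(-0.5)
  iv <- interval_set("chrA", 0, 25, lay)
  expect_equal(window_means(ct, iv, 10), rep(-0.5, 3))
  tr <- step_track(c(0, 10, 20), c(10, 20, 25), c(1, 2, 4))
  expect_equal(window_means(tr, iv, 10), c(1, 2, 4))
})

test_that("interval and window means match the per-base oracle", {
  withr::local_seed(201)
  for (i in 1:20) {
    l <- rand_layout()
    tr <- rand_track(l)
    iv <- rand_intervals(l, 1, max_w = 500)
    for (pol in c("exclude_missing", "zero_fill")) {
      vec <- expand_track(tr, l)[[
        as.character(GenomicRanges::seqnames(iv))]]
      expect_equal(mean_over_interval(tr, iv, pol),
                   oracle_base_mean(vec, GenomicRanges::start(iv),
                                    GenomicRanges::end(iv), pol),
                   tolerance = 1e-9)
      expect_equal(window_means(tr, iv, 7, pol),
                   oracle_window_means(tr, iv, 7, l, pol),
                   tolerance = 1e-9)
    }
  }
})

test_that("scaled_region_profile: constant track, plateau, bin structure", {
  ct <- const_track(2.5)
  regs <- interval_set(c("chrA", "chrA"), c(300, 600), c(500, 700), lay)
  pm <- scaled_region_profile(ct, regs, body_bins = 10, flank_bins = 5)
  expect_equal(dim(pm), c(2L, 20L))
  expect_true(all(unclass(pm) == 2.5))

  plat <- step_track(c(0, 300, 500), c(300, 500, 1000), c(0, 2, 0))
  pm2 <- scaled_region_profile(plat, interval_set("chrA", 300, 500, lay),
                               body_bins = 10, flank_bins = 10)
  expect_equal(as.numeric(pm2[1, 11:20]), rep(2, 10))   # body
  expect_equal(as.numeric(pm2[1, c(1:10, 21:30)]), rep(0, 20))
  expect_error(scaled_region_profile(ct, regs[0]), "empty")
})

test_that("strand flip reverses profile columns (involution)", {
  withr::local_seed(202)
  tr <- rand_track(lay, n_steps = 40)
  plus <- interval_set("chrA", 200, 420, lay, strand = "+")
  minus <- interval_set("chrA", 200, 420, lay, strand = "-")
  pp <- scaled_region_profile(tr, plus, body_bins = 7, flank_bins = 3)
  pp_m <- scaled_region_profile(tr, minus, body_bins = 7, flank_bins = 3)
  expect_equal(as.numeric(pp_m[1, ]), rev(as.numeric(pp[1, ])))
})

test_that("scaled profile values match a per-base binning oracle", {
  withr::local_seed(203)
  oracle_row <- function(tr, l, chrom, s, e, nb, nf) {
    vec <- expand_track(tr, l)[[chrom]]
    L <- e - s + 1
    bw <- function(len, k) (len %/% k) + (seq_len(k) <= len %% k)
    w <- c(bw(L, nf), bw(L, nb), bw(L, nf))
    starts <- (s - L) + cumsum(c(0, w[-length(w)]))
    mapply(function(ws, wd) {
      if (wd == 0) return(NA_real_)
      a <- max(ws, 1); b <- min(ws + wd - 1, length(vec))
      if (a > b) NA_real_ else oracle_base_mean(vec, a, b)
    }, starts, w)
  }
  for (i in 1:10) {
    l <- rand_layout()
    tr <- rand_track(l)
    regs <- rand_intervals(l, 4, max_w = 300)
    pm <- scaled_region_profile(tr, regs, body_bins = 9, flank_bins = 4)
    for (r in seq_along(regs)) {
      expect_equal(as.numeric(pm[r, ]),
                   oracle_row(tr, l,
                              as.character(GenomicRanges::seqnames(regs))[r],
                              GenomicRanges::start(regs)[r],
                              GenomicRanges::end(regs)[r], 9, 4),
                   tolerance = 1e-9)
    }
  }
})

test_that("anchored_profile centres on strand-aware anchors and clips", {
  ct <- const_track(1)
  g <- interval_set("chrA", 500, 600, lay, strand = "+")
  ap <- anchored_profile(ct, g, flank_bp = 100, bin_bp = 20)
  expect_equal(dim(ap), c(1L, 10L))
  expect_true(all(unclass(ap) == 1))

  edge <- interval_set("chrA", 0, 100, lay, strand = "+")
  ape <- anchored_profile(ct, edge, flank_bp = 100, bin_bp = 20)
  expect_true(all(is.na(ape[1, 1:5])))   # upstream of base 0
  expect_true(all(ape[1, 6:10] == 1))
  expect_error(anchored_profile(ct, g, flank_bp = 90, bin_bp = 20),
               "multiple")

  ## minus-strand anchor at end; compare with mirrored plus-strand oracle
  withr::local_seed(204)
  tr <- rand_track(lay, 40)
  gm <- interval_set("chrA", 300, 500, lay, strand = "-")
  apm <- anchored_profile(tr, gm, flank_bp = 100, bin_bp = 20)
  vec <- expand_track(tr, lay)$chrA
  pos <- 500                       # 1-based anchor = end for minus strand
  want <- vapply(seq(pos + 100 - 20, pos - 100, by = -20), function(ws)
    oracle_base_mean(vec, ws, ws + 19), numeric(1))
  expect_equal(as.numeric(apm[1, ]), want, tolerance = 1e-9)
})

test_that("aggregate_profile computes per-bin means and medians", {
  m <- structure(rbind(c(0, 0), c(2, 0), c(NA, 9)),
                 kind = "scaled", body_bins = 2L, flank_bins = 0L,
                 class = c("profile_matrix", "matrix", "array"))
  expect_equal(as.numeric(aggregate_profile(m, "mean")), c(1, 3))
  expect_equal(as.numeric(aggregate_profile(m, "median")), c(1, 0))
  one <- m[1, , drop = FALSE]
  expect_equal(as.numeric(aggregate_profile(one, "mean")), c(0, 0))
  expect_equal(as.numeric(aggregate_profile(one, "median")), c(0, 0))
})
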