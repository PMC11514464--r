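lay <- genome_layout(c(chrA = 1000, chrB = 500))

test_that("gene_binding_scores averages 10 bp window means over gene bodies", {
  lens <- GenomeInfoDb::seqlengths(lay)
  g <- interval_set(names(lens), rep(0, 2), lens, lay)
  S4Vectors::mcols(g)$score <- 0.7
  ct <- signal_track(g)
  genes <- interval_set(c("chrA", "chrB"), c(100, 50), c(225, 300), lay,
                        name = c("g1", "g2"))
  bs <- gene_binding_scores(ct, genes)
  expect_equal(bs$average_log2, c(0.7, 0.7))

  st <- interval_set(rep("chrA", 3), c(0, 10, 20), c(10, 20, 25), lay)
  S4Vectors::mcols(st)$score <- c(1, 2, 4)
  tr <- signal_track(st)
  one <- interval_set("chrA", 0, 25, lay, name = "g")
  expect_equal(gene_binding_scores(tr, one)$average_log2, 7 / 3)
  ## gene with zero covered bases is unscored
  far <- interval_set("chrA", 500, 600, lay, name = "far")
  expect_true(is.na(gene_binding_scores(tr, far)$average_log2))
  expect_error(gene_binding_scores(tr, far[0]), "empty")
})

test_that("binding scores match an explicit window-tiling oracle", {
  withr::local_seed(301)
  for (i in 1:10) {
    l <- rand_layout()
    tr <- rand_track(l)
    genes <- rand_intervals(l, 10, max_w = 300)
    names(genes) <- paste0("g", seq_along(genes))
    bs <- gene_binding_scores(tr, genes, window_bp = 10)
    for (k in seq_along(genes)) {
      wm <- oracle_window_means(tr, genes[k], 10, l)
      want <- if (all(is.na(wm))) NA_real_ else mean(wm, na.rm = TRUE)
      expect_equal(bs$average_log2[k], want, tolerance = 1e-9)
    }
  }
})

test_that("top-fraction classification: counts, floor-with-minimum, ties", {
  tab <- data.frame(gene = sprintf("g%03d", 1:100),
                    average_log2 = sample(seq(0.01, 1, length.out = 100)),
                    n_windows = 10L, rank = NA_integer_, bound = NA)
  cl <- classify_bound_top_fraction(tab, 0.10)
  expect_equal(sum(cl$bound), 10L)
  expect_equal(sort(cl$average_log2[cl$bound]),
               sort(tab$average_log2, decreasing = TRUE)[10:1])
  expect_equal(attr(cl, "min_bound_score"),
               sort(tab$average_log2, decreasing = TRUE)[10])
  expect_true(min(cl$average_log2[cl$bound]) >=
                max(cl$average_log2[!cl$bound]))

  five <- tab[1:5, ]
  expect_equal(sum(classify_bound_top_fraction(five, 0.10)$bound), 1L)

  ties <- data.frame(gene = c("b", "a", "c"), average_log2 = c(1, 1, 1),
                     n_windows = 1L, rank = NA_integer_, bound = NA)
  t1 <- classify_bound_top_fraction(ties, 0.5)
  expect_equal(ties$gene[t1$bound], "a")   # score desc, then id asc
  ## invariant to row order
  perm <- ties[c(3, 1, 2), ]
  t2 <- classify_bound_top_fraction(perm, 0.5)
  expect_equal(sort(perm$gene[t2$bound]), sort(ties$gene[t1$bound]))
  expect_error(classify_bound_top_fraction(tab, 1.2), "fraction")
})

test_that("randomize_regions preserves lengths and is uniform over starts", {
  ## a region as long as the only chromosome has a single valid start
  tiny <- genome_layout(c(chrA = 100))
  forced <- withr::with_seed(1, randomize_regions(
    interval_set("chrA", 0, 100, tiny), tiny))
  expect_equal(GenomicRanges::start(forced), 1L)

  withr::local_seed(302)
  regs <- rand_intervals(lay, 20, max_w = 200)
  r <- randomize_regions(regs, lay)
  expect_equal(sort(GenomicRanges::width(r)),
               sort(GenomicRanges::width(regs)))
  expect_true(all(GenomicRanges::end(r) <=
                    GenomeInfoDb::seqlengths(lay)[
                      as.character(GenomicRanges::seqnames(r))]))

  ## chi-square goodness of fit of starts against the uniform law over all
  ## valid positions: a length-41 region has 960 valid starts on chrA and
  ## 460 on chrB (1420 in total); 10k placements drawn in one batch
  l2 <- genome_layout(c(chrA = 1000, chrB = 500))
  batch <- interval_set(rep("chrA", 10000), rep(0, 10000),
                        rep(41, 10000), l2)
  g <- randomize_regions(batch, l2)
  off <- ifelse(as.character(GenomicRanges::seqnames(g)) == "chrB",
                960, 0)
  draws <- GenomicRanges::start(g) + off
  cell <- cut(draws, breaks = seq(0, 1420, length.out = 21))
  pv <- stats::chisq.test(table(cell))$p.value
  expect_gt(pv, 0.01)
  expect_error(randomize_regions(interval_set("chrA", 0, 900, l2),
                                 genome_layout(c(chrX = 100))),
               "exceeds|longer")
})

test_that("count_gene_overlaps counts elements with >= 1 bp overlap", {
  genes <- interval_set(rep("chrA", 3), c(0, 100, 300), c(50, 200, 400),
                        lay)
  expect_equal(count_gene_overlaps(genes, genes[0]), 0L)
  all_in <- interval_set("chrA", 0, 1000, lay)
  expect_equal(count_gene_overlaps(genes, all_in), 3L)
  withr::local_seed(303)
  for (i in 1:10) {
    l <- rand_layout()
    g <- rand_intervals(l, 30, max_w = 100)
    r <- rand_intervals(l, 10, max_w = 400)
    expect_equal(count_gene_overlaps(g, r),
                 sum(oracle_overlap_bp(g, r, l) >= 1))
  }
})

test_that("permutation test: pseudocount p, bounds, degenerate sd", {
  l <- genome_layout(c(chrA = 10000))
  regions <- interval_set("chrA", 4000, 6000, l)
  genes <- interval_set(rep("chrA", 10), seq(4100, 5900, length.out = 10),
                        seq(4100, 5900, length.out = 10) + 50, l)
  pt <- permutation_overlap_test(genes, regions, n_perm = 99, seed = 5)
  expect_gte(pt$p_value, 1 / (pt$n_perm + 1))
  expect_lte(pt$p_value, 1)
  expect_equal(pt$observed, 10L)
  expect_equal(pt$alternative, "greater")
  ## n_perm = 1 with permuted == observed forces p = 1
  whole <- interval_set("chrA", 0, 10000, l)
  p1 <- suppressWarnings(
    permutation_overlap_test(genes, whole, n_perm = 1, seed = 1))
  expect_equal(p1$p_value, 1)
  expect_warning(
    permutation_overlap_test(genes, whole, n_perm = 5, seed = 1),
    "degenerate")
  ## same seed reproduces the whole permuted distribution
  pt2 <- permutation_overlap_test(genes, regions, n_perm = 99, seed = 5)
  expect_identical(pt$permuted, pt2$permuted)
})

test_that("bin_distances: forced cases, sentinel handling, recount oracle", {
  allz <- bin_distances(rep(0, 7))
  expect_equal(allz$count, c(7, 0, 0, 0, 0))
  ex <- bin_distances(c(0, 5e3, 5e4), c(0, 1e4, 1e5, 1e6))
  expect_equal(ex$count[1:4], c(1, 1, 1, 0))
  withna <- bin_distances(c(0, NA, 2e6, NA))
  expect_equal(attr(withna, "n_no_neighbor"), 2L)
  expect_equal(sum(withna$count), 2)
  expect_error(bin_distances(c(0, 1), c(0, 5, 5)), "increasing")
  expect_error(bin_distances(c(-1), c(0, 5)), ">= 0")

  withr::local_seed(304)
  d <- c(0, rexp(200, 1e-5))
  bd <- bin_distances(d)
  edges <- c(0, 1e4, 1e5, 1e6, Inf)
  want <- c(sum(d == 0), vapply(1:4, function(i)
    sum(d > edges[i] & d <= edges[i + 1]), numeric(1)))
  expect_equal(bd$count, want)
})

test_that("ks_compare: identity, full separation, exact enumeration", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_compare(x, x)
  expect_equal(same$d_statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- ks_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$d_statistic, 1)
  expect_error(ks_compare(numeric(0), x), "empty")

  withr::local_seed(305)
  for (i in 1:5) {
    a <- sample(0:5, 4, replace = TRUE)   # ties on purpose
    b <- sample(0:5, 5, replace = TRUE)
    ex <- ks_compare(a, b, method = "exact")
    expect_equal(ex$p_value, oracle_ks_exact(a, b))
  }
})

test_that("hochberg_adjust equals the step-up formula and p.adjust edge cases", {
  expect_equal(hochberg_adjust(0.2), 0.2)
  expect_equal(hochberg_adjust(rep(0.03, 4)), rep(0.03, 4))
  expect_equal(hochberg_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  expect_error(hochberg_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.2, 0.01, 0.8)
  expect_true(all(hochberg_adjust(p) >= p))
})

test_that("ks_family adjusts across the declared family", {
  withr::local_seed(306)
  s <- list(a = rnorm(20), b = rnorm(20, 2), c = rnorm(20))
  fam <- ks_family(s)
  expect_equal(nrow(fam), 3L)
  expect_equal(fam$p_adjusted, hochberg_adjust(fam$p_value))
  expect_true(all(fam$p_adjusted >= fam$p_value))
})
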