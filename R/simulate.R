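#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulator with defaults chosen to emulate the
#' statistical shape of a broad-domain lamina ChIP study on a desk-scale toy
#' genome: 3 chromosomes of 10 Mb; broad domains of 1-3 Mb covering 15% of
#' the genome (the middle of the 11-20% range such domain sets occupy);
#' 215 differentially expressed genes (80 up, 135 down) among 600 genes,
#' with 60% of the downregulated ones planted inside the "knockout" domain
#' set; a log2-ratio track with a positive plateau inside domains and
#' negative background outside, plus Gaussian step noise.
#'
#' @param seed integer seed; every generator output is a pure function of
#'   the config including this seed.
#' @param chrom_lengths named vector defining the toy genome.
#' @param n_genes,gene_length_range gene count and length range (bp).
#' @param domain_coverage,domain_length_range broad-domain genome-coverage
#'   target fraction and length range (bp).
#' @param clad_coverage,clad_length_range same for the synthetic cLAD set.
#' @param n_narrow_peaks,narrow_length_range narrow (MACS2-style) peak count
#'   and length range.
#' @param plateau,background,noise_sd,step_bp signal-track parameters
#'   (log2-ratio units; step width in bp).
#' @param n_up,n_down planted up-/downregulated DEG counts.
#' @param frac_down_in_domains,frac_up_in_domains fraction of down-/up-DEGs
#'   planted fully inside domains (the rest are placed clear of them).
#' @param qpcr_bio_reps,qpcr_tech_reps,qpcr_effect qPCR table shape and the
#'   fold effect planted at positive loci in the "KO" sample.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1e7, chr2 = 1e7,
                                         chr3 = 1e7),
                       n_genes = 600L,
                       gene_length_range = c(2e3, 2e4),
                       domain_coverage = 0.15,
                       domain_length_range = c(1e6, 3e6),
                       clad_coverage = 0.30,
                       clad_length_range = c(5e5, 2e6),
                       n_narrow_peaks = 200L,
                       narrow_length_range = c(200, 1000),
                       plateau = 0.8, background = -0.2,
                       noise_sd = 0.3, step_bp = 100L,
                       n_up = 80L, n_down = 135L,
                       frac_down_in_domains = 0.6,
                       frac_up_in_domains = 0.1,
                       qpcr_bio_reps = 3L, qpcr_tech_reps = 3L,
                       qpcr_effect = 3) {
  stopifnot(domain_coverage > 0, domain_coverage < 1,
            n_up + n_down <= n_genes,
            frac_down_in_domains >= 0, frac_down_in_domains <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Build the genome layout of a simulation
#'
#' The layout is part of the config, not of the random draw: changing the
#' seed changes placements but never the genome itself.
#'
#' @param config a [sim_config()].
#' @return a `Seqinfo`.
#' @export
simulate_layout <- function(config) genome_layout(config$chrom_lengths)

## Uniform placement of one interval of length L over the genome (chromosome
## weighted by valid starts). Returns c(chrom_index, start) in 1-based coords.
#' @noRd
place_uniform <- function(lens, L) {
  v <- pmax(lens - L + 1, 0)
  if (all(v == 0)) stop("length ", L, " exceeds every chromosome")
  ci <- sum(cumsum(v) < stats::runif(1) * sum(v)) + 1L
  c(ci, floor(stats::runif(1) * v[ci]) + 1)
}

#' Simulate a merged set of broad domains at a target genome coverage
#'
#' Domain lengths are drawn uniformly from `length_range` until their sum
#' reaches the coverage target; the final length is clipped so the realized
#' coverage matches the target. Domains are placed uniformly over the
#' genome by rejection sampling so that they neither overlap nor abut,
#' giving a merged set whose coverage equals the drawn total exactly.
#'
#' @param layout a `Seqinfo`.
#' @param coverage target genome fraction, in (0, 1).
#' @param length_range domain length range in bp.
#' @param max_tries placement attempts per domain before declaring the
#'   target infeasible.
#' @return a merged `GRanges`.
#' @export
simulate_broad_domains <- function(layout, coverage = 0.15,
                                   length_range = c(1e6, 3e6),
                                   max_tries = 1000L) {
  if (coverage <= 0 || coverage >= 1) stop("'coverage' must be in (0, 1)")
  lens <- layout_lengths(layout)
  target <- coverage * sum(lens)
  if (coverage > 0.6)
    stop("coverage target ", coverage,
         " infeasible for non-overlapping broad domains")
  draws <- numeric(0)
  while (sum(draws) < target) {
    remaining <- target - sum(draws)
    draws <- c(draws,
               if (remaining <= length_range[2L])
                 max(1, round(remaining))  # final length clipped to target
               else round(stats::runif(1, length_range[1L],
                                       length_range[2L])))
  }
  draws <- sort(draws, decreasing = TRUE)  # place large domains first
  chrom <- integer(0); start <- numeric(0); end <- numeric(0)
  for (L in draws) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- place_uniform(lens, L)
      ## keep >= 1 bp gap to every placed domain so the set stays merged
      same <- which(chrom == p[1L])
      conflict <- start[same] <= p[2L] + L & end[same] >= p[2L] - 1
      if (!any(conflict)) {
        chrom <- c(chrom, p[1L])
        start <- c(start, p[2L])
        end <- c(end, p[2L] + L - 1)
        placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place a ", L, " bp domain; coverage target ",
           coverage, " infeasible")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(names(lens)[chrom], levels = names(lens)),
    ranges = IRanges::IRanges(start = start, end = end),
    seqinfo = layout)
  merge_intervals(gr)
}

## Place an interval of length L subject to a predicate on the candidate.
#' @noRd
place_where <- function(lens, L, layout, ok, max_tries = 2000L) {
  for (try in seq_len(max_tries)) {
    p <- place_uniform(lens, L)
    cand <- GenomicRanges::GRanges(
      seqnames = factor(names(lens)[p[1L]], levels = names(lens)),
      ranges = IRanges::IRanges(start = p[2L], width = L),
      seqinfo = layout)
    if (ok(cand)) return(cand)
  }
  stop("could not place a ", L, " bp interval; layout too crowded")
}

#' Simulate genes with a planted differential-expression structure
#'
#' Generates non-overlapping gene bodies and a matching differential
#' expression table. A configurable fraction of downregulated (and
#' upregulated) DEGs is planted fully inside the domain set; all other
#' genes are placed clear of domains (planted DEGs) or uniformly
#' (non-DEGs). The emitted table is constructed so the threshold rules of
#' [select_degs()] recover exactly the planted DEG set: DEGs get
#' |log2FC| >= 1.6, p <= 0.049 and one library's CPM >= 10, while non-DEGs
#' fail exactly one rule (small fold change, or p > 0.05, or all CPM < 10).
#'
#' @param layout a `Seqinfo`.
#' @param domains merged `GRanges` of broad domains.
#' @param config a [sim_config()].
#' @return list with `genes` (named stranded `GRanges`, mcols `class` in
#'   up/down/none) and `de` (data.frame gene, log2fc, p_value, cpm_1..3,
#'   count_1..3, fpkm_1..3).
#' @export
simulate_genes_and_degs <- function(layout, domains, config) {
  lens <- layout_lengths(layout)
  n <- config$n_genes
  glen <- round(stats::runif(n, config$gene_length_range[1L],
                             config$gene_length_range[2L]))
  cls <- c(rep("down", config$n_down), rep("up", config$n_up),
           rep("none", n - config$n_down - config$n_up))
  n_down_in <- round(config$frac_down_in_domains * config$n_down)
  n_up_in <- round(config$frac_up_in_domains * config$n_up)
  place_kind <- rep("any", n)
  place_kind[cls == "down"] <- rep(c("inside", "outside"),
                                   c(n_down_in,
                                     config$n_down - n_down_in))
  place_kind[cls == "up"] <- rep(c("inside", "outside"),
                                 c(n_up_in, config$n_up - n_up_in))
  placed <- GenomicRanges::GRanges(seqinfo = layout)
  dom_w <- GenomicRanges::width(domains)
  ord <- order(place_kind != "inside")  # planted genes claim domain space first
  out <- vector("list", n)
  for (i in ord) {
    L <- glen[i]
    if (place_kind[i] == "inside") {
      slots <- pmax(dom_w - L + 1, 0)
      if (all(slots == 0))
        stop("no domain can contain a ", L, " bp gene")
      cand <- NULL
      for (try in seq_len(2000L)) {
        di <- sum(cumsum(slots) < stats::runif(1) * sum(slots)) + 1L
        s <- GenomicRanges::start(domains)[di] +
          floor(stats::runif(1) * slots[di])
        cand <- GenomicRanges::GRanges(
          seqnames = GenomicRanges::seqnames(domains)[di],
          ranges = IRanges::IRanges(start = s, width = L),
          seqinfo = layout)
        if (!IRanges::overlapsAny(cand, placed, ignore.strand = TRUE))
          break
        cand <- NULL
      }
      if (is.null(cand)) stop("could not place planted gene inside domains")
    } else if (place_kind[i] == "outside") {
      cand <- place_where(lens, L, layout, function(g)
        !IRanges::overlapsAny(g, domains, ignore.strand = TRUE) &&
          !IRanges::overlapsAny(g, placed, ignore.strand = TRUE))
    } else {
      cand <- place_where(lens, L, layout, function(g)
        !IRanges::overlapsAny(g, placed, ignore.strand = TRUE))
    }
    placed <- c(placed, cand)
    out[[i]] <- cand
  }
  genes <- do.call(c, out)
  GenomicRanges::strand(genes) <- sample(c("+", "-"), n, replace = TRUE)
  names(genes) <- sprintf("gene%04d", seq_len(n))
  S4Vectors::mcols(genes)$class <- cls
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)

  id <- names(genes); gcls <- S4Vectors::mcols(genes)$class
  m <- length(id)
  sgn <- ifelse(gcls == "up", 1, ifelse(gcls == "down", -1,
                                        sample(c(-1, 1), m, TRUE)))
  is_deg <- gcls != "none"
  lfc <- sgn * stats::runif(m, 1.6, 5)
  p <- stats::runif(m, 1e-8, 0.049)
  cpm <- matrix(stats::runif(3 * m, 0, 500), m, 3)
  cpm[cbind(seq_len(m), sample(3L, m, TRUE))] <-
    stats::runif(m, 10, 500)  # guarantee the >=10 CPM library for DEGs
  mode <- sample(3L, m, TRUE, prob = c(0.7, 0.15, 0.15))
  nd <- which(!is_deg)
  for (i in nd) {
    if (mode[i] == 1L) {            # fails the fold-change rule
      lfc[i] <- stats::runif(1, -1.4, 1.4)
      p[i] <- stats::runif(1)
    } else if (mode[i] == 2L) {     # fails the p-value rule
      p[i] <- stats::runif(1, 0.051, 1)
    } else {                        # fails the CPM rule
      cpm[i, ] <- stats::runif(3, 0, 9.5)
    }
  }
  counts <- matrix(stats::runif(3 * m, 6, 1e4), m, 3)
  low <- intersect(nd, sample(m, round(0.05 * m)))
  counts[cbind(low, sample(3L, length(low), TRUE))] <-
    stats::runif(length(low), 0, 5)
  fpkm <- matrix(stats::runif(3 * m, 0.6, 50), m, 3)
  lowf <- intersect(nd, sample(m, round(0.1 * m)))
  fpkm[cbind(lowf, sample(3L, length(lowf), TRUE))] <-
    stats::runif(length(lowf), 0, 0.45)
  de <- data.frame(gene = id, log2fc = lfc, p_value = p,
                   cpm_1 = cpm[, 1L], cpm_2 = cpm[, 2L], cpm_3 = cpm[, 3L],
                   count_1 = counts[, 1L], count_2 = counts[, 2L],
                   count_3 = counts[, 3L],
                   fpkm_1 = fpkm[, 1L], fpkm_2 = fpkm[, 2L],
                   fpkm_3 = fpkm[, 3L],
                   planted_class = gcls, stringsAsFactors = FALSE)
  list(genes = genes, de = de)
}

#' Simulate a log2-ratio signal track with a plateau inside domains
#'
#' The genome is tiled into `step_bp` steps (final partial step retained);
#' steps whose midpoint falls inside a domain get the plateau value, others
#' the background, each plus Gaussian noise of sd `noise_sd`.
#'
#' @inheritParams simulate_genes_and_degs
#' @return a log2-ratio signal track.
#' @export
simulate_signal_track <- function(layout, domains, config) {
  lens <- layout_lengths(layout)
  chroms <- GenomicRanges::GRanges(
    seqnames = factor(names(lens), levels = names(lens)),
    ranges = IRanges::IRanges(start = 1, end = lens),
    seqinfo = layout)
  steps <- unlist(GenomicRanges::slidingWindows(
    chroms, width = as.integer(config$step_bp),
    step = as.integer(config$step_bp)), use.names = FALSE)
  mid <- GenomicRanges::resize(steps, width = 1L, fix = "center")
  inside <- IRanges::overlapsAny(mid, domains, ignore.strand = TRUE)
  base <- ifelse(inside, config$plateau, config$background)
  S4Vectors::mcols(steps)$score <-
    base + stats::rnorm(length(steps), 0, config$noise_sd)
  signal_track(steps, "log2_ratio")
}

#' Simulate narrow (MACS2-style) peaks
#'
#' @inheritParams simulate_broad_domains
#' @param n number of peaks.
#' @return a `GRanges` (peaks may overlap).
#' @export
simulate_narrow_peaks <- function(layout, n = 200L,
                                  length_range = c(200, 1000)) {
  lens <- layout_lengths(layout)
  L <- round(stats::runif(n, length_range[1L], length_range[2L]))
  pos <- vapply(L, function(l) place_uniform(lens, l), numeric(2))
  GenomicRanges::GRanges(
    seqnames = factor(names(lens)[pos[1L, ]], levels = names(lens)),
    ranges = IRanges::IRanges(start = pos[2L, ], width = L),
    seqinfo = layout)
}

#' Simulate a ChIP-qPCR percent-input table
#'
#' Four loci (two "positive" with a planted KO enrichment, two negative
#' controls), samples WT and KO, specific and IgG antibodies, with
#' multiplicative batch factors per biological replicate -- the structure
#' the per-(locus, replicate) normalization removes.
#'
#' @param config a [sim_config()].
#' @return data.frame (locus, sample, replicate = biological replicate,
#'   tech_rep, antibody, percent_input).
#' @export
simulate_qpcr_table <- function(config) {
  loci <- c("pos1", "pos2", "neg1", "neg2")
  base <- stats::setNames(stats::runif(length(loci), 0.5, 3), loci)
  grid <- expand.grid(locus = loci, sample = c("WT", "KO"),
                      replicate = seq_len(config$qpcr_bio_reps),
                      tech_rep = seq_len(config$qpcr_tech_reps),
                      antibody = c("specific", "IgG"),
                      stringsAsFactors = FALSE)
  batch <- exp(stats::rnorm(config$qpcr_bio_reps, 0, 0.3))
  fold <- ifelse(grid$antibody == "IgG", 0.1,
                 ifelse(grid$sample == "KO" &
                          grepl("^pos", grid$locus),
                        config$qpcr_effect, 1.2))
  grid$percent_input <- base[grid$locus] * fold * batch[grid$replicate] *
    exp(stats::rnorm(nrow(grid), 0, 0.1))
  grid
}

#' Generate a complete synthetic fixture directory
#'
#' One seeded call emits every input the pipeline consumes: a chrom-sizes
#' file, gene BED, two broad-domain BEDs emulating a wildtype and a
#' "knockout" condition (the configured fraction of downregulated DEGs is
#' planted inside the KO domains; the WT domains are drawn independently,
#' so relocalization toward down-DEGs is built into the KO set only), a
#' synthetic cLAD BED, narrow peaks, one log2-ratio bedGraph per condition,
#' the DE/expression table, the qPCR table, and a JSON manifest recording
#' the seed and config. Outputs are byte-identical for identical configs.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
make_fixture <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(config$seed, {
    layout <- simulate_layout(config)
    domains_ko <- simulate_broad_domains(layout, config$domain_coverage,
                                         config$domain_length_range)
    domains_wt <- simulate_broad_domains(layout, config$domain_coverage,
                                         config$domain_length_range)
    clads <- simulate_broad_domains(layout, config$clad_coverage,
                                    config$clad_length_range)
    gd <- simulate_genes_and_degs(layout, domains_ko, config)
    narrow <- simulate_narrow_peaks(layout, config$n_narrow_peaks,
                                    config$narrow_length_range)
    track_ko <- simulate_signal_track(layout, domains_ko, config)
    track_wt <- simulate_signal_track(layout, domains_wt, config)
    qpcr <- simulate_qpcr_table(config)

    paths <- list(
      chrom_sizes = file.path(dir, "genome.chrom.sizes"),
      genes = file.path(dir, "genes.bed"),
      domains_ko = file.path(dir, "domains_ko.bed"),
      domains_wt = file.path(dir, "domains_wt.bed"),
      clads = file.path(dir, "clads_synthetic.bed"),
      narrow_peaks = file.path(dir, "narrow_peaks.bed"),
      track_ko = file.path(dir, "signal_ko.bedGraph"),
      track_wt = file.path(dir, "signal_wt.bedGraph"),
      de_table = file.path(dir, "de_table.tsv"),
      qpcr = file.path(dir, "qpcr.tsv"),
      manifest = file.path(dir, "manifest.json"))
    lens <- layout_lengths(layout)
    utils::write.table(data.frame(names(lens),
                                  format(lens, scientific = FALSE,
                                         trim = TRUE)),
                       paths$chrom_sizes, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_bed(gd$genes, paths$genes)
    write_bed(domains_ko, paths$domains_ko)
    write_bed(domains_wt, paths$domains_wt)
    write_bed(clads, paths$clads)
    write_bed(narrow, paths$narrow_peaks)
    write_bedgraph(track_ko, paths$track_ko)
    write_bedgraph(track_wt, paths$track_wt)
    utils::write.table(gd$de, paths$de_table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(qpcr, paths$qpcr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- list(seed = config$seed,
                     config = unclass(config),
                     files = lapply(paths, basename))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(layout = layout, domains_ko = domains_ko,
                   domains_wt = domains_wt, clads = clads,
                   genes = gd$genes, de = gd$de, narrow = narrow,
                   track_ko = track_ko, track_wt = track_wt,
                   qpcr = qpcr, paths = paths))
  })
}
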