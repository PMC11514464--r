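#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), resolves it against documented
#' ranges, and reports every violation collectively rather than stopping at
#' the first.
#'
#' @param config path to a YAML file, or a list.
#' @return a validated list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  defaults <- list(n_perm = 1000L, bound_fraction = 0.10, window_bp = 10L,
                   body_bins = 100L, flank_bins = 100L,
                   anchor_flank_bp = 50000L, anchor_bin_bp = 1000L,
                   distance_bins = c(0, 1e4, 1e5, 1e6),
                   min_count = 5, fpkm_min = 0.5, min_cpm = 10,
                   abs_lfc = 1.5, p_max = 0.05, alpha = 0.05,
                   seed = 1L, stages = c("overlaps", "gene_classes",
                                         "permtest", "distances",
                                         "binding", "profiles",
                                         "expression", "qpcr"))
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  problems <- character(0)
  need_files <- c("chrom_sizes", "genes", "domains_ko", "domains_wt",
                  "de_table")
  opt_files <- c("clads", "track_ko", "track_wt", "qpcr")
  inputs <- config$inputs
  if (is.null(inputs)) {
    problems <- c(problems, "missing 'inputs' section")
  } else {
    for (k in need_files)
      if (is.null(inputs[[k]]))
        problems <- c(problems, paste0("inputs$", k, " is required"))
    for (k in c(need_files, opt_files)) {
      pth <- inputs[[k]]
      if (!is.null(pth) && !file.exists(pth))
        problems <- c(problems, paste0("inputs$", k, ": file not found: ",
                                       pth))
    }
  }
  if (config$n_perm < 1)
    problems <- c(problems, "n_perm must be >= 1")
  if (config$bound_fraction <= 0 || config$bound_fraction >= 1)
    problems <- c(problems, "bound_fraction must be in (0, 1)")
  if (config$window_bp < 1)
    problems <- c(problems, "window_bp must be >= 1")
  unknown <- setdiff(config$stages,
                     defaults$stages)
  if (length(unknown))
    problems <- c(problems, paste0("unknown stage: ",
                                   paste(unknown, collapse = ", ")))
  if (length(problems))
    stop("invalid pipeline config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  structure(config, class = "pipeline_config")
}

#' Run the full chromatin-association pipeline
#'
#' Composes the module operations in analysis order over the configured
#' inputs: base-pair Venn partitions of the two condition domain sets (and
#' cLADs), DEG class summaries, overlap permutation tests for up- and
#' downregulated genes against the KO domains, closest-distance
#' distributions with a Hochberg-corrected KS family, windowed binding
#' scores with top-fraction classification, scaled and TSS-anchored signal
#' profiles, expression threshold flags, and qPCR normalization /
#' fold-enrichment. Every random draw comes from the single configured
#' seed, so identical (inputs, config, seed) give an identical report.
#'
#' @param config a `pipeline_config`, a list, or a YAML path
#'   (see [validate_config()]).
#' @param out_dir optional output directory; when given, every section is
#'   written as TSV plus a JSON manifest.
#' @return a list of class `analysis_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  inp <- config$inputs
  layout <- read_chrom_sizes(inp$chrom_sizes)
  genes <- read_bed(inp$genes, layout)
  if (is.null(names(genes))) names(genes) <- as.character(seq_along(genes))
  domains_ko <- read_bed(inp$domains_ko, layout)
  domains_wt <- read_bed(inp$domains_wt, layout)
  clads <- if (!is.null(inp$clads)) read_bed(inp$clads, layout) else NULL
  de <- utils::read.table(inp$de_table, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  de <- select_degs(de, min_cpm = config$min_cpm,
                    abs_lfc = config$abs_lfc, p_max = config$p_max)
  up <- genes[de$gene[de$deg & de$direction == "up"]]
  down <- genes[de$gene[de$deg & de$direction == "down"]]
  non <- genes[setdiff(names(genes), de$gene[de$deg])]
  report <- list(manifest = list(seed = config$seed,
                                 parameters = config[setdiff(
                                   names(config), "inputs")],
                                 inputs = inp))
  stages <- config$stages

  if ("overlaps" %in% stages) {
    sets <- list(KO = domains_ko, WT = domains_wt)
    if (!is.null(clads)) sets$cLAD <- clads
    report$venn <- venn_partition(sets)
  }
  if ("gene_classes" %in% stages)
    report$gene_classes <- summarize_gene_classes(
      genes, de, list(KO = domains_ko, WT = domains_wt), clads)
  if ("permtest" %in% stages) {
    report$permtest <- list(
      up = permutation_overlap_test(up, domains_ko,
                                    n_perm = config$n_perm,
                                    alpha = config$alpha,
                                    seed = config$seed),
      down = permutation_overlap_test(down, domains_ko,
                                      n_perm = config$n_perm,
                                      alpha = config$alpha,
                                      seed = config$seed + 1L))
  }
  if ("distances" %in% stages) {
    dists <- list(up = closest_distance(up, domains_ko),
                  down = closest_distance(down, domains_ko),
                  non_deg = closest_distance(non, domains_ko))
    report$distance_bins <- lapply(names(dists), function(nm)
      bin_distances(dists[[nm]], config$distance_bins, label = nm))
    names(report$distance_bins) <- names(dists)
    report$ks <- ks_family(lapply(dists, function(d) d[!is.na(d)]))
  }
  if ("binding" %in% stages && !is.null(inp$track_ko)) {
    track <- read_bedgraph(inp$track_ko, layout)
    report$binding <- classify_bound_top_fraction(
      gene_binding_scores(track, genes, window_bp = config$window_bp),
      fraction = config$bound_fraction)
  }
  if ("profiles" %in% stages && !is.null(inp$track_ko)) {
    track <- read_bedgraph(inp$track_ko, layout)
    pm <- scaled_region_profile(track, domains_ko,
                                body_bins = config$body_bins,
                                flank_bins = config$flank_bins)
    deg_genes <- genes[de$gene[de$deg]]
    ap <- anchored_profile(track, deg_genes,
                           flank_bp = config$anchor_flank_bp,
                           bin_bp = config$anchor_bin_bp)
    report$profiles <- list(
      scaled = pm,
      scaled_mean = aggregate_profile(pm, "mean"),
      scaled_median = aggregate_profile(pm, "median"),
      tss = ap,
      tss_mean = aggregate_profile(ap, "mean"))
  }
  if ("expression" %in% stages) {
    kept <- filter_low_counts(de, min_count = config$min_count)
    report$expression <- list(
      n_genes = nrow(de),
      n_kept = nrow(kept),
      expressed = stats::setNames(flag_expressed(de,
                                                 fpkm_min = config$fpkm_min),
                                  de$gene),
      n_deg_up = length(up), n_deg_down = length(down))
  }
  if ("qpcr" %in% stages && !is.null(inp$qpcr)) {
    q <- utils::read.table(inp$qpcr, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    qn <- normalize_percent_input(q)
    fe <- fold_enrichment(data.frame(
      locus = qn$locus, sample = qn$sample,
      replicate = paste(qn$replicate, qn$tech_rep, sep = "."),
      antibody = qn$antibody, value = qn$normalized,
      stringsAsFactors = FALSE))
    tt <- lapply(split(qn[qn$antibody != "IgG", ],
                       qn$locus[qn$antibody != "IgG"]), function(d)
      qpcr_t_test(d$normalized[d$sample == "WT"],
                  d$normalized[d$sample == "KO"]))
    report$qpcr <- list(normalized = qn, fold_enrichment = fe,
                        t_tests = tt)
  }
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

## Serialize an analysis report as TSV sections + JSON manifest.
#' @noRd
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$venn)) tsv(report$venn, "venn_partition.tsv")
  if (!is.null(report$gene_classes))
    tsv(report$gene_classes, "gene_classes.tsv")
  if (!is.null(report$permtest)) {
    pt <- do.call(rbind, lapply(names(report$permtest), function(nm) {
      x <- report$permtest[[nm]]
      data.frame(gene_set = nm, observed = x$observed,
                 mean_perm = x$mean_perm, sd_perm = x$sd_perm,
                 z_score = x$z_score, p_value = x$p_value,
                 alternative = x$alternative, critical = x$critical,
                 n_perm = x$n_perm)
    }))
    tsv(pt, "permutation_tests.tsv")
    for (nm in names(report$permtest))
      tsv(data.frame(permuted = report$permtest[[nm]]$permuted),
          paste0("permuted_", nm, ".tsv"))
  }
  if (!is.null(report$distance_bins)) {
    db <- do.call(rbind, lapply(names(report$distance_bins), function(nm) {
      d <- report$distance_bins[[nm]]
      data.frame(gene_set = nm, d,
                 n_no_neighbor = attr(d, "n_no_neighbor"))
    }))
    tsv(db, "distance_bins.tsv")
  }
  if (!is.null(report$ks)) tsv(report$ks, "ks_tests.tsv")
  if (!is.null(report$binding)) tsv(report$binding, "binding_scores.tsv")
  if (!is.null(report$profiles)) {
    write_profile(report$profiles$scaled,
                  file.path(out_dir, "profile_scaled.tsv"))
    write_profile(report$profiles$tss,
                  file.path(out_dir, "profile_tss.tsv"))
    tsv(data.frame(bin = names(report$profiles$scaled_mean),
                   mean = as.numeric(report$profiles$scaled_mean),
                   median = as.numeric(report$profiles$scaled_median)),
        "profile_scaled_aggregate.tsv")
  }
  if (!is.null(report$qpcr)) {
    tsv(report$qpcr$normalized, "qpcr_normalized.tsv")
    tsv(report$qpcr$fold_enrichment, "qpcr_fold_enrichment.tsv")
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
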