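#' Pipeline configuration with study defaults
#'
#' Collects every tunable constant of the analysis in one validated list.
#' The defaults are the study conditions: 100 bp signal bins, 500 bp GC
#' windows sliding every 100 bp, 40 bp summit merge distance, temporal
#' thresholds (+1, -0.5, +0.5, +2 log2 units), DEG rule |log2FC| > 1 with
#' FDR < 0.05, and a family-wise flag threshold of FDR < 0.05.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param genome named list of [simulate_genome()] arguments.
#' @param chip named list of [simulate_chip_counts()] arguments.
#' @param expression named list of [simulate_expression_table()] arguments.
#' @param knockout named list with `shift` and `noise_sd` for the planted
#'   knockout contrast.
#' @param threec named list: `planted_if` (named list of per-condition
#'   profiles, or `NULL` to skip the 3C section) plus
#'   [simulate_3c()] arguments.
#' @param bin_width,gc_window,gc_step,merge_distance core window/merge
#'   constants in bp.
#' @param dynamics a [dynamics_params()].
#' @param fdr_alpha flag threshold for the association layer.
#' @param replicon_scope replicons counted in coverage fractions
#'   (`NULL` = all).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            genome = list(),
                            chip = list(),
                            expression = list(),
                            knockout = list(shift = 1, noise_sd = 0.3),
                            threec = list(
                              planted_if = list(
                                wt_aerobic = c(
                                  d40 = 0.01, d30 = 0.02, d20 = 0.08,
                                  d10 = 0.30, u10 = 0.30, u20 = 0.08,
                                  u30 = 0.02, u40 = 0.005)),
                              efficiency = 1.9, ct_noise_sd = 0.15,
                              n_replicates = 3),
                            bin_width = 100L, gc_window = 500L,
                            gc_step = 100L, merge_distance = 40L,
                            dynamics = dynamics_params(),
                            fdr_alpha = 0.05,
                            replicon_scope = NULL) {
  stopifnot(inherits(dynamics, "dynamics_params"))
  if (bin_width <= 0L || gc_step <= 0L || gc_window < gc_step)
    stop_fmt("invalid window sizes")
  if (merge_distance < 0) stop_fmt("merge_distance must be >= 0")
  structure(list(seed = seed, genome = genome, chip = chip,
                 expression = expression, knockout = knockout,
                 threec = threec, bin_width = as.integer(bin_width),
                 gc_window = as.integer(gc_window),
                 gc_step = as.integer(gc_step),
                 merge_distance = merge_distance, dynamics = dynamics,
                 fdr_alpha = fdr_alpha, replicon_scope = replicon_scope),
            class = "pipeline_config")
}

#' Run the full synthetic-study pipeline
#'
#' simulate -> binding signal & GC -> consensus peaks/regions -> gene/TU
#' occupancy & genome coverage -> temporal classes -> association
#' statistics -> knockout Wilcoxon layer -> 3C quantification. Deterministic
#' given `config$seed`. When `outdir` is given, TSV tables and a plain-text
#' report are written there; the numbers in the report are the returned
#' module outputs, not recomputed.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory (created if missing).
#' @return a list of class `pipeline_result` with elements `sim`, `chip`,
#'   `signal`, `gc`, `signal_gc_correlation`, `regions`, `summits`,
#'   `gene_occupancy`, `tu_occupancy`, `coverage_fraction`, `classes`,
#'   `class_recovery`, `enrichment`, `sigma_association`, `wilcoxon`,
#'   `threec`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  ## ---- simulate genome and ChIP
  sim <- do.call(simulate_genome,
                 c(config$genome, list(seed = sub_seed(seed, 1L))))
  chip <- do.call(simulate_chip_counts,
                  c(list(assembly = sim$assembly, truth = sim$truth,
                         bin_width = config$bin_width,
                         seed = sub_seed(seed, 2L)), config$chip))
  ## ---- windowed signal and GC
  ip_pool <- pool_tracks(chip$ip, "ip_pooled")
  input_pool <- pool_tracks(chip$input, "input_pooled")
  signal <- binding_signal(ip_pool, input_pool)
  gc <- gc_windows(sim$assembly, config$gc_window, config$gc_step)
  r_sig_gc <- signal_gc_correlation(signal, gc)
  ## ---- consensus regions and summits
  regions <- intersect_broad(chip$regions$replicates[[1L]],
                             chip$regions$replicates[[2L]],
                             chip$regions$control)
  summits <- lapply(chip$summits, function(s)
    merge_summits(s$replicates[[1L]], s$replicates[[2L]], s$control,
                  distance = config$merge_distance))
  ## ---- occupancy
  gene_occ <- classify_occupancy(sim$annotations, regions,
                                 assembly = sim$assembly)
  tu_occ <- classify_tu_occupancy(sim$annotations, regions,
                                  assembly = sim$assembly)
  coverage <- genome_coverage_fraction(regions, sim$assembly,
                                       config$replicon_scope)
  ## ---- temporal classes
  expr <- do.call(simulate_expression_table,
                  c(list(gene_classes = sim$truth$gene_classes,
                         seed = sub_seed(seed, 3L)), config$expression))
  classes <- classify_dynamics(expr, config$dynamics)
  recovery <- mean(as.character(classes$klass) ==
                     sim$truth$gene_classes[classes$gene_id])
  ## ---- association layer
  bound <- stats::setNames(gene_occ$klass != "not_bound",
                           gene_occ$feature_id)
  present <- intersect(c("transient", "plateau", "continuous", "late"),
                       unique(as.character(classes$klass)))
  enrichment <- if (length(present)) {
    class_enrichment(classes, bound, classes_to_test = present,
                     alpha = config$fdr_alpha)
  } else {    # null run: no upregulated genes at all
    data.frame(klass = character(), class_bound = integer(),
               class_unbound = integer(), ref_bound = integer(),
               ref_unbound = integer(), or_cmle = numeric(),
               or_sample = numeric(), p_value = numeric(),
               fdr = numeric(), flag = character())
  }
  sigma <- lapply(summits, function(s)
    summit_region_association(s, regions, sim$assembly,
                              bin = config$bin_width))
  sigma_tab <- data.frame(
    factor = names(sigma),
    or_cmle = vapply(sigma, `[[`, numeric(1L), "or_cmle"),
    or_sample = vapply(sigma, `[[`, numeric(1L), "or_sample"),
    p_value = vapply(sigma, `[[`, numeric(1L), "p_value"),
    row.names = NULL, stringsAsFactors = FALSE)
  sigma_tab$fdr <- bh_fdr(sigma_tab$p_value)
  sigma_tab$flag <- ifelse(sigma_tab$fdr < config$fdr_alpha,
                           "significant", "ns")
  ## ---- knockout Wilcoxon layer: planted derepression of covered genes
  entire_ids <- gene_occ$feature_id[gene_occ$klass == "entire"]
  ko <- simulate_knockout_contrast(sim$annotations$gene_id, entire_ids,
                                   shift = config$knockout$shift,
                                   noise_sd = config$knockout$noise_sd,
                                   seed = sub_seed(seed, 4L))
  ko_fc <- stats::setNames(ko[[2L]], ko$gene_id)
  wilcox <- occupancy_expression_shift(gene_occ, ko_fc,
                                       alpha = config$fdr_alpha)
  ## ---- 3C
  threec <- NULL
  if (!is.null(config$threec$planted_if)) {
    tc <- config$threec
    profiles <- lapply(seq_along(tc$planted_if), function(i)
      simulate_3c(tc$planted_if[[i]],
                  efficiency = tc$efficiency %||% 1.9,
                  ct_noise_sd = tc$ct_noise_sd %||% 0.15,
                  n_replicates = tc$n_replicates %||% 3,
                  sample_id = names(tc$planted_if)[i],
                  seed = sub_seed(seed, 10L + i)))
    threec <- lapply(profiles, interaction_frequency)
    names(threec) <- names(tc$planted_if)
  }
  res <- structure(
    list(sim = sim, chip = chip, signal = signal, gc = gc,
         signal_gc_correlation = r_sig_gc, regions = regions,
         summits = summits, gene_occupancy = gene_occ,
         tu_occupancy = tu_occ, coverage_fraction = coverage,
         classes = classes, class_recovery = recovery,
         enrichment = enrichment, sigma_association = sigma_tab,
         wilcoxon = wilcox, threec = threec, config = config),
    class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_report(res, outdir)
  res
}

# Sum replicate tracks into one pooled track.
pool_tracks <- function(tracks, sample_id) {
  counts <- tracks[[1L]]$counts
  if (length(tracks) > 1L)
    for (t in tracks[-1L])
      counts <- Map(`+`, counts, t$counts)
  binned_track(counts, bin_width = tracks[[1L]]$bin_width,
               lengths = stats::setNames(tracks[[1L]]$lengths,
                                         names(counts)),
               total_count = sum(vapply(tracks, `[[`, numeric(1L),
                                        "total_count")),
               sample_id = sample_id)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  genome coverage by consensus regions: %.1f%%\n",
              100 * x$coverage_fraction))
  cat(sprintf("  signal-GC correlation (pearson): %.3f\n",
              x$signal_gc_correlation))
  occ <- table(x$gene_occupancy$klass)
  cat(sprintf("  gene occupancy: %d not bound / %d partial / %d entire\n",
              occ[["not_bound"]], occ[["partial"]], occ[["entire"]]))
  cat(sprintf("  temporal class recovery: %.1f%%\n",
              100 * x$class_recovery))
  invisible(x)
}

#' Write the pipeline report directory
#'
#' TSV tables for every stage plus `report.txt` with the headline numbers
#' (coverage fraction, occupancy histogram, class counts, enrichment table,
#' sigma-factor odds ratios, signal-GC correlation, 3C profiles), echoing
#' the parameters applied at each stage.
#'
#' @param res a `pipeline_result`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_report <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, name) utils::write.table(
    d, file.path(outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_fasta(res$sim$assembly, file.path(outdir, "genome.fasta"))
  write_annotations(res$sim$annotations, file.path(outdir, "genes.gff3"))
  write_bed3(res$regions, file.path(outdir, "consensus_regions.bed"))
  tsv(res$gene_occupancy, "gene_occupancy.tsv")
  tsv(res$tu_occupancy, "tu_occupancy.tsv")
  tsv(as.data.frame(res$classes), "gene_classes.tsv")
  tsv(res$enrichment, "class_enrichment.tsv")
  tsv(res$sigma_association, "sigma_association.tsv")
  tsv(res$wilcoxon, "occupancy_wilcoxon.tsv")
  write_signal_bedgraph(res$signal, file.path(outdir, "binding_signal.bedGraph"))
  write_signal_bedgraph(res$gc, file.path(outdir, "gc_content.bedGraph"))
  if (!is.null(res$threec))
    for (nm in names(res$threec))
      tsv(res$threec[[nm]]$profile, sprintf("threec_profile_%s.tsv", nm))
  occ <- table(res$gene_occupancy$klass)
  cls <- table(res$classes$klass)
  cfg <- res$config
  lines <- c(
    "NAP occupancy pipeline report",
    sprintf("seed: %d", cfg$seed),
    sprintf("bin_width=%d gc_window=%d gc_step=%d merge_distance=%g",
            cfg$bin_width, cfg$gc_window, cfg$gc_step, cfg$merge_distance),
    sprintf("binding signal: (IP_w/Input_w)*(TotalInput/TotalIP); %d bp bins",
            cfg$bin_width),
    "",
    sprintf("genome coverage by consensus binding regions: %.4f (%.1f%%)",
            res$coverage_fraction, 100 * res$coverage_fraction),
    sprintf("signal-GC correlation (pearson): %.4f",
            res$signal_gc_correlation),
    sprintf("gene occupancy: not_bound=%d partial=%d entire=%d",
            occ[["not_bound"]], occ[["partial"]], occ[["entire"]]),
    sprintf("temporal classes: %s",
            paste(sprintf("%s=%d", names(cls), as.integer(cls)),
                  collapse = " ")),
    sprintf("temporal class recovery vs truth: %.4f", res$class_recovery),
    "",
    "sigma-factor association (odds of summit bins lying NAP-free):",
    sprintf("  %s: OR=%.3f p=%.3g fdr=%.3g %s",
            res$sigma_association$factor, res$sigma_association$or_cmle,
            res$sigma_association$p_value, res$sigma_association$fdr,
            res$sigma_association$flag),
    if (is.null(res$threec)) "3C section: skipped (no planted profiles)"
    else "3C profiles written per condition.")
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(outdir)
}
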