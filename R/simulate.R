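#' Simulate a small multi-replicon genome with AT-rich tracts
#'
#' Generates the genomic ground truth every downstream stage is tested
#' against: replicon sequences with a uniform background GC content and
#' planted low-GC (AT-rich) tracts; genes tiling the genome in operons of
#' 1-7 genes (transcriptional units), with a stated fraction flagged as
#' insertion-sequence (IS) elements placed preferentially inside the
#' tracts; planted temporal expression classes, with transiently
#' upregulated genes preferentially inside the tracts; and point-binding
#' sigma-factor summits excluded from the tracts with per-factor
#' probabilities. The planted tract set is the broad binder's true
#' footprint (`truth$nap_regions`).
#'
#' @param lengths named numeric vector of replicon lengths in bp.
#' @param circular logical, recycled across replicons.
#' @param background_gc background GC fraction (0-1).
#' @param at_tracts data frame with columns `length` and `gc`, one row per
#'   planted tract; `NULL` builds a default set of 13 tracts totalling
#'   15.7% of the genome at GC `tract_gc`.
#' @param tract_gc GC fraction of default tracts.
#' @param n_genes number of genes to tile.
#' @param is_fraction fraction of genes flagged as IS elements.
#' @param p_is_in_tract probability an IS gene is drawn from inside tracts.
#' @param class_counts named counts of planted temporal classes
#'   (`transient`, `plateau`, `continuous`, `late`); remaining genes are
#'   `none`.
#' @param p_in_nap named per-class probabilities that a class member is
#'   drawn from the genes overlapping the planted footprint.
#' @param sigma_factors named list; each element a list with `n` (number of
#'   summits) and `exclusion` (probability a summit is forced into
#'   footprint-free space).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a list with elements `assembly` (a [genome_assembly()]),
#'   `annotations` (a [gene_annotations()] frame) and `truth` (list:
#'   `nap_regions`, `sigma_summits`, `gene_classes`, `is_genes`, `seed`).
#' @export
simulate_genome <- function(lengths = c(chromosome = 540000, plasmid = 60000),
                            circular = TRUE,
                            background_gc = 0.48,
                            at_tracts = NULL,
                            tract_gc = 0.33,
                            n_genes = 600,
                            is_fraction = 0.035,
                            p_is_in_tract = 0.65,
                            class_counts = c(transient = 30, plateau = 90,
                                             continuous = 60, late = 20),
                            p_in_nap = c(transient = 0.9, plateau = 0.3,
                                         continuous = 0.3, late = 0.3),
                            sigma_factors = list(
                              sigE = list(n = 150, exclusion = 0.95),
                              sigA = list(n = 200, exclusion = 0.75)),
                            seed = 1) {
  if (is.null(names(lengths))) stop_fmt("'lengths' must be named")
  if (background_gc <= 0 || background_gc >= 1 ||
      tract_gc <= 0 || tract_gc >= 1)
    stop_fmt("GC fractions must lie strictly between 0 and 1")
  lengths <- vapply(lengths, as.integer, integer(1L))
  if (is.null(at_tracts)) {
    w <- c(16, 13, 11, 10, 9, 8, 7, 6, 5, 5, 4, 3, 3)
    budget <- 0.157 * sum(lengths)
    at_tracts <- data.frame(length = round(budget * w / sum(w)),
                            gc = tract_gc)
  }
  if (any(at_tracts$gc <= 0 | at_tracts$gc >= 1))
    stop_fmt("tract GC fractions must lie strictly between 0 and 1")
  if (any(at_tracts$length > max(lengths) - 2000L))
    stop_fmt("tract of %d bp exceeds the longest replicon",
             max(at_tracts$length))
  local_seed(seed, {
    ## ---- place tracts (largest first, non-overlapping, 1 kb separation)
    margin <- 1000L
    placed <- data.frame(replicon = character(), start = integer(),
                         end = integer())
    for (tl in sort(at_tracts$length, decreasing = TRUE)) {
      ok <- FALSE
      for (try in 1:2000) {
        r <- sample(names(lengths), 1L, prob = as.numeric(lengths))
        hi <- lengths[[r]] - tl - margin
        if (hi <= margin) next
        s <- sample.int(hi - margin, 1L) + margin
        same <- placed[placed$replicon == r, ]
        if (nrow(same) == 0L ||
            all(s + tl + margin <= same$start | s >= same$end + margin)) {
          placed <- rbind(placed,
                          data.frame(replicon = r, start = s, end = s + tl))
          ok <- TRUE
          break
        }
      }
      if (!ok) stop_fmt("could not place a %d bp tract; genome too crowded", tl)
    }
    tract_gc_by_row <- at_tracts$gc[order(at_tracts$length,
                                          decreasing = TRUE)]
    ## ---- sequences
    seqs <- character(0)
    for (r in names(lengths)) {
      n <- lengths[[r]]
      p <- rep(background_gc, n)
      rows <- which(placed$replicon == r)
      for (i in rows) {
        idx <- (placed$start[i] + 1L):placed$end[i]
        p[idx] <- tract_gc_by_row[i]
      }
      is_gc <- stats::runif(n) < p
      chars <- character(n)
      chars[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
      chars[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
      seqs[[r]] <- paste(chars, collapse = "")
    }
    assembly <- genome_assembly(seqs, circular = circular)
    nap_regions <- normalize_intervals(
      interval_set(placed$replicon, placed$start, placed$end))
    ## ---- genes tiling the genome in operons
    genes <- list(); tu_n <- 0L
    operon_p <- c(0.45, 0.2, 0.12, 0.09, 0.07, 0.04, 0.03)
    for (r in names(lengths)) {
      pos <- sample.int(200L, 1L)
      len <- lengths[[r]]
      while (length(genes) < n_genes && pos + 400L < len - 100L) {
        k <- sample.int(7L, 1L, prob = operon_p)
        tu_n <- tu_n + 1L
        tu <- sprintf("TU%04d", tu_n)
        strand <- sample(c("+", "-"), 1L)
        for (j in seq_len(k)) {
          gl <- max(300L, round(stats::rnorm(1L, 800, 150)))
          if (pos + gl > len - 50L || length(genes) >= n_genes) break
          genes[[length(genes) + 1L]] <-
            data.frame(replicon = r, start = pos, end = pos + gl,
                       strand = strand, tu_id = tu)
          pos <- pos + gl + sample(10:60, 1L)
        }
        pos <- pos + round(stats::rexp(1L, 1 / 200)) + 60L
      }
    }
    if (length(genes) < n_genes)
      stop_fmt("genome too short: placed %d of %d genes",
               length(genes), n_genes)
    gd <- if (length(genes)) do.call(rbind, genes) else
      data.frame(replicon = character(), start = integer(),
                 end = integer(), strand = character(),
                 tu_id = character())
    gd$gene_id <- sprintf("g%04d", seq_len(nrow(gd)))
    ## one singleton-TU gene loses its TU assignment (annotation gap)
    singles <- names(which(table(gd$tu_id) == 1L))
    if (length(singles))
      gd$tu_id[gd$tu_id == sample(singles, 1L)] <- NA_character_
    ## ---- IS flags: preferentially inside tracts
    in_nap <- overlap_bp(interval_set(gd$replicon, gd$start, gd$end),
                         nap_regions) > 0
    n_is <- round(is_fraction * nrow(gd))
    is_ids <- draw_conditional(gd$gene_id, in_nap, n_is, p_is_in_tract)
    gd$is_insertion_sequence <- gd$gene_id %in% is_ids
    ann <- gene_annotations(gd$gene_id, gd$replicon, gd$start, gd$end,
                            gd$strand, gd$is_insertion_sequence, gd$tu_id)
    validate_annotations(ann, assembly)
    ## ---- planted temporal classes
    if (nrow(gd) == 0L) class_counts <- class_counts[0]
    if (sum(class_counts) > nrow(gd))
      stop_fmt("class_counts exceed the number of genes")
    classes <- stats::setNames(rep("none", nrow(gd)), gd$gene_id)
    free <- gd$gene_id
    for (cl in names(class_counts)) {
      pool_in <- in_nap[match(free, gd$gene_id)]
      ids <- draw_conditional(free, pool_in, class_counts[[cl]],
                              p_in_nap[[cl]] %||% mean(in_nap))
      classes[ids] <- cl
      free <- setdiff(free, ids)
    }
    ## ---- sigma-factor summits, excluded from the footprint
    free_space <- complement_intervals(nap_regions, assembly)
    summits <- list()
    for (f in names(sigma_factors)) {
      sf <- sigma_factors[[f]]
      forced <- stats::runif(sf$n) < sf$exclusion
      pos <- data.frame(replicon = character(sf$n),
                        position = integer(sf$n))
      for (i in seq_len(sf$n)) {
        src <- if (forced[i]) free_space else
          interval_set(names(lengths), 0L, unname(lengths))
        pos[i, ] <- sample_position(src)
      }
      summits[[f]] <- data.frame(factor = f, pos,
                                 exclusion = sf$exclusion)
    }
    sigma_summits <- do.call(rbind, summits)
    rownames(sigma_summits) <- NULL
    list(assembly = assembly, annotations = ann,
         truth = list(nap_regions = nap_regions,
                      sigma_summits = sigma_summits,
                      gene_classes = classes,
                      is_genes = is_ids,
                      seed = seed))
  })
}

# Sample `n` ids such that ~p of them come from the `flag` (TRUE) pool.
draw_conditional <- function(ids, flag, n, p) {
  n_in <- stats::rbinom(1L, n, p)
  n_in <- min(n_in, sum(flag))
  n_out <- min(n - n_in, sum(!flag))
  c(if (n_in > 0) sample(ids[flag], n_in),
    if (n_out > 0) sample(ids[!flag], n_out))
}

# Uniformly sample one genomic position from an interval set.
sample_position <- function(x) {
  w <- x$end - x$start
  i <- sample.int(nrow(x), 1L, prob = w)
  data.frame(replicon = x$replicon[i],
             position = x$start[i] + sample.int(w[i], 1L) - 1L)
}

#' Simulate binned ChIP read counts and candidate peak lists
#'
#' Per-bin counts are Poisson: IP bins have mean `depth * (1 +
#' (enrichment - 1) * f)` where `f` is the fraction of the bin inside the
#' planted footprint (so boundaries are soft at bin resolution), and input
#' and untagged-control bins have mean `depth` everywhere. Optional
#' artifact regions are enriched in the IP replicates *and* the control, so
#' the consensus stage must remove them. Candidate broad regions are the
#' planted footprint with endpoints jittered per replicate
#' (`boundary_sd`); candidate summits are the planted sigma positions
#' jittered per replicate (`summit_jitter_sd`) plus replicate-specific
#' uniform noise summits.
#'
#' @param assembly,truth output of [simulate_genome()].
#' @param enrichment fold enrichment inside the footprint (>= 1).
#' @param depth mean reads per bin (> 0).
#' @param n_replicates number of IP/input replicates (default 2).
#' @param with_control generate an untagged control track and lists?
#' @param bin_width bin width in bp.
#' @param boundary_sd per-replicate Gaussian jitter (bp) on broad-region
#'   endpoints.
#' @param summit_jitter_sd per-replicate Gaussian jitter (bp) on summit
#'   positions.
#' @param n_noise_summits replicate-specific false summits per factor.
#' @param artifact_regions optional `interval_set` of artifact loci
#'   enriched in IP and control alike.
#' @param seed integer seed.
#' @return a list: `ip` and `input` (lists of [binned_track()]s),
#'   `control` (track or `NULL`), `regions` (list `replicates`, `control`),
#'   `summits` (per factor: list `replicates`, `control`).
#' @export
simulate_chip_counts <- function(assembly, truth, enrichment = 8,
                                 depth = 50, n_replicates = 2,
                                 with_control = TRUE, bin_width = 100L,
                                 boundary_sd = 25, summit_jitter_sd = 10,
                                 n_noise_summits = 5,
                                 artifact_regions = NULL, seed = 1) {
  if (depth <= 0) stop_fmt("depth must be positive")
  if (enrichment < 1) stop_fmt("enrichment must be >= 1")
  len <- replicon_lengths(assembly)
  bin_width <- as.integer(bin_width)
  bins <- lapply(stats::setNames(names(len), names(len)), function(r) {
    s <- seq.int(0L, len[[r]] - 1L, by = bin_width)
    interval_set(rep(r, length(s)), s, pmin(s + bin_width, len[[r]]))
  })
  frac_in <- function(regions) lapply(bins, function(b) {
    if (is.null(regions) || nrow(regions) == 0L) return(numeric(nrow(b)))
    overlap_bp(b, regions) / (b$end - b$start)
  })
  f_nap <- frac_in(truth$nap_regions)
  f_art <- frac_in(artifact_regions)
  local_seed(seed, {
    draw <- function(means, id) {
      counts <- lapply(means, function(m) stats::rpois(length(m), m))
      names(counts) <- names(bins)
      binned_track(counts, bin_width = bin_width, lengths = len,
                   sample_id = id)
    }
    ip_means <- lapply(names(bins), function(r)
      depth * (1 + (enrichment - 1) * f_nap[[r]]) *
        (1 + (enrichment - 1) * f_art[[r]]))
    ctrl_means <- lapply(names(bins), function(r)
      depth * (1 + (enrichment - 1) * f_art[[r]]))
    flat_means <- lapply(bins, function(b) rep(depth, nrow(b)))
    ip <- lapply(seq_len(n_replicates), function(i)
      draw(ip_means, sprintf("ip_rep%d", i)))
    input <- lapply(seq_len(n_replicates), function(i)
      draw(flat_means, sprintf("input_rep%d", i)))
    control <- if (with_control) draw(ctrl_means, "control") else NULL
    ## candidate broad regions
    jitter_regions <- function(regions) {
      if (is.null(regions) || nrow(regions) == 0L) return(interval_set())
      s <- regions$start + round(stats::rnorm(nrow(regions), 0, boundary_sd))
      e <- regions$end + round(stats::rnorm(nrow(regions), 0, boundary_sd))
      s <- pmax(0L, s); e <- pmin(unname(len[regions$replicon]), e)
      keep <- s < e
      normalize_intervals(interval_set(regions$replicon[keep],
                                       s[keep], e[keep]))
    }
    planted_plus <- if (is.null(artifact_regions)) truth$nap_regions else
      normalize_intervals(rbind(as.data.frame(truth$nap_regions),
                                as.data.frame(artifact_regions)))
    region_reps <- lapply(seq_len(n_replicates), function(i)
      jitter_regions(planted_plus))
    region_ctrl <- if (with_control) jitter_regions(artifact_regions) else
      interval_set()
    ## candidate summits
    noise_summits <- function(n) {
      if (n == 0L) return(NULL)
      pos <- do.call(rbind, lapply(seq_len(n), function(i)
        sample_position(interval_set(names(len), 0L, unname(len)))))
      data.frame(pos, score = stats::rnorm(n, 8, 2))
    }
    summit_lists <- list()
    factors <- unique(truth$sigma_summits$factor)
    for (f in factors) {
      planted <- truth$sigma_summits[truth$sigma_summits$factor == f, ]
      reps <- lapply(seq_len(n_replicates), function(i) {
        p <- planted$position +
          round(stats::rnorm(nrow(planted), 0, summit_jitter_sd))
        p <- pmax(0L, pmin(unname(len[planted$replicon]) - 1L, p))
        d <- rbind(data.frame(replicon = planted$replicon, position = p,
                              score = stats::rnorm(nrow(planted), 30, 3)),
                   noise_summits(n_noise_summits))
        summit_set(d, sample_id = sprintf("%s_rep%d", f, i))
      })
      ctrl <- if (with_control)
        summit_set(noise_summits(n_noise_summits) %||%
                     data.frame(replicon = character(),
                                position = integer(), score = numeric()),
                   sample_id = sprintf("%s_control", f)) else summit_set()
      summit_lists[[f]] <- list(replicates = reps, control = ctrl)
    }
    list(ip = ip, input = input, control = control,
         regions = list(replicates = region_reps, control = region_ctrl),
         summits = summit_lists)
  })
}

#' Simulate a time-course contrast table from planted classes
#'
#' Planted log2 fold-change means per class and contrast
#' (`t0_vs_t1`, `t1_vs_t4`, `t0_vs_t4`): transient `(+e, -e, 0)`, plateau
#' `(+e, 0, +e)`, continuous `(+e, +e, +2e)`, late `(0, +2e, +2e)`, none
#' `(0, 0, 0)`, with iid Gaussian noise of sd `noise_sd` on every contrast.
#' FDR columns are planted, not computed (differential-expression fitting
#' is out of scope): below `fdr_alpha` for contrasts with a planted
#' nonzero mean, uniform on (0, 1) otherwise.
#'
#' @param gene_classes named character vector of planted classes
#'   (`truth$gene_classes`).
#' @param effect planted effect size `e` in log2 units.
#' @param fdr_alpha planted-FDR ceiling for true effects.
#' @param noise_sd Gaussian noise sd in log2 units.
#' @param seed integer seed.
#' @return a contrast table data frame.
#' @export
simulate_expression_table <- function(gene_classes, effect = 2,
                                      fdr_alpha = 0.05, noise_sd = 0.2,
                                      seed = 1) {
  e <- effect
  means <- list(transient = c(e, -e, 0), plateau = c(e, 0, e),
                continuous = c(e, e, 2 * e), late = c(0, 2 * e, 2 * e),
                none = c(0, 0, 0))
  bad <- setdiff(unique(gene_classes), names(means))
  if (length(bad)) stop_fmt("unknown gene class '%s'", bad[1L])
  n <- length(gene_classes)
  mu <- t(vapply(gene_classes, function(cl) means[[cl]], numeric(3L)))
  local_seed(seed, {
    fc <- mu + matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
    fdr <- matrix(stats::runif(3L * n), n, 3L)
    fdr[mu != 0] <- stats::runif(sum(mu != 0), 0, fdr_alpha)
    data.frame(gene_id = names(gene_classes),
               t0_vs_t1_log2fc = fc[, 1L], t0_vs_t1_fdr = fdr[, 1L],
               t1_vs_t4_log2fc = fc[, 2L], t1_vs_t4_fdr = fdr[, 2L],
               t0_vs_t4_log2fc = fc[, 3L], t0_vs_t4_fdr = fdr[, 3L],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a knockout-vs-wildtype contrast with a planted occupancy shift
#'
#' Genes in `shifted_ids` get a planted mean log2 fold change of `shift`
#' (derepression upon deleting the repressive binder), all others 0, with
#' Gaussian noise; planted FDRs as in [simulate_expression_table()].
#'
#' @param gene_ids all gene ids.
#' @param shifted_ids genes carrying the planted shift.
#' @param shift planted log2 fold change.
#' @param noise_sd Gaussian noise sd.
#' @param fdr_alpha planted-FDR ceiling for shifted genes.
#' @param contrast contrast name used for the output columns.
#' @param seed integer seed.
#' @return a contrast table data frame with one contrast.
#' @export
simulate_knockout_contrast <- function(gene_ids, shifted_ids, shift = 1,
                                       noise_sd = 0.3, fdr_alpha = 0.05,
                                       contrast = "dnap_vs_wt_t0",
                                       seed = 1) {
  mu <- ifelse(gene_ids %in% shifted_ids, shift, 0)
  local_seed(seed, {
    fc <- mu + stats::rnorm(length(gene_ids), 0, noise_sd)
    fdr <- stats::runif(length(gene_ids))
    fdr[mu != 0] <- stats::runif(sum(mu != 0), 0, fdr_alpha)
    out <- data.frame(gene_id = gene_ids, fc, fdr,
                      stringsAsFactors = FALSE)
    names(out)[2:3] <- paste0(contrast, c("_log2fc", "_fdr"))
    out
  })
}

#' Simulate a 3C-qPCR Ct table from planted interaction frequencies
#'
#' The generative model is the exact inverse of the quantification: a
#' locus with relative concentration c has
#' `Ct = Ct0 - log(c) / log(efficiency)`. Calibration records follow this
#' law exactly over a dilution series (treated as averaged technical
#' replicates); sample records are generated from
#' `planted_if[locus] * bait_quantity[replicate]` with Gaussian Ct noise,
#' and the bait fragment itself is measured per replicate as the internal
#' control.
#'
#' @param planted_if named numeric vector of true interaction frequencies
#'   per locus (the bait is added automatically).
#' @param efficiency amplification factor per cycle (1 < efficiency <= 2).
#' @param ct_noise_sd Gaussian noise sd on sample Ct values (cycles).
#' @param n_replicates biological replicates (default 3).
#' @param dilution_steps number of calibration points (>= 3).
#' @param dilution_factor fold dilution between consecutive points.
#' @param sample_id sample label.
#' @param bait_locus_id label of the bait locus.
#' @param seed integer seed.
#' @return a [ct_table()].
#' @export
simulate_3c <- function(planted_if, efficiency = 1.9, ct_noise_sd = 0.15,
                        n_replicates = 3, dilution_steps = 5,
                        dilution_factor = 10, sample_id = "wt_aerobic",
                        bait_locus_id = "bait", seed = 1) {
  if (is.null(names(planted_if))) stop_fmt("'planted_if' must be named")
  if (any(planted_if <= 0)) stop_fmt("planted interaction frequencies must be positive")
  if (efficiency <= 1) stop_fmt("efficiency must exceed 1")
  if (dilution_steps < 3) stop_fmt("need >= 3 dilution steps")
  loci <- c(bait_locus_id, names(planted_if))
  local_seed(seed, {
    ct0 <- stats::setNames(stats::runif(length(loci), 19, 23), loci)
    conc <- dilution_factor^-(seq_len(dilution_steps) - 1L)
    calibration <- do.call(rbind, lapply(loci, function(l)
      data.frame(locus_id = l, relative_concentration = conc,
                 ct = ct0[[l]] - log(conc) / log(efficiency))))
    q <- stats::runif(n_replicates, 0.2, 0.8)   # bait amount per replicate
    rows <- list()
    for (rep_i in seq_len(n_replicates)) {
      ab <- c(stats::setNames(q[rep_i], bait_locus_id),
              planted_if * q[rep_i])
      ct <- ct0[loci] - log(ab[loci]) / log(efficiency) +
        stats::rnorm(length(loci), 0, ct_noise_sd)
      rows[[rep_i]] <- data.frame(locus_id = loci, sample_id = sample_id,
                                  replicate = rep_i, ct = as.numeric(ct))
    }
    ct_table(do.call(rbind, rows), calibration, bait_locus_id)
  })
}
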