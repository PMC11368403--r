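# A compact simulated study shared by the blocks below.
small_genome_args <- list(
  lengths = c(chr = 100000, p1 = 20000),
  at_tracts = data.frame(length = c(6000, 5000, 4000, 3800), gc = 0.33),
  n_genes = 110,
  class_counts = c(transient = 10, plateau = 15, continuous = 10, late = 5),
  sigma_factors = list(sigE = list(n = 40, exclusion = 0.95),
                       sigA = list(n = 50, exclusion = 0.75)))

test_that("simulate_genome is deterministic and honours its parameters", {
  a <- do.call(simulate_genome, c(small_genome_args, list(seed = 61)))
  b <- do.call(simulate_genome, c(small_genome_args, list(seed = 61)))
  expect_identical(a, b)
  c2 <- do.call(simulate_genome, c(small_genome_args, list(seed = 62)))
  expect_false(identical(a$assembly$seq, c2$assembly$seq))
  expect_identical(unname(replicon_lengths(a$assembly)), c(100000L, 20000L))
  expect_identical(nrow(a$annotations), 110L)
  expect_identical(sum(is.na(a$annotations$tu_id)), 1L)
  tb <- table(a$truth$gene_classes)
  expect_identical(
    as.integer(tb[c("transient", "plateau", "continuous", "late")]),
    c(10L, 15L, 10L, 5L))
  # planted footprint stays within replicon bounds
  len <- replicon_lengths(a$assembly)
  expect_true(all(a$truth$nap_regions$end <=
                    len[a$truth$nap_regions$replicon]))
})

test_that("planted AT tracts realize their target GC content", {
  sim <- do.call(simulate_genome, c(small_genome_args, list(seed = 63)))
  chars <- strsplit(sim$assembly$seq[[1]], "")[[1]]
  for (i in which(sim$truth$nap_regions$replicon == "chr")) {
    s <- sim$truth$nap_regions$start[i]
    e <- sim$truth$nap_regions$end[i]
    gc <- mean(chars[(s + 1):e] %in% c("G", "C"))
    expect_lt(abs(gc - 0.33), 0.03)
  }
  # background well away from tracts sits near 0.48
  free <- complement_intervals(sim$truth$nap_regions, sim$assembly)
  big <- free[free$replicon == "chr", ][1, ]
  gc_bg <- mean(chars[(big$start + 1):big$end] %in% c("G", "C"))
  expect_lt(abs(gc_bg - 0.48), 0.03)
})

test_that("degenerate generator inputs behave as specified", {
  empty <- simulate_genome(lengths = c(chr = 30000),
                           at_tracts = data.frame(length = 3000, gc = 0.33),
                           n_genes = 0, sigma_factors = list(), seed = 64)
  expect_identical(nrow(empty$annotations), 0L)
  expect_error(simulate_genome(lengths = c(chr = 10000),
                               at_tracts = data.frame(length = 9500,
                                                      gc = 0.3),
                               seed = 1),
               "exceeds")
  expect_error(simulate_genome(lengths = c(chr = 10000),
                               background_gc = 1.2, seed = 1), "between")
})

test_that("ChIP counts carry the planted enrichment and respect errors", {
  sim <- do.call(simulate_genome, c(small_genome_args, list(seed = 65)))
  chip <- simulate_chip_counts(sim$assembly, sim$truth, enrichment = 8,
                               depth = 50, seed = 66)
  sig <- binding_signal(chip$ip[[1]], chip$input[[1]])
  inside <- overlap_bp(interval_set(sig$replicon, sig$start, sig$end),
                       sim$truth$nap_regions) == (sig$end - sig$start)
  # raw IP counts inside the footprint have mean depth x enrichment
  ip_all <- unlist(chip$ip[[1]]$counts, use.names = FALSE)
  expect_lt(abs(mean(ip_all[inside]) - 400) / 400, 0.1)
  # the library-total rescaling preserves the in/out signal ratio
  ratio <- mean(sig$value[inside & sig$defined]) /
    mean(sig$value[!inside & sig$defined])
  expect_lt(abs(ratio - 8) / 8, 0.1)
  # null enrichment: IP indistinguishable from input
  chip0 <- simulate_chip_counts(sim$assembly, sim$truth, enrichment = 1,
                                depth = 50, seed = 67)
  sig0 <- binding_signal(chip0$ip[[1]], chip0$input[[1]])
  expect_lt(abs(mean(sig0$value[sig0$defined]) - 1), 0.05)
  expect_error(simulate_chip_counts(sim$assembly, sim$truth, depth = 0,
                                    seed = 1), "depth")
  expect_error(simulate_chip_counts(sim$assembly, sim$truth,
                                    enrichment = 0.5, seed = 1),
               "enrichment")
})

test_that("a planted artifact locus appears in control and is removed by consensus", {
  sim <- do.call(simulate_genome, c(small_genome_args, list(seed = 68)))
  artifact <- interval_set("chr", 70000, 72000)
  chip <- simulate_chip_counts(sim$assembly, sim$truth,
                               artifact_regions = artifact, seed = 69)
  # the artifact is enriched in the control track
  ctrl_bins <- chip$control$counts$chr[701:720]
  expect_gt(mean(ctrl_bins), 200)
  # replicate candidates contain it, the consensus does not
  expect_gt(total_length(intersect_intervals(
    chip$regions$replicates[[1]], artifact)), 1500)
  consensus <- intersect_broad(chip$regions$replicates[[1]],
                               chip$regions$replicates[[2]],
                               chip$regions$control)
  expect_equal(total_length(intersect_intervals(consensus, artifact)), 0)
})

test_that("expression tables recover planted classes exactly without noise", {
  classes <- stats::setNames(
    rep(c("transient", "plateau", "continuous", "late", "none"),
        c(10, 15, 10, 5, 60)), paste0("g", 1:100))
  tab <- simulate_expression_table(classes, effect = 2, noise_sd = 0,
                                   seed = 70)
  cl <- classify_dynamics(tab)
  expect_identical(stats::setNames(as.character(cl$klass), cl$gene_id),
                   classes)
  # zero effect collapses everything to "none"
  tab0 <- simulate_expression_table(classes, effect = 0, noise_sd = 0,
                                    seed = 71)
  expect_true(all(classify_dynamics(tab0)$klass == "none"))
})

test_that("generated files re-read into equal in-memory objects", {
  sim <- do.call(simulate_genome, c(small_genome_args, list(seed = 72)))
  dir <- withr::local_tempdir()
  write_fasta(sim$assembly, file.path(dir, "g.fasta"))
  asm <- read_fasta(file.path(dir, "g.fasta"), circular = TRUE)
  expect_identical(asm$seq, sim$assembly$seq)
  write_annotations(sim$annotations, file.path(dir, "g.gff3"), "gff3")
  ann <- read_annotations(file.path(dir, "g.gff3"), assembly = asm)
  rn <- function(d) { rownames(d) <- NULL; d }
  expect_identical(rn(ann[order(ann$gene_id), names(sim$annotations)]),
                   rn(sim$annotations[order(sim$annotations$gene_id), ]))
  write_bed3(sim$truth$nap_regions, file.path(dir, "r.bed"))
  expect_identical(read_bed3(file.path(dir, "r.bed")),
                   sim$truth$nap_regions)
})
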