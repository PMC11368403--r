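test_that("fisher_exact handles the symmetric null and degenerate tables", {
  r <- fisher_exact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r$or_cmle, 1)
  expect_equal(r$p_value, 1)
  r <- fisher_exact(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(r$or_cmle, Inf)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact(matrix(c(0.5, 1, 1, 1), 2)), "non-negative")
})

test_that("fisher_exact agrees with enumeration and grid oracles", {
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  r <- fisher_exact(tab)
  expect_equal(r$p_value, oracle_fisher_p(tab), tolerance = 1e-12)
  expect_equal(r$or_cmle, oracle_fisher_or(tab), tolerance = 1e-4)
  set.seed(51)
  for (i in 1:40) {
    tab <- random_table(30)
    r <- fisher_exact(tab)
    expect_equal(r$p_value, oracle_fisher_p(tab), tolerance = 1e-12)
    or <- oracle_fisher_or(tab)
    if (is.na(or)) next                      # single-point support
    if (is.finite(or) && or > 0) {
      expect_equal(r$or_cmle, or, tolerance = 1e-4)
    } else {
      expect_identical(r$or_cmle, or)
    }
  }
})

test_that("the conditional-MLE OR matches the fisher.test estimate", {
  set.seed(57)
  for (i in 1:20) {
    tab <- random_table(20) + 1L             # away from degenerate margins
    r <- fisher_exact(tab)
    ref <- unname(stats::fisher.test(tab)$estimate)
    expect_equal(r$or_cmle, ref, tolerance = 0.02)
  }
})

test_that("swapping the rows of a 2x2 table inverts the OR, keeps p", {
  set.seed(52)
  for (i in 1:10) {
    tab <- random_table(25) + 1L   # keep away from degenerate margins
    a <- fisher_exact(tab)
    b <- fisher_exact(tab[2:1, ])
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$or_sample, 1 / b$or_sample, tolerance = 1e-12)
    expect_equal(a$or_cmle, 1 / b$or_cmle, tolerance = 1e-6)
  }
})

test_that("BH adjustment matches closed forms and is order-preserving", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.005, 0.04, 0.9)), c(0.015, 0.06, 0.9))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(53)
  p <- runif(30)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  perm <- sample.int(30)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("class enrichment: identity gives OR 1; planted bias is flagged", {
  kl <- stats::setNames(rep(c("transient", "none"), c(40, 60)),
                        paste0("g", 1:100))
  bound <- stats::setNames(rep(c(TRUE, FALSE), 50), paste0("g", 1:100))
  # a class tested against itself as reference: OR exactly 1, never flagged
  res <- class_enrichment(kl, bound, reference = "transient",
                          classes_to_test = "transient")
  expect_equal(res$or_cmle, 1)
  expect_identical(res$flag, "ns")
  # planted bias: transient genes bound at 0.9, others at 0.3
  set.seed(54)
  kl2 <- stats::setNames(rep(c("transient", "plateau", "continuous", "late"),
                             c(30, 90, 60, 20)), paste0("g", 1:200))
  bound2 <- stats::setNames(
    runif(200) < ifelse(kl2 == "transient", 0.9, 0.3), names(kl2))
  res2 <- class_enrichment(kl2, bound2)
  expect_identical(res2$flag[res2$klass == "transient"], "enriched")
  expect_true(all(res2$fdr >= res2$p_value))
  kl3 <- kl2[kl2 != "late"]
  expect_error(class_enrichment(kl3, bound2), "empty margin")
})

test_that("summit-region association: degenerate and null layouts", {
  asm <- genome_assembly(c(chr = strrep("A", 100000)))
  regions <- interval_set("chr", 50000, 100000)   # half the genome bound
  set.seed(55)
  free_summits <- summit_set("chr", sample.int(49000, 60), runif(60))
  r <- summit_region_association(free_summits, regions, asm)
  expect_identical(r$or_cmle, Inf)
  expect_identical(unname(r$table[1, 2]), 0L)  # no summit bin in a region
  expect_gte(r$table[1, 1], 1L)
  uni <- summit_set("chr", sample.int(100000, 200) - 1L, runif(200))
  r2 <- summit_region_association(uni, regions, asm)
  expect_gt(r2$or_cmle, 0.5)
  expect_lt(r2$or_cmle, 2)
  expect_identical(sum(r2$table), 1000L)          # all bins counted once
})

test_that("occupancy-shift Wilcoxon layer: nulls, exact small-sample p, planted shift", {
  occ <- structure(
    data.frame(feature_id = paste0("g", 1:8),
               klass = factor(rep(c("not_bound", "entire"), each = 4),
                              levels = c("not_bound", "partial", "entire")),
               overlap_fraction = rep(c(0, 1), each = 4)),
    class = c("occupancy_calls", "data.frame"))
  # complete separation of two groups of 4: exact rank p = 2/choose(8,4)
  fc <- stats::setNames(c(1, 2, 3, 4, 11, 12, 13, 14), occ$feature_id)
  res <- occupancy_expression_shift(occ, fc)
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  # identical groups: p = 1
  fc_null <- stats::setNames(rep(c(1, 2, 3, 4), 2), occ$feature_id)
  expect_equal(occupancy_expression_shift(occ, fc_null)$p_value, 1)
  # planted +1 shift of entirely covered genes is detected
  set.seed(56)
  occ2 <- structure(
    data.frame(feature_id = paste0("g", 1:120),
               klass = factor(rep(c("not_bound", "partial", "entire"),
                                  each = 40),
                              levels = c("not_bound", "partial", "entire")),
               overlap_fraction = rep(c(0, 0.5, 1), each = 40)),
    class = c("occupancy_calls", "data.frame"))
  fc2 <- stats::setNames(rnorm(120, 0, 0.3) +
                           rep(c(0, 0, 1), each = 40), occ2$feature_id)
  res2 <- occupancy_expression_shift(occ2, fc2)
  row <- res2[res2$group1 == "not_bound" & res2$group2 == "entire", ]
  expect_identical(row$flag, "significant")
})
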