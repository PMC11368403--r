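#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test: the p-value sums the hypergeometric probabilities
#' of all tables (at the observed margins) no more probable than the
#' observed one. The primary odds ratio is the conditional maximum
#' likelihood estimate under the noncentral hypergeometric model (the
#' convention of `fisher.test`, which this wraps); the sample cross-product
#' estimate is reported alongside. Zero and infinite odds ratios at
#' degenerate margins are permitted.
#'
#' @param table a 2x2 matrix of non-negative integer counts.
#' @return a list of class `contingency_result`: `table`, `or_cmle`,
#'   `or_sample`, `p_value`, `fdr` (NA until adjusted within a family).
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_fmt("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)) || any(!is.finite(table)))
    stop_fmt("cell counts must be non-negative integers")
  storage.mode(table) <- "integer"
  ft <- stats::fisher.test(table)
  or_sample <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  structure(list(table = table,
                 or_cmle = cmle_odds_ratio(table),
                 or_sample = or_sample,
                 p_value = ft$p.value,
                 fdr = NA_real_),
            class = "contingency_result")
}

# Conditional MLE of the odds ratio: the root of the conditional score
# equation E[X | psi] = a under the noncentral hypergeometric model,
# solved to near machine precision on the log-odds scale. Degenerate
# margins give 0 / Inf (0 when the support is a single point, matching
# the fisher.test convention).
cmle_odds_ratio <- function(table) {
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- a + table[2, 1]
  lo <- max(0L, k - n); hi <- min(k, m)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  xs <- lo:hi
  lw <- lchoose(m, xs) + lchoose(n, k - xs)
  score <- function(lpsi) {
    w <- lw + xs * lpsi
    p <- exp(w - max(w))
    sum(xs * p) / sum(p) - a
  }
  exp(stats::uniroot(score, c(-45, 45), tol = 1e-12)$root)
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result>\n")
  print(x$table)
  cat(sprintf("  OR (conditional MLE) %.4g; OR (sample) %.4g; p = %.4g",
              x$or_cmle, x$or_sample, x$p_value))
  if (!is.na(x$fdr)) cat(sprintf("; FDR = %.4g", x$fdr))
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, order-preserving by
#' input index (wraps `p.adjust(method = "fdr")`).
#' @param p numeric vector of p-values.
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_fmt("p-values outside [0, 1]")
  stats::p.adjust(p, method = "fdr")
}

#' Occupancy enrichment of expression classes
#'
#' For each temporal class, a 2x2 table of (gene in class vs gene in the
#' reference set) by (overlapped by a binding region vs not), tested with
#' Fisher's exact test; BH adjustment across the family of classes. A class
#' is flagged `enriched` when `fdr < alpha` with OR > 1 and
#' `anti_enriched` when `fdr < alpha` with OR < 1. The reference row counts
#' every reference-set gene, so a class identical to its reference gives
#' OR 1 exactly.
#'
#' @param classes a `dynamics_classes` frame (or named factor/character of
#'   classes keyed by gene id).
#' @param bound named logical: is each gene overlapped by a binding region?
#' @param reference `"all_upregulated"` (the derived union set) or the name
#'   of a class to use as reference.
#' @param classes_to_test character vector of class names to test.
#' @param alpha flag threshold on the FDR (default 0.05).
#' @return a data frame: class, the four cell counts, `or_cmle`,
#'   `or_sample`, `p_value`, `fdr`, `flag`.
#' @export
class_enrichment <- function(classes, bound,
                             reference = "all_upregulated",
                             classes_to_test = c("transient", "plateau",
                                                 "continuous", "late"),
                             alpha = 0.05) {
  if (inherits(classes, "dynamics_classes")) {
    kl <- stats::setNames(as.character(classes$klass), classes$gene_id)
  } else kl <- stats::setNames(as.character(classes), names(classes))
  if (is.null(names(bound))) stop_fmt("'bound' must be named by gene id")
  missing <- setdiff(names(kl), names(bound))
  if (length(missing))
    stop_fmt("no occupancy call for gene '%s'", missing[1L])
  bound <- bound[names(kl)]
  ref_ids <- if (identical(reference, "all_upregulated")) {
    names(kl)[kl != "none"]
  } else names(kl)[kl == reference]
  if (length(ref_ids) == 0L) stop_fmt("empty margin: reference set is empty")
  rows <- lapply(classes_to_test, function(cl) {
    ids <- names(kl)[kl == cl]
    if (length(ids) == 0L)
      stop_fmt("empty margin: class '%s' has no genes", cl)
    tab <- rbind(c(sum(bound[ids]), sum(!bound[ids])),
                 c(sum(bound[ref_ids]), sum(!bound[ref_ids])))
    res <- fisher_exact(tab)
    data.frame(klass = cl,
               class_bound = tab[1, 1], class_unbound = tab[1, 2],
               ref_bound = tab[2, 1], ref_unbound = tab[2, 2],
               or_cmle = res$or_cmle, or_sample = res$or_sample,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$flag <- ifelse(out$fdr < alpha & out$or_cmle > 1, "enriched",
                     ifelse(out$fdr < alpha & out$or_cmle < 1,
                            "anti_enriched", "ns"))
  out
}

#' Summit / binding-region anti-co-occurrence
#'
#' Discretizes the genome into `bin` bp bins and tests the 2x2 association
#' between "bin contains >= 1 consensus summit" and "bin midpoint lies in
#' the NAP-free space" with Fisher's exact test. The odds ratio is oriented
#' as the odds of a summit-containing bin lying free over those odds for
#' summit-less bins, so OR > 1 means the point binder avoids the broad
#' binder's regions.
#'
#' @param summits a `consensus_summits` object (or a data frame with
#'   `replicon` and `position`).
#' @param regions an `interval_set` of broad binding regions.
#' @param assembly a `genome_assembly`.
#' @param bin bin width in bp (default 100, the signal bin width).
#' @return a `contingency_result`; its `table` has rows
#'   (summit, no summit) and columns (free, bound).
#' @export
summit_region_association <- function(summits, regions, assembly,
                                      bin = 100L) {
  if (inherits(summits, "consensus_summits")) summits <- summits$summits
  bin <- as.integer(bin)
  if (bin <= 0L) stop_fmt("bin must be positive")
  regions <- normalize_intervals(regions)
  len <- replicon_lengths(assembly)
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("summit", "no_summit"), c("free", "bound")))
  for (r in names(len)) {
    starts <- seq.int(0L, len[[r]] - 1L, by = bin)
    mids <- pmin(starts + bin %/% 2L, len[[r]] - 1L)
    reg <- regions[regions$replicon == r, , drop = FALSE]
    in_region <- rep(FALSE, length(starts))
    if (nrow(reg)) {
      ir <- IRanges::IRanges(reg$start + 1L, reg$end)
      in_region <- IRanges::overlapsAny(
        IRanges::IRanges(mids + 1L, mids + 1L), ir)
    }
    pos <- summits$position[summits$replicon == r]
    has_summit <- tabulate(pmin(pos %/% bin + 1L, length(starts)),
                           nbins = length(starts)) > 0L
    tab[1, 1] <- tab[1, 1] + sum(has_summit & !in_region)
    tab[1, 2] <- tab[1, 2] + sum(has_summit & in_region)
    tab[2, 1] <- tab[2, 1] + sum(!has_summit & !in_region)
    tab[2, 2] <- tab[2, 2] + sum(!has_summit & in_region)
  }
  fisher_exact(tab)
}

#' Expression shift across occupancy classes
#'
#' Pairwise two-sample Wilcoxon rank-sum tests of a per-gene log2
#' fold-change between each pair of occupancy classes (`not_bound`,
#' `partial`, `entire`), BH-adjusted across the pairs. Exact p-values are
#' used for small tie-free groups and the normal approximation with tie
#' correction otherwise (the `wilcox.test` convention).
#'
#' @param occupancy an `occupancy_calls` frame.
#' @param log2fc named numeric vector of per-gene log2 fold changes (e.g. a
#'   knockout-vs-wildtype contrast), keyed by feature id.
#' @param alpha flag threshold on the FDR (default 0.05).
#' @return a data frame: `group1`, `group2`, group sizes, group medians,
#'   `p_value`, `fdr`, `flag`.
#' @export
occupancy_expression_shift <- function(occupancy, log2fc, alpha = 0.05) {
  if (is.null(names(log2fc))) stop_fmt("'log2fc' must be named by feature id")
  ids <- intersect(occupancy$feature_id, names(log2fc))
  if (length(ids) == 0L) stop_fmt("no shared feature ids")
  kl <- stats::setNames(as.character(occupancy$klass), occupancy$feature_id)[ids]
  x <- log2fc[ids]
  present <- intersect(c("not_bound", "partial", "entire"), unique(kl))
  if (length(present) < 2L)
    stop_fmt("need at least two occupancy classes with data")
  pairs <- utils::combn(present, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x1 <- x[kl == g1]; x2 <- x[kl == g2]
    p <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
    data.frame(group1 = g1, group2 = g2,
               n1 = length(x1), n2 = length(x2),
               median1 = stats::median(x1), median2 = stats::median(x2),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$flag <- ifelse(out$fdr < alpha, "significant", "ns")
  out
}
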