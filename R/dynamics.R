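#' Thresholds for the DEG rule and temporal classification
#'
#' All thresholds are strict inequalities ("more than twofold" excludes the
#' boundary). `up1_log2fc` gates the initial upregulation call (log2 fold
#' change over the first hour in low oxygen), `transient_drop` /
#' `continuous_rise` split the 1–4 h behaviour, `late_log2fc` is the 0–4 h
#' gate for genes missing the early response, and `deg_log2fc` / `deg_fdr`
#' define differential expression between strains. `up1_fdr` optionally
#' adds an FDR gate to the early upregulation screen (off by default,
#' mirroring a fold-change-only screen).
#'
#' @param up1_log2fc,transient_drop,continuous_rise,late_log2fc,deg_log2fc
#'   log2 fold-change thresholds (defaults 1, -0.5, 0.5, 2, 1).
#' @param deg_fdr FDR threshold for DEG calls (default 0.05).
#' @param up1_fdr optional FDR gate for the early upregulation call
#'   (default `NULL`: none).
#' @return a list of class `dynamics_params`.
#' @export
dynamics_params <- function(up1_log2fc = 1, transient_drop = -0.5,
                            continuous_rise = 0.5, late_log2fc = 2,
                            deg_log2fc = 1, deg_fdr = 0.05, up1_fdr = NULL) {
  if (!(transient_drop < 0 && 0 < continuous_rise))
    stop_fmt("need transient_drop < 0 < continuous_rise")
  structure(list(up1_log2fc = up1_log2fc, transient_drop = transient_drop,
                 continuous_rise = continuous_rise, late_log2fc = late_log2fc,
                 deg_log2fc = deg_log2fc, deg_fdr = deg_fdr,
                 up1_fdr = up1_fdr),
            class = "dynamics_params")
}

# Pull the log2fc/fdr columns of one contrast, erroring by name when absent.
contrast_cols <- function(table, contrast, need_fdr = FALSE) {
  fc_col <- paste0(contrast, "_log2fc")
  fdr_col <- paste0(contrast, "_fdr")
  if (!fc_col %in% names(table))
    stop_fmt("contrast column '%s' missing from table", fc_col)
  if (need_fdr && !fdr_col %in% names(table))
    stop_fmt("contrast column '%s' missing from table", fdr_col)
  list(log2fc = table[[fc_col]],
       fdr = if (fdr_col %in% names(table)) table[[fdr_col]] else NULL)
}

#' Call differentially expressed genes for one contrast
#'
#' `up` iff `log2fc > deg_log2fc` and `fdr < deg_fdr`; `down` iff
#' `log2fc < -deg_log2fc` and `fdr < deg_fdr`; otherwise `ns`.
#'
#' @param table a contrast table: data frame with `gene_id` and
#'   `<contrast>_log2fc` / `<contrast>_fdr` columns.
#' @param contrast contrast name, e.g. `"dnap_vs_wt_t0"`.
#' @param params a [dynamics_params()].
#' @return factor (`up`/`down`/`ns`) named by `gene_id`.
#' @export
call_degs <- function(table, contrast, params = dynamics_params()) {
  cc <- contrast_cols(table, contrast, need_fdr = TRUE)
  sig <- cc$fdr < params$deg_fdr
  call <- ifelse(sig & cc$log2fc > params$deg_log2fc, "up",
                 ifelse(sig & cc$log2fc < -params$deg_log2fc, "down", "ns"))
  stats::setNames(factor(call, levels = c("up", "down", "ns")),
                  table$gene_id)
}

#' Temporal classification of upregulated genes
#'
#' Genes upregulated within the first hour (`t0_vs_t1` log2FC above
#' `up1_log2fc`) are split by their 1–4 h behaviour: `transient` if the
#' `t1_vs_t4` log2FC falls below `transient_drop`, `continuous` if it rises
#' above `continuous_rise`, otherwise `plateau`. Genes missing the early
#' response are `late` if their `t0_vs_t4` log2FC exceeds `late_log2fc`,
#' else `none`. The derived set `all_upregulated` is the union of the
#' early-upregulated classes and `late`.
#'
#' @param table a contrast table with `t0_vs_t1`, `t1_vs_t4` and `t0_vs_t4`
#'   log2fc columns (plus `t0_vs_t1_fdr` if `params$up1_fdr` is set).
#' @param params a [dynamics_params()].
#' @return a data frame of class `dynamics_classes` (`gene_id`, `klass`)
#'   with attribute `all_upregulated` (character vector of gene ids).
#' @examples
#' tb <- data.frame(gene_id = "g", t0_vs_t1_log2fc = 2,
#'                  t1_vs_t4_log2fc = -1, t0_vs_t4_log2fc = 1)
#' classify_dynamics(tb)$klass  # transient
#' @export
classify_dynamics <- function(table, params = dynamics_params()) {
  fc1 <- contrast_cols(table, "t0_vs_t1",
                       need_fdr = !is.null(params$up1_fdr))
  fc14 <- contrast_cols(table, "t1_vs_t4")
  fc04 <- contrast_cols(table, "t0_vs_t4")
  up1 <- fc1$log2fc > params$up1_log2fc
  if (!is.null(params$up1_fdr)) up1 <- up1 & fc1$fdr < params$up1_fdr
  klass <- rep("none", nrow(table))
  klass[up1] <- ifelse(
    fc14$log2fc[up1] < params$transient_drop, "transient",
    ifelse(fc14$log2fc[up1] > params$continuous_rise, "continuous", "plateau"))
  late <- !up1 & fc04$log2fc > params$late_log2fc
  klass[late] <- "late"
  out <- data.frame(gene_id = table$gene_id,
                    klass = factor(klass, levels = c("transient", "plateau",
                                                     "continuous", "late",
                                                     "none")),
                    stringsAsFactors = FALSE)
  class(out) <- c("dynamics_classes", "data.frame")
  attr(out, "all_upregulated") <- table$gene_id[klass != "none"]
  out
}

#' Read / write contrast tables as TSV
#'
#' Wide TSV with a `gene_id` column and `<contrast>_log2fc` /
#' `<contrast>_fdr` pairs.
#' @param path file path.
#' @param table the contrast table.
#' @return `read_contrast_table()`: a data frame.
#' @export
read_contrast_table <- function(path) {
  if (!file.exists(path)) stop_fmt("contrast table not found: %s", path)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tb))
    stop_fmt("contrast table '%s' lacks a gene_id column", path)
  fdr_cols <- grep("_fdr$", names(tb), value = TRUE)
  for (cl in fdr_cols)
    if (any(tb[[cl]] < 0 | tb[[cl]] > 1, na.rm = TRUE))
      stop_fmt("FDR column '%s' outside [0, 1]", cl)
  tb
}

#' @rdname read_contrast_table
#' @export
write_contrast_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
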