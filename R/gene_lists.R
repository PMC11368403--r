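#' Read a published gene/TU list
#'
#' Parses a TSV gene list with TU (transcriptional unit) assignments, as
#' printed in published tables of upregulated genes: columns `gene_id` and
#' `tu_id` (literal `NA` marks a gene without a TU assignment), plus any
#' further annotation columns, which are kept as-is. The package ships the
#' transiently upregulated gene list under
#' `system.file("extdata", "transient_genes_tu.tsv", package = "napscape")`.
#'
#' @param path path to the TSV.
#' @return a data frame; `summary_gene_tu_list()` gives the headline
#'   counts: genes, distinct TUs, genes without a TU.
#' @examples
#' path <- system.file("extdata", "transient_genes_tu.tsv",
#'                     package = "napscape")
#' summary_gene_tu_list(read_gene_tu_list(path))
#' @export
read_gene_tu_list <- function(path) {
  if (!file.exists(path)) stop_fmt("gene list not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = "NA")
  if (!all(c("gene_id", "tu_id") %in% names(d)))
    stop_fmt("gene list '%s' needs gene_id and tu_id columns", path)
  if (anyDuplicated(d$gene_id))
    stop_fmt("duplicated gene_id in '%s'", path)
  d
}

#' @rdname read_gene_tu_list
#' @param gene_list a data frame from `read_gene_tu_list()`.
#' @export
summary_gene_tu_list <- function(gene_list) {
  c(n_genes = nrow(gene_list),
    n_tus = length(unique(gene_list$tu_id[!is.na(gene_list$tu_id)])),
    n_missing_tu = sum(is.na(gene_list$tu_id)))
}
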