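#' Classify genes by extent of occupancy
#'
#' For each feature, the fraction of its bases covered by the union of the
#' binding regions, and a three-way class: `not_bound` (fraction 0),
#' `partial` (0 < fraction < 1) or `entire` (fraction 1). Any >= 1 bp
#' overlap counts as bound by default; `min_overlap_fraction` reclassifies
#' features at or below that covered fraction as `not_bound` for
#' sensitivity analyses.
#'
#' @param features a `gene_annotations` frame (or any data frame with
#'   `replicon`, `start`, `end` and an id column named `gene_id` or
#'   `feature_id`).
#' @param regions an `interval_set` of binding regions.
#' @param assembly optional `genome_assembly`; when given, features are
#'   bounds-checked against it.
#' @param min_overlap_fraction features with covered fraction <= this value
#'   are called `not_bound` (default 0).
#' @return a data frame of class `occupancy_calls`: `feature_id`, `klass`
#'   (factor `not_bound`/`partial`/`entire`), `overlap_fraction`.
#' @examples
#' g <- gene_annotations("g1", "chr", 100, 200)
#' classify_occupancy(g, interval_set("chr", 150, 160))
#' @export
classify_occupancy <- function(features, regions, assembly = NULL,
                               min_overlap_fraction = 0) {
  id <- features$gene_id %||% features$feature_id
  if (is.null(id)) stop_fmt("features need a gene_id or feature_id column")
  if (!is.null(assembly)) {
    len <- replicon_lengths(assembly)
    unknown <- setdiff(unique(features$replicon), names(len))
    if (length(unknown))
      stop_fmt("feature on unknown replicon '%s'", unknown[1L])
    if (any(features$end > len[features$replicon]))
      stop_fmt("feature extends beyond its replicon")
  }
  fl <- features$end - features$start
  if (any(fl <= 0)) stop_fmt("feature with non-positive length")
  ov <- overlap_bp(interval_set(features$replicon, features$start,
                                features$end), regions)
  frac <- ov / fl
  klass <- ifelse(frac <= min_overlap_fraction | frac == 0, "not_bound",
                  ifelse(frac == 1, "entire", "partial"))
  out <- data.frame(feature_id = as.character(id),
                    klass = factor(klass,
                                   levels = c("not_bound", "partial", "entire")),
                    overlap_fraction = frac,
                    stringsAsFactors = FALSE)
  class(out) <- c("occupancy_calls", "data.frame")
  out
}

#' Classify transcriptional units by occupancy
#'
#' Each TU is treated as one feature spanning from the minimum start to the
#' maximum end of its member genes (intergenic gaps included: a TU is one
#' transcript unit). Genes with `NA` TU are skipped.
#'
#' @param tus a `gene_annotations` frame with a `tu_id` column.
#' @inheritParams classify_occupancy
#' @return an `occupancy_calls` frame keyed by `tu_id`.
#' @export
classify_tu_occupancy <- function(tus, regions, assembly = NULL,
                                  min_overlap_fraction = 0) {
  if (is.null(tus$tu_id)) stop_fmt("annotations lack a tu_id column")
  keep <- !is.na(tus$tu_id)
  if (!any(keep)) stop_fmt("no member genes: every tu_id is NA")
  d <- tus[keep, ]
  reps <- tapply(d$replicon, d$tu_id, function(x) unique(x))
  multi <- vapply(reps, length, integer(1L)) > 1L
  if (any(multi))
    stop_fmt("TU '%s' spans multiple replicons", names(reps)[multi][1L])
  span <- data.frame(
    feature_id = names(reps),
    replicon = unlist(reps),
    start = as.integer(tapply(d$start, d$tu_id, min)),
    end = as.integer(tapply(d$end, d$tu_id, max)),
    stringsAsFactors = FALSE)
  classify_occupancy(span, regions, assembly = assembly,
                     min_overlap_fraction = min_overlap_fraction)
}

#' Fraction of the genome covered by binding regions
#'
#' Merged region length divided by the summed length of the replicons in
#' scope. Whether plasmids count toward "the entire genome" is a scope
#' choice: the default uses all replicons.
#'
#' @param regions an `interval_set`.
#' @param assembly a `genome_assembly`.
#' @param replicon_scope character vector of replicon names to include
#'   (default: all).
#' @return a fraction in \[0, 1\].
#' @export
genome_coverage_fraction <- function(regions, assembly,
                                     replicon_scope = NULL) {
  len <- replicon_lengths(assembly)
  scope <- replicon_scope %||% names(len)
  unknown <- setdiff(scope, names(len))
  if (length(unknown)) stop_fmt("unknown replicon in scope: '%s'", unknown[1L])
  regions <- normalize_intervals(regions)
  regions <- regions[regions$replicon %in% scope, , drop = FALSE]
  total_length(regions) / sum(as.numeric(len[scope]))
}
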