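#' Strandless genomic interval sets
#'
#' Binding regions and broad peaks are carried as plain data frames of
#' `(replicon, start, end)` in 0-based half-open coordinates. Interval
#' algebra (merging, intersection, complement, overlap counting) is done on
#' IRanges under the hood; the 1-based closed conversion happens only at
#' that boundary.
#'
#' @param replicon character vector (or a data frame with columns
#'   `replicon`, `start`, `end`, in which case the other arguments are
#'   ignored).
#' @param start,end 0-based half-open coordinates.
#' @return a data frame with class `interval_set` prepended.
#' @examples
#' x <- interval_set("chr", c(0, 50), c(100, 150))
#' normalize_intervals(x)
#' @export
interval_set <- function(replicon = character(), start = integer(),
                         end = integer()) {
  if (is.data.frame(replicon)) {
    df <- replicon
    stopifnot(all(c("replicon", "start", "end") %in% names(df)))
    replicon <- df$replicon; start <- df$start; end <- df$end
  }
  x <- data.frame(replicon = as.character(replicon),
                  start = as.integer(start), end = as.integer(end),
                  stringsAsFactors = FALSE)
  if (any(x$start < 0L)) stop_fmt("negative interval start")
  if (any(x$start >= x$end)) stop_fmt("interval with start >= end")
  class(x) <- c("interval_set", "data.frame")
  x
}

# interval_set <-> per-replicon IRanges (1-based closed)
.iv_split <- function(x) {
  split(IRanges::IRanges(x$start + 1L, x$end), x$replicon)
}

.iv_unsplit <- function(lst) {
  reps <- rep(names(lst), vapply(lst, length, integer(1L)))
  if (length(reps) == 0L) return(interval_set())
  ir <- do.call(c, unname(lst))
  interval_set(reps, BiocGenerics::start(ir) - 1L, BiocGenerics::end(ir))
}

#' Normalize an interval set
#'
#' Sorts intervals and merges overlapping *and bookended* intervals, so a
#' normalized set is sorted, non-overlapping and non-adjacent within each
#' replicon. Idempotent. A binding region is a genomic footprint:
#' zero-gap fragments are one region.
#'
#' @param x an `interval_set`.
#' @return a normalized `interval_set`.
#' @export
normalize_intervals <- function(x) {
  x <- interval_set(x)
  if (nrow(x) == 0L) return(x)
  .iv_unsplit(lapply(.iv_split(x), IRanges::reduce))
}

#' Total base pairs covered by an interval set
#' @param x an `interval_set` (normalized or not; overlaps are not
#'   double-counted).
#' @return number of covered base pairs.
#' @export
total_length <- function(x) {
  x <- normalize_intervals(x)
  sum(as.numeric(x$end - x$start))
}

#' Base-pair intersection and difference of interval sets
#' @param a,b `interval_set`s.
#' @return a normalized `interval_set`.
#' @export
intersect_intervals <- function(a, b) {
  a <- normalize_intervals(a); b <- normalize_intervals(b)
  reps <- intersect(unique(a$replicon), unique(b$replicon))
  if (length(reps) == 0L) return(interval_set())
  la <- .iv_split(a); lb <- .iv_split(b)
  out <- lapply(stats::setNames(reps, reps), function(r)
    IRanges::intersect(la[[r]], lb[[r]]))
  .iv_unsplit(out[vapply(out, length, integer(1L)) > 0L])
}

#' @rdname intersect_intervals
#' @export
setdiff_intervals <- function(a, b) {
  a <- normalize_intervals(a); b <- normalize_intervals(b)
  if (nrow(a) == 0L) return(a)
  la <- .iv_split(a); lb <- .iv_split(b)
  out <- lapply(stats::setNames(names(la), names(la)), function(r) {
    if (is.null(lb[[r]])) la[[r]] else IRanges::setdiff(la[[r]], lb[[r]])
  })
  .iv_unsplit(out[vapply(out, length, integer(1L)) > 0L])
}

#' Complement of an interval set within an assembly
#' @param x an `interval_set`.
#' @param assembly a `genome_assembly` providing replicon bounds.
#' @return normalized `interval_set` of uncovered space.
#' @export
complement_intervals <- function(x, assembly) {
  len <- replicon_lengths(assembly)
  whole <- interval_set(names(len), 0L, unname(len))
  setdiff_intervals(whole, x)
}

#' Jaccard index of two interval sets
#'
#' Covered-base intersection over covered-base union; 1 when both sets have
#' zero length.
#' @param a,b `interval_set`s.
#' @return a number in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  inter <- total_length(intersect_intervals(a, b))
  uni <- total_length(a) + total_length(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Per-interval overlap (bp) with a second set
#'
#' For each row of `features`, the number of its bases covered by the union
#' of `regions`. Used by the occupancy classifier.
#' @param features,regions `interval_set`s (features need not be disjoint).
#' @return numeric vector along rows of `features`.
#' @export
overlap_bp <- function(features, regions) {
  features <- interval_set(features)
  regions <- normalize_intervals(regions)
  out <- numeric(nrow(features))
  if (nrow(features) == 0L || nrow(regions) == 0L) return(out)
  for (r in intersect(unique(features$replicon), unique(regions$replicon))) {
    fi <- which(features$replicon == r)
    fr <- IRanges::IRanges(features$start[fi] + 1L, features$end[fi])
    rr <- IRanges::IRanges(regions$start[regions$replicon == r] + 1L,
                           regions$end[regions$replicon == r])
    hits <- IRanges::findOverlaps(fr, rr)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        fr[S4Vectors::queryHits(hits)], rr[S4Vectors::subjectHits(hits)]))
      out[fi] <- out[fi] + as.numeric(
        tapply(ov, factor(S4Vectors::queryHits(hits),
                          levels = seq_along(fr)), sum, default = 0))
    }
  }
  out
}

#' Read/write BED3 interval sets
#'
#' BED is 0-based half-open on disk, matching the in-memory convention.
#' @param path file path.
#' @param x an `interval_set`.
#' @return `read_bed3()`: an `interval_set`; `write_bed3()`: `path`.
#' @export
read_bed3 <- function(path) {
  if (!file.exists(path)) stop_fmt("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr))
}

#' @rdname read_bed3
#' @export
write_bed3 <- function(x, path) {
  x <- interval_set(x)
  gr <- GenomicRanges::GRanges(x$replicon,
                               IRanges::IRanges(x$start + 1L, x$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
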