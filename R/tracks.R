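#' Binned read-count tracks
#'
#' Fixed-width per-bin read counts for one sample (IP, input or untagged
#' control) across all replicons of an assembly. `total_count` is the
#' sample's genome-wide mapped-read total carried as metadata: the binding
#' signal formula normalizes by library totals, which in general exceed the
#' per-replicon bin sums.
#'
#' @param counts named list of non-negative numeric vectors, one per
#'   replicon, one element per bin.
#' @param bin_width bin width in bp (default 100).
#' @param lengths optional named replicon lengths in bp; defaults to
#'   `bins * bin_width`. The number of bins must equal
#'   `ceiling(length / bin_width)`.
#' @param total_count genome-wide total for the sample; defaults to the sum
#'   of all counts.
#' @param sample_id free-text label.
#' @return an object of class `binned_track`.
#' @export
binned_track <- function(counts, bin_width = 100L, lengths = NULL,
                         total_count = NULL, sample_id = "") {
  stopifnot(is.list(counts), length(counts) > 0L, !is.null(names(counts)))
  counts <- lapply(counts, as.numeric)
  if (any(vapply(counts, function(x) any(x < 0 | !is.finite(x)), logical(1L))))
    stop_fmt("bin counts must be non-negative and finite")
  bin_width <- as.integer(bin_width)
  if (bin_width <= 0L) stop_fmt("bin_width must be positive")
  nbins <- vapply(counts, length, integer(1L))
  if (is.null(lengths)) {
    lengths <- nbins * bin_width
    names(lengths) <- names(counts)
  } else {
    lengths <- lengths[names(counts)]
    if (anyNA(lengths)) stop_fmt("lengths missing for some replicons")
    if (!all(nbins == ceiling(lengths / bin_width)))
      stop_fmt("bin count does not match ceiling(length / bin_width)")
  }
  csum <- sum(vapply(counts, sum, numeric(1L)))
  if (is.null(total_count)) total_count <- csum
  if (total_count < csum - 1e-9)
    stop_fmt("total_count (%g) below the sum of bin counts (%g)",
             total_count, csum)
  lengths <- stats::setNames(as.integer(lengths), names(counts))
  structure(list(counts = counts, bin_width = bin_width,
                 lengths = lengths, total_count = total_count,
                 sample_id = sample_id),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> '%s': %d replicon(s), %d bp bins, total %g\n",
              x$sample_id, length(x$counts), x$bin_width, x$total_count))
  invisible(x)
}

# start coordinates (0-based) of all bins of one replicon
bin_starts <- function(track, replicon) {
  seq.int(0L, by = track$bin_width,
          length.out = length(track$counts[[replicon]]))
}

#' Write / read a binned track as bedGraph
#'
#' Fixed-step bedGraph; the library total is stored in a
#' `#total_count=` comment so a round trip reproduces the track exactly.
#' @param track a `binned_track`.
#' @param path file path.
#' @param bin_width expected bin width on read.
#' @return `read_bedgraph_track()`: a `binned_track`; the writer returns
#'   `path` invisibly.
#' @export
write_bedgraph_track <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#total_count=%.10g", track$total_count), con)
  writeLines(sprintf("#sample_id=%s", track$sample_id), con)
  for (r in names(track$counts)) {
    s <- bin_starts(track, r)
    e <- pmin(s + track$bin_width, track$lengths[[r]])
    writeLines(sprintf("%s\t%d\t%d\t%.10g", r, s, e, track$counts[[r]]), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph_track
#' @export
read_bedgraph_track <- function(path, bin_width = 100L) {
  if (!file.exists(path)) stop_fmt("bedGraph not found: %s", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines) &
                  !startsWith(lines, "track")]
  if (length(body) == 0L) stop_fmt("no records in bedGraph '%s'", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L)) stop_fmt("malformed bedGraph line in '%s'", path)
  df <- data.frame(replicon = vapply(parts, `[[`, "", 1L),
                   start = as.integer(vapply(parts, `[[`, "", 2L)),
                   end = as.integer(vapply(parts, `[[`, "", 3L)),
                   value = as.numeric(vapply(parts, `[[`, "", 4L)))
  counts <- list(); lens <- integer()
  for (r in unique(df$replicon)) {
    d <- df[df$replicon == r, ]
    d <- d[order(d$start), ]
    if (!all(d$start == seq.int(0L, by = bin_width, length.out = nrow(d))))
      stop_fmt("bedGraph '%s' is not fixed-step at %d bp on '%s'",
               path, bin_width, r)
    counts[[r]] <- d$value
    lens[[r]] <- d$end[nrow(d)]
  }
  tc <- sub("^#total_count=", "", grep("^#total_count=", meta, value = TRUE))
  sid <- sub("^#sample_id=", "", grep("^#sample_id=", meta, value = TRUE))
  binned_track(counts, bin_width = bin_width, lengths = lens,
               total_count = if (length(tc)) as.numeric(tc[1L]) else NULL,
               sample_id = if (length(sid)) sid[1L] else "")
}

#' Candidate summit sets
#'
#' Single-base positions of maximal enrichment from a narrow-peak caller,
#' per replicate or for the untagged control.
#'
#' @param replicon,position,score vectors (position 0-based); or a data
#'   frame with those columns as the first argument.
#' @param sample_id free-text label.
#' @return a data frame with class `summit_set` prepended.
#' @export
summit_set <- function(replicon = character(), position = integer(),
                       score = numeric(), sample_id = "") {
  if (is.data.frame(replicon)) {
    df <- replicon
    position <- df$position; score <- df$score %||% rep(0, nrow(df))
    replicon <- df$replicon
  }
  if (length(score) == 0L && length(position) > 0L)
    score <- rep(0, length(position))
  x <- data.frame(replicon = as.character(replicon),
                  position = as.integer(position),
                  score = as.numeric(score), stringsAsFactors = FALSE)
  if (any(x$position < 0L)) stop_fmt("negative summit position")
  attr(x, "sample_id") <- sample_id
  class(x) <- c("summit_set", "data.frame")
  x
}

#' Read / write summits as BED (1 bp intervals)
#' @param path file path.
#' @param x a `summit_set`.
#' @param sample_id label attached on read.
#' @return `read_summits_bed()`: a `summit_set`.
#' @export
read_summits_bed <- function(path, sample_id = "") {
  gr <- rtracklayer::import(path, format = "bed")
  sc <- S4Vectors::mcols(gr)$score
  summit_set(as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr) - 1L,
             if (is.null(sc)) rep(0, length(gr)) else as.numeric(sc),
             sample_id = sample_id)
}

#' @rdname read_summits_bed
#' @export
write_summits_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(x$replicon,
                               IRanges::IRanges(x$position + 1L, x$position + 1L))
  gr$name <- sprintf("summit_%d", seq_len(nrow(x)))
  gr$score <- x$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
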