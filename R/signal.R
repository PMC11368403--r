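#' Input-normalized ChIP binding signal per bin
#'
#' For each bin w the signal is
#' \deqn{S(w) = \frac{IP_w}{Input_w} \cdot \frac{TotalInput}{TotalIP},}
#' i.e. the IP/input count ratio rescaled by the library totals. The
#' rescaling makes S scale-invariant: multiplying either library (counts and
#' total alike) by a constant leaves S unchanged, and the Input-weighted
#' mean of S over defined bins equals TotalInput/TotalIP times the ratio of
#' genome-wide sums — exactly 1 when the totals are the genome-wide sums.
#'
#' Bins with `Input_w == 0` are marked undefined (`defined = FALSE`,
#' `value = NA`) and excluded downstream: a division-by-zero bin is data
#' absence, not signal.
#'
#' @param ip,input `binned_track`s on the same replicon/bin grid.
#' @return a `window_signal` data frame: `replicon`, `start`, `end`,
#'   `value`, `defined`.
#' @examples
#' ip <- binned_track(list(chr = c(10, 30)), 100, total_count = 40)
#' inp <- binned_track(list(chr = c(20, 20)), 100, total_count = 40)
#' binding_signal(ip, inp)$value  # 0.5, 1.5
#' @export
binding_signal <- function(ip, input) {
  stopifnot(inherits(ip, "binned_track"), inherits(input, "binned_track"))
  if (ip$bin_width != input$bin_width)
    stop_fmt("bin grid mismatch: bin widths %d vs %d",
             ip$bin_width, input$bin_width)
  if (!identical(names(ip$counts), names(input$counts)) ||
      !identical(lengths(ip$counts), lengths(input$counts)))
    stop_fmt("bin grid mismatch: replicons or bin counts differ")
  scale <- input$total_count / ip$total_count
  out <- lapply(names(ip$counts), function(r) {
    ipw <- ip$counts[[r]]; inw <- input$counts[[r]]
    s <- bin_starts(ip, r)
    defined <- inw > 0
    val <- rep(NA_real_, length(ipw))
    val[defined] <- (ipw[defined] / inw[defined]) * scale
    data.frame(replicon = r, start = s,
               end = pmin(s + ip$bin_width, ip$lengths[[r]]),
               value = val, defined = defined)
  })
  out <- do.call(rbind, out)
  class(out) <- c("window_signal", "data.frame")
  out
}

#' Sliding-window GC content
#'
#' GC percentage in `window` bp windows anchored every `step` bp:
#' `100 * (#G + #C) / (#A + #C + #G + #T)`. `N` bases count in neither the
#' numerator nor the denominator; a window of only `N` is undefined. Other
#' ambiguity codes raise an error. Windows on circular replicons wrap
#' across the origin; on linear replicons the final windows truncate.
#'
#' @param assembly a `genome_assembly`.
#' @param window window width in bp (default 500); must be `>= step`.
#' @param step anchor spacing in bp (default 100).
#' @return a `window_signal` data frame (`value` = GC percentage; `end` is
#'   the unwrapped window end, capped at the replicon end for linear
#'   replicons).
#' @export
gc_windows <- function(assembly, window = 500L, step = 100L) {
  stopifnot(inherits(assembly, "genome_assembly"))
  window <- as.integer(window); step <- as.integer(step)
  if (step <= 0L || window < step) stop_fmt("need window >= step > 0")
  out <- lapply(replicon_names(assembly), function(r) {
    sq <- assembly$seq[[r]]
    len <- nchar(sq)
    chars <- strsplit(sq, "", fixed = TRUE)[[1L]]
    if (any(!chars %in% c("A", "C", "G", "T", "N")))
      stop_fmt("replicon '%s' has ambiguity codes other than N", r)
    circular <- assembly$circular[[r]]
    if (circular && window > 1L) {
      ext <- c(chars, chars[seq_len(min(window - 1L, len))])
    } else ext <- chars
    gc_cum <- c(0, cumsum(ext %in% c("G", "C")))
    n_cum <- c(0, cumsum(ext == "N"))
    starts <- seq.int(0L, len - 1L, by = step)
    ends_raw <- pmin(starts + window, length(ext))
    gc <- gc_cum[ends_raw + 1L] - gc_cum[starts + 1L]
    nn <- n_cum[ends_raw + 1L] - n_cum[starts + 1L]
    denom <- (ends_raw - starts) - nn
    val <- ifelse(denom > 0, 100 * gc / denom, NA_real_)
    data.frame(replicon = r, start = starts,
               end = if (circular) starts + window else pmin(starts + window, len),
               value = val, defined = denom > 0)
  })
  out <- do.call(rbind, out)
  class(out) <- c("window_signal", "data.frame")
  out
}

#' Correlation between binding signal and GC content
#'
#' Pairs the two window sets by shared anchor (`replicon` + `start`), drops
#' pairs where either value is undefined, and returns the requested
#' correlation coefficient. With the default grids (100 bp signal bins,
#' 500 bp GC windows sliding every 100 bp) each signal bin pairs with the
#' GC window anchored at its own start.
#'
#' @param signal,gc `window_signal` frames on the same anchor grid.
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient in \[-1, 1\].
#' @export
signal_gc_correlation <- function(signal, gc,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- merge(signal[, c("replicon", "start", "value")],
             gc[, c("replicon", "start", "value")],
             by = c("replicon", "start"), suffixes = c("_sig", "_gc"))
  m <- m[is.finite(m$value_sig) & is.finite(m$value_gc), ]
  if (nrow(m) < 3L) stop_fmt("fewer than 3 defined window pairs")
  stats::cor(m$value_sig, m$value_gc, method = method)
}

#' Write a window signal as bedGraph
#'
#' Undefined windows are omitted from the file.
#' @param x a `window_signal`.
#' @param path file path.
#' @export
write_signal_bedgraph <- function(x, path) {
  d <- x[x$defined, ]
  writeLines(sprintf("%s\t%d\t%d\t%.10g", d$replicon, d$start, d$end,
                     d$value), path)
  invisible(path)
}
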