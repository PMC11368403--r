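#' Replicate-consensus narrow summits
#'
#' Pools the candidate summits of two replicates and the untagged control,
#' single-linkage clusters them per replicon at a maximum gap of `distance`
#' bp (chains merge: every summit within `distance` of any cluster member
#' joins it), and keeps the clusters that contain at least one summit from
#' each replicate and none from the control. A control summit anywhere in a
#' chain poisons the whole cluster — the most conservative reading of
#' "identified in both replicates but not in the control".
#'
#' The consensus position is the floor of the mean of the two replicate
#' positions; when a cluster holds several summits from one replicate the
#' strongest-scored one represents that replicate.
#'
#' @param rep1,rep2 `summit_set`s for the two biological replicates.
#' @param control `summit_set` for the untagged control (may be empty or
#'   `NULL`).
#' @param distance maximum merge distance in bp (default 40).
#' @return an object of class `consensus_summits`: a list with `summits`
#'   (data frame `replicon`, `position`) and `provenance` (contributing
#'   replicate positions per consensus summit).
#' @examples
#' r1 <- summit_set("chr", 100, 5); r2 <- summit_set("chr", 120, 7)
#' merge_summits(r1, r2, summit_set())$summits$position  # 110
#' @export
merge_summits <- function(rep1, rep2, control = NULL, distance = 40L) {
  if (!is.numeric(distance) || length(distance) != 1L || distance < 0)
    stop_fmt("merge distance must be a non-negative number")
  if (is.null(control)) control <- summit_set()
  tag <- function(s, src)
    data.frame(replicon = s$replicon, position = s$position,
               score = s$score, source = rep(src, nrow(s)))
  pool <- rbind(tag(rep1, "rep1"), tag(rep2, "rep2"),
                tag(control, "control"))
  summits <- list(); prov <- list()
  for (r in unique(pool$replicon)) {
    d <- pool[pool$replicon == r, ]
    d <- d[order(d$position, d$source), ]
    gap <- diff(d$position)
    cluster <- cumsum(c(1L, as.integer(gap > distance)))
    for (cl in split(d, cluster)) {
      if (!all(c("rep1", "rep2") %in% cl$source)) next
      if ("control" %in% cl$source) next
      s1 <- cl[cl$source == "rep1", ]
      s2 <- cl[cl$source == "rep2", ]
      p1 <- s1$position[which.max(s1$score)]
      p2 <- s2$position[which.max(s2$score)]
      summits[[length(summits) + 1L]] <-
        data.frame(replicon = r, position = as.integer(floor((p1 + p2) / 2)))
      prov[[length(prov) + 1L]] <-
        data.frame(replicon = r, rep1_position = p1, rep2_position = p2)
    }
  }
  summits <- if (length(summits)) do.call(rbind, summits) else
    data.frame(replicon = character(), position = integer())
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(replicon = character(), rep1_position = integer(),
               rep2_position = integer())
  ord <- order(summits$replicon, summits$position)
  structure(list(summits = summits[ord, , drop = FALSE],
                 provenance = prov[ord, , drop = FALSE],
                 distance = distance),
            class = "consensus_summits")
}

#' @export
print.consensus_summits <- function(x, ...) {
  cat(sprintf("<consensus_summits> %d summit(s), merge distance %g bp\n",
              nrow(x$summits), x$distance))
  invisible(x)
}

#' Replicate-consensus broad binding regions
#'
#' Base-pair intersection of the broad peaks of two replicates; any
#' resulting interval overlapping a control peak is then removed whole
#' ("excluding those called by the control" names peaks, not base pairs).
#' The output is normalized.
#'
#' @param rep1,rep2 `interval_set`s of broad peaks per replicate.
#' @param control `interval_set` of control peaks (may be empty or `NULL`).
#' @param min_control_overlap minimum overlap required for exclusion: the
#'   default `1L` excludes on any >= 1 bp overlap; a value in (0, 1) is
#'   read as a minimum overlapped fraction of the intersected interval.
#' @return a normalized `interval_set`.
#' @export
intersect_broad <- function(rep1, rep2, control = NULL,
                            min_control_overlap = 1L) {
  inter <- intersect_intervals(rep1, rep2)
  if (is.null(control) || nrow(inter) == 0L) return(inter)
  control <- normalize_intervals(control)
  if (nrow(control) == 0L) return(inter)
  ov <- overlap_bp(inter, control)
  thr <- if (min_control_overlap < 1) {
    pmax(1, min_control_overlap * (inter$end - inter$start))
  } else min_control_overlap
  normalize_intervals(inter[ov < thr, , drop = FALSE])
}
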