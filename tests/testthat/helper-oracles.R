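# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (sorting/cumsum tricks, IRanges, fisher.test) so that
# agreement is evidence, not tautology.

# Transitive-closure summit clustering: build the full adjacency matrix,
# expand components by repeated neighbourhood union, then apply the
# retention rule (>= 1 summit from each replicate, none from control).
oracle_merge_summits <- function(rep1, rep2, control, distance) {
  tag <- function(s, src)
    data.frame(replicon = s$replicon, position = s$position,
               score = s$score, source = rep(src, nrow(s)))
  pool <- rbind(tag(rep1, "rep1"), tag(rep2, "rep2"),
                tag(control, "control"))
  n <- nrow(pool)
  out <- list()
  if (n > 0) {
    adj <- outer(seq_len(n), seq_len(n), function(i, j)
      pool$replicon[i] == pool$replicon[j] &
        abs(pool$position[i] - pool$position[j]) <= distance)
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      members <- i
      repeat {
        grown <- which(apply(adj[members, , drop = FALSE], 2, any))
        if (length(grown) == length(members)) break
        members <- grown
      }
      comp[members] <- cid
    }
    for (k in unique(comp)) {
      cl <- pool[comp == k, ]
      if (!all(c("rep1", "rep2") %in% cl$source)) next
      if ("control" %in% cl$source) next
      s1 <- cl[cl$source == "rep1", ]
      s2 <- cl[cl$source == "rep2", ]
      p1 <- s1$position[which.max(s1$score)]
      p2 <- s2$position[which.max(s2$score)]
      out[[length(out) + 1L]] <- data.frame(
        replicon = cl$replicon[1L],
        position = as.integer(floor((p1 + p2) / 2)))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(replicon = character(), position = integer())
  res <- res[order(res$replicon, res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Per-base covered fraction of one feature against a region list.
oracle_overlap_fraction <- function(f_start, f_end, regions) {
  covered <- unique(unlist(Map(
    function(s, e) seq.int(s, e - 1L), regions$start, regions$end)))
  mean(seq.int(f_start, f_end - 1L) %in% covered)
}

# Two-sided Fisher p by full hypergeometric enumeration at the observed
# margins, summing all table probabilities <= the observed one.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

# Conditional MLE of the odds ratio: arg-max of the noncentral
# hypergeometric likelihood, located by golden-section search on log(psi).
oracle_fisher_or <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  if (lo == hi) return(NA_real_)   # single-point support: OR not estimable
  if (a == hi) return(Inf)
  if (a == lo) return(0)
  xs <- lo:hi
  lw <- lchoose(m, xs) + lchoose(n, k - xs)
  loglik <- function(lpsi) {
    t <- lw + xs * lpsi
    (lw[xs == a] + a * lpsi) - (max(t) + log(sum(exp(t - max(t)))))
  }
  opt <- stats::optimize(loglik, c(-40, 40), maximum = TRUE,
                         tol = 1e-10)
  exp(opt$maximum)
}

# Random 2x2 table with all margins <= max_margin.
random_table <- function(max_margin = 30) {
  repeat {
    tab <- matrix(sample.int(max_margin + 1L, 4, replace = TRUE) - 1L, 2)
    if (all(rowSums(tab) <= max_margin) && all(colSums(tab) <= max_margin) &&
        sum(tab) > 0)
      return(tab)
  }
}

# Sliding-window GC by direct substring counting (wrapping by index
# arithmetic), independent of the cumulative-sum implementation.
oracle_gc_window <- function(seq_chars, start, window, circular) {
  len <- length(seq_chars)
  idx <- start + seq_len(window)          # 1-based
  if (circular) idx <- ((idx - 1L) %% len) + 1L else idx <- idx[idx <= len]
  w <- seq_chars[idx]
  w <- w[w != "N"]
  if (length(w) == 0) return(NA_real_)
  100 * sum(w %in% c("G", "C")) / length(w)
}
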