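#' qPCR Ct tables for 3C quantification
#'
#' Holds the cycle-threshold observations of a 3C-qPCR experiment: one
#' record per (locus primer, sample, replicate), plus a calibration dilution
#' series per locus measured on a randomly ligated digest of the purified
#' genome. The bait locus (the restriction fragment carrying the operon of
#' interest) serves as the internal control for normalization.
#'
#' @param samples data frame with columns `locus_id`, `sample_id`,
#'   `replicate`, `ct`.
#' @param calibration data frame with columns `locus_id`,
#'   `relative_concentration`, `ct`.
#' @param bait_locus_id the internal-control locus.
#' @return a list of class `ct_table`.
#' @export
ct_table <- function(samples, calibration, bait_locus_id) {
  need_s <- c("locus_id", "sample_id", "replicate", "ct")
  need_c <- c("locus_id", "relative_concentration", "ct")
  if (!all(need_s %in% names(samples)))
    stop_fmt("samples need columns: %s", paste(need_s, collapse = ", "))
  if (!all(need_c %in% names(calibration)))
    stop_fmt("calibration needs columns: %s", paste(need_c, collapse = ", "))
  if (any(samples$ct <= 0) || any(calibration$ct <= 0))
    stop_fmt("Ct values must be positive")
  if (any(calibration$relative_concentration <= 0))
    stop_fmt("calibration concentrations must be positive")
  for (l in unique(samples$locus_id)) {
    cal <- calibration[calibration$locus_id == l, ]
    if (nrow(cal) < 3L ||
        length(unique(cal$relative_concentration)) < 2L)
      stop_fmt(paste0("locus '%s' needs >= 3 calibration points spanning",
                      " >= 2 dilution steps"), l)
  }
  if (!bait_locus_id %in% samples$locus_id)
    stop_fmt("bait locus '%s' has no sample records", bait_locus_id)
  structure(list(samples = samples, calibration = calibration,
                 bait_locus_id = bait_locus_id),
            class = "ct_table")
}

#' Fit a per-locus standard curve
#'
#' Least-squares fit of Ct on log10(relative concentration) over the
#' locus's calibration dilution series. The amplification efficiency
#' (fold amplification per cycle) is `10^(-1/slope)`; a perfect-efficiency
#' assay doubles per cycle, giving a slope of about -3.32 cycles per
#' 10-fold dilution.
#'
#' @param calibration data frame with columns `relative_concentration` and
#'   `ct` for one locus (>= 3 points, >= 2 distinct concentrations).
#' @param locus_id optional label.
#' @return a list of class `standard_curve`: `locus_id`, `intercept` (Ct at
#'   concentration 1), `slope` (cycles per log10 concentration),
#'   `efficiency`, `r_squared`.
#' @examples
#' cal <- data.frame(relative_concentration = c(1, 0.1, 0.01),
#'                   ct = c(20, 23.3219, 26.6439))
#' fit_standard_curve(cal)$efficiency  # ~2
#' @export
fit_standard_curve <- function(calibration, locus_id = "") {
  if (nrow(calibration) < 3L)
    stop_fmt("locus '%s': need >= 3 calibration points", locus_id)
  if (length(unique(calibration$relative_concentration)) < 2L)
    stop_fmt("locus '%s': a single concentration cannot span a curve",
             locus_id)
  fit <- stats::lm(ct ~ log10(relative_concentration), data = calibration)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    stop_fmt("locus '%s': inverted dilution series (slope %.3g >= 0)",
             locus_id, slope)
  structure(list(locus_id = locus_id,
                 intercept = unname(stats::coef(fit)[1L]),
                 slope = slope,
                 efficiency = 10^(-1 / slope),
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %s: slope %.4g cycles/log10, efficiency %.4g, R2 %.4g\n",
    x$locus_id, x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

#' Invert a standard curve: Ct to relative abundance
#'
#' `abundance = 10^((ct - intercept) / slope)`, on the calibration's
#' concentration scale (the undiluted calibration sample is 1). This is the
#' delta-delta-Ct quantification through explicit curve inversion; when the
#' slope equals `-1/log10(2)` it reduces to the familiar `2^-ddCt`
#' shortcut.
#'
#' @param ct Ct value(s).
#' @param curve a `standard_curve`.
#' @return relative abundance(s).
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Bait-normalized interaction frequencies
#'
#' For every replicate of every sample, each locus's ligation-product
#' abundance (from its own standard curve) is divided by the bait
#' fragment's abundance in the same replicate, giving the interaction
#' frequency relative to the random-ligation calibration. Replicates are
#' aggregated by the arithmetic mean of the frequencies; individual
#' replicate values are retained. Replicates lacking a bait measurement are
#' dropped with a warning; a locus/sample with no usable replicate is an
#' error.
#'
#' @param x a [ct_table()].
#' @return a list of class `interaction_profile`: `profile` (data frame
#'   `locus_id`, `sample_id`, `mean_if`, `n_replicates`), `replicates`
#'   (per-replicate frequencies), `curves` (per-locus standard curves).
#' @export
interaction_frequency <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  loci <- unique(x$samples$locus_id)
  curves <- lapply(stats::setNames(loci, loci), function(l)
    fit_standard_curve(x$calibration[x$calibration$locus_id == l, ], l))
  bait <- x$samples[x$samples$locus_id == x$bait_locus_id, ]
  bait$abundance <- quantify(bait$ct, curves[[x$bait_locus_id]])
  rows <- list()
  for (l in setdiff(loci, x$bait_locus_id)) {
    d <- x$samples[x$samples$locus_id == l, ]
    d$abundance <- quantify(d$ct, curves[[l]])
    m <- merge(d, bait[, c("sample_id", "replicate", "abundance")],
               by = c("sample_id", "replicate"),
               suffixes = c("", "_bait"), all.x = TRUE)
    dropped <- is.na(m$abundance_bait)
    if (any(dropped)) {
      warning(sprintf(
        "locus '%s': dropping %d replicate(s) without a bait record",
        l, sum(dropped)), call. = FALSE)
      m <- m[!dropped, ]
    }
    if (nrow(m) == 0L)
      stop_fmt("locus '%s': no replicate has a bait measurement", l)
    m$interaction_frequency <- m$abundance / m$abundance_bait
    rows[[l]] <- m[, c("locus_id", "sample_id", "replicate",
                       "interaction_frequency")]
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  agg <- stats::aggregate(interaction_frequency ~ locus_id + sample_id,
                          data = reps, FUN = mean)
  n <- stats::aggregate(interaction_frequency ~ locus_id + sample_id,
                        data = reps, FUN = length)
  profile <- data.frame(locus_id = agg$locus_id, sample_id = agg$sample_id,
                        mean_if = agg$interaction_frequency,
                        n_replicates = n$interaction_frequency,
                        stringsAsFactors = FALSE)
  structure(list(profile = profile, replicates = reps, curves = curves),
            class = "interaction_profile")
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat(sprintf("<interaction_profile> %d locus/sample combination(s)\n",
              nrow(x$profile)))
  print(utils::head(x$profile, 10L))
  invisible(x)
}

#' Read / write Ct tables as TSV
#'
#' Two TSVs: sample records (`locus_id`, `sample_id`, `replicate`, `ct`)
#' and calibration records (`locus_id`, `relative_concentration`, `ct`).
#' @param samples_path,calibration_path file paths.
#' @param bait_locus_id the internal-control locus.
#' @param x a `ct_table`.
#' @return `read_ct_table()`: a `ct_table`.
#' @export
read_ct_table <- function(samples_path, calibration_path, bait_locus_id) {
  ct_table(utils::read.delim(samples_path, stringsAsFactors = FALSE),
           utils::read.delim(calibration_path, stringsAsFactors = FALSE),
           bait_locus_id)
}

#' @rdname read_ct_table
#' @export
write_ct_table <- function(x, samples_path, calibration_path) {
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$calibration, calibration_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(samples_path, calibration_path))
}
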