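# Molecular sex determination from length-normalised per-chromosome read
# counts: loess expectation of the XX null over autosomes, t-based 95%
# interval, observed-X / expected ratio.

#' Per-chromosome read counts and intensities
#'
#' Intensity = mapped read count / chromosome length. The mitochondrial
#' contig is excluded; X is flagged.
#'
#' @param reads aligned `read_table` (endogenous reads are counted).
#' @param ref a [mini_reference()] (lengths suffice).
#' @return data.frame of class `chrom_counts`: name, length, count,
#'   intensity, is_autosome, is_x.
#' @export
chrom_counts <- function(reads, ref) {
  stopifnot(inherits(ref, "mini_reference"))
  chrom <- ref$chromosomes[!ref$chromosomes$is_mt, , drop = FALSE]
  aligned <- reads[reads$chrom != "*" & reads$endogenous, , drop = FALSE]
  cnt <- table(factor(aligned$chrom, levels = chrom$name))
  out <- data.frame(name = chrom$name, length = chrom$length,
                    count = as.integer(cnt),
                    intensity = as.integer(cnt) / chrom$length,
                    is_autosome = chrom$is_autosome, is_x = chrom$is_x,
                    stringsAsFactors = FALSE)
  class(out) <- c("chrom_counts", "data.frame")
  out
}

#' Loess expectation of X-chromosome intensity under the XX null
#'
#' Fits a loess regression (span 0.80) of intensity on chromosome length
#' over the autosomes only — the X is never part of the fit — and predicts
#' the intensity an XX individual would show at the X chromosome's length,
#' with a t-based 95% prediction interval (residual noise included, so an
#' XX individual's observed X falls inside ~95% of the time).
#'
#' @param counts a [chrom_counts()] table.
#' @param span loess span in (0, 1].
#' @param level interval level.
#' @return list with `predicted`, `lower`, `upper`, `se`, `df`, `span`.
#' @export
loess_expectation <- function(counts, span = 0.80, level = 0.95) {
  if (span <= 0 || span > 1) stopf("span must lie in (0, 1]")
  aut <- counts[counts$is_autosome & counts$count > 0, , drop = FALSE]
  if (nrow(aut) < 5) stopf("need at least 5 autosomes with nonzero counts")
  xrow <- counts[counts$is_x, , drop = FALSE]
  if (nrow(xrow) != 1) stopf("exactly one X chromosome required")
  fit <- stats::loess(intensity ~ length, data = aut, span = span,
                      degree = 2, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, newdata = data.frame(length = xrow$length), se = TRUE)
  df <- max(pr$df, 2)
  # prediction interval: fit uncertainty + residual scatter
  s_pred <- sqrt(pr$se.fit^2 + pr$residual.scale^2)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  list(predicted = as.numeric(pr$fit),
       lower = as.numeric(pr$fit - tq * s_pred),
       upper = as.numeric(pr$fit + tq * s_pred),
       se = as.numeric(s_pred), df = df, span = span)
}

#' Classify molecular sex from chromosome counts
#'
#' Computes the ratio `r` of observed X intensity to the loess-predicted XX
#' expectation. Labels: `XX` when the observed X intensity lies inside the
#' 95% XX interval; `XY` when it lies outside and `r` falls in the
#' [0.35, 0.65] band around the 0.5 expectation for a single X copy;
#' `ambiguous` otherwise.
#'
#' @param counts a [chrom_counts()] table.
#' @param expectation optional result of [loess_expectation()]; computed
#'   if omitted.
#' @param xy_band acceptance band for the XY ratio.
#' @param span loess span, passed through when fitting here.
#' @return list of class `sex_call`: `observed`, `expected`, `lower`,
#'   `upper`, `ratio`, `label`.
#' @export
classify_sex <- function(counts, expectation = NULL, xy_band = c(0.35, 0.65),
                         span = 0.80) {
  if (sum(counts$count[counts$is_autosome]) == 0) stopf("zero autosomal reads")
  if (is.null(expectation)) expectation <- loess_expectation(counts, span = span)
  obs <- counts$intensity[counts$is_x]
  r <- obs / expectation$predicted
  label <- if (obs >= expectation$lower && obs <= expectation$upper) "XX"
           else if (r >= xy_band[1] && r <= xy_band[2]) "XY"
           else "ambiguous"
  structure(list(observed = obs, expected = expectation$predicted,
                 lower = expectation$lower, upper = expectation$upper,
                 ratio = r, label = label),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("Molecular sex: %s (X/autosome intensity ratio %.3f; XX interval [%.3g, %.3g])\n",
              x$label, x$ratio, x$lower, x$upper))
  invisible(x)
}

#' Replicated sexing experiment on the miniature genome
#'
#' Simulates `n_reps` individuals of the given karyotype at uniform
#' coverage, runs the loess sexing procedure on each, and returns the
#' per-replicate X/expected intensity ratios and labels. This is the
#' calibration experiment behind the 50% (XY) and 100% (XX) intensity
#' expectations.
#'
#' @param sex `"XX"` or `"XY"`.
#' @param n_reps number of replicate individuals.
#' @param mean_depth autosomal depth per replicate.
#' @param seed integer seed; replicate i uses `seed * 1000 + i`.
#' @param ref a [mini_reference()] (lengths only needed).
#' @return data.frame with columns `ratio` and `label`, one row per
#'   replicate.
#' @export
sex_ratio_experiment <- function(sex, n_reps = 100L, mean_depth = 0.3,
                                 seed = 1L, ref = mini_reference()) {
  cfg <- sim_config(mean_depth = mean_depth, endogenous_fraction = 1)
  out <- lapply(seq_len(n_reps), function(i) {
    rds <- simulate_ancient_reads(ref, cfg, sex = sex, emit_sequences = FALSE,
                                  seed = seed * 1000L + i)
    call <- classify_sex(chrom_counts(rds, ref))
    data.frame(ratio = call$ratio, label = call$label)
  })
  do.call(rbind, out)
}
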