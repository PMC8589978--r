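# Outgroup-f3 and D-statistics with weighted block-jackknife uncertainty,
# BH correction and the group-level affinity comparisons.

fstat_result <- function(kind, pops, value, se, n_snps, n_blocks) {
  z <- if (is.na(se) || se == 0) NA_real_ else value / se
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(kind = kind, pops = pops, value = value, se = se,
                 z = z, p = p, p_adj = NA_real_,
                 n_snps = n_snps, n_blocks = n_blocks),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6f  SE %.6f  Z %.2f  p %.3g%s  (%d SNPs, %d blocks)\n",
              x$kind, paste(x$pops, collapse = ", "), x$value, x$se,
              ifelse(is.na(x$z), NA, x$z), x$p,
              if (!is.na(x$p_adj)) sprintf("  p.adj %.3g", x$p_adj) else "",
              x$n_snps, x$n_blocks))
  invisible(x)
}

# Contiguous physical blocks: chromosome x floor(pos / block_size).
block_ids <- function(chrom, pos, block_size) {
  paste(chrom, (as.numeric(pos) - 1) %/% block_size, sep = ":")
}

# Weighted delete-one-block jackknife for a ratio statistic
# sum(num)/sum(den), block weights = per-block site counts (Busing et al.
# 1999 delete-m formulae, the procedure used for f-statistics).
jackknife_ratio <- function(num, den, blocks) {
  keep <- tapply(seq_along(num), blocks, length) > 0
  ids <- names(keep)[keep]
  g <- length(ids)
  if (g < 2) stopf("block jackknife needs at least 2 non-empty blocks, got %d", g)
  bn <- as.numeric(tapply(num, blocks, sum)[ids])
  bd <- as.numeric(tapply(den, blocks, sum)[ids])
  m <- as.numeric(tapply(rep(1, length(num)), blocks, sum)[ids])
  N <- sum(bn); D <- sum(bd); n <- sum(m)
  theta <- N / D
  theta_j <- (N - bn) / (D - bd)
  if (any(!is.finite(theta_j))) stopf("a delete-one block leaves a zero denominator")
  h <- n / m
  theta_J <- g * theta - sum((1 - m / n) * theta_j)
  var_J <- sum((h * theta - (h - 1) * theta_j - theta_J)^2 / (h - 1)) / g
  list(estimate = theta, se = sqrt(var_J), n_blocks = g)
}

#' Weighted block jackknife of a per-site mean
#'
#' Partitions the genome into contiguous physical blocks (default 5 Mb),
#' and computes the delete-one-block jackknife standard error of the mean
#' of `terms`, weighting blocks by their site counts.
#'
#' @param terms per-site statistic values.
#' @param chrom,pos per-site chromosome and 1-based position.
#' @param block_size block span in bases.
#' @return list with `estimate`, `se`, `n_blocks`.
#' @export
block_jackknife <- function(terms, chrom, pos, block_size = 5e6) {
  stopifnot(length(terms) == length(chrom), length(terms) == length(pos))
  jackknife_ratio(terms, rep(1, length(terms)),
                  block_ids(chrom, pos, block_size))
}

# Shared site selection: rows of freqs$freq non-missing in all given pops.
usable_sites <- function(freqs, pops) {
  f <- freqs$freq[, pops, drop = FALSE]
  which(rowSums(is.na(f)) == 0)
}

#' Outgroup f3 statistic
#'
#' `f3(O; A, B)` = mean over usable sites of `(o - a)(o - b)`, the shared
#' drift of A and B relative to the outgroup O; reported unnormalised.
#' Standard error, Z and two-sided normal p come from the weighted block
#' jackknife.
#'
#' @param freqs output of [allele_freqs()].
#' @param outgroup,a,b population labels (columns of `freqs$freq`).
#' @param block_size jackknife block span in bases.
#' @param require_blocks if `FALSE`, fewer than 2 non-empty blocks yields
#'   `NA` uncertainty instead of an error (used when only the point value
#'   is needed).
#' @return an `fstat_result`.
#' @export
outgroup_f3 <- function(freqs, outgroup, a, b, block_size = 5e6,
                        require_blocks = TRUE) {
  sites <- usable_sites(freqs, c(outgroup, a, b))
  if (length(sites) == 0) stopf("no usable sites for f3(%s; %s, %s)", outgroup, a, b)
  o <- freqs$freq[sites, outgroup]; fa <- freqs$freq[sites, a]; fb <- freqs$freq[sites, b]
  terms <- (o - fa) * (o - fb)
  blocks <- block_ids(freqs$positions$chrom[sites], freqs$positions$pos[sites],
                      block_size)
  jk <- if (!require_blocks && length(unique(blocks)) < 2)
    list(estimate = mean(terms), se = NA_real_, n_blocks = length(unique(blocks)))
  else jackknife_ratio(terms, rep(1, length(terms)), blocks)
  fstat_result("f3", c(outgroup, a, b), mean(terms), jk$se,
               length(sites), jk$n_blocks)
}

#' D statistic (ABBA-BABA)
#'
#' `D(W, X; Y, Z)` = sum of `(w - x)(y - z)` over usable sites divided by
#' the sum of `(w + x - 2wx)(y + z - 2yz)`; uncertainty via the weighted
#' block jackknife applied to the numerator/denominator ratio.
#'
#' @inheritParams outgroup_f3
#' @param w,x,y,z population labels.
#' @return an `fstat_result`.
#' @export
d_statistic <- function(freqs, w, x, y, z, block_size = 5e6,
                        require_blocks = TRUE) {
  pops <- c(w, x, y, z)
  sites <- usable_sites(freqs, pops)
  if (length(sites) == 0) stopf("no usable sites for D(%s)", paste(pops, collapse = ", "))
  fw <- freqs$freq[sites, w]; fx <- freqs$freq[sites, x]
  fy <- freqs$freq[sites, y]; fz <- freqs$freq[sites, z]
  num <- (fw - fx) * (fy - fz)
  den <- (fw + fx - 2 * fw * fx) * (fy + fz - 2 * fy * fz)
  if (sum(den) == 0) stopf("degenerate D statistic: zero denominator")
  blocks <- block_ids(freqs$positions$chrom[sites], freqs$positions$pos[sites],
                      block_size)
  jk <- if (!require_blocks && length(unique(blocks)) < 2)
    list(estimate = sum(num) / sum(den), se = NA_real_,
         n_blocks = length(unique(blocks)))
  else jackknife_ratio(num, den, blocks)
  fstat_result("D", pops, sum(num) / sum(den), jk$se, length(sites), jk$n_blocks)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, elementwise >= input, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Attach BH-adjusted p-values to a batch of f-statistic results
#'
#' @param results list of `fstat_result` objects from one batch of tests.
#' @return the list with `p_adj` filled in.
#' @export
adjust_fstats <- function(results) {
  p <- vapply(results, `[[`, numeric(1), "p")
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- bh_adjust(p[ok])
  for (i in seq_along(results)) results[[i]]$p_adj <- padj[i]
  results
}

#' Tabulate f-statistic results
#'
#' @param results list of `fstat_result` objects.
#' @return data.frame with one row per test.
#' @export
fstat_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(kind = r$kind, pops = paste(r$pops, collapse = ","),
               value = r$value, se = r$se, z = r$z, p = r$p, p_adj = r$p_adj,
               n_snps = r$n_snps, n_blocks = r$n_blocks,
               stringsAsFactors = FALSE)))
}

#' Compare f3 affinity between two groups of modern populations
#'
#' Two-sided Mann-Whitney U test on f3 values grouped by label (e.g. the
#' ancient individual's f3 with European vs non-European breeds), with
#' group medians.
#'
#' @param values numeric f3 values.
#' @param groups group label per value (exactly two distinct labels).
#' @return list with `medians`, `U`, `p`.
#' @export
compare_affinity_groups <- function(values, groups) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stopf("exactly two groups required, got %d", length(lv))
  g1 <- values[groups == lv[1]]; g2 <- values[groups == lv[2]]
  if (length(g1) == 0 || length(g2) == 0) stopf("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(g1, g2, alternative = "two.sided"))
  list(medians = stats::setNames(c(stats::median(g1), stats::median(g2)), lv),
       U = unname(wt$statistic), p = wt$p.value)
}

#' Rank correlation between two f3 vectors
#'
#' Spearman correlation of outgroup-f3 affinity vectors paired by modern
#' population label.
#'
#' @param v1,v2 named numeric vectors over the same modern populations.
#' @return list with `rho`, `p`, `n`.
#' @export
correlate_f3 <- function(v1, v2) {
  if (length(v1) != length(v2)) stopf("f3 vectors differ in length")
  if (!is.null(names(v1)) && !is.null(names(v2))) {
    if (!setequal(names(v1), names(v2))) stopf("f3 vectors cover different populations")
    v2 <- v2[names(v1)]
  }
  if (length(v1) < 3) stopf("need at least 3 paired values")
  ct <- suppressWarnings(stats::cor.test(v1, v2, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(v1))
}
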