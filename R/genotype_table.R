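# Genotype container: SNPs x individuals dosage matrix aligned to a panel.
#
# Dosages count the alt allele. Diploid individuals use the 0/1/2 scale;
# pseudohaploid individuals are stored on a haploid 0/1 scale (a single
# randomly drawn allele) and flagged via ind$ploidy, so that allele
# frequency computations count each of them as ONE observation. Only the
# EIGENSTRAT writer expands pseudohaploid calls to the conventional 0/2.

#' Construct a genotype table
#'
#' @param geno integer matrix, rows = panel sites, columns = individuals;
#'   `NA` marks missing. Diploid columns hold 0/1/2, pseudohaploid 0/1.
#' @param ind data.frame with columns `id`, `population`, `ploidy`
#'   (`"diploid"` or `"pseudohaploid"`).
#' @param panel a [snp_panel()] with one row per genotype row.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(geno, ind, panel) {
  stopifnot(is.matrix(geno), inherits(panel, "snp_panel"),
            nrow(geno) == nrow(panel$sites), ncol(geno) == nrow(ind),
            all(c("id", "population", "ploidy") %in% names(ind)))
  if (anyDuplicated(ind$id)) stopf("individual ids must be unique")
  if (!all(ind$ploidy %in% c("diploid", "pseudohaploid")))
    stopf("ploidy must be 'diploid' or 'pseudohaploid'")
  dip <- ind$ploidy == "diploid"
  if (length(geno) && !all(is.na(geno))) {
    rng <- range(geno, na.rm = TRUE)
    if (any(geno[, dip, drop = FALSE] > 2, na.rm = TRUE) || rng[1] < 0)
      stopf("diploid dosages must be in {0,1,2}")
    if (any(geno[, !dip, drop = FALSE] > 1, na.rm = TRUE))
      stopf("pseudohaploid dosages are stored on a haploid 0/1 scale")
  }
  colnames(geno) <- ind$id
  structure(list(geno = geno, ind = ind, panel = panel), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("Genotype table: %d SNPs x %d individuals (%d populations), %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$ind$population)), 100 * miss))
  tab <- table(x$ind$population, x$ind$ploidy)
  print(tab)
  invisible(x)
}

#' Per-individual genotyped-site counts
#' @param x a [genotype_table()].
#' @return named integer vector of non-missing site counts.
#' @export
site_counts <- function(x) colSums(!is.na(x$geno))

#' Merge genotype tables on the intersection of their panels
#'
#' Tables are joined on `snp_id`; allele pairs must agree exactly at every
#' shared site (no strand flipping is attempted — a conflicting pair is a
#' hard error naming the SNP). Individuals are concatenated; population and
#' ploidy annotations are preserved.
#'
#' @param tables list of [genotype_table()] objects.
#' @return a merged [genotype_table()] over the shared SNPs.
#' @export
merge_datasets <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "genotype_table")))
  if (length(tables) == 1L) return(tables[[1L]])
  shared <- Reduce(intersect, lapply(tables, function(t) t$panel$sites$snp_id))
  if (length(shared) == 0) stopf("no shared SNPs between tables")
  ref <- tables[[1L]]$panel$sites
  ref <- ref[match(shared, ref$snp_id), , drop = FALSE]
  genos <- lapply(tables, function(t) {
    i <- match(shared, t$panel$sites$snp_id)
    s <- t$panel$sites[i, , drop = FALSE]
    bad <- which(s$ref_allele != ref$ref_allele | s$alt_allele != ref$alt_allele)
    if (length(bad))
      stopf("conflicting allele pairs at SNP(s): %s",
            paste(utils::head(s$snp_id[bad], 5), collapse = ", "))
    t$geno[i, , drop = FALSE]
  })
  ind <- do.call(rbind, lapply(tables, `[[`, "ind"))
  if (anyDuplicated(ind$id)) stopf("duplicate individual ids across tables")
  genotype_table(do.call(cbind, genos), ind, snp_panel(ref))
}

#' Population allele frequencies from a genotype table
#'
#' Frequency of the alt allele per site per population. Diploid individuals
#' contribute two allele observations per non-missing site, pseudohaploid
#' individuals one — counting a single random read as two observations
#' would artificially inflate sample sizes in the f-statistics downstream.
#'
#' @param x a [genotype_table()].
#' @param populations population labels to compute (default all).
#' @return list with matrices `freq` (NA where a population has no data)
#'   and `n_obs` (allele observations per site), sites x populations.
#' @export
allele_freqs <- function(x, populations = unique(x$ind$population)) {
  stopifnot(inherits(x, "genotype_table"))
  unknown <- setdiff(populations, x$ind$population)
  if (length(unknown)) stopf("unknown population label(s): %s", paste(unknown, collapse = ", "))
  n_site <- nrow(x$geno)
  freq <- nobs <- matrix(NA_real_, n_site, length(populations),
                         dimnames = list(x$panel$sites$snp_id, populations))
  for (j in seq_along(populations)) {
    cols <- which(x$ind$population == populations[j])
    g <- x$geno[, cols, drop = FALSE]
    ploidy_n <- ifelse(x$ind$ploidy[cols] == "diploid", 2, 1)
    obs <- (!is.na(g)) %*% ploidy_n
    alt <- rowSums(g, na.rm = TRUE)
    f <- ifelse(obs > 0, alt / obs, NA_real_)
    freq[, j] <- f
    nobs[, j] <- obs
  }
  list(freq = freq, n_obs = nobs,
       positions = x$panel$sites[, c("chrom", "pos")])
}
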