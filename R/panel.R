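# SNP panel: the biallelic marker catalogue genotypes are called against.

PURINES <- c("A", "G"); PYRIMIDINES <- c("C", "T")

is_transversion_pair <- function(ref, alt)
  !((ref %in% PURINES & alt %in% PURINES) |
    (ref %in% PYRIMIDINES & alt %in% PYRIMIDINES))

#' Construct a SNP panel
#'
#' @param sites data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref_allele`, `alt_allele`, and optionally `is_functional` (selected-
#'   locus flag, default `FALSE`). The transversion flag is derived from the
#'   allele pair (a pair is a transversion unless it is A/G or C/T).
#' @return object of class `snp_panel`.
#' @export
snp_panel <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("snp_id", "chrom", "pos", "ref_allele", "alt_allele") %in% names(sites)))
  sites$chrom <- as.character(sites$chrom)
  sites$snp_id <- as.character(sites$snp_id)
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref_allele %in% bases) || !all(sites$alt_allele %in% bases))
    stopf("alleles must be single bases A/C/G/T")
  if (any(sites$ref_allele == sites$alt_allele))
    stopf("ref and alt alleles must differ")
  if (anyDuplicated(sites[c("chrom", "pos")]))
    stopf("positions must be unique per chromosome")
  if (anyDuplicated(sites$snp_id)) stopf("snp_id values must be unique")
  sites$is_transversion <- is_transversion_pair(sites$ref_allele, sites$alt_allele)
  if (is.null(sites$is_functional)) sites$is_functional <- FALSE
  structure(list(sites = sites), class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d sites on %d chromosomes (%d transversions, %d functional)\n",
              nrow(x$sites), length(unique(x$sites$chrom)),
              sum(x$sites$is_transversion), sum(x$sites$is_functional)))
  invisible(x)
}

# Generic evenly spaced panel used when a simulation needs sites but no
# explicit panel was supplied: sites round-robin across 26 autosome names,
# alternating transition/transversion allele pairs.
generic_panel <- function(n_snps, n_chrom = 26L, spacing = 1000L) {
  chrom <- paste0("chr", rep_len(seq_len(n_chrom), n_snps))
  idx <- stats::ave(seq_len(n_snps), chrom, FUN = seq_along)
  pairs <- list(c("C", "T"), c("A", "C"), c("A", "G"), c("C", "G"))
  pick <- pairs[rep_len(seq_along(pairs), n_snps)]
  snp_panel(data.frame(
    snp_id = paste0("snp", seq_len(n_snps)),
    chrom = chrom, pos = idx * spacing,
    ref_allele = vapply(pick, `[`, character(1), 1L),
    alt_allele = vapply(pick, `[`, character(1), 2L),
    stringsAsFactors = FALSE))
}

#' Build a panel from a sequenced reference
#'
#' Draws `n_snps` positions uniformly across the given chromosomes, takes
#' the reference base as the ref allele and a random distinct base as alt.
#' Used to make read-level genotyping tests self-consistent with a
#' [mini_reference()] carrying sequences.
#'
#' @param ref a [mini_reference()] with sequences.
#' @param n_snps number of sites.
#' @param chroms chromosome names to draw from (default: autosomes).
#' @param seed integer seed.
#' @return a [snp_panel()].
#' @export
panel_from_reference <- function(ref, n_snps, chroms = NULL, seed = 1L) {
  stopifnot(inherits(ref, "mini_reference"))
  tab <- ref$chromosomes
  if (is.null(chroms)) chroms <- tab$name[tab$is_autosome]
  tab <- tab[tab$name %in% chroms, , drop = FALSE]
  with_seed(seed, {
    cum <- cumsum(tab$length)
    sites <- NULL
    repeat {
      need <- n_snps - NROW(sites)
      if (need <= 0) break
      gpos <- sort(sample.int(sum(tab$length), need))
      ci <- findInterval(gpos - 1, c(0, cum))  # chromosome index
      pos <- gpos - c(0, cum)[ci]
      cand <- data.frame(chrom = tab$name[ci], pos = pos, stringsAsFactors = FALSE)
      sites <- unique(rbind(sites, cand))
    }
    sites <- sites[order(match(sites$chrom, tab$name), sites$pos), ][seq_len(n_snps), ]
    refb <- mapply(function(cn, p) substring(ref_seq(ref, cn), p, p),
                   sites$chrom, sites$pos, USE.NAMES = FALSE)
    altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                   character(1), USE.NAMES = FALSE)
    snp_panel(data.frame(snp_id = paste0("snp", seq_len(n_snps)),
                         chrom = sites$chrom, pos = sites$pos,
                         ref_allele = refb, alt_allele = altb,
                         stringsAsFactors = FALSE))
  })
}

#' Subset a panel or genotype table to transversion sites
#'
#' Deamination produces C->T (and G->A) transitions; restricting to
#' transversions removes any residual postmortem-damage signal from
#' downstream statistics.
#'
#' @param x a [snp_panel()] or [genotype_table()].
#' @return object of the same class restricted to transversion sites, with
#'   attributes `n_kept` and `n_dropped`.
#' @export
filter_transversions <- function(x) UseMethod("filter_transversions")

#' @export
filter_transversions.snp_panel <- function(x) {
  keep <- x$sites$is_transversion
  if (!any(keep)) warning("no transversion sites remain")
  out <- snp_panel(x$sites[keep, , drop = FALSE])
  attr(out, "n_kept") <- sum(keep); attr(out, "n_dropped") <- sum(!keep)
  out
}

#' @export
filter_transversions.genotype_table <- function(x) {
  keep <- x$panel$sites$is_transversion
  if (!any(keep)) warning("no transversion sites remain")
  out <- genotype_table(x$geno[keep, , drop = FALSE], x$ind,
                        snp_panel(x$panel$sites[keep, , drop = FALSE]))
  attr(out, "n_kept") <- sum(keep); attr(out, "n_dropped") <- sum(!keep)
  out
}
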