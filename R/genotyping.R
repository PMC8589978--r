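# Pseudohaploid genotype calling, capture-probe design, ancestral-state
# assignment and the selected-locus derived-allele summary.

# Base a read shows at 1-based reference position `pos` (reference
# orientation). Minus-strand sequences are stored as sequenced, i.e. the
# reverse complement of the reference segment.
read_base_at <- function(read, pos) {
  o <- pos - 1 - read$start           # 0-based offset into the segment
  if (o < 0 || o >= read$length) return(NA_character_)
  if (read$strand == "+") substring(read$sequence, o + 1, o + 1)
  else COMPLEMENT[[substring(read$sequence, read$length - o, read$length - o)]]
}

#' Pseudohaploid genotype calling
#'
#' At every panel site covered by at least one read, one covering read is
#' chosen uniformly at random (seeded) and its base at the site represents
#' the genotype. A base matching neither the ref nor the alt allele (e.g. a
#' residual damage artifact) makes the site missing, as does zero coverage.
#' Calls are stored on the haploid 0/1 scale with ploidy
#' `"pseudohaploid"`.
#'
#' @param reads filtered, trimmed, aligned `read_table` for one individual.
#' @param ref [mini_reference()] with sequences.
#' @param panel [snp_panel()].
#' @param id,population individual id and population label for the output.
#' @param seed integer seed making the random read choice reproducible.
#' @return a one-individual [genotype_table()].
#' @export
pseudohaploid_call <- function(reads, ref, panel, id = "sample",
                               population = "ancient", seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"))
  if (nrow(panel$sites) == 0) stopf("empty panel")
  aligned <- reads[reads$chrom != "*" & !is.na(reads$sequence), , drop = FALSE]
  sites <- panel$sites
  calls <- rep(NA_integer_, nrow(sites))
  with_seed(seed, {
    for (cn in unique(sites$chrom)) {
      si <- which(sites$chrom == cn)
      r <- aligned[aligned$chrom == cn, , drop = FALSE]
      if (nrow(r) == 0) next
      ends <- r$start + r$length
      for (k in si) {
        pos <- sites$pos[k]
        cover <- which(r$start <= pos - 1 & ends >= pos)
        if (length(cover) == 0) next
        pick <- cover[sample.int(length(cover), 1L)]
        b <- read_base_at(r[pick, ], pos)
        calls[k] <- if (is.na(b)) NA_integer_
                    else if (b == sites$ref_allele[k]) 0L
                    else if (b == sites$alt_allele[k]) 1L
                    else NA_integer_
      }
    }
  })
  genotype_table(matrix(calls, ncol = 1),
                 data.frame(id = id, population = population,
                            ploidy = "pseudohaploid", stringsAsFactors = FALSE),
                 panel)
}

#' Design capture probes for a SNP panel
#'
#' Four 60-base probes per SNP: reference- and alternative-allele probes
#' centered on the SNP (0-based offset 29 of 60), and two reference-sequence
#' flanking probes abutting the centered window on each side. SNPs within
#' 89 bases of a chromosome end cannot host the flanks and are recorded as
#' failures; the rest proceed.
#'
#' @param panel a [snp_panel()].
#' @param ref [mini_reference()] with sequences.
#' @param probe_length probe length (the centered probes place the SNP at
#'   0-based offset `probe_length/2 - 1`).
#' @return list of class `probe_set`: data.frame `probes`
#'   (snp_id, kind, chrom, start (1-based), sequence) and character vector
#'   `failed` of undesignable snp_ids.
#' @export
design_probes <- function(panel, ref, probe_length = 60L) {
  stopifnot(inherits(panel, "snp_panel"), probe_length %% 2 == 0)
  half_up <- probe_length / 2L - 1L   # bases before the SNP in centered probes
  half_dn <- probe_length / 2L        # bases after
  flank_span <- half_up + probe_length  # 89 for length 60
  sites <- panel$sites
  rows <- list(); failed <- character(0)
  for (k in seq_len(nrow(sites))) {
    pos <- sites$pos[k]; cn <- sites$chrom[k]
    L <- ref$chromosomes$length[ref$chromosomes$name == cn]
    if (length(L) == 0) { failed <- c(failed, sites$snp_id[k]); next }
    if (pos - flank_span < 1 || pos + flank_span + 1 > L) {
      failed <- c(failed, sites$snp_id[k]); next
    }
    s <- ref_seq(ref, cn)
    cen_start <- pos - half_up
    cen <- substring(s, cen_start, pos + half_dn)
    alt <- cen
    substr(alt, half_up + 1L, half_up + 1L) <- sites$alt_allele[k]
    refc <- cen
    substr(refc, half_up + 1L, half_up + 1L) <- sites$ref_allele[k]
    left <- substring(s, cen_start - probe_length, cen_start - 1L)
    right <- substring(s, pos + half_dn + 1L, pos + half_dn + probe_length)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = sites$snp_id[k],
      kind = c("ref_centered", "alt_centered", "left_flank", "right_flank"),
      chrom = cn,
      start = c(cen_start, cen_start, cen_start - probe_length, pos + half_dn + 1L),
      sequence = c(refc, alt, left, right), stringsAsFactors = FALSE)
  }
  structure(list(probes = if (length(rows)) do.call(rbind, rows)
                          else data.frame(),
                 failed = failed, probe_length = probe_length),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("Probe set: %d probes for %d SNPs (%d undesignable)\n",
              NROW(x$probes), NROW(x$probes) / 4, length(x$failed)))
  invisible(x)
}

#' Assign per-SNP ancestral states from two outgroup genotype vectors
#'
#' The ancestral allele is the allele both outgroup taxa carry as a
#' homozygous (or pseudohaploid) call; any disagreement or missingness
#' leaves the site unassigned.
#'
#' @param panel a [snp_panel()] (or its subset of selected loci).
#' @param outgroup1,outgroup2 integer vectors on the diploid dosage scale
#'   (0/1/2, `NA` missing), aligned with `panel` rows; pseudohaploid calls
#'   may be supplied as 0/2.
#' @return character vector per site: `"ref"`, `"alt"`, or `"unassigned"`.
#' @export
assign_ancestral_state <- function(panel, outgroup1, outgroup2) {
  n <- nrow(panel$sites)
  stopifnot(length(outgroup1) == n, length(outgroup2) == n)
  state <- rep("unassigned", n)
  both_ref <- !is.na(outgroup1) & !is.na(outgroup2) & outgroup1 == 0 & outgroup2 == 0
  both_alt <- !is.na(outgroup1) & !is.na(outgroup2) & outgroup1 == 2 & outgroup2 == 2
  state[both_ref] <- "ref"
  state[both_alt] <- "alt"
  state
}

#' Derived-allele carriers among ancient individuals at selected loci
#'
#' For each locus with an assigned ancestral state, reports whether at
#' least one (and whether every) ancient individual carries the derived
#' (non-ancestral) allele, and the fraction of assigned loci with at least
#' one ancient carrier.
#'
#' @param table a [genotype_table()] containing the ancient individuals.
#' @param ancestral per-site states from [assign_ancestral_state()].
#' @param ancient_ids ids of the ancient individuals in `table`.
#' @return list with per-locus data.frame `loci` (snp_id, ancestral,
#'   n_carriers, any_carrier, all_carriers) over assigned loci, and scalars
#'   `n_assigned`, `fraction_any_carrier`.
#' @export
derived_allele_summary <- function(table, ancestral, ancient_ids) {
  stopifnot(inherits(table, "genotype_table"),
            length(ancestral) == nrow(table$geno))
  if (!all(ancient_ids %in% table$ind$id))
    stopf("unknown ancient id(s): %s",
          paste(setdiff(ancient_ids, table$ind$id), collapse = ", "))
  assigned <- which(ancestral != "unassigned")
  if (length(assigned) == 0) stopf("no loci with an assigned ancestral state")
  cols <- match(ancient_ids, table$ind$id)
  g <- table$geno[assigned, cols, drop = FALSE]
  ph <- table$ind$ploidy[cols] == "pseudohaploid"
  # derived dosage: count of the non-ancestral allele
  max_dose <- matrix(rep(ifelse(ph, 1, 2), each = length(assigned)), nrow = length(assigned))
  derived <- g
  flip <- ancestral[assigned] == "alt"
  derived[flip, ] <- max_dose[flip, , drop = FALSE] - g[flip, , drop = FALSE]
  carrier <- derived > 0
  any_c <- rowSums(carrier, na.rm = TRUE) > 0
  # all_carriers: every ancient with data carries the derived allele
  all_c <- apply(carrier, 1, function(z) {
    z2 <- z[!is.na(z)]
    length(z2) > 0 && all(z2)
  })
  loci <- data.frame(snp_id = table$panel$sites$snp_id[assigned],
                     ancestral = ancestral[assigned],
                     n_carriers = rowSums(carrier, na.rm = TRUE),
                     any_carrier = any_c, all_carriers = all_c,
                     stringsAsFactors = FALSE)
  list(loci = loci, n_assigned = length(assigned),
       fraction_any_carrier = mean(any_c))
}
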