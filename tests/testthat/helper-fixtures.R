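# Shared fixtures and independent oracles, all built in code at test time.

# Small sequenced reference for read-level tests.
tiny_ref <- function(n_aut = 3L, len = 5e4, seed = 11L) {
  mini_reference(n_autosomes = n_aut, autosome_lengths = rep(len, n_aut),
                 x_length = round(len / 2), mt_length = 16616L,
                 with_sequences = TRUE, seed = seed)
}

# Outgroup + three west + three east modern populations, for affinity tests.
six_pop_tree <- function() {
  edges <- data.frame(
    parent = c("root", "root", "dom", "dom", "W", "W", "W", "E", "E", "E"),
    child = c("outgroup", "dom", "W", "E", "w1", "w2", "w3", "e1", "e2", "e3"),
    drift = c(0.15, 0.02, 0.06, 0.06, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02))
  population_tree(edges, c(outgroup = "outgroup",
                           w1 = "modern_west", w2 = "modern_west", w3 = "modern_west",
                           e1 = "modern_east", e2 = "modern_east", e3 = "modern_east"))
}

# Random frequency object in the allele_freqs() shape, for f-stat oracles.
rand_freq_obj <- function(n_sites, pops = c("O", "A", "B", "C"), seed = 1L,
                          n_chrom = 4L) {
  set.seed(seed)
  f <- matrix(runif(n_sites * length(pops)), n_sites,
              dimnames = list(NULL, pops))
  list(freq = f, n_obs = f * 0 + 10,
       positions = data.frame(chrom = paste0("chr", rep_len(seq_len(n_chrom), n_sites)),
                              pos = ave(seq_len(n_sites),
                                        rep_len(seq_len(n_chrom), n_sites),
                                        FUN = seq_along) * 1000))
}

# Independent per-site loop oracles (no vectorisation shared with the
# implementation).
oracle_f3 <- function(freqs, o, a, b) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(freqs$freq))) {
    fo <- freqs$freq[i, o]; fa <- freqs$freq[i, a]; fb <- freqs$freq[i, b]
    if (!is.na(fo) && !is.na(fa) && !is.na(fb)) {
      tot <- tot + (fo - fa) * (fo - fb); n <- n + 1
    }
  }
  unname(tot / n)
}

oracle_d <- function(freqs, w, x, y, z) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(freqs$freq))) {
    fw <- freqs$freq[i, w]; fx <- freqs$freq[i, x]
    fy <- freqs$freq[i, y]; fz <- freqs$freq[i, z]
    if (anyNA(c(fw, fx, fy, fz))) next
    num <- num + (fw - fx) * (fy - fz)
    den <- den + (fw + fx - 2 * fw * fx) * (fy + fz - 2 * fy * fz)
  }
  unname(num / den)
}

# Copy a reference with alt alleles planted at the panel sites where
# `carry` is 1: a haploid "individual genome" reads can be simulated from.
plant_variants <- function(ref, panel, carry) {
  s <- panel$sites
  for (k in which(carry == 1L)) {
    seqname <- s$chrom[k]
    substr(ref$sequences[[seqname]], s$pos[k], s$pos[k]) <- s$alt_allele[k]
  }
  ref
}

# Genotype table built directly from a dosage matrix (diploid).
gt_from_matrix <- function(m, populations, panel = NULL, prefix = "i") {
  if (is.null(panel)) panel <- ovipop:::generic_panel(nrow(m))
  genotype_table(m, data.frame(id = paste0(prefix, seq_len(ncol(m))),
                               population = populations, ploidy = "diploid"),
                 panel)
}
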