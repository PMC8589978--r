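# Synthetic-data generators: drifted allele frequencies, genotypes,
# damaged ancient reads on a miniature reference, and control-region
# fragment replicates.

#' Simulation configuration
#'
#' Bundles the knobs shared by the generators. Defaults describe the study
#' conditions the package emulates: short log-normal fragments (minimum
#' 35 bp, mean around 70 bp), 5' C->T / 3' G->A deamination around 30% at
#' the terminal base, an endogenous fraction of 2%, and shallow shotgun
#' depth.
#'
#' @param n_snps number of biallelic sites to simulate.
#' @param root_freq_law length-2 numeric: the root allele frequency is drawn
#'   uniformly from this interval (kept away from 0/1 so drift has room).
#' @param individuals_per_pop individuals drawn per population.
#' @param seed integer seed; the same seed reproduces every artifact.
#' @param delta_max probability of deamination at the terminal base.
#' @param decay exponential per-base decay rate of the damage curve.
#' @param background position-independent residual damage probability.
#' @param base_error uniform sequencing substitution error per base.
#' @param fragment_meanlog,fragment_sdlog log-scale parameters of the
#'   log-normal fragment length law.
#' @param fragment_min minimum fragment length (post-filter floor, 35 bp).
#' @param endogenous_fraction proportion of reads that are endogenous.
#' @param mean_depth expected reads per autosomal site.
#' @param missing_rate genotype missingness injected by [draw_genotypes()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 1000L,
                       root_freq_law = c(0.05, 0.95),
                       individuals_per_pop = 10L,
                       seed = 1L,
                       delta_max = 0.30, decay = 0.70, background = 0.01,
                       base_error = 0,
                       fragment_meanlog = log(70), fragment_sdlog = 0.35,
                       fragment_min = 35L,
                       endogenous_fraction = 0.02,
                       mean_depth = 0.3,
                       missing_rate = 0) {
  if (!is.numeric(n_snps) || n_snps < 1) stopf("n_snps must be >= 1")
  for (nm in c("delta_max", "decay", "background", "base_error",
               "endogenous_fraction", "missing_rate"))
    check_prob(get(nm), nm)
  if (decay < 0) stopf("decay must be >= 0")
  if (fragment_min < 1) stopf("fragment_min must be >= 1")
  structure(list(n_snps = as.integer(n_snps), root_freq_law = root_freq_law,
                 individuals_per_pop = as.integer(individuals_per_pop),
                 seed = as.integer(seed),
                 delta_max = delta_max, decay = decay, background = background,
                 base_error = base_error,
                 fragment_meanlog = fragment_meanlog,
                 fragment_sdlog = fragment_sdlog,
                 fragment_min = as.integer(fragment_min),
                 endogenous_fraction = endogenous_fraction,
                 mean_depth = mean_depth, missing_rate = missing_rate),
            class = "sim_config")
}

#' Miniature reference genome
#'
#' A desk-scale stand-in for a sheep reference: 26 autosomes with lengths
#' decreasing from 3.0 Mb to 0.5 Mb, an X chromosome of 2.0 Mb, and a
#' mitochondrial contig of 16,616 bases (long enough that control-region
#' position 15,534 exists). Sequences are random and only generated when
#' `with_sequences = TRUE`; placement-level simulations (sexing, coverage)
#' need only the lengths.
#'
#' @param n_autosomes number of autosomes.
#' @param autosome_lengths autosome lengths in bases.
#' @param x_length,mt_length X and MT lengths in bases.
#' @param with_sequences generate random sequences (memory ~ genome size).
#' @param seed seed for sequence generation.
#' @return object of class `mini_reference`: data.frame `chromosomes`
#'   (name, length, is_autosome, is_x, is_mt) plus named character vector
#'   `sequences` (possibly NULL).
#' @export
mini_reference <- function(n_autosomes = 26L,
                           autosome_lengths = round(seq(3e6, 5e5, length.out = n_autosomes)),
                           x_length = 2e6, mt_length = 16616L,
                           with_sequences = FALSE, seed = 1L) {
  stopifnot(length(autosome_lengths) == n_autosomes, all(autosome_lengths > 0))
  chrom <- data.frame(
    name = c(paste0("chr", seq_len(n_autosomes)), "chrX", "chrMT"),
    length = as.numeric(c(autosome_lengths, x_length, mt_length)),
    is_autosome = c(rep(TRUE, n_autosomes), FALSE, FALSE),
    is_x = c(rep(FALSE, n_autosomes), TRUE, FALSE),
    is_mt = c(rep(FALSE, n_autosomes), FALSE, TRUE),
    stringsAsFactors = FALSE)
  seqs <- NULL
  if (with_sequences) {
    seqs <- with_seed(seed, random_dna(chrom$length))
    names(seqs) <- chrom$name
  }
  structure(list(chromosomes = chrom, sequences = seqs,
                 mt_reference_name = "chrMT"),
            class = "mini_reference")
}

#' @export
print.mini_reference <- function(x, ...) {
  cat(sprintf("Miniature reference: %d contigs, %.1f Mb total%s\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              if (is.null(x$sequences)) " (lengths only)" else ""))
  invisible(x)
}

ref_seq <- function(ref, chrom) {
  if (is.null(ref$sequences))
    stopf("reference was built without sequences (with_sequences = FALSE)")
  s <- ref$sequences[[chrom]]
  if (is.null(s)) stopf("unknown chromosome '%s'", chrom)
  s
}

# Balding-Nichols transition: child frequency given parent frequency f and
# drift d, Beta(f(1-d)/d, (1-f)(1-d)/d); mean f, variance d f (1-f).
# Frequencies already fixed at 0 or 1 are absorbed.
drift_freq <- function(f, d) {
  if (d == 0) return(f)
  out <- f
  seg <- f > 0 & f < 1
  if (any(seg)) {
    k <- (1 - d) / d
    out[seg] <- stats::rbeta(sum(seg), f[seg] * k, (1 - f[seg]) * k)
  }
  out
}

#' Simulate allele frequencies down a population tree
#'
#' Draws root frequencies from the configured law, then propagates them down
#' every branch with a Balding--Nichols beta step of variance
#' `d * f * (1 - f)` per branch. Deterministic under `config$seed`.
#'
#' @param tree a [population_tree()].
#' @param config a [sim_config()].
#' @return matrix of allele frequencies, `n_snps` rows x one column per tree
#'   node (leaves and internal nodes; leaf columns are what downstream
#'   samplers use), with attribute `roles`.
#' @export
simulate_frequencies <- function(tree, config) {
  stopifnot(inherits(tree, "population_tree"), inherits(config, "sim_config"))
  with_seed(config$seed, {
    freqs <- matrix(NA_real_, nrow = config$n_snps, ncol = length(tree$order),
                    dimnames = list(NULL, tree$order))
    freqs[, tree$root] <- stats::runif(config$n_snps,
                                       config$root_freq_law[1], config$root_freq_law[2])
    for (i in seq_len(nrow(tree$edges))) {
      # edges are stored parent-first because population_tree() orders them
      parent <- tree$edges$parent[i]; child <- tree$edges$child[i]
      freqs[, child] <- drift_freq(freqs[, parent], tree$edges$drift[i])
    }
    structure(freqs[, tree$leaves, drop = FALSE], roles = tree$roles)
  })
}

#' Draw genotypes from population allele frequencies
#'
#' Diploid individuals get binomial(2, f) alt-allele dosages; pseudohaploid
#' individuals a single Bernoulli(f) draw stored on a haploid 0/1 scale
#' (exported to EIGENSTRAT as 0/2). Missingness is injected completely at
#' random at `config$missing_rate`.
#'
#' @param freqs frequency matrix from [simulate_frequencies()] (or any
#'   numeric matrix, columns = populations).
#' @param populations columns of `freqs` to sample from (default all).
#' @param mode `"diploid"` or `"pseudohaploid"`.
#' @param config a [sim_config()]; uses `individuals_per_pop`,
#'   `missing_rate`, `seed`.
#' @param panel optional [snp_panel()] to attach; a generic panel is built
#'   if omitted.
#' @param seed overrides `config$seed` when given.
#' @return a [genotype_table()].
#' @export
draw_genotypes <- function(freqs, populations = colnames(freqs),
                           mode = c("diploid", "pseudohaploid"),
                           config = sim_config(), panel = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!all(populations %in% colnames(freqs)))
    stopf("unknown population(s): %s",
          paste(setdiff(populations, colnames(freqs)), collapse = ", "))
  f <- freqs[, populations, drop = FALSE]
  if (any(f < 0 | f > 1)) stopf("frequencies must lie in [0, 1]")
  n_snps <- nrow(f)
  n_ind <- config$individuals_per_pop
  if (is.null(panel)) panel <- generic_panel(n_snps)
  if (nrow(panel$sites) != n_snps) stopf("panel size does not match frequency table")
  with_seed(if (is.null(seed)) config$seed else seed, {
    mats <- lapply(populations, function(pop) {
      p <- rep(f[, pop], times = n_ind)
      g <- if (mode == "diploid") stats::rbinom(length(p), 2L, p)
           else stats::rbinom(length(p), 1L, p)
      matrix(g, nrow = n_snps, ncol = n_ind)
    })
    geno <- do.call(cbind, mats)
    if (config$missing_rate > 0)
      geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
    ind <- data.frame(
      id = unlist(lapply(populations, function(p) paste0(p, "_", seq_len(n_ind)))),
      population = rep(populations, each = n_ind),
      ploidy = mode, stringsAsFactors = FALSE)
    genotype_table(geno, ind, panel)
  })
}

# Chromosome sampling intensity: length x copy number.
chrom_copy_number <- function(ref, sex) {
  cn <- ifelse(ref$chromosomes$is_autosome, 2,
               ifelse(ref$chromosomes$is_x, if (sex == "XY") 1 else 2, 2))
  stats::setNames(cn, ref$chromosomes$name)
}

#' Simulate aligned ancient reads on a miniature reference
#'
#' Endogenous reads are placed uniformly with per-chromosome intensity
#' proportional to length x copy number (X has copy number 1 in XY males),
#' lengths drawn from the truncated log-normal law, strands uniform, and
#' postmortem damage applied on the strand as sequenced: C->T at 5' offsets
#' and G->A at 3' offsets with probability
#' `delta_max * exp(-decay * offset) + background`, plus a uniform
#' substitution error. Non-endogenous (contaminant) reads are emitted with
#' `endogenous = FALSE` at rate `1 - endogenous_fraction` and carry random
#' sequence unaligned to the reference (chrom `"*"`).
#'
#' @param ref a [mini_reference()]; sequences required unless
#'   `emit_sequences = FALSE`.
#' @param config a [sim_config()].
#' @param sex `"XX"` or `"XY"` (controls X-chromosome copy number).
#' @param emit_sequences if `FALSE`, only placements are generated (the
#'   `sequence` column is `NA`); used for coverage/sexing experiments on
#'   references too large to hold as sequence.
#' @param seed overrides `config$seed`.
#' @return data.frame of class `read_table` with columns
#'   `chrom, start, length, strand, sequence, endogenous` (0-based
#'   half-open `start .. start+length`).
#' @export
simulate_ancient_reads <- function(ref, config, sex = c("XX", "XY"),
                                   emit_sequences = TRUE, seed = NULL) {
  sex <- match.arg(sex)
  stopifnot(inherits(ref, "mini_reference"), inherits(config, "sim_config"))
  if (config$mean_depth <= 0) stopf("mean_depth must be > 0")
  chrom <- ref$chromosomes
  cn <- chrom_copy_number(ref, sex)
  mean_len <- exp(config$fragment_meanlog + config$fragment_sdlog^2 / 2)
  with_seed(if (is.null(seed)) config$seed else seed, {
    # expected endogenous reads so that autosomal depth ~ mean_depth
    lambda <- config$mean_depth * (cn / 2) * chrom$length / mean_len
    n_per_chrom <- stats::rpois(length(lambda), lambda)
    n_endo <- sum(n_per_chrom)
    chroms <- rep(chrom$name, n_per_chrom)
    lens <- pmax(round(stats::rlnorm(n_endo, config$fragment_meanlog,
                                     config$fragment_sdlog)),
                 config$fragment_min)
    lens <- pmin(lens, rep(chrom$length, n_per_chrom))  # tiny contigs
    maxstart <- rep(chrom$length, n_per_chrom) - lens
    starts <- floor(stats::runif(n_endo) * (maxstart + 1))
    strands <- sample(c("+", "-"), n_endo, replace = TRUE)
    seqs <- rep(NA_character_, n_endo)
    if (emit_sequences && n_endo > 0) {
      seqs <- substr_many(ref, chroms, starts, lens)
      minus <- strands == "-"
      seqs[minus] <- revcomp(seqs[minus])
      seqs <- apply_damage(seqs, config)
    }
    # contaminants: endogenous_fraction = endo / total
    ef <- config$endogenous_fraction
    if (ef <= 0) stopf("endogenous_fraction must be > 0 when simulating reads")
    n_cont <- if (ef < 1) stats::rpois(1L, n_endo * (1 - ef) / ef) else 0L
    cont <- if (n_cont > 0) {
      clens <- pmax(round(stats::rlnorm(n_cont, config$fragment_meanlog,
                                        config$fragment_sdlog)),
                    config$fragment_min)
      data.frame(chrom = "*", start = 0, length = clens, strand = "+",
                 sequence = if (emit_sequences) random_dna(clens) else NA_character_,
                 endogenous = FALSE, stringsAsFactors = FALSE)
    } else NULL
    endo <- data.frame(chrom = chroms, start = starts, length = lens,
                       strand = strands, sequence = seqs, endogenous = TRUE,
                       stringsAsFactors = FALSE)
    out <- rbind(endo, cont)
    rownames(out) <- NULL
    class(out) <- c("read_table", "data.frame")
    out
  })
}

# Extract many reference substrings, grouped per chromosome for speed.
substr_many <- function(ref, chroms, starts, lens) {
  out <- character(length(chroms))
  for (cn in unique(chroms)) {
    i <- which(chroms == cn)
    s <- ref_seq(ref, cn)
    out[i] <- substring(s, starts[i] + 1, starts[i] + lens[i])
  }
  out
}

# Damage curve: terminal-base probability delta_max decaying exponentially
# with offset, on top of a constant background.
damage_prob <- function(offset, config)
  config$delta_max * exp(-config$decay * offset) + config$background

# Apply 5' C->T and 3' G->A deamination plus uniform sequencing error to
# read sequences given in sequencing orientation.
apply_damage <- function(seqs, config) {
  if (length(seqs) == 0) return(seqs)
  bases <- strsplit(seqs, "")
  lens <- lengths(bases)
  flat <- unlist(bases, use.names = FALSE)
  idx <- rep(seq_along(lens), lens)
  off5 <- sequence(lens) - 1L
  off3 <- rep(lens, lens) - sequence(lens)
  if (config$delta_max > 0 || config$background > 0) {
    p5 <- damage_prob(off5, config)
    hit5 <- flat == "C" & stats::runif(length(flat)) < p5
    p3 <- damage_prob(off3, config)
    hit3 <- flat == "G" & stats::runif(length(flat)) < p3
    flat[hit5] <- "T"
    flat[hit3] <- "A"
  }
  if (config$base_error > 0) {
    err <- stats::runif(length(flat)) < config$base_error
    if (any(err)) {
      alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
      flat[err] <- vapply(flat[err], function(b)
        substring(alt[[b]], s <- sample.int(3L, 1L), s), character(1))
    }
  }
  vapply(split(flat, idx), paste, character(1), collapse = "")[as.character(seq_along(lens))]
}

#' Simulate replicated 144-bp control-region fragments
#'
#' Each replicate is the reference fragment with the sample's
#' haplogroup-defining alleles planted at the diagnostic sites, random
#' transitions at non-diagnostic sites at `error_rate`, and convergent
#' transitions at diagnostic sites (towards each site's alternative allele)
#' at `homoplasy_rate` -- the homoplasy mechanism the fragment-based
#' classifier has to survive.
#'
#' @param diagnostic a [diagnostic_table()].
#' @param truth_labels named character vector: sample id -> haplogroup.
#' @param n_replicates replicates per sample (recycled).
#' @param error_rate per-site transition probability at non-diagnostic sites.
#' @param homoplasy_rate per-site convergent transition probability at
#'   diagnostic sites.
#' @param seed integer seed.
#' @return data.frame with columns `sample, replicate, sequence, source`.
#' @export
simulate_mt_replicates <- function(diagnostic, truth_labels, n_replicates = 2L,
                                   error_rate = 0, homoplasy_rate = 0, seed = 1L) {
  stopifnot(inherits(diagnostic, "diagnostic_table"))
  check_prob(error_rate, "error_rate"); check_prob(homoplasy_rate, "homoplasy_rate")
  bad <- setdiff(truth_labels, diagnostic$haplogroups)
  if (length(bad)) stopf("unknown haplogroup label(s): %s", paste(bad, collapse = ", "))
  if (is.null(names(truth_labels)))
    names(truth_labels) <- paste0("S", seq_along(truth_labels))
  n_replicates <- rep_len(n_replicates, length(truth_labels))
  frag_len <- diagnostic$fragment_end - diagnostic$fragment_start + 1L
  diag_off <- diagnostic$sites$position - diagnostic$fragment_start + 1L
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  with_seed(seed, {
    rows <- list()
    for (s in seq_along(truth_labels)) {
      hg <- truth_labels[[s]]
      planted <- strsplit(diagnostic$fragment_reference, "")[[1L]]
      planted[diag_off] <- unlist(diagnostic$sites[[paste0("hg_", hg)]])
      for (r in seq_len(n_replicates[s])) {
        b <- planted
        if (error_rate > 0) {
          nd <- setdiff(seq_len(frag_len), diag_off)
          hit <- nd[stats::runif(length(nd)) < error_rate]
          b[hit] <- transition[b[hit]]
        }
        if (homoplasy_rate > 0) {
          hit <- diag_off[stats::runif(length(diag_off)) < homoplasy_rate]
          b[hit] <- transition[b[hit]]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = names(truth_labels)[s], replicate = r,
          sequence = paste(b, collapse = ""), source = "sanger_fragment",
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate full synthetic mitogenomes with known haplogroups
#'
#' Embeds a (possibly perturbed) control-region fragment carrying each
#' sample's haplogroup pattern into a random mitogenome background, for
#' validating fragment-based classification against full-sequence truth.
#'
#' @param diagnostic a [diagnostic_table()].
#' @param truth_labels named character vector: sample id -> haplogroup.
#' @param error_rate,homoplasy_rate as in [simulate_mt_replicates()].
#' @param mt_length mitogenome length (>= fragment end).
#' @param seed integer seed.
#' @return named character vector of mitogenome sequences.
#' @export
simulate_mitogenomes <- function(diagnostic, truth_labels, error_rate = 0,
                                 homoplasy_rate = 0, mt_length = 16616L,
                                 seed = 1L) {
  stopifnot(mt_length >= diagnostic$fragment_end)
  frags <- simulate_mt_replicates(diagnostic, truth_labels, n_replicates = 1L,
                                  error_rate = error_rate,
                                  homoplasy_rate = homoplasy_rate, seed = seed)
  with_seed(seed + 1L, {
    pre <- random_dna(diagnostic$fragment_start - 1L)
    post <- random_dna(mt_length - diagnostic$fragment_end)
    stats::setNames(paste0(pre, frags$sequence, post), frags$sample)
  })
}
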