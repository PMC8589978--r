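# Damage profiling, PMD scoring, filtering, coverage, length authentication.

mk_reads <- function(ref, cfg, seed = 1) simulate_ancient_reads(ref, cfg, seed = seed)

test_that("damage profile is zero on undamaged reads and recovers the curve", {
  ref <- tiny_ref()
  clean <- mk_reads(ref, sim_config(delta_max = 0, background = 0, base_error = 0,
                                    mean_depth = 0.5, endogenous_fraction = 1))
  prof <- damage_profile(clean, ref, window = 25)
  expect_true(all(prof$rate_5p_CT[prof$n_obs_5p > 0] == 0))
  expect_true(all(prof$rate_3p_GA[prof$n_obs_3p > 0] == 0))
  expect_error(damage_profile(clean[0, ], ref), "empty")

  dam <- mk_reads(tiny_ref(n_aut = 4, len = 1e5),
                  sim_config(delta_max = 0.3, decay = 0.3, background = 0.01,
                             base_error = 0, mean_depth = 4, endogenous_fraction = 1),
                  seed = 5)
  ref4 <- tiny_ref(n_aut = 4, len = 1e5)
  prof2 <- damage_profile(dam, ref4, window = 25)
  p <- 0.31
  expect_lt(abs(prof2$rate_5p_CT[1] - p), 3 * sqrt(p * (1 - p) / prof2$n_obs_5p[1]))
  expect_lt(abs(prof2$rate_3p_GA[1] - p), 3 * sqrt(p * (1 - p) / prof2$n_obs_3p[1]))
  # severity of the emulated libraries falls in the observed ancient band
  expect_gt(prof2$rate_5p_CT[1], 0.20)
  expect_lt(prof2$rate_5p_CT[1], 0.42)
  # decay towards background along the read
  expect_lt(prof2$rate_5p_CT[20], 0.1)
})

test_that("profiles are strand-consistent under label flip + reverse complement", {
  # flipping the strand label while reverse-complementing the sequence views
  # the same molecule from the other end: the 5' C->T profile becomes the
  # 3' G->A profile and vice versa, exactly
  ref <- tiny_ref()
  rds <- mk_reads(ref, sim_config(delta_max = 0.3, decay = 0.5, background = 0,
                                  base_error = 0, mean_depth = 0.5,
                                  endogenous_fraction = 1), seed = 2)
  prof1 <- damage_profile(rds, ref, window = 20)
  flipped <- rds
  flipped$strand <- ifelse(rds$strand == "+", "-", "+")
  flipped$sequence <- revcomp(rds$sequence)
  prof2 <- damage_profile(flipped, ref, window = 20)
  expect_equal(prof2$rate_5p_CT, prof1$rate_3p_GA)
  expect_equal(prof2$rate_3p_GA, prof1$rate_5p_CT)
  expect_equal(prof2$n_obs_5p, prof1$n_obs_3p)
})

test_that("pmd_score matches the hand-evaluated likelihood ratio", {
  # one synthetic read placed on a constructed reference segment
  ref <- tiny_ref()
  # find a read window starting with C on chr1
  s <- ref$sequences[["chr1"]]
  start <- regexpr("C", s)[1] - 1L
  refseg <- substring(s, start + 1, start + 20)
  params <- pmd_params(delta_max = 0.3, decay = 0.3, background = 0,
                       epsilon = 0.001)
  # observed = reference with a T at offset 0 (a C there by construction)
  obs <- refseg
  substr(obs, 1, 1) <- "T"
  rd <- data.frame(chrom = "chr1", start = start, length = 20L, strand = "+",
                   sequence = obs, endogenous = TRUE)
  sc_t <- pmd_score(rd, ref, params)
  rd_match <- rd; rd_match$sequence <- refseg
  sc_c <- pmd_score(rd_match, ref, params)
  d0 <- 0.3
  expected_t_contrib <- log((d0 + (1 - d0) * 0.001) / 0.001)
  expect_equal(sc_t - sc_c, expected_t_contrib - log(1 - d0), tolerance = 1e-9)
  expect_lt(abs(expected_t_contrib - log(0.3 / 0.001)), 0.01)
  # read spanning no C/G positions scores exactly 0
  at <- gregexpr("[AT]{8}", s)[[1]][1]
  rd0 <- data.frame(chrom = "chr1", start = at - 1L, length = 8L, strand = "+",
                    sequence = substring(s, at, at + 7), endogenous = TRUE)
  expect_identical(pmd_score(rd0, ref, params), 0)
})

test_that("damaged reads score higher than undamaged reads on average", {
  ref <- tiny_ref()
  params <- pmd_params(delta_max = 0.3, decay = 0.3, background = 0.01)
  dam <- mk_reads(ref, sim_config(delta_max = 0.3, decay = 0.3, background = 0.01,
                                  base_error = 0, mean_depth = 0.4,
                                  endogenous_fraction = 1), seed = 3)
  clean <- mk_reads(ref, sim_config(delta_max = 0, background = 0, base_error = 0,
                                    mean_depth = 0.4, endogenous_fraction = 1),
                    seed = 4)
  expect_gt(mean(pmd_score(dam, ref, params)), mean(pmd_score(clean, ref, params)))
})

test_that("filtering applies length, mismatch, PMD and trim rules in order", {
  ref <- tiny_ref()
  s <- ref$sequences[["chr1"]]
  mk <- function(start, len, seq) data.frame(chrom = "chr1", start = start,
                                             length = len, strand = "+",
                                             sequence = seq, endogenous = TRUE)
  short <- mk(100, 34L, substring(s, 101, 134))            # fails length
  seg100 <- substring(s, 201, 300)
  mutated <- strsplit(seg100, "")[[1]]
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  mutated[1:11] <- flip[mutated[1:11]]                      # 11 mismatches / 100
  noisy <- mk(200, 100L, paste(mutated, collapse = ""))
  ok <- mk(400, 50L, substring(s, 401, 450))
  reads <- rbind(short, noisy, ok)
  out <- filter_reads(reads, ref)
  rep <- attr(out, "filter_report")
  expect_equal(unname(rep["length"]), 1)
  expect_equal(unname(rep["mismatch"]), 1)
  expect_equal(nrow(out), 1)
  # 10 mismatches in 100 is exactly 0.10 and is retained
  mutated10 <- strsplit(seg100, "")[[1]]
  mutated10[1:10] <- flip[mutated10[1:10]]
  ten <- mk(200, 100L, paste(mutated10, collapse = ""))
  expect_equal(nrow(filter_reads(rbind(ten), ref)), 1)
  # trimming arithmetic: 50-base read trimmed by 10 leaves 30 aligned bases
  trimmed <- filter_reads(rbind(ok), ref, trim = 10)
  expect_equal(trimmed$length, 30)
  expect_equal(trimmed$start, 410)
  expect_equal(trimmed$sequence, substring(s, 411, 440))
  expect_error(filter_reads(reads, ref, trim = -1), "trim")
})

test_that("filtering is idempotent under identical parameters", {
  ref <- tiny_ref()
  rds <- mk_reads(ref, sim_config(mean_depth = 0.3, endogenous_fraction = 1,
                                  base_error = 0.002), seed = 6)
  once <- filter_reads(rds, ref, trim = 10)
  twice <- filter_reads(once, ref, trim = 10)
  expect_equal(nrow(twice), nrow(once))
  expect_identical(twice$sequence, once$sequence)
  expect_identical(twice$start, once$start)
})

test_that("trimming by 10 removes the damage signal from the retained segment", {
  ref <- tiny_ref(n_aut = 4, len = 1e5)
  cfg <- sim_config(mean_depth = 4, endogenous_fraction = 1, base_error = 0,
                    seed = 9)  # default damage curve
  rds <- simulate_ancient_reads(ref, cfg)
  prof_before <- damage_profile(rds, ref, window = 12)
  expect_gt(prof_before$rate_5p_CT[1], 0.2)
  trimmed <- filter_reads(rds, ref, trim = 10)
  prof <- damage_profile(trimmed, ref, window = 12)
  bg <- cfg$background
  expect_lt(prof$rate_5p_CT[1], bg + 3 * sqrt(bg * (1 - bg) / prof$n_obs_5p[1]))
  expect_lt(prof$rate_3p_GA[1], bg + 3 * sqrt(bg * (1 - bg) / prof$n_obs_3p[1]))
})

test_that("endogenous fraction and coverage summaries follow their definitions", {
  rds <- data.frame(chrom = c(rep("chr1", 2), rep("*", 98)),
                    start = c(10, 20, rep(0, 98)), length = 40L, strand = "+",
                    sequence = NA_character_,
                    endogenous = c(TRUE, TRUE, rep(FALSE, 98)))
  expect_equal(endogenous_fraction(rds), 0.02)
  expect_equal(endogenous_fraction(rds[1:2, ]), 1.0)
  expect_equal(endogenous_fraction(rds[3:12, ]), 0.0)
  expect_error(endogenous_fraction(rds[0, ]), "empty")

  ref1 <- mini_reference(n_autosomes = 1L, autosome_lengths = 800,
                         x_length = 100, mt_length = 100)
  one <- data.frame(chrom = "chr1", start = 0, length = 100L, strand = "+",
                    sequence = NA_character_, endogenous = TRUE)
  expect_equal(coverage_summary(one, ref1)$genome_depth, 0.1)
  # per-SNP depth: site covered by the read counts it; uncovered sites are 0
  panel <- snp_panel(data.frame(snp_id = c("a", "b"), chrom = "chr1",
                                pos = c(50, 500), ref_allele = "A",
                                alt_allele = "C"))
  cs <- coverage_summary(one, ref1, panel)
  expect_equal(cs$snp_cover, c(1, 0))
  expect_equal(cs$snp_depth, 0.5)
  # uniform simulation recovers the configured depth within 10%
  ref <- tiny_ref()
  rds2 <- simulate_ancient_reads(ref, sim_config(mean_depth = 0.25,
                                                 endogenous_fraction = 1, seed = 2),
                                 emit_sequences = FALSE)
  expect_lt(abs(coverage_summary(rds2, ref)$genome_depth - 0.25) / 0.25, 0.1)
})

test_that("length-stratified f3 vectors from one individual are positively correlated", {
  tr <- six_pop_tree()
  n <- 160
  ref <- tiny_ref(n_aut = 4, len = 3e4, seed = 31)
  panel <- panel_from_reference(ref, n, seed = 32)
  cfg <- sim_config(n_snps = n, individuals_per_pop = 8, seed = 33)
  fr <- simulate_frequencies(tr, cfg)
  modern <- draw_genotypes(fr, colnames(fr), "diploid", cfg, panel = panel)
  # haploid genome of a west-cluster individual; reads carry its variants
  set.seed(34)
  carry <- rbinom(n, 1, fr[, "w1"])
  ind_ref <- plant_variants(ref, panel, carry)
  rds <- simulate_ancient_reads(ind_ref, sim_config(mean_depth = 3,
                                                    endogenous_fraction = 1,
                                                    delta_max = 0, background = 0,
                                                    seed = 35))
  auth <- authenticate_by_length(rds, ref, panel, modern, "outgroup",
                                 length_cut = 70, seed = 36)
  expect_gt(auth$spearman$rho, 0)
  expect_type(auth$pearson$r, "double")
  expect_length(auth$f3_short, 6)
  # identical affinity vectors correlate perfectly
  expect_equal(correlate_f3(auth$f3_short, auth$f3_short)$rho, 1)
})

test_that("mismatched-source length classes decouple the affinity vectors", {
  tr <- six_pop_tree()
  n <- 120
  ref <- tiny_ref(n_aut = 3, len = 2.5e4, seed = 41)
  panel <- panel_from_reference(ref, n, seed = 42)
  wins <- 0; total <- 40
  for (i in seq_len(total)) {
    cfg <- sim_config(n_snps = n, individuals_per_pop = 6, seed = 5000 + i)
    fr <- simulate_frequencies(tr, cfg)
    modern <- draw_genotypes(fr, colnames(fr), "diploid", cfg, panel = panel)
    set.seed(6000 + i)
    carry_w <- rbinom(n, 1, fr[, "w1"])
    carry_e <- rbinom(n, 1, fr[, "e1"])
    quiet <- sim_config(mean_depth = 2.5, endogenous_fraction = 1,
                        delta_max = 0, background = 0, seed = 7000 + i)
    rds_w <- simulate_ancient_reads(plant_variants(ref, panel, carry_w), quiet)
    rds_e <- simulate_ancient_reads(plant_variants(ref, panel, carry_e),
                                    quiet, seed = 8000 + i)
    matched <- authenticate_by_length(rds_w, ref, panel, modern, "outgroup",
                                      length_cut = 70, seed = 9000 + i)
    mixed_reads <- rbind(rds_w[rds_w$length <= 70, ],
                         rds_e[rds_e$length > 70, ])
    class(mixed_reads) <- c("read_table", "data.frame")
    mixed <- authenticate_by_length(mixed_reads, ref, panel, modern, "outgroup",
                                    length_cut = 70, seed = 9000 + i)
    if (mixed$spearman$rho < matched$spearman$rho) wins <- wins + 1
  }
  expect_gte(wins / total, 0.8)
})
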