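# Control-region fragment extraction, haplogroup calling, consensus
# workflow, accuracy validation and frequency statistics.

dt <- example_diagnostic_table()

test_that("diagnostic table invariants hold and bad tables are rejected", {
  expect_equal(dt$haplogroups, c("A", "B", "C", "D", "E"))
  expect_equal(nrow(dt$sites), 5)
  expect_equal(nchar(dt$fragment_reference), 144)
  dup <- dt$sites
  dup$hg_A <- dup$hg_B
  expect_error(diagnostic_table(dup, fragment_reference = dt$fragment_reference),
               "pairwise distinct")
  out_of_range <- dt$sites
  out_of_range$position[1] <- 15000L
  expect_error(diagnostic_table(out_of_range,
                                fragment_reference = dt$fragment_reference),
               "inside the fragment")
})

test_that("fragment extraction returns the 144-base window and checks bounds", {
  mito <- simulate_mitogenomes(dt, c(m = "B"), seed = 2)
  frag <- extract_fragment(mito[[1]], dt)
  expect_equal(nchar(frag), 144)
  expect_equal(15534 - 15391 + 1, 144)
  expect_error(extract_fragment(substring(mito[[1]], 1, 15533), dt), "cover")
  # the reference fragment itself carries the reference alleles at every site
  off <- dt$sites$position - dt$fragment_start + 1
  expect_equal(unname(substring(dt$fragment_reference, off, off)),
               dt$sites$ref_base)
})

test_that("planted patterns round-trip through the classifier for all five haplogroups", {
  for (hg in dt$haplogroups) {
    reps <- simulate_mt_replicates(dt, setNames(hg, "s"), n_replicates = 1,
                                   seed = 3)
    res <- call_haplogroup(reps$sequence[1], dt)
    expect_equal(res$label, hg)
    expect_equal(res$distance, 0)
    expect_length(res$conflicts, 0)
  }
  expect_error(call_haplogroup("ACGT", dt), "144")
})

test_that("N bases and convergent transitions follow the nearest-pattern rule", {
  reps <- simulate_mt_replicates(dt, c(s = "C"), n_replicates = 1, seed = 4)
  seq_c <- reps$sequence[1]
  off <- dt$sites$position - dt$fragment_start + 1
  # all-N diagnostic sites cannot be assigned
  all_n <- seq_c
  for (o in off) substr(all_n, o, o) <- "N"
  expect_equal(call_haplogroup(all_n, dt)$label, "unassigned")
  # one N at another haplogroup's diagnostic site: C still nearest at distance 1
  one_n <- seq_c
  substr(one_n, off[1], off[1]) <- "N"
  res <- call_haplogroup(one_n, dt)
  expect_equal(res$label, "C")
  expect_equal(res$distance, 1)
  expect_equal(res$conflicts, dt$sites$position[1])
  # N at C's own site removes the distinguishing base: tie with B -> unassigned
  own_n <- seq_c
  substr(own_n, off[2], off[2]) <- "N"
  expect_equal(call_haplogroup(own_n, dt)$label, "unassigned")
  # a convergent transition pulling a C pattern toward D creates a tie -> unassigned
  conv <- seq_c
  substr(conv, off[3], off[3]) <- dt$sites$hg_D[3]
  expect_equal(call_haplogroup(conv, dt)$label, "unassigned")
})

test_that("consensus workflow: concordant pairs, third-round majority, single sequences", {
  two <- consensus_call(c("B", "B"), sample = "s1")
  expect_equal(two$label, "B"); expect_equal(two$confidence, "high")
  maj <- consensus_call(c("B", "A", "B"), sample = "s2")
  expect_equal(maj$label, "B"); expect_equal(maj$n_support, 2)
  disc <- consensus_call(c("B", "A"), sample = "s3")
  expect_equal(disc$label, "unassigned")
  single <- consensus_call("D", sample = "s4")
  expect_equal(single$label, "D"); expect_equal(single$confidence, "low")
  expect_error(consensus_call(character(0)), "at least one")
  # order invariance
  expect_equal(consensus_call(c("A", "B", "B"))$label,
               consensus_call(c("B", "B", "A"))$label)
  # mitogenome override wins over the fragment consensus
  over <- consensus_call(c("B", "B"), mitogenome_call = "D", sample = "s5")
  expect_equal(over$label, "D")
  expect_true(over$mitogenome_override)
})

test_that("noiseless validation is perfect and confusion rows conserve counts", {
  labels <- setNames(rep(dt$haplogroups, each = 4), paste0("m", 1:20))
  mitos <- simulate_mitogenomes(dt, labels, seed = 6)
  val <- validate_fragment_accuracy(mitos, labels, dt)
  expect_equal(val$accuracy, 1.0)
  expect_equal(unname(rowSums(val$confusion)[dt$haplogroups]), rep(4, 5))
  expect_error(validate_fragment_accuracy(character(0), character(0), dt), "no mitogenomes")
})

test_that("homoplasy degrades accuracy as the single-site perturbation analysis predicts", {
  h <- 0.08
  n <- 400
  labels <- setNames(sample(dt$haplogroups, n, TRUE), paste0("m", seq_len(n)))
  mitos <- simulate_mitogenomes(dt, labels, homoplasy_rate = h, seed = 7)
  val <- validate_fragment_accuracy(mitos, labels, dt)
  # enumeration of single-site transitions under the nearest-pattern rule:
  # B with a hit at the A-half-site or any non-B pattern with its own site
  # reverted lands exactly on another pattern (miscall); B's other hits and
  # most single hits elsewhere stay nearest to the truth (distance-1 rescue);
  # expected accuracy = 1 - P(miscall), computed by exhaustive perturbation
  exp_acc <- local({
    off <- dt$sites$position - dt$fragment_start + 1
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    acc <- 0
    for (hg in dt$haplogroups) {
      pat <- vapply(seq_len(5), function(k) dt$sites[[paste0("hg_", hg)]][k],
                    character(1))
      # probability over independent site flips (enumerate all 2^5 hit masks)
      p_ok <- 0
      for (mask in 0:31) {
        bits <- as.logical(bitwAnd(mask, 2^(0:4)))
        prob <- prod(ifelse(bits, h, 1 - h))
        obs <- pat
        obs[bits] <- transition[obs[bits]]
        res <- call_haplogroup({
          s <- dt$fragment_reference
          for (k in seq_len(5)) substr(s, off[k], off[k]) <- obs[k]
          s
        }, dt)
        if (res$label == hg) p_ok <- p_ok + prob
      }
      acc <- acc + p_ok / 5
    }
    acc
  })
  expect_lt(abs(val$accuracy - exp_acc), 3 * sqrt(exp_acc * (1 - exp_acc) / n))
})

test_that("Clopper-Pearson frequencies reproduce the printed worked example", {
  calls <- data.frame(sample = paste0("s", 1:79),
                      label = c(rep("A", 4), rep("B", 75)),
                      confidence = "high", stringsAsFactors = FALSE)
  tab <- haplogroup_frequencies_ci(calls)
  a <- tab[tab$haplogroup == "A", ]
  expect_equal(a$k, 4); expect_equal(a$n, 79)
  expect_equal(round(100 * a$freq), 5)
  expect_equal(round(100 * a$lower), 1)
  expect_equal(round(100 * a$upper), 12)
  # boundary cases: 0/n has lower bound exactly 0, n/n upper bound exactly 1
  calls2 <- data.frame(sample = paste0("y", 1:10),
                       label = rep(c("A", "B"), c(6, 4)), confidence = "high")
  grouping <- setNames(rep(c("g1", "g2"), c(6, 4)), calls2$sample)
  tg <- haplogroup_frequencies_ci(calls2, grouping)
  a_g2 <- tg[tg$group == "g2" & tg$haplogroup == "A", ]
  expect_equal(a_g2$k, 0); expect_identical(a_g2$lower, 0)
  a_g1 <- tg[tg$group == "g1" & tg$haplogroup == "A", ]
  expect_equal(a_g1$k, 6); expect_identical(a_g1$upper, 1)
  # high-confidence restriction drops single-amplification samples
  mixed <- data.frame(sample = paste0("z", 1:4),
                      label = c("A", "A", "B", "B"),
                      confidence = c("high", "low", "high", "high"))
  t_all <- haplogroup_frequencies_ci(mixed, confidence_set = "all")
  t_high <- haplogroup_frequencies_ci(mixed, confidence_set = "high_only")
  expect_equal(t_all$n[1], 4); expect_equal(t_high$n[1], 3)
  # CIs nest: the 99% interval contains the 95% interval
  t95 <- haplogroup_frequencies_ci(calls, level = 0.95)
  t99 <- haplogroup_frequencies_ci(calls, level = 0.99)
  expect_true(all(t99$lower <= t95$lower & t99$upper >= t95$upper))
  expect_true(all(t95$lower <= t95$freq & t95$freq <= t95$upper))
})

test_that("Fisher comparisons match hypergeometric and permutation oracles", {
  same <- compare_frequencies(rep(c("A", "B"), c(5, 5)), rep(c("A", "B"), c(5, 5)))
  expect_equal(same$p, 1)
  expect_equal(same$w, 0)
  # 2x2 [[1,9],[9,1]]: full hypergeometric enumeration
  g1 <- rep(c("A", "B"), c(1, 9)); g2 <- rep(c("A", "B"), c(9, 1))
  res <- compare_frequencies(g1, g2)
  dh <- function(k) dhyper(k, 10, 10, 10)
  p_exact <- sum(dh(0:10)[dh(0:10) <= dh(1) + 1e-12])
  expect_equal(res$p, p_exact, tolerance = 1e-9)
  # Cohen's w from the same table, by hand
  tab <- res$table
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  w_hand <- sqrt(sum((tab - expected)^2 / expected) / sum(tab))
  expect_equal(res$w, w_hand, tolerance = 1e-12)
  # r x 2 exact p vs Monte-Carlo permutation on a 3x2 table
  l1 <- rep(c("A", "B", "C"), c(6, 2, 2))
  l2 <- rep(c("A", "B", "C"), c(1, 5, 4))
  res3 <- compare_frequencies(l1, l2)
  set.seed(9)
  pool <- c(l1, l2)
  n1 <- length(l1)
  probs <- replicate(20000, {
    idx <- sample(length(pool), n1)
    t_perm <- cbind(table(factor(pool[idx], levels = c("A", "B", "C"))),
                    table(factor(pool[-idx], levels = c("A", "B", "C"))))
    stats::fisher.test(t_perm)$p.value
  })
  # MC estimate of P(table at least as extreme) via the p-value ordering
  mc <- mean(probs <= res3$p + 1e-12)
  expect_lt(abs(res3$p - mc), 3 * sqrt(mc * (1 - mc) / 20000))
  expect_error(compare_frequencies(character(0), "A"), "non-empty")
})
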