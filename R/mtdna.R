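# Mitochondrial haplogroup classification from the 144-bp control-region
# fragment: diagnostic-site tables, per-replicate calls, the replicate
# consensus workflow, fragment-accuracy validation and frequency
# statistics.

#' Diagnostic-site table for haplogroups A-E
#'
#' Describes the control-region fragment (1-based inclusive interval on the
#' reference mitogenome, 15,391-15,534 by convention) and the diagnostic
#' sites: for each position, the reference base and the base each
#' haplogroup carries. Haplogroup allele patterns must be pairwise
#' distinct.
#'
#' @param sites data.frame with columns `position`, `ref_base`, and one
#'   `hg_<label>` column per haplogroup (e.g. `hg_A` .. `hg_E`).
#' @param fragment_start,fragment_end fragment interval, 1-based inclusive.
#' @param fragment_reference the fragment's reference sequence
#'   (`fragment_end - fragment_start + 1` bases); reference bases at the
#'   diagnostic positions must agree with `sites$ref_base`.
#' @param reference_name identifier of the reference mitogenome.
#' @return object of class `diagnostic_table`.
#' @export
diagnostic_table <- function(sites, fragment_start = 15391L, fragment_end = 15534L,
                             fragment_reference, reference_name = "reference_mt") {
  stopifnot(is.data.frame(sites), all(c("position", "ref_base") %in% names(sites)))
  hg_cols <- grep("^hg_", names(sites), value = TRUE)
  if (length(hg_cols) < 2) stopf("need at least two haplogroup columns (hg_*)")
  frag_len <- fragment_end - fragment_start + 1L
  if (nchar(fragment_reference) != frag_len)
    stopf("fragment_reference must be %d bases", frag_len)
  if (any(sites$position < fragment_start | sites$position > fragment_end))
    stopf("all diagnostic positions must lie inside the fragment")
  off <- sites$position - fragment_start + 1L
  ref_at <- substring(fragment_reference, off, off)
  if (!all(ref_at == sites$ref_base))
    stopf("fragment_reference disagrees with ref_base at a diagnostic site")
  pat <- vapply(hg_cols, function(cl) paste(sites[[cl]], collapse = ""), character(1))
  if (anyDuplicated(pat)) stopf("haplogroup allele patterns must be pairwise distinct")
  structure(list(sites = sites, fragment_start = fragment_start,
                 fragment_end = fragment_end,
                 fragment_reference = toupper(fragment_reference),
                 reference_name = reference_name,
                 haplogroups = sub("^hg_", "", hg_cols)),
            class = "diagnostic_table")
}

#' Load the bundled synthetic diagnostic table
#'
#' A synthetic five-site table (the real supplementary site list is not
#' redistributed): the reference carries the haplogroup-B pattern and each
#' of A, C, D, E differs from it by a single transition at its own site, so
#' patterns are pairwise distinct and single convergent transitions can
#' create the misassignment behaviour the classifier must handle.
#'
#' @param seed seed for the synthetic fragment background sequence.
#' @return a [diagnostic_table()].
#' @export
example_diagnostic_table <- function(seed = 42L) {
  path <- system.file("extdata", "diagnostic_sites_synthetic.tsv", package = "ovipop")
  sites <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character")
  sites$position <- as.integer(sites$position)
  frag <- with_seed(seed, random_dna(144L))
  off <- sites$position - 15391L + 1L
  frag_v <- strsplit(frag, "")[[1L]]
  frag_v[off] <- sites$ref_base
  diagnostic_table(sites, 15391L, 15534L, paste(frag_v, collapse = ""),
                   reference_name = "synthetic_mt_reference")
}

#' Extract the control-region fragment from a mitogenome
#'
#' @param mitogenome full mitogenome sequence (character string).
#' @param table a [diagnostic_table()] giving the interval.
#' @return the fragment (144 bases for the default interval); absent bases
#'   are not tolerated — a too-short sequence is an error.
#' @export
extract_fragment <- function(mitogenome, table) {
  stopifnot(inherits(table, "diagnostic_table"))
  if (nchar(mitogenome) < table$fragment_end)
    stopf("mitogenome (%d bases) does not cover the fragment end (%d)",
          nchar(mitogenome), table$fragment_end)
  toupper(substring(mitogenome, table$fragment_start, table$fragment_end))
}

#' Classify one fragment replicate
#'
#' Reads the diagnostic bases and compares them with each haplogroup's
#' pattern. An exact match wins; otherwise the nearest pattern by Hamming
#' distance over the diagnostic sites is taken when it is unique and at
#' distance 1; ties or distance > 1 give `"unassigned"`. `N` at a
#' diagnostic site mismatches every pattern. Diagnostic sites whose base
#' matches neither the reference nor the called pattern are reported as
#' conflicts.
#'
#' @param sequence fragment-length sequence (aligned, no indels).
#' @param table a [diagnostic_table()].
#' @return list with `label`, `distance`, `conflicts` (positions), and
#'   `diagnostic_bases`.
#' @export
call_haplogroup <- function(sequence, table) {
  stopifnot(inherits(table, "diagnostic_table"))
  frag_len <- table$fragment_end - table$fragment_start + 1L
  sequence <- toupper(sequence)
  if (nchar(sequence) != frag_len)
    stopf("sequence must be %d bases, got %d", frag_len, nchar(sequence))
  off <- table$sites$position - table$fragment_start + 1L
  obs <- substring(sequence, off, off)
  dists <- vapply(table$haplogroups, function(hg) {
    pat <- table$sites[[paste0("hg_", hg)]]
    sum(obs != pat | obs == "N")
  }, numeric(1))
  best <- min(dists)
  winners <- names(dists)[dists == best]
  label <- if (best == 0 && length(winners) == 1) winners
           else if (best == 1 && length(winners) == 1) winners
           else "unassigned"
  conflicts <- integer(0)
  if (label != "unassigned") {
    pat <- table$sites[[paste0("hg_", label)]]
    conflicts <- table$sites$position[obs != pat]
  }
  list(label = label, distance = best, conflicts = conflicts,
       diagnostic_bases = stats::setNames(obs, table$sites$position))
}

#' Replicate consensus haplogroup call
#'
#' The replication workflow: two or more concordant replicate labels give a
#' high-confidence call; two discordant labels require a third round and
#' the majority is taken (no majority or no third replicate leaves the
#' sample unassigned); a single replicate yields its label at low
#' confidence. A mitogenome-based call, when available, overrides the
#' fragment consensus and is flagged.
#'
#' @param replicate_calls character vector of per-replicate labels (from
#'   [call_haplogroup()]), in any order.
#' @param mitogenome_call optional label derived from full mitogenome data.
#' @param sample sample id carried through to the result.
#' @return list of class `haplogroup_call`: `sample`, `label`,
#'   `confidence` (`"high"`/`"low"`), `n_replicates`, `n_support`,
#'   `mitogenome_override`.
#' @export
consensus_call <- function(replicate_calls, mitogenome_call = NULL, sample = NA) {
  n <- length(replicate_calls)
  if (n == 0) stopf("at least one replicate is required")
  tab <- sort(table(replicate_calls), decreasing = TRUE)
  if (n == 1) {
    label <- replicate_calls[1]; confidence <- "low"; support <- 1L
  } else if (max(tab) >= 2 && sum(tab == max(tab)) == 1) {
    label <- names(tab)[1]; confidence <- "high"; support <- as.integer(max(tab))
  } else if (max(tab) >= 2) {
    # two labels tied at >= 2 (e.g. A A B B): no consensus
    label <- "unassigned"; confidence <- "high"; support <- 0L
  } else {
    # all singletons with n >= 2: discordant pair lacking a deciding round
    label <- "unassigned"; confidence <- "high"; support <- 0L
  }
  override <- FALSE
  if (!is.null(mitogenome_call)) {
    override <- TRUE
    label <- mitogenome_call
    confidence <- "high"
    support <- max(support, 1L)
  }
  structure(list(sample = sample, label = label, confidence = confidence,
                 n_replicates = n, n_support = support,
                 mitogenome_override = override),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("Sample %s: haplogroup %s (%s confidence, %d/%d replicates%s)\n",
              x$sample, x$label, x$confidence, x$n_support, x$n_replicates,
              if (x$mitogenome_override) ", mitogenome override" else ""))
  invisible(x)
}

#' Consensus calls for a replicate table
#'
#' @param replicates data.frame as produced by [simulate_mt_replicates()]
#'   (columns `sample`, `sequence`).
#' @param table a [diagnostic_table()].
#' @param mitogenome_calls optional named character vector of overrides.
#' @return data.frame: sample, label, confidence, n_replicates, n_support,
#'   mitogenome_override.
#' @export
call_samples <- function(replicates, table, mitogenome_calls = NULL) {
  out <- lapply(split(replicates, replicates$sample), function(df) {
    labels <- vapply(df$sequence, function(s) call_haplogroup(s, table)$label,
                     character(1), USE.NAMES = FALSE)
    mg <- if (!is.null(mitogenome_calls) && df$sample[1] %in% names(mitogenome_calls))
      mitogenome_calls[[df$sample[1]]] else NULL
    cc <- consensus_call(labels, mg, sample = df$sample[1])
    data.frame(sample = cc$sample, label = cc$label, confidence = cc$confidence,
               n_replicates = cc$n_replicates, n_support = cc$n_support,
               mitogenome_override = cc$mitogenome_override,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate fragment-based haplogroup assignment against mitogenomes
#'
#' Classifies the extracted fragment of each labelled mitogenome and
#' reports the accuracy and the truth-by-call confusion matrix.
#'
#' @param mitogenomes character vector of full mitogenome sequences.
#' @param truth_labels haplogroup label per mitogenome.
#' @param table a [diagnostic_table()].
#' @return list with `accuracy`, `confusion` (truth x call), `n`.
#' @export
validate_fragment_accuracy <- function(mitogenomes, truth_labels, table) {
  if (length(mitogenomes) == 0) stopf("no mitogenomes supplied")
  stopifnot(length(mitogenomes) == length(truth_labels))
  calls <- vapply(mitogenomes, function(m)
    call_haplogroup(extract_fragment(m, table), table)$label,
    character(1), USE.NAMES = FALSE)
  lev <- union(table$haplogroups, "unassigned")
  confusion <- table(factor(truth_labels, levels = lev),
                     factor(calls, levels = lev), dnn = c("truth", "call"))
  list(accuracy = mean(calls == truth_labels), confusion = confusion,
       n = length(calls))
}

#' Haplogroup frequencies with exact binomial confidence intervals
#'
#' Per-group per-haplogroup proportions with Clopper-Pearson 95% CIs,
#' computed on all calls or on the high-confidence set only (excluding
#' single-replicate samples).
#'
#' @param calls data.frame from [call_samples()] (columns `sample`,
#'   `label`, `confidence`).
#' @param grouping named character vector: sample -> group (a single group
#'   is assumed when omitted).
#' @param confidence_set `"all"` or `"high_only"`.
#' @param level confidence level.
#' @return data.frame: group, haplogroup, k, n, freq, lower, upper.
#' @export
haplogroup_frequencies_ci <- function(calls, grouping = NULL,
                                      confidence_set = c("all", "high_only"),
                                      level = 0.95) {
  confidence_set <- match.arg(confidence_set)
  if (confidence_set == "high_only")
    calls <- calls[calls$confidence == "high", , drop = FALSE]
  group <- if (is.null(grouping)) rep("all", nrow(calls))
           else unname(grouping[calls$sample])
  if (NROW(calls) == 0 || anyNA(group)) stopf("every call needs a group; none may be empty")
  hgs <- sort(unique(calls$label))
  out <- do.call(rbind, lapply(unique(group), function(gr) {
    sub <- calls$label[group == gr]
    n <- length(sub)
    if (n == 0) stopf("empty group '%s'", gr)
    do.call(rbind, lapply(hgs, function(h) {
      k <- sum(sub == h)
      ci <- stats::binom.test(k, n, conf.level = level)$conf.int
      data.frame(group = gr, haplogroup = h, k = k, n = n, freq = k / n,
                 lower = ci[1], upper = ci[2], stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Compare haplogroup composition between two groups
#'
#' Fisher's exact test on the haplogroup x group contingency table (2x2 via
#' the hypergeometric distribution, r x 2 via exact enumeration over tables
#' with fixed margins) and Cohen's w effect size `sqrt(chi2 / N)` from the
#' same table.
#'
#' @param labels1,labels2 haplogroup labels of the two groups.
#' @return list of class `frequency_comparison`: `table`, `p`, `w`.
#' @export
compare_frequencies <- function(labels1, labels2) {
  if (length(labels1) == 0 || length(labels2) == 0)
    stopf("both groups must be non-empty")
  lev <- sort(union(labels1, labels2))
  tab <- cbind(group1 = table(factor(labels1, levels = lev)),
               group2 = table(factor(labels2, levels = lev)))
  if (sum(tab) == 0) stopf("all-zero contingency table")
  ft <- stats::fisher.test(tab, workspace = 2e6)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  w <- sqrt(as.numeric(chi$statistic) / sum(tab))
  structure(list(table = tab, p = ft$p.value, w = w),
            class = "frequency_comparison")
}

#' @export
print.frequency_comparison <- function(x, ...) {
  cat(sprintf("Haplogroup frequency comparison: Fisher exact p = %.4g, Cohen's w = %.3f\n",
              x$p, x$w))
  print(x$table)
  invisible(x)
}
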