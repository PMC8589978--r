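# Shared internal helpers: seeded RNG scoping, sequence utilities, validation.

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# All stochastic entry points funnel through this so that identical seeds
# give bit-identical outputs regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

check_prob <- function(x, name) {
  if (!is_prob(x)) stopf("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Random DNA string(s) of the given lengths (uniform base composition).
random_dna <- function(lengths) {
  vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
}

# Panel positions are 1-based; read tables are 0-based half-open
# [start, start + length).  These two helpers are the only place the
# conversion happens.
pos1_to_interval0 <- function(pos) list(start = pos - 1L, end = pos)
interval0_covers_pos1 <- function(start, end, pos) start <= pos - 1L & end >= pos
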