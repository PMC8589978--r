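# File formats: EIGENSTRAT geno/snp/ind, TSV read tables, FASTA, panels,
# diagnostic-site tables. All plain text; round-trips are bit-exact.

#' Write a genotype table as EIGENSTRAT geno/snp/ind
#'
#' `geno`: one line per SNP, one character per individual, alt-allele count
#' with 9 = missing; pseudohaploid calls are expanded to the diploid 0/2
#' convention on output. `snp`: id, chrom, genetic position (0.0), physical
#' position, ref, alt. `ind`: id, sex (U), population.
#'
#' @param x a [genotype_table()].
#' @param prefix path prefix; writes `<prefix>.geno`, `.snp`, `.ind`.
#' @return invisibly, the three file paths.
#' @export
write_eigenstrat <- function(x, prefix) {
  stopifnot(inherits(x, "genotype_table"))
  g <- x$geno
  ph <- x$ind$ploidy == "pseudohaploid"
  if (any(ph)) g[, ph] <- g[, ph, drop = FALSE] * 2L
  g[is.na(g)] <- 9L
  lines <- apply(g, 1L, paste, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  s <- x$panel$sites
  writeLines(sprintf("%s\t%s\t%.1f\t%d\t%s\t%s", s$snp_id, s$chrom, 0,
                     as.integer(s$pos), s$ref_allele, s$alt_allele),
             paste0(prefix, ".snp"))
  writeLines(sprintf("%s\tU\t%s", x$ind$id, x$ind$population),
             paste0(prefix, ".ind"))
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}

#' Read an EIGENSTRAT geno/snp/ind trio
#'
#' @param prefix path prefix as in [write_eigenstrat()].
#' @param ploidy per-individual ploidy modes (recycled); EIGENSTRAT itself
#'   does not record ploidy, so pseudohaploid individuals (stored as 0/2/9)
#'   must be declared to be folded back to the haploid 0/1 scale.
#' @return a [genotype_table()].
#' @export
read_eigenstrat <- function(prefix, ploidy = "diploid") {
  lines <- readLines(paste0(prefix, ".geno"))
  g <- matrix(as.integer(unlist(strsplit(lines, ""), use.names = FALSE)),
              nrow = length(lines), byrow = TRUE)
  g[g == 9L] <- NA_integer_
  s <- utils::read.table(paste0(prefix, ".snp"), sep = "\t",
                         col.names = c("snp_id", "chrom", "gpos", "pos", "ref_allele", "alt_allele"),
                         colClasses = c("character", "character", "numeric",
                                        "integer", "character", "character"))
  ind <- utils::read.table(paste0(prefix, ".ind"), sep = "\t",
                           col.names = c("id", "sex", "population"),
                           colClasses = "character")
  ind$ploidy <- rep_len(ploidy, nrow(ind))
  ph <- ind$ploidy == "pseudohaploid"
  if (any(ph)) {
    sub <- g[, ph, drop = FALSE]
    if (any(sub == 1L, na.rm = TRUE))
      stopf("heterozygous call in an individual declared pseudohaploid")
    g[, ph] <- sub %/% 2L
  }
  genotype_table(g, ind[, c("id", "population", "ploidy")],
                 snp_panel(s[, c("snp_id", "chrom", "pos", "ref_allele", "alt_allele")]))
}

#' Write / read the aligned-read TSV dialect
#'
#' Columns `chrom start length strand sequence endogenous`; `start` is
#' 0-based, reads cover the half-open interval `[start, start + length)`.
#'
#' @param reads a `read_table` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_read_table <- function(reads, path) {
  df <- as.data.frame(reads)
  df$endogenous <- ifelse(df$endogenous, "1", "0")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_table
#' @export
read_read_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(chrom = "character", start = "numeric",
                                         length = "integer", strand = "character",
                                         sequence = "character", endogenous = "integer"))
  df$endogenous <- df$endogenous == 1L
  class(df) <- c("read_table", "data.frame")
  df
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(lapply(seqs, function(s) strsplit(s, "")[[1L]]),
                      names = names(seqs), file.out = path, nbchar = 70)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                          as.string = TRUE)
  stats::setNames(toupper(vapply(x, as.character, character(1))), names(x))
}

#' Write a JSON manifest of simulation truth parameters
#'
#' Records the generating parameters of a simulation so recovery tests can
#' compare estimates against truth without re-deriving them.
#'
#' @param params named list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
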