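# smartpca-style PCA: fit on complete modern diploid data, project
# low-coverage samples by least squares on their observed SNPs.

#' Fit a PCA model on modern genotypes
#'
#' Dosages are centered per SNP by the mean and scaled by
#' `sqrt(p(1-p))` with `p = mean dosage / 2` (the drift-variance
#' normalisation smartpca uses). Missing entries in the fit set are
#' mean-imputed (they are absent from simulated modern data); monomorphic
#' SNPs carry no information and are dropped from the model.
#'
#' @param table [genotype_table()] of diploid modern individuals.
#' @param n_components number of components to retain.
#' @return object of class `pca_model` with per-SNP `center`/`scale`,
#'   `loadings` (SNPs x components, orthonormal), `scores` (individuals x
#'   components), `eigenvalues`, `explained`, `snp_ids`, `ind`.
#' @export
pca_fit <- function(table, n_components = 10L) {
  stopifnot(inherits(table, "genotype_table"))
  if (ncol(table$geno) < 2) stopf("need at least 2 individuals")
  ph <- table$ind$ploidy == "pseudohaploid"
  g <- table$geno
  if (any(ph)) g[, ph] <- g[, ph, drop = FALSE] * 2L  # haploid calls to diploid scale
  X <- t(g)                                # individuals x SNPs
  mu <- colMeans(X, na.rm = TRUE)
  p_hat <- mu / 2
  sc <- sqrt(p_hat * (1 - p_hat))
  poly <- is.finite(sc) & sc > 0
  if (sum(poly) < 2) stopf("need at least 2 polymorphic SNPs")
  X <- X[, poly, drop = FALSE]
  mu <- mu[poly]; sc <- sc[poly]
  X <- sweep(X, 2, mu)
  X[is.na(X)] <- 0                         # mean imputation after centering
  X <- sweep(X, 2, sc, "/")
  k <- min(n_components, nrow(X) - 1L, ncol(X))
  sv <- svd(X, nu = k, nv = k)
  eig <- sv$d^2 / (nrow(X) - 1)
  structure(list(center = mu, scale = sc,
                 loadings = sv$v,
                 scores = sv$u %*% diag(sv$d[seq_len(k)], k),
                 eigenvalues = eig[seq_len(k)],
                 explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
                 snp_ids = table$panel$sites$snp_id[poly],
                 ind = table$ind),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d SNPs, %d individuals, %d components\n",
              length(x$snp_ids), nrow(x$scores), ncol(x$loadings)))
  cat("Explained variance:", paste(sprintf("%.1f%%", 100 * x$explained),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Least-squares projection of a (possibly very incomplete) sample
#'
#' The lsqproject approach: restrict the model's loadings to the SNPs the
#' sample was genotyped at, standardise the observed dosages with the
#' model's centering and scaling, and solve the least-squares problem for
#' the component coordinates. No imputation is performed at projection
#' time.
#'
#' @param model a [pca_model()].
#' @param dosages named numeric vector (or 1-column matrix) of diploid-scale
#'   dosages indexed by snp_id; pseudohaploid calls supplied as 0/2. `NA` =
#'   missing.
#' @return numeric vector of coordinates on the model's components.
#' @export
pca_project <- function(model, dosages) {
  stopifnot(inherits(model, "pca_model"))
  if (is.matrix(dosages)) dosages <- stats::setNames(dosages[, 1L], rownames(dosages))
  idx <- match(model$snp_ids, names(dosages))
  x <- dosages[idx]
  ok <- !is.na(x)
  if (sum(ok) < 2) stopf("sample shares fewer than 2 genotyped SNPs with the model")
  V <- model$loadings[ok, , drop = FALSE]
  xs <- (x[ok] - model$center[ok]) / model$scale[ok]
  fit <- qr.solve(V, xs)
  as.numeric(fit)
}

#' Project every individual of a genotype table
#'
#' @param model a [pca_model()].
#' @param table a [genotype_table()].
#' @return matrix individuals x components.
#' @export
pca_project_table <- function(model, table) {
  ph <- table$ind$ploidy == "pseudohaploid"
  g <- table$geno
  if (any(ph)) g[, ph] <- g[, ph, drop = FALSE] * 2L
  rownames(g) <- table$panel$sites$snp_id
  out <- t(apply(g, 2, function(col) pca_project(model, stats::setNames(col, rownames(g)))))
  rownames(out) <- table$ind$id
  out
}
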