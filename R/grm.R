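# VanRaden genomic relationship matrix and its SVD.

#' Compute the VanRaden genomic relationship matrix
#'
#' G = Z Z' / k, where column i of Z is the dosage of SNP i centered by
#' twice its pooled allele frequency (computed over all genotyped
#' individuals in the cohort) and k = 2 * sum_i p_i (1 - p_i). Missing
#' dosages are mean-imputed to 2 p_i, i.e. zero after centering.
#' Monomorphic SNPs carry no information and are excluded from both Z and
#' k.
#'
#' @param dataset a `genotype_dataset` with >= 2 samples
#' @return object of class `grm`: list with `values` (samples x samples
#'   symmetric matrix), `samples` (the sample table), `k_denominator`,
#'   `n_snps_used`.
#' @export
compute_grm <- function(dataset) {
  validate_genotype_dataset(dataset)
  d <- dataset$dosages
  if (nrow(d) < 2L) stop("GRM needs >= 2 samples")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly))
    stop("all SNPs monomorphic: GRM undefined (k = 0)")
  Z <- sweep(d[, poly, drop = FALSE], 2L, 2 * p[poly])
  Z[is.na(Z)] <- 0  # mean imputation: centered missing dosage is 0
  k <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / k
  dimnames(G) <- list(dataset$samples$sample_id, dataset$samples$sample_id)
  structure(list(values = G, samples = dataset$samples,
                 k_denominator = k, n_snps_used = sum(poly)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("VanRaden GRM:", nrow(x$values), "samples,",
      x$n_snps_used, "SNPs used, k =", format(x$k_denominator), "\n")
  invisible(x)
}

#' SVD of a genomic relationship matrix
#'
#' Because the GRM is symmetric positive semidefinite, its singular values
#' coincide with its eigenvalues and the left singular vectors with the
#' eigenvectors (up to sign). The sign convention fixes the
#' largest-magnitude entry of each component positive. `components` holds
#' the vectors scaled by their singular values (useful as plotting scores);
#' `vectors` the raw orthonormal basis.
#'
#' @param grm a `grm` (or a plain symmetric matrix)
#' @param n_components number of leading components to keep
#' @return object of class `grm_svd`: `components` (scaled scores),
#'   `vectors`, `singular_values` (non-increasing), `variance_explained`
#'   (fractions of the trace), `samples`.
#' @export
svd_grm <- function(grm, n_components = 10) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  if (n_components < 1) stop("n_components must be >= 1")
  n_components <- min(n_components, nrow(G))
  sv <- svd(G)
  d <- sv$d
  U <- sv$u
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  ve <- if (sum(d) > 0) d / sum(d) else rep(0, length(d))
  keep <- seq_len(n_components)
  scores <- U[, keep, drop = FALSE] %*% diag(d[keep], n_components)
  dimnames(scores) <- list(rownames(G), paste0("PC", keep))
  structure(list(components = scores,
                 vectors = U[, keep, drop = FALSE],
                 singular_values = d,
                 variance_explained = ve,
                 samples = if (inherits(grm, "grm")) grm$samples else NULL),
            class = "grm_svd")
}

#' @export
print.grm_svd <- function(x, ...) {
  cat("GRM SVD:", ncol(x$components), "components kept\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 5)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Export SVD component scores as a table
#'
#' @param svd_res a `grm_svd`
#' @return data.frame sample_id, population, PC1..PCk (scaled scores)
#' @export
svd_scores <- function(svd_res) {
  stopifnot(inherits(svd_res, "grm_svd"))
  base <- if (!is.null(svd_res$samples)) svd_res$samples else
    data.frame(sample_id = rownames(svd_res$components))
  cbind(base, as.data.frame(svd_res$components))
}
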