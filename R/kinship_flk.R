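# Population kinship matrix from allele frequencies and the FLK test.
#
# The FLK null models the vector of population allele frequencies at a
# neutral SNP as centred on an ancestral frequency p0 with covariance
# p0 (1 - p0) F, where F is the between-population drift (kinship) matrix
# read off a rooted population tree: F[i,j] is the branch length shared by
# populations i and j on their root-to-leaf paths. F is estimated from
# Reynolds genetic distances via neighbor-joining, rooted on an outgroup
# that is then discarded.

#' Pairwise Reynolds genetic distances between populations
#'
#' Ratio-of-sums Reynolds coancestry distance scaled to be additive in
#' drift: d(i,j) = sum_l (p_il - p_jl)^2 / sum_l (pbar_l - p_il p_jl) with
#' pbar the pair mean (twice the classic Reynolds ratio). Under pure drift
#' this estimates F_ii + F_jj - 2 F_ij, so neighbor-joining on it returns
#' branch lengths directly in drift units. Sample-frequency noise is
#' deliberately NOT bias-corrected: the kinship must describe the
#' covariance of the sample frequencies that the FLK statistic actually
#' sees, which includes binomial sampling on top of drift.
#'
#' @param freqs a `pop_freqs`
#' @return symmetric distance matrix with population dimnames
#' @export
reynolds_dist <- function(freqs) {
  P <- freqs$freqs
  r <- nrow(P)
  D <- matrix(0, r, r, dimnames = list(freqs$populations,
                                       freqs$populations))
  for (i in seq_len(r)) for (j in seq_len(r)) {
    if (j <= i) next
    ok <- !is.na(P[i, ]) & !is.na(P[j, ])
    pbar <- (P[i, ok] + P[j, ok]) / 2
    den <- sum(pbar - P[i, ok] * P[j, ok])
    if (den <= 0) stop("no polymorphic SNPs shared by ",
                       freqs$populations[i], " and ", freqs$populations[j])
    D[i, j] <- D[j, i] <- sum((P[i, ok] - P[j, ok])^2) / den
  }
  D
}

#' Build the FLK population kinship matrix
#'
#' Computes Reynolds distances, fits a neighbor-joining tree, roots it on
#' the outgroup branch, drops the outgroup, and reads F off the rooted
#' ingroup tree: F[i,i] = root-to-leaf branch length, F[i,j] = shared
#' root-to-divergence length. Negative NJ branch lengths are clamped to 0
#' with a warning; if F is not positive definite it is jittered by 1e-8 on
#' the diagonal with a warning.
#'
#' @param freqs a `pop_freqs` with >= 3 populations including the outgroup
#' @param outgroup outgroup population label (used only for rooting,
#'   excluded from F)
#' @return object of class `kinship_f`: list with `populations`, `F`
#'   (covariance matrix), `tree` (rooted ingroup `ape::phylo`)
#' @export
build_kinship <- function(freqs, outgroup) {
  if (!(outgroup %in% freqs$populations))
    stop("outgroup not found: ", outgroup)
  if (length(freqs$populations) < 3L)
    stop("kinship estimation needs >= 3 populations including the outgroup")
  D <- reynolds_dist(freqs)
  tree <- ape::nj(as.dist(D))
  if (any(tree$edge.length < 0)) {
    warning("negative neighbor-joining branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  tree <- ape::drop.tip(tree, outgroup)
  F <- shared_branch_matrix(tree)
  ev <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    warning("kinship matrix not positive definite; jittering diagonal by 1e-8")
    diag(F) <- diag(F) + 1e-8
  }
  structure(list(populations = rownames(F), F = F, tree = tree),
            class = "kinship_f")
}

# F[i,j] = shared root-to-MRCA path length on a rooted tree (additive,
# lengths already in drift units)
shared_branch_matrix <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  path_edges <- function(node) {
    out <- integer(0)
    while (node != root) {
      e <- parent_edge[node]
      out <- c(e, out)
      node <- tree$edge[e, 1L]
    }
    out
  }
  paths <- lapply(seq_len(n_tip), path_edges)
  F <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip)) for (j in i:n_tip) {
    shared <- intersect(paths[[i]], paths[[j]])
    F[i, j] <- F[j, i] <- sum(tree$edge.length[shared])
  }
  F
}

#' @export
print.kinship_f <- function(x, ...) {
  cat("FLK kinship matrix over", length(x$populations), "populations:\n")
  print(round(x$F, 4))
  invisible(x)
}

#' The FLK test of excess population differentiation
#'
#' For each SNP with population frequency vector p (outgroup excluded),
#' the ancestral frequency is estimated by generalized least squares,
#' p0 = (1' F^-1 p) / (1' F^-1 1), and the statistic is the quadratic form
#' FLK = (p - p0 1)' [p0 (1 - p0) F]^-1 (p - p0 1), chi-square with
#' (n_pops - 1) degrees of freedom under neutral drift. SNPs whose p0
#' estimate falls outside (0,1) are undefined (`NA`) and counted in the
#' `n_excluded` attribute.
#'
#' @param freqs a `pop_freqs`; populations must cover `kinship$populations`
#' @param kinship a `kinship_f` (or plain PD matrix with dimnames)
#' @return data.frame with per-SNP columns `flk`, `p_value`, plus `p0`;
#'   attributes `df` and `n_excluded`
#' @export
flk <- function(freqs, kinship) {
  F <- if (inherits(kinship, "kinship_f")) kinship$F else as.matrix(kinship)
  pops <- rownames(F)
  idx <- match(pops, freqs$populations)
  if (anyNA(idx))
    stop("populations missing from freqs: ",
         paste(pops[is.na(idx)], collapse = ", "))
  P <- freqs$freqs[idx, , drop = FALSE]
  r <- length(pops)
  Fi <- solve(F)
  one <- rep(1, r)
  w <- as.vector(Fi %*% one)        # p0 = w'p / (1'F^-1 1)
  denom <- sum(w)
  p0 <- as.vector(crossprod(w, P)) / denom
  Dm <- P - matrix(p0, nrow = r, ncol = ncol(P), byrow = TRUE)
  q <- colSums(Dm * (Fi %*% Dm))
  het <- p0 * (1 - p0)
  stat <- ifelse(het > 0, q / het, NA_real_)
  usable <- !is.na(stat) & p0 > 0 & p0 < 1 &
    colSums(is.na(P)) == 0
  stat[!usable] <- NA_real_
  df <- r - 1L
  pv <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  out <- data.frame(flk = stat, p_value = pv, p0 = p0)
  attr(out, "df") <- df
  attr(out, "n_excluded") <- sum(!usable)
  out
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 on the grid
#' lambda = 0.05, 0.10, ..., 0.95 via pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda)), extrapolated to lambda -> 1 with a cubic smoothing
#' spline (the "smoother" method) or taken at lambda = 0.5 ("fixed"); the
#' estimate is capped at 1. q-values are the step-up minima
#' q(p_(i)) = min_\{t >= p_(i)\} pi0 m t / rank(t), monotone in p.
#'
#' @param p_values numeric vector in (0, 1]
#' @param pi0_method "smoother" (default) or "fixed"
#' @param pi0 optional numeric override of the pi0 estimate
#' @return numeric q-values in the input order; attribute `pi0`
#' @export
qvalues <- function(p_values, pi0_method = c("smoother", "fixed"),
                    pi0 = NULL) {
  pi0_method <- match.arg(pi0_method)
  keep <- !is.na(p_values)
  p <- p_values[keep]
  if (!length(p)) stop("no p-values supplied")
  stopifnot(all(p > 0), all(p <= 1))
  m <- length(p)
  if (is.null(pi0)) pi0 <- estimate_pi0(p, pi0_method)
  o <- order(p)
  ranked <- p[o]
  raw <- pi0 * m * ranked / seq_len(m)
  qv <- rev(cummin(rev(raw)))
  qv <- pmin(qv, 1)
  out <- rep(NA_real_, length(p_values))
  out[keep][o] <- qv
  attr(out, "pi0") <- pi0
  out
}

estimate_pi0 <- function(p, method) {
  m <- length(p)
  if (method == "fixed") {
    pi0 <- sum(p > 0.5) / (m * 0.5)
    return(min(max(pi0, 1 / m), 1))
  }
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)),
                  numeric(1))
  fit <- try(stats::smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
  pi0 <- if (inherits(fit, "try-error")) {
    sum(p > 0.5) / (m * 0.5)  # fallback: fixed lambda = 0.5
  } else {
    stats::predict(fit, x = max(lambda))$y
  }
  min(max(pi0, 1 / m), 1)
}
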