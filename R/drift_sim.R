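# Pure-drift genotype simulator.
#
# Allele frequencies evolve root -> leaf along a population tree whose
# branch lengths are drift coefficients c in (0,1). Along each branch the
# descendant frequency is Balding-Nichols distributed:
#   p | p0 ~ Beta(p0 (1-c)/c, (1-p0)(1-c)/c),
# so E[p] = p0 and Var[p] = c p0 (1-p0); the boundaries 0 and 1 are
# absorbing. Genotypes are Binomial(2, p_leaf) per diploid sample
# (Hardy-Weinberg within populations, no linkage disequilibrium).

#' One Balding-Nichols drift step
#'
#' Draws descendant allele frequencies after drift of strength `c` from
#' ancestral frequencies `p0`: for interior `p0` a
#' Beta(p0(1-c)/c, (1-p0)(1-c)/c) variate with mean `p0` and variance
#' `c p0 (1-p0)`; `p0` of 0 or 1 is returned unchanged (fixation is
#' absorbing under pure drift).
#'
#' @param p0 numeric vector of ancestral frequencies in [0,1]
#' @param c drift coefficient, strictly inside (0,1)
#' @return numeric vector of descendant frequencies, same length as `p0`
#' @export
drift_transition <- function(p0, c) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c >= 1)
    stop("drift coefficient c must lie strictly in (0, 1), got ", c)
  stopifnot(all(p0 >= 0), all(p0 <= 1))
  p <- p0
  interior <- p0 > 0 & p0 < 1
  k <- (1 - c) / c
  p[interior] <- stats::rbeta(sum(interior),
                              p0[interior] * k, (1 - p0[interior]) * k)
  p
}

#' Parse a drift tree from Newick
#'
#' Branch lengths are read as drift coefficients and must lie in (0,1).
#'
#' @param newick Newick string (or an `ape::phylo`, returned as-is after
#'   validation)
#' @return an `ape::phylo` with `edge.length` in (0,1)
#' @export
drift_tree <- function(newick) {
  tree <- if (inherits(newick, "phylo")) newick else ape::read.tree(text = newick)
  if (is.null(tree) || is.null(tree$edge.length))
    stop("could not parse Newick tree with branch lengths: ", newick)
  if (any(tree$edge.length <= 0) || any(tree$edge.length >= 1))
    stop("all branch lengths must be drift coefficients in (0, 1)")
  tree
}

#' The default desk-scale scenario tree
#'
#' Seven leaves mirroring a livestock design: a distant outgroup `D`, a
#' related breed `L`, a historic line `LW_Old` and four modern farm lines
#' `LW_1..LW_4`. Branch lengths are plausible drift coefficients for a few
#' dozen generations of strong breeding.
#'
#' @return an `ape::phylo`
#' @export
study_tree <- function() {
  drift_tree(paste0(
    "(((((LW_1:0.03,LW_2:0.03):0.01,(LW_3:0.03,LW_4:0.03):0.01):0.02,",
    "LW_Old:0.05):0.03,L:0.08):0.05,D:0.25);"
  ))
}

# label for every node: leaves keep tip labels; internal nodes use
# node.label if present, else "node<k>"
node_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  inner <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", seq_len(n_node) + n_tip)
  c(tree$tip.label, inner)
}

#' Cumulative drift (kinship) matrix implied by a drift tree
#'
#' The exact between-population covariance structure of the simulator:
#' `F[i, j] = 1 - prod(1 - c_b)` over branches `b` shared by the root-to-leaf
#' paths of populations i and j (so the diagonal is each population's total
#' drift from the root). Used as the "true kinship" in FLK calibration.
#'
#' @param tree an `ape::phylo` with drift-coefficient branch lengths
#' @param drop optional leaf labels to exclude (e.g. the outgroup)
#' @return symmetric matrix with leaf labels as dimnames
#' @export
kinship_from_tree <- function(tree, drop = NULL) {
  tree <- drift_tree(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  # path of edge indices root -> node
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
    F[i, j] <- F[j, i] <- 1 - prod(1 - tree$edge.length[shared])
  }
  if (!is.null(drop)) {
    keep <- setdiff(rownames(F), drop)
    F <- F[keep, keep, drop = FALSE]
  }
  F
}

#' Specify loci under selection for the simulator
#'
#' Selection is modelled as excess differentiation on one branch: either an
#' inflated drift coefficient `c_sel` (mechanism "drift", the default) or a
#' deterministic push of the allele2 frequency toward fixation by fraction
#' `shift` of the remaining distance (mechanism "shift").
#'
#' @param branch label of the child node of the branch under selection (a
#'   leaf label, or an internal node label / "node<k>")
#' @param n_loci number of selected loci (ignored if `loci` given)
#' @param c_sel inflated drift coefficient for mechanism "drift"
#' @param mechanism "drift" or "shift"
#' @param shift push fraction for mechanism "shift"
#' @param loci explicit SNP indices; if `NULL`, `n_loci` indices are chosen
#'   as `clustered` runs of consecutive SNPs (sweep-like) or uniformly.
#' @param cluster_size run length when placing clustered loci
#' @param clustered place loci in consecutive runs (default) to mimic the
#'   footprint of a selective sweep in SNP-dense data
#' @return a `selection_spec` list
#' @export
selection_spec <- function(branch, n_loci = 50, c_sel = 0.5,
                           mechanism = c("drift", "shift"), shift = 0.8,
                           loci = NULL, cluster_size = 10, clustered = TRUE) {
  structure(list(branch = branch, n_loci = n_loci, c_sel = c_sel,
                 mechanism = match.arg(mechanism), shift = shift,
                 loci = loci, cluster_size = cluster_size,
                 clustered = clustered),
            class = "selection_spec")
}

choose_selected_loci <- function(spec, n_snps) {
  if (!is.null(spec$loci)) {
    loci <- as.integer(spec$loci)
    if (any(loci < 1L) || any(loci > n_snps))
      stop("selected loci indices out of range 1..", n_snps)
    return(loci)
  }
  n <- spec$n_loci
  if (n > n_snps) stop("more selected loci than SNPs")
  if (!spec$clustered) return(sort(sample.int(n_snps, n)))
  cs <- min(spec$cluster_size, n)
  n_runs <- ceiling(n / cs)
  starts <- sort(sample.int(max(n_snps - cs + 1L, 1L), n_runs))
  loci <- unique(unlist(lapply(starts, function(s) s:(s + cs - 1L))))
  sort(loci[seq_len(min(n, length(loci)))])
}

#' Simulate a genotype dataset under pure drift
#'
#' Ancestral allele frequencies are drawn iid from `ancestral_freq_dist`
#' (default Uniform(0.05, 0.95)), propagated root-to-leaf with
#' [drift_transition()] per branch, optionally perturbed at selected loci
#' (see [selection_spec()]), and genotypes are sampled Binomial(2, p_leaf).
#' SNPs are laid out on `n_chrom` chromosomes at `spacing_bp` intervals
#' (25 kb by default, a typical medium-density array spacing).
#'
#' @param tree drift tree: `ape::phylo` or Newick string; branch lengths are
#'   drift coefficients in (0,1)
#' @param n_snps number of SNPs
#' @param samples_per_pop diploid samples per leaf: scalar, or named vector
#'   over leaf labels
#' @param selected optional [selection_spec()] or list of them
#' @param ancestral_freq_dist function(n) returning n ancestral frequencies
#' @param seed integer seed; fixed seed gives bit-identical output
#' @param n_chrom,spacing_bp SNP map layout
#' @return list with `dataset` (a [genotype_dataset()]) and `truth`
#'   (class `sim_truth`: `ancestral`, `leaf_freqs` pops x SNPs,
#'   `selected` data.frame(snp_index, branch, mechanism, c_sel), `seed`,
#'   `tree`)
#' @export
simulate_dataset <- function(tree, n_snps = 5000, samples_per_pop = 30,
                             selected = NULL,
                             ancestral_freq_dist = function(n)
                               stats::runif(n, 0.05, 0.95),
                             seed = NULL, n_chrom = 18,
                             spacing_bp = 25000) {
  stopifnot(n_snps >= 1)
  tree <- drift_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  labels <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L

  if (inherits(selected, "selection_spec")) selected <- list(selected)
  sel_by_branch <- list()
  sel_rows <- list()
  for (sp in selected) {
    child <- match(sp$branch, labels)
    if (is.na(child))
      stop("selection branch not in tree: ", sp$branch)
    loci <- choose_selected_loci(sp, n_snps)
    key <- as.character(child)
    sel_by_branch[[key]] <- c(sel_by_branch[[key]],
                              list(list(spec = sp, loci = loci)))
    sel_rows[[length(sel_rows) + 1L]] <-
      data.frame(snp_index = loci, branch = sp$branch,
                 mechanism = sp$mechanism,
                 c_sel = if (sp$mechanism == "drift") sp$c_sel else NA_real_,
                 stringsAsFactors = FALSE)
  }

  ancestral <- ancestral_freq_dist(n_snps)
  stopifnot(all(ancestral >= 0), all(ancestral <= 1))

  # preorder propagation of frequency vectors down the tree
  node_freq <- vector("list", max(tree$edge))
  node_freq[[root]] <- ancestral
  tree <- stats::reorder(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    c_bg <- tree$edge.length[e]
    p <- drift_transition(node_freq[[parent]], c_bg)
    for (sel in sel_by_branch[[as.character(child)]]) {
      loci <- sel$loci
      sp <- sel$spec
      p0 <- node_freq[[parent]][loci]
      if (sp$mechanism == "drift") {
        p[loci] <- drift_transition(p0, sp$c_sel)
      } else {
        p[loci] <- pmin(1, p0 + sp$shift * (1 - p0))
      }
    }
    node_freq[[child]] <- p
  }
  leaf_freqs <- do.call(rbind, node_freq[seq_len(n_tip)])
  rownames(leaf_freqs) <- tree$tip.label

  if (length(samples_per_pop) == 1L)
    samples_per_pop <- stats::setNames(rep(samples_per_pop, n_tip),
                                       tree$tip.label)
  if (!all(tree$tip.label %in% names(samples_per_pop)))
    stop("samples_per_pop must name every leaf")

  chrom <- rep(seq_len(n_chrom), length.out = n_snps)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(n_snps), chrom),
                       function(ix) seq_along(ix) * spacing_bp),
                use.names = FALSE)
  snps <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(n_snps)),
    chrom = as.character(chrom), pos_bp = as.integer(pos),
    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)

  dos_blocks <- vector("list", n_tip)
  sample_ids <- character(0)
  pops <- character(0)
  for (i in seq_len(n_tip)) {
    lab <- tree$tip.label[i]
    ns <- samples_per_pop[[lab]]
    g <- matrix(stats::rbinom(ns * n_snps, 2L,
                              rep(leaf_freqs[i, ], each = ns)),
                nrow = ns)
    dos_blocks[[i]] <- g
    sample_ids <- c(sample_ids, sprintf("%s_%03d", lab, seq_len(ns)))
    pops <- c(pops, rep(lab, ns))
  }
  dataset <- genotype_dataset(
    do.call(rbind, dos_blocks), snps,
    data.frame(sample_id = sample_ids, population = pops,
               stringsAsFactors = FALSE))

  sel_df <- if (length(sel_rows)) do.call(rbind, sel_rows) else
    data.frame(snp_index = integer(0), branch = character(0),
               mechanism = character(0), c_sel = numeric(0))
  truth <- structure(list(ancestral = ancestral, leaf_freqs = leaf_freqs,
                          selected = sel_df, seed = seed, tree = tree,
                          snps = snps),
                     class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' Write simulator ground truth as a TSV
#'
#' One row per SNP: id, ancestral frequency, realized frequency per leaf
#' population, selected flag and branch.
#'
#' @param truth a `sim_truth`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  lf <- t(truth$leaf_freqs)
  colnames(lf) <- paste0("freq_", rownames(truth$leaf_freqs))
  sel <- rep(FALSE, length(truth$ancestral))
  br <- rep(NA_character_, length(truth$ancestral))
  sel[truth$selected$snp_index] <- TRUE
  br[truth$selected$snp_index] <- truth$selected$branch
  out <- data.frame(snp_id = truth$snps$snp_id,
                    ancestral_freq = truth$ancestral, lf,
                    selected = sel, branch = br,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
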