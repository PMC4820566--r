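#' Read an ensemble of Newick trees
#'
#' Reads one or more rooted, branch-length-bearing trees from a Newick file
#' (one tree per line or concatenated). Tip labels are normalized with
#' [normalize_species()] so they join to dataset species names.
#'
#' @param path Newick file.
#' @param max_trees optional cap on the number of trees read.
#' @return a `phylo_ensemble`: list of `ape::phylo` trees plus the common
#'   tip-label set.
#' @export
read_tree_ensemble <- function(path, max_trees = NULL) {
  if (!file.exists(path))
    bm_stop(paste0("file not found: ", path), "bm_io_error")
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) bm_stop(paste0("Newick parse error: ",
                                                       conditionMessage(e)),
                                                "bm_parse_error"))
  if (is.null(trees))
    bm_stop("Newick parse error: no trees found", "bm_parse_error")
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!is.null(max_trees)) trees <- trees[seq_len(min(max_trees, length(trees)))]
  as_phylo_ensemble(trees)
}

#' Build a tree ensemble from a list of `phylo` objects
#'
#' @param trees list of `ape::phylo` trees (or a `multiPhylo`).
#' @return a `phylo_ensemble`.
#' @export
as_phylo_ensemble <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (is.null(tr$edge.length))
      bm_stop(paste0("tree ", i, " has no branch lengths"), "bm_parse_error")
    tr$tip.label <- normalize_species(tr$tip.label)
    tr
  })
  tip_sets <- lapply(trees, function(tr) sort(tr$tip.label))
  if (length(unique(tip_sets)) > 1)
    warning("tip label sets differ across trees; prune before analysis")
  structure(list(trees = trees, tip_labels = tip_sets[[1]]),
            class = "phylo_ensemble")
}

#' @export
print.phylo_ensemble <- function(x, ...) {
  cat(sprintf("Phylogenetic ensemble: %d tree(s), %d tips\n",
              length(x$trees), length(x$tip_labels)))
  invisible(x)
}

#' Prune every tree in an ensemble to a species set
#'
#' Restricts each tree to `species` (names normalized first), collapsing
#' internal degree-2 nodes with branch lengths summed. Species missing from
#' any tree raise an error naming them; nothing is dropped silently.
#'
#' @param ensemble a `phylo_ensemble`.
#' @param species character vector of species to keep.
#' @return pruned `phylo_ensemble`.
#' @export
prune_ensemble <- function(ensemble, species) {
  stopifnot(inherits(ensemble, "phylo_ensemble"))
  species <- unique(normalize_species(species))
  missing <- setdiff(species, ensemble$tip_labels)
  if (length(missing))
    bm_stop(paste0("species missing from tree(s): ",
                   paste(missing, collapse = ", ")), "bm_species_mismatch")
  trees <- lapply(ensemble$trees, function(tr) {
    pruned <- ape::keep.tip(tr, species)
    # keep.tip reroots at the subset MRCA; restore the shared stem below it
    # as a root edge so Brownian depths from the original root are preserved
    tip <- species[1]
    d_old <- ape::node.depth.edgelength(tr)[match(tip, tr$tip.label)]
    d_new <- ape::node.depth.edgelength(pruned)[match(tip, pruned$tip.label)]
    lost <- d_old - d_new
    if (lost > 1e-12)
      pruned$root.edge <- (pruned$root.edge %||% 0) + lost
    pruned
  })
  as_phylo_ensemble(trees)
}

#' Brownian-motion phylogenetic correlation matrix
#'
#' Under Brownian motion the expected covariance of a trait between two tips
#' is the shared root-to-MRCA path length, and its variance is the tip's
#' root-to-tip depth. The correlation C_ij = V_ij / sqrt(V_ii V_jj) is
#' returned; for a non-ultrametric tree the per-pair normalization keeps the
#' diagonal exactly 1 without rescaling the input tree. The result is
#' invariant to multiplying all branch lengths by a constant, which is why
#' the model is parameterized on correlations rather than covariances.
#'
#' @param tree a rooted `ape::phylo` tree with positive root-to-tip depths.
#' @return a `phylo_correlation`: list with `species_order` and matrix `C`
#'   (symmetric, unit diagonal, positive semidefinite).
#' @export
bm_correlation <- function(tree) {
  if (inherits(tree, "phylo_ensemble")) {
    if (length(tree$trees) != 1)
      bm_stop("bm_correlation takes one tree; iterate over the ensemble",
              "bm_domain_error")
    tree <- tree$trees[[1]]
  }
  stopifnot(inherits(tree, "phylo"))
  V <- ape::vcv.phylo(tree)  # shared root-to-MRCA path lengths
  rownames(V) <- colnames(V) <- normalize_species(rownames(V))
  if (!is.null(tree$root.edge) && tree$root.edge > 0)
    V <- V + tree$root.edge   # shared stem retained by prune_ensemble
  depths <- diag(V)
  if (any(depths <= 0))
    bm_stop("degenerate tree: zero root-to-tip depth", "bm_degenerate_tree")
  s <- 1 / sqrt(depths)
  C <- V * tcrossprod(s)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(list(species_order = rownames(V), C = C),
            class = "phylo_correlation")
}

#' @export
print.phylo_correlation <- function(x, ...) {
  cat(sprintf("Brownian-motion correlation matrix over %d species\n",
              length(x$species_order)))
  invisible(x)
}

#' Correlation matrices for a whole ensemble, aligned to one species order
#'
#' @param ensemble a pruned `phylo_ensemble`.
#' @return list of `phylo_correlation` objects, all with the same
#'   `species_order` (that of the first tree).
#' @export
ensemble_correlations <- function(ensemble) {
  stopifnot(inherits(ensemble, "phylo_ensemble"))
  first <- bm_correlation(ensemble$trees[[1]])
  ord <- first$species_order
  lapply(ensemble$trees, function(tr) {
    pc <- bm_correlation(tr)
    idx <- match(ord, pc$species_order)
    structure(list(species_order = ord, C = pc$C[idx, idx, drop = FALSE]),
              class = "phylo_correlation")
  })
}
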