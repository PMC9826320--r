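# Phylogenetic correlation structure for the meta-analytic models. Trees are
# ape "phylo" objects; the correlation matrix is the proportion of
# root-to-tip depth shared by each species pair under Grafen branch lengths.

#' Read a rooted Newick tree
#'
#' Thin wrapper over [ape::read.tree()] accepting a file path or a Newick
#' string, with duplicate-tip validation (the meta-analytic correlation
#' matrix needs unique species labels).
#'
#' @param text Newick string, or `file` a path.
#' @param file Optional path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' Assign Grafen branch lengths
#'
#' Each internal node is given height (number of descendant tips - 1),
#' raised to `rho` and scaled so the root has height 1 and every tip height
#' 0; branch lengths are parent height minus child height, yielding an
#' ultrametric tree without dated branch lengths. Polytomies are handled
#' natively (heights depend only on descendant tip counts).
#'
#' @param tree A rooted `phylo` object with at least 2 tips.
#' @param rho Power applied to relative node heights (default 1).
#' @return The tree with branch lengths set.
#' @export
grafen_lengths <- function(tree, rho = 1) {
  # note: a basal polytomy (e.g. a star tree) is fine; node heights depend
  # only on descendant tip counts
  if (ape::Ntip(tree) < 2) stop("tree must have at least 2 tips")
  ape::compute.brlen(tree, method = "Grafen", power = rho)
}

#' Species correlation matrix from an ultrametric tree
#'
#' `A[i, j]` is the root-to-MRCA(i, j) path length divided by total tree
#' depth (so `A[i, i] = 1`); the shared-ancestry correlation used for the
#' phylogenetic random effect.
#'
#' @param tree An ultrametric `phylo` object with branch lengths (see
#'   [grafen_lengths()]).
#' @param tol Relative tolerance for the ultrametricity check.
#' @return Symmetric positive semi-definite matrix with unit diagonal,
#'   species labels as dimnames.
#' @export
phylo_correlation <- function(tree, tol = 1e-8) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.ultrametric(tree, tol = tol))
    stop("tree is not ultrametric; correlations are ill-defined")
  A <- ape::vcv(tree, corr = TRUE)
  A[A < 0 & A > -1e-12] <- 0
  A
}

#' Write a species correlation matrix as CSV
#'
#' Species order is kept in both the header and a leading `species` column.
#'
#' @param A Correlation matrix with species dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylo_correlation <- function(A, path) {
  df <- data.frame(species = rownames(A), A, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
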