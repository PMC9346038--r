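#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (used as the fallback when no user tree is
#' supplied, and for ortholog-group clustering). Negative branch-length
#' estimates are clamped to 0.
#'
#' @param distances Symmetric numeric matrix with zero diagonal.
#' @param labels Optional taxon labels (defaults to the matrix dimnames).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distances, labels = NULL) {
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances) ||
      max(abs(distances - t(distances))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(distances)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (nrow(distances) < 3L) stop("need at least 3 taxa for neighbor joining")
  if (!is.null(labels)) dimnames(distances) <- list(labels, labels)
  if (is.null(rownames(distances)))
    stop("labels required (none found on the distance matrix)")
  tree <- ape::nj(distances)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Fallback distances for NJ from a codon alignment: per-pair proportion of
# differing nucleotide sites over shared non-gap positions.
.alignment_p_distances <- function(alignment) {
  seqs <- alignment$sequences
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(chars) <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- chars[i, ] != "-" & chars[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok)) mean(chars[i, ok] != chars[j, ok]) else 0
  }
  d
}

# Validate a phylo tree against an alignment and precompute the postorder
# edge structure consumed by the C++ pruning kernels.
.prep_tree <- function(tree, alignment) {
  stopifnot(inherits(tree, "phylo"), inherits(alignment, "CodonAlignment"))
  taxa <- rownames(alignment$states)
  if (!setequal(tree$tip.label, taxa))
    stop("tree tip labels must exactly cover the alignment taxa")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- alignment$states[tr$tip.label, , drop = FALSE]
  states[is.na(states)] <- 0L
  list(tree = tr, edge = tr$edge, elen = tr$edge.length,
       ntip = length(tr$tip.label), nnode = tr$Nnode,
       states = states)
}

#' Log-likelihood of a single alignment column under the codon model
#'
#' Felsenstein pruning with missing data marginalized; the root is weighted
#' by the equilibrium codon frequencies.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param column Named vector over taxa: codon strings (e.g. `"ATG"`), sense
#'   codon state indices, or `NA` for missing.
#' @param Q A `RateMatrix` from [mg94_rate_matrix()].
#' @return Log-likelihood (finite and <= 0 whenever a state is observed).
#' @export
site_log_likelihood <- function(tree, column, Q) {
  stopifnot(inherits(Q, "RateMatrix"))
  code <- .code()
  if (is.character(column)) {
    st <- unname(code$codon_index[toupper(column)])
    names(st) <- names(column)
    column <- st
  }
  if (is.null(names(column))) stop("column must be named by taxon")
  if (!setequal(names(column), tree$tip.label))
    stop("column taxa do not match tree tips: ",
         paste(setdiff(tree$tip.label, names(column)), collapse = ","))
  tr <- ape::reorder.phylo(tree, "postorder")
  st <- column[tr$tip.label]
  st[is.na(st)] <- 0L
  dec <- .codon_decomp(Q$Q, Q$freqs)
  cpp_lik_site(dec$values, dec$L, dec$R, Q$freqs, tr$edge, tr$edge.length,
               length(tr$tip.label), tr$Nnode, as.integer(st), 1.0)
}

#' Per-column log-likelihoods of an alignment under the codon model
#'
#' @param alignment A `CodonAlignment`.
#' @param tree A `phylo` tree with branch lengths covering the alignment taxa.
#' @param Q A `RateMatrix`.
#' @return Numeric vector of per-column log-likelihoods.
#' @export
alignment_log_likelihood <- function(alignment, tree, Q) {
  stopifnot(inherits(Q, "RateMatrix"))
  pp <- .prep_tree(tree, alignment)
  dec <- .codon_decomp(Q$Q, Q$freqs)
  cpp_lik_all(dec$values, dec$L, dec$R, Q$freqs, pp$edge, pp$elen,
              pp$ntip, pp$nnode, pp$states, 1.0)
}
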