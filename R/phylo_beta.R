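# Phylogenetic beta diversity: neighbor-joining tree over OTU representatives
# (distance = 1 - alignment identity, midpoint-rooted), weighted and
# unweighted UniFrac by branch traversal, principal coordinates analysis, and
# a UPGMA sample dendrogram.

#' Pairwise alignment distance matrix
#'
#' `1 - identity` for every sequence pair, using the package aligner. The
#' span-normalized identity (`identity_global`: matches over
#' `max(aligned columns, min(sequence lengths))`) is used so that a short
#' perfect local match between unrelated sequences does not yield distance 0.
#'
#' @param seqs named character vector of sequences (names become labels).
#' @param ... alignment parameters for [align_pair()].
#' @return symmetric distance matrix.
#' @export
alignment_dist <- function(seqs, ...) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- align_pair(seqs[[i]], seqs[[j]], ...)
      d[i, j] <- d[j, i] <- 1 - a[["identity_global"]]
    }
  }
  d
}

#' Build a phylogenetic tree over OTU representatives
#'
#' Neighbor-joining on `1 - identity` distances, negative branch lengths
#' clamped to zero, midpoint-rooted. Input order is normalized by label so
#' the tree is a deterministic function of the sequence set.
#'
#' @param seqs named character vector (names = OTU ids, must be unique).
#' @param ... alignment parameters.
#' @return a rooted `phylo` tree with the OTU ids as tips.
#' @export
build_tree <- function(seqs, ...) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  seqs <- seqs[order(names(seqs))]
  d <- alignment_dist(seqs, ...)
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  tr
}

# per-edge descendant proportions: matrix (n_edges x n_samples) where entry
# [e, s] is the fraction of sample s's reads descending from edge e's child
.edge_proportions <- function(tree, props) {
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  node_p <- matrix(0, nnode, ncol(props))
  node_p[seq_len(ntip), ] <- props[tree$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    node_p[parent, ] <- node_p[parent, ] + node_p[child, ]
  }
  list(tree = tree, edge_p = node_p[tree$edge[, 2], , drop = FALSE])
}

.as_props <- function(counts, tree) {
  m <- unclass(counts)
  missing <- setdiff(rownames(m), tree$tip.label)
  if (length(missing))
    stop("leaves missing from tree: ", paste(head(missing, 5), collapse = ", "))
  extra <- setdiff(tree$tip.label, rownames(m))
  if (length(extra)) {
    m <- rbind(m, matrix(0, length(extra), ncol(m),
                         dimnames = list(extra, colnames(m))))
  }
  sweep(m, 2, colSums(m), "/")[tree$tip.label, , drop = FALSE]
}

#' UniFrac distance matrix
#'
#' Weighted UniFrac: `sum_b l_b * |pA_b - pB_b|` where `p_b` is the fraction
#' of a sample's reads descending from branch `b`; the normalized variant
#' divides by `sum_leaves d_root(leaf) * (pA_leaf + pB_leaf)` and lies in
#' \[0, 1\]. Unweighted UniFrac: unique branch length over total branch length
#' spanned by either presence set,
#' `sum_b l_b |IA - IB| / sum_b l_b max(IA, IB)`.
#'
#' @param tree rooted `phylo` whose tips cover the rows of `counts`.
#' @param counts OTU x sample count (or proportion) matrix.
#' @param weighted weighted (TRUE, default) or unweighted variant.
#' @param normalized normalize the weighted variant to \[0, 1\] (default TRUE;
#'   ignored for unweighted).
#' @return symmetric sample x sample distance matrix.
#' @export
unifrac <- function(tree, counts, weighted = TRUE, normalized = TRUE) {
  props <- .as_props(counts, tree)
  ep <- .edge_proportions(tree, props)
  tr <- ep$tree
  lb <- tr$edge.length
  edge_p <- ep$edge_p
  ns <- ncol(props)
  d <- matrix(0, ns, ns, dimnames = list(colnames(props), colnames(props)))
  if (weighted && normalized) {
    depth <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    names(depth) <- tr$tip.label
    depth <- depth[rownames(props)]
  }
  for (a in seq_len(ns - 1)) {
    for (b in (a + 1):ns) {
      if (weighted) {
        raw <- sum(lb * abs(edge_p[, a] - edge_p[, b]))
        if (normalized) {
          dd <- sum(depth * (props[, a] + props[, b]))
          raw <- if (dd > 0) raw / dd else 0
        }
      } else {
        ia <- edge_p[, a] > 0
        ib <- edge_p[, b] > 0
        denom <- sum(lb * (ia | ib))
        raw <- if (denom > 0) sum(lb * xor(ia, ib)) / denom else 0
      }
      d[a, b] <- d[b, a] <- raw
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering `B = -1/2 * J D^2 J` followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square root
#' of their (positive) eigenvalues. Negative eigenvalues are reported but
#' excluded from the variance fractions.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param axes number of axes to return (default 3).
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `variance_explained` (per returned
#'   axis, fractions of the positive-eigenvalue total).
#' @export
pcoa <- function(d, axes = 3) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  naxes <- min(axes, sum(pos))
  coords <- matrix(0, n, naxes)
  if (naxes > 0)
    coords <- e$vectors[, seq_len(naxes), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(naxes)]), naxes)
  dimnames(coords) <- list(rownames(d),
                           if (naxes > 0) paste0("PC", seq_len(naxes)))
  tot <- sum(e$values[pos])
  ve <- if (tot > 0 && naxes > 0) e$values[seq_len(naxes)] / tot else numeric(0)
  structure(list(coordinates = coords, eigenvalues = e$values,
                 variance_explained = ve),
            class = "pcoa_result")
}

#' UPGMA dendrogram of samples
#'
#' Average-linkage agglomerative clustering of a distance matrix, returned as
#' a `phylo` tree (serializable to Newick with [ape::write.tree()]). Merge
#' heights are non-decreasing; ultrametric inputs are reproduced exactly by
#' the cophenetic distances.
#'
#' @param d symmetric distance matrix.
#' @return a `phylo` tree of the samples.
#' @export
upgma_dendrogram <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  hc <- hclust(as.dist(d), method = "average")
  ape::as.phylo(hc)
}
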