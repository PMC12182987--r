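#' Augment connectivity with indirect pathways via effective conductance
#'
#' Treats each subject's connectivity matrix as a resistor network in which
#' every direct connection is an electrical conductance. The augmented
#' connectivity between regions i and j is the pairwise effective
#' conductance `1 / R_eff(i, j)`, computed from the Moore-Penrose
#' pseudoinverse of the graph Laplacian as
#' `R_eff(i, j) = L+_ii + L+_jj - 2 L+_ij`. This aggregates all parallel
#' (multi-synaptic) pathways: two regions joined only through intermediate
#' regions acquire a positive augmented connection, and a directly connected
#' pair can only gain from additional indirect routes. Region pairs in
#' different connected components get 0.
#'
#' @param original a `connectivity_table` of direct (unaugmented)
#'   connectivity.
#' @return A `connectivity_table` of augmented connectivity, same shape.
#' @examples
#' # a 3-region chain: the two end regions acquire the series conductance
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 2; m[2, 3] <- m[3, 2] <- 3
#' tab <- connectivity_table(matrix(vectorize_connectivity(m), 1),
#'                           "s1", n_regions = 3)
#' augment_conductance(tab)$values   # (1,3) entry = 2*3/(2+3)
#' @export
augment_conductance <- function(original) {
  stopifnot(inherits(original, "connectivity_table"))
  out <- original$values
  for (k in seq_len(nrow(out))) {
    m <- devectorize_connectivity(original$values[k, ], original$n_regions)
    out[k, ] <- vectorize_connectivity(effective_conductance(m))
  }
  with_values(original, out)
}

#' Pairwise effective conductance of a weighted graph
#'
#' @param conductance symmetric non-negative matrix of edge conductances
#'   (zero diagonal); entry `(i, j)` is the conductance of the direct edge.
#' @return Symmetric matrix of effective conductances; 0 for pairs with no
#'   connecting path and on the diagonal.
#' @export
effective_conductance <- function(conductance) {
  conductance <- as.matrix(conductance)
  n <- nrow(conductance)
  diag(conductance) <- 0
  out <- matrix(0, n, n)
  g <- igraph::graph_from_adjacency_matrix(conductance > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) < 2L) next
    sub <- conductance[idx, idx, drop = FALSE]
    lap <- diag(rowSums(sub)) - sub
    lp <- MASS::ginv(lap)
    d <- diag(lp)
    reff <- outer(d, d, `+`) - 2 * lp
    diag(reff) <- 1                       # placeholder, overwritten below
    out[idx, idx] <- 1 / reff
  }
  diag(out) <- 0
  out[out < 0] <- 0
  (out + t(out)) / 2
}
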