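#' Build the node feature matrix for the embedding model
#'
#' Default structural features are the node degree and a one-hot encoding
#' of the entity type, z-score normalised column-wise (constant columns map
#' to zero). For transductive link prediction on attribute-poor graphs an
#' identity block (one column per node) can be appended; through the first
#' weight matrix this acts as a trainable free embedding per node, the
#' standard remedy when structural features alone cannot distinguish
#' otherwise exchangeable nodes.
#'
#' @param kg a `kg_graph`.
#' @param identity append a one-hot identity block? (default `FALSE` here;
#'   the trainer enables it via its config for transductive runs).
#' @return a numeric matrix, one row per node (rownames = node ids).
#' @export
node_feature_matrix <- function(kg, identity = FALSE) {
  stopifnot(inherits(kg, "kg_graph"))
  ids <- kg$nodes$id
  n <- length(ids)
  pairs <- kg_pairs(kg)
  deg <- tabulate(match(c(pairs$u, pairs$v), ids), nbins = n)
  types <- sort(unique(kg$nodes$type))
  onehot <- matrix(0, n, length(types),
                   dimnames = list(NULL, paste0("type_", types)))
  onehot[cbind(seq_len(n), match(kg$nodes$type, types))] <- 1
  X <- cbind(degree = deg, onehot)
  X <- apply(X, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  X <- matrix(X, nrow = n, dimnames = list(ids, colnames(X)))
  if (identity) {
    eye <- diag(n)
    colnames(eye) <- paste0("id_", seq_len(n))
    X <- cbind(X, eye)
  }
  X
}

#' Adjacency-spectral positional features
#'
#' Leading eigenvectors of the (symmetric) adjacency matrix built from the
#' supplied edges, z-scored column-wise. Spectral coordinates are the
#' classical positional feature for graphs without informative node
#' attributes: community/block structure concentrates in the leading
#' non-trivial eigenvectors. The trainer computes these from the
#' *training* edges only, so held-out links never leak into the features.
#'
#' @param ids node ids (row order of the result).
#' @param edges tibble of edges (`u`, `v`).
#' @param k number of leading eigenvectors (capped at the node count).
#' @return an n x k numeric matrix (rownames = ids).
#' @export
spectral_features <- function(ids, edges, k = 16) {
  n <- length(ids)
  k <- min(k, n)
  A <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    ui <- match(edges$u, ids)
    vi <- match(edges$v, ids)
    A[cbind(ui, vi)] <- 1
    A[cbind(vi, ui)] <- 1
  }
  ev <- eigen(A, symmetric = TRUE)
  S <- ev$vectors[, seq_len(k), drop = FALSE]
  S <- apply(S, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  S <- matrix(S, nrow = n,
              dimnames = list(ids, paste0("spec_", seq_len(k))))
  S
}

# Row-normalised adjacency operator (mean aggregation) from an edge list.
# Nodes without neighbours get an all-zero row: their aggregated neighbour
# feature is the zero vector.
mean_aggregator <- function(ids, edges) {
  n <- length(ids)
  if (nrow(edges) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  ui <- match(edges$u, ids)
  vi <- match(edges$v, ids)
  A <- Matrix::sparseMatrix(i = c(ui, vi), j = c(vi, ui),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  scale <- ifelse(deg > 0, 1 / deg, 0)
  Matrix::Diagonal(x = scale) %*% A
}
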