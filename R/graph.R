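#' p-nearest-neighbor weight matrix
#'
#' For each item `i`, let `N_p(i)` be the `p` items (excluding `i` itself)
#' with the largest similarity to `i`, ties broken by smaller index. The
#' weight between `i` and `j` is 1 when each is in the other's neighbor set,
#' 0 when neither is, and 0.5 when exactly one is. The diagonal is 0, so the
#' sparsified graph carries no self-loops.
#'
#' @param S A [similarity_matrix] or a plain symmetric matrix.
#' @param p Neighbor count, `1 <= p <= dim - 1`.
#' @return A symmetric matrix with entries in `{0, 0.5, 1}` and zero diagonal.
#' @export
pnn_weights <- function(S, p) {
  S <- similarity_values(S)
  d <- nrow(S)
  if (p < 1 || p > d - 1) {
    abort("p must satisfy 1 <= p <= dim - 1", class = "grmfc_domain_error")
  }
  # in_set[i, j] = TRUE iff j is among the p most similar items to i
  in_set <- matrix(FALSE, d, d)
  for (i in seq_len(d)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(s, decreasing = TRUE)[seq_len(p)]  # stable: ties by index
    in_set[i, nb] <- TRUE
  }
  N <- (in_set + t(in_set)) / 2
  diag(N) <- 0
  N
}

#' Sparsify a similarity matrix by neighbor weights
#'
#' Elementwise product of the similarity matrix and a p-nearest-neighbor
#' weight matrix, yielding the weighted adjacency of the neighbor graph.
#'
#' @param S A [similarity_matrix] or plain matrix.
#' @param N Weight matrix from [pnn_weights] (same dimension).
#' @return The sparsified similarity matrix (zero diagonal, symmetric).
#' @export
sparsify_similarity <- function(S, N) {
  S <- similarity_values(S)
  if (!all(dim(S) == dim(N))) {
    abort("similarity and weight matrices must have the same shape",
          class = "grmfc_domain_error")
  }
  N * S
}

#' Degree matrix, combinatorial and normalized graph Laplacian
#'
#' From a non-negative symmetric weighted adjacency `S_hat`, computes the
#' degree matrix `D` (`D_ii = sum_r S_hat_ir`), the combinatorial Laplacian
#' `L = D - S_hat`, and the normalized Laplacian
#' `L_norm = D^{-1/2} L D^{-1/2}`. Zero-degree vertices use the pseudo-inverse
#' convention: their `D^{-1/2}` entry is 0, so their row and column of
#' `L_norm` vanish.
#'
#' @param S_hat Symmetric non-negative matrix (typically from
#'   [sparsify_similarity]).
#' @return A list with `D` (diagonal degree matrix), `L`, and `L_norm`.
#' @export
normalized_laplacian <- function(S_hat) {
  if (any(S_hat < 0)) {
    abort("adjacency entries must be non-negative",
          class = "grmfc_domain_error")
  }
  deg <- rowSums(S_hat)
  L <- diag(deg, nrow(S_hat)) - S_hat
  d_is <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L_norm <- d_is * L * rep(d_is, each = nrow(L))  # D^{-1/2} L D^{-1/2}
  L_norm <- (L_norm + t(L_norm)) / 2
  list(D = diag(deg, nrow(S_hat)), L = L, L_norm = L_norm)
}

#' Build all graph operators for one side of the problem
#'
#' Convenience wrapper chaining [pnn_weights], [sparsify_similarity] and
#' [normalized_laplacian].
#'
#' @param S A [similarity_matrix] or plain matrix.
#' @param p Neighbor count (default 5, the conventional choice for
#'   graph-regularized factorization on these benchmarks).
#' @return A list of class `graph_operators` with `N`, `S_hat`, `D`, `L`,
#'   `L_norm`, and `p`.
#' @export
graph_operators <- function(S, p = 5) {
  S <- similarity_values(S)
  p <- min(p, nrow(S) - 1L)
  N <- pnn_weights(S, p)
  S_hat <- sparsify_similarity(S, N)
  lap <- normalized_laplacian(S_hat)
  structure(c(list(N = N, S_hat = S_hat, p = p), lap),
            class = "graph_operators")
}

# accept either the S4-ish wrapper or a bare matrix
similarity_values <- function(S) {
  if (inherits(S, "similarity_matrix")) S$S else as.matrix(S)
}
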