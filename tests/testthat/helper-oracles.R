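# Independent brute-force oracles. These deliberately use explicit loops and
# naive formulations so they share no code path with the package internals.

# neighbor-set enumeration: the p most similar items to i, excluding i,
# ties broken by smaller index
oracle_neighbor_set <- function(S, i, p) {
  others <- setdiff(seq_len(nrow(S)), i)
  # sort by (-similarity, index): stable lexicographic tie-break
  ord <- others[order(-S[i, others], others)]
  ord[seq_len(p)]
}

oracle_pnn <- function(S, p) {
  d <- nrow(S)
  N <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      if (i == j) next
      i_in_j <- i %in% oracle_neighbor_set(S, j, p)
      j_in_i <- j %in% oracle_neighbor_set(S, i, p)
      N[i, j] <- if (i_in_j && j_in_i) 1 else if (!i_in_j && !j_in_i) 0 else 0.5
    }
  }
  N
}

# scalar-loop evaluation of the regularized objective
oracle_objective <- function(X, Y, M, L_d, L_t, lambda_d, lambda_t) {
  n <- nrow(X); m <- nrow(Y); k <- ncol(X)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    pred <- 0
    for (l in seq_len(k)) pred <- pred + X[i, l] * Y[j, l]
    acc <- acc + 0.5 * (M[i, j] - pred)^2
  }
  tr_quad <- function(L, A) {
    s <- 0
    for (l in seq_len(ncol(A))) {
      for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
        s <- s + A[i, l] * L[i, j] * A[j, l]
      }
    }
    s
  }
  acc + lambda_d * tr_quad(L_d, X) + lambda_t * tr_quad(L_t, Y)
}

oracle_auglag <- function(X, Y, M, U, V, Lambda, Pi, L_d, L_t,
                          lambda_d, lambda_t, alpha, beta) {
  acc <- oracle_objective(X, Y, M, L_d, L_t, lambda_d, lambda_t)
  for (i in seq_len(nrow(X))) for (l in seq_len(ncol(X))) {
    d <- X[i, l] - U[i, l]
    acc <- acc + Lambda[i, l] * d + alpha / 2 * d^2
  }
  for (l in seq_len(nrow(V))) for (j in seq_len(ncol(V))) {
    d <- Y[j, l] - V[l, j]
    acc <- acc + Pi[l, j] * d + beta / 2 * d^2
  }
  acc
}

# pairwise-comparison AUC with half credit for ties
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (sp in pos) for (sn in neg) {
    wins <- wins + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# step-method AUPR: iterate over distinct thresholds from high to low
oracle_aupr <- function(labels, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (th in thresholds) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# random symmetric similarity matrix with unit diagonal
rand_similarity <- function(d) {
  S <- matrix(runif(d * d), d, d)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

rand_laplacian <- function(d, p = 2) {
  S <- rand_similarity(d)
  normalized_laplacian(sparsify_similarity(S, pnn_weights(S, p)))$L_norm
}

# small random solver state with consistent shapes
rand_state <- function(n, m, k) {
  list(
    X = matrix(rnorm(n * k), n, k),
    Y = matrix(rnorm(m * k), m, k),
    M = matrix(rnorm(n * m), n, m),
    U = matrix(abs(rnorm(n * k)), n, k),
    V = matrix(abs(rnorm(m * k)), k, m),
    Lambda = matrix(rnorm(n * k), n, k),
    Pi = matrix(rnorm(m * k), k, m),
    L_d = rand_laplacian(n),
    L_t = rand_laplacian(m)
  )
}
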