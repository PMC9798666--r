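#' Projection onto an index set of known interactions
#'
#' Returns a copy of `A` in which every entry whose position is *not* in
#' `omega` is set to zero. `omega` is the set of known-interaction positions;
#' this projection expresses the consistency constraint that predictions must
#' agree with the known interactions.
#'
#' @param A Numeric matrix.
#' @param omega Two-column integer matrix of `(i, j)` positions, or a logical
#'   matrix of the same shape as `A`.
#' @return Matrix of the same shape as `A`.
#' @export
project_omega <- function(A, omega) {
  out <- matrix(0, nrow(A), ncol(A))
  if (is.logical(omega)) {
    if (!all(dim(omega) == dim(A))) {
      abort("mask shape must match the matrix", class = "grmfc_domain_error")
    }
    out[omega] <- A[omega]
  } else if (NROW(omega) > 0) {
    omega <- as.matrix(omega)
    if (max(omega[, 1]) > nrow(A) || max(omega[, 2]) > ncol(A)) {
      abort("omega indexes outside the matrix", class = "grmfc_domain_error")
    }
    out[omega] <- A[omega]
  }
  out
}

#' Projection onto the non-negative orthant
#'
#' Elementwise `max(A, 0)`.
#'
#' @param A Numeric matrix or vector.
#' @return Same shape, negatives replaced by zero.
#' @export
project_nonneg <- function(A) {
  pmax(A, 0)
}

#' Regularized factorization objective
#'
#' `0.5 * ||M - X Y^T||_F^2 + lambda_d * Tr(X^T L_d X) +
#' lambda_t * Tr(Y^T L_t Y)`: reconstruction error of the working prediction
#' matrix plus Laplacian smoothness penalties on the drug and target latent
#' factors.
#'
#' @param X,Y Latent factor matrices (`n x k`, `m x k`).
#' @param M Working prediction matrix (`n x m`).
#' @param L_d,L_t Normalized Laplacians (or `NULL` when the corresponding
#'   weight is 0).
#' @param lambda_d,lambda_t Non-negative regularization weights.
#' @return A scalar.
#' @export
grmfc_objective <- function(X, Y, M, L_d = NULL, L_t = NULL,
                            lambda_d = 0, lambda_t = 0) {
  val <- 0.5 * sum((M - X %*% t(Y))^2)
  if (lambda_d > 0) val <- val + lambda_d * sum(X * (L_d %*% X))
  if (lambda_t > 0) val <- val + lambda_t * sum(Y * (L_t %*% Y))
  val
}

#' Augmented Lagrangian of the split formulation
#'
#' The objective of the split problem (auxiliary non-negative copies
#' `U = X`, `V = Y^T`) augmented with multiplier terms and quadratic
#' penalties:
#' `objective + Lambda . (X - U) + Pi . (Y^T - V) +
#'  (alpha/2) ||X - U||_F^2 + (beta/2) ||Y^T - V||_F^2`,
#' where `.` is the elementwise (Frobenius) inner product.
#'
#' @inheritParams grmfc_objective
#' @param U `n x k` non-negative copy of `X`.
#' @param V `k x m` non-negative copy of `t(Y)`.
#' @param Lambda,Pi Multiplier matrices (`n x k`, `k x m`).
#' @param alpha,beta Positive penalty parameters.
#' @return A scalar.
#' @export
grmfc_augmented_lagrangian <- function(X, Y, M, U, V, Lambda, Pi,
                                       L_d = NULL, L_t = NULL,
                                       lambda_d = 0, lambda_t = 0,
                                       alpha = 0.5, beta = 0.01) {
  grmfc_objective(X, Y, M, L_d, L_t, lambda_d, lambda_t) +
    sum(Lambda * (X - U)) + sum(Pi * (t(Y) - V)) +
    alpha / 2 * sum((X - U)^2) + beta / 2 * sum((t(Y) - V)^2)
}

# solve A %*% t(X) = t(B) for X with A symmetric positive definite (Cholesky);
# returns B %*% A^{-1} without forming the inverse
solve_spd_right <- function(A, B) {
  R <- chol(A)
  t(backsolve(R, forwardsolve(t(R), t(B))))
}

# One closed-form block update per matrix, each a single SPD solve. The
# Laplacian term is handled semi-implicitly: writing L = I - W on non-isolated
# vertices, the identity part joins the left-hand side's diagonal shift and
# only the smoothing part -lambda*(L - I)*X_prev is lagged at the previous
# iterate. The fixed points are identical to the fully lagged rule, but the
# lagged-term feedback gain drops from lambda*rho(L)/alpha (which exceeds 1 —
# and diverges — for small penalty parameters) to lambda/(alpha + lambda) < 1.
update_X <- function(M, Y, X_prev, U, Lambda, L_d, lambda_d, alpha) {
  RHS <- M %*% Y + alpha * U - Lambda
  shift <- alpha
  if (lambda_d > 0) {
    RHS <- RHS - lambda_d * (L_d %*% X_prev - X_prev)
    shift <- alpha + lambda_d
  }
  k <- ncol(Y)
  solve_spd_right(crossprod(Y) + diag(shift, k), RHS)
}

update_Y <- function(M, X_new, Y_prev, V, Pi, L_t, lambda_t, beta) {
  RHS <- crossprod(M, X_new) + beta * t(V) - t(Pi)
  shift <- beta
  if (lambda_t > 0) {
    RHS <- RHS - lambda_t * (L_t %*% Y_prev - Y_prev)
    shift <- beta + lambda_t
  }
  k <- ncol(X_new)
  solve_spd_right(crossprod(X_new) + diag(shift, k), RHS)
}

update_M <- function(X_new, Y_new, Z, omega_mask) {
  M <- X_new %*% t(Y_new)
  M[omega_mask] <- Z[omega_mask]  # exact consistency with known interactions
  M
}

update_U <- function(X_new, Lambda, alpha) {
  project_nonneg(X_new + Lambda / alpha)
}

update_V <- function(Y_new, Pi, beta) {
  project_nonneg(t(Y_new) + Pi / beta)
}

#' Solver configuration
#'
#' Collects and validates the hyperparameters of the alternating-direction
#' solver. Defaults follow the reference experimental settings:
#' `alpha = 0.5`, `beta = 0.01`, step length `gamma = 1.618`, stopping
#' tolerance `epsilon = 1e-6`, rank `k = 50` (clamped to `min(n, m)` at fit
#' time), neighbor count `p = 5`.
#'
#' @param k Latent rank (`>= 1`; clamped to `min(n, m)` with a warning).
#' @param lambda_d,lambda_t Graph regularization weights (`>= 0`).
#' @param alpha,beta Positive penalty parameters of the augmented Lagrangian.
#' @param gamma Multiplier step length in `(0, (1 + sqrt(5)) / 2]`.
#' @param epsilon Relative-change stopping tolerance (`> 0`).
#' @param max_iter Iteration cap.
#' @param p Neighbor count for graph sparsification.
#' @param seed Integer seed for the random initialization.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(k = 50, lambda_d = 0.01, lambda_t = 0.01,
                          alpha = 0.5, beta = 0.01, gamma = 1.618,
                          epsilon = 1e-6, max_iter = 500, p = 5, seed = 1) {
  if (k < 1) abort("k must be at least 1", class = "grmfc_domain_error")
  if (alpha <= 0 || beta <= 0) {
    abort("alpha and beta must be positive", class = "grmfc_domain_error")
  }
  if (gamma <= 0 || gamma > (1 + sqrt(5)) / 2 + 1e-12) {
    abort("gamma must lie in (0, (1 + sqrt(5)) / 2]",
          class = "grmfc_domain_error")
  }
  if (epsilon <= 0) abort("epsilon must be positive",
                          class = "grmfc_domain_error")
  if (lambda_d < 0 || lambda_t < 0) {
    abort("regularization weights must be non-negative",
          class = "grmfc_domain_error")
  }
  structure(list(k = k, lambda_d = lambda_d, lambda_t = lambda_t,
                 alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon, max_iter = max_iter, p = p, seed = seed),
            class = "solver_config")
}

#' Fit the constrained graph-regularized factorization
#'
#' Factorizes the interaction matrix as `Z ~ X Y^T` with non-negative factor
#' copies, Laplacian smoothness penalties built from the drug and target
#' similarity graphs, and a hard consistency constraint pinning every known
#' interaction: the working prediction matrix `M` equals 1 on the known
#' interaction set at every iterate, exactly. The split problem is solved by
#' an alternating-direction method on the augmented Lagrangian: per sweep,
#' closed-form updates of `X`, `Y` (one SPD linear solve each; the smoothing
#' part of the Laplacian term is lagged at the previous iterate, its identity
#' part handled implicitly), the constrained update of `M`,
#' non-negative projections for `U`, `V`, then gradient-ascent multiplier
#' steps with step length `gamma`. Iteration stops when the relative
#' Frobenius change of `M` falls below `epsilon` or after `max_iter` sweeps.
#'
#' Initialization: `X`, `Y` entries are Uniform(0, c) with
#' `c = sqrt(mean(Z) / k)` (scale-matched to the data), `U = X`, `V = t(Y)`,
#' multipliers zero, `M = Z`.
#'
#' @param data An [interaction_data] object (or a plain 0/1 matrix).
#' @param drug_sim,target_sim [similarity_matrix] objects (or plain matrices)
#'   matching the rows / columns of `data`. May be `NULL` when the
#'   corresponding `lambda` is 0.
#' @param config A [solver_config]; individual fields can be overridden via
#'   `...`.
#' @param ... Named overrides for `config` fields, e.g. `k = 10`.
#' @return An object of class `grmfc_fit` with elements `M` (prediction
#'   scores, known interactions pinned at 1), `U`, `V` (the reported
#'   non-negative factors), `X`, `Y`, `Lambda`, `Pi`, `trace` (a tibble of
#'   per-iteration objective, relative change and primal residuals),
#'   `converged`, `iterations`, `config`, and the identifier lists.
#' @examples
#' sim <- simulate_dti(n = 20, m = 15, k_true = 3, seed = 7)
#' fit <- grmfc_fit(sim$data, sim$drug_sim, sim$target_sim, k = 4,
#'                  max_iter = 200)
#' glance(fit)
#' @export
grmfc_fit <- function(data, drug_sim = NULL, target_sim = NULL,
                      config = solver_config(), ...) {
  if (!inherits(data, "interaction_data")) data <- interaction_data(data)
  dots <- list(...)
  if (length(dots)) config <- do.call(solver_config, modifyList(
    config[setdiff(names(config), "")], dots))
  Z <- data$Z
  n <- nrow(Z); m <- ncol(Z)
  k <- config$k
  if (k > min(n, m)) {
    warn(sprintf("k = %d exceeds min(n, m) = %d; clamping", k, min(n, m)))
    k <- min(n, m)
  }
  check_sim_dim <- function(S, len, axis) {
    if (!is.null(S)) {
      S <- similarity_values(S)
      if (nrow(S) != len) {
        abort(sprintf("%s similarity dimension (%d) does not match Z (%d)",
                      axis, nrow(S), len),
              class = "grmfc_validation_error")
      }
      S
    } else NULL
  }
  Sd <- check_sim_dim(drug_sim, n, "drug")
  St <- check_sim_dim(target_sim, m, "target")
  L_d <- if (config$lambda_d > 0) {
    if (is.null(Sd)) abort("lambda_d > 0 requires a drug similarity matrix",
                           class = "grmfc_validation_error")
    graph_operators(Sd, config$p)$L_norm
  }
  L_t <- if (config$lambda_t > 0) {
    if (is.null(St)) abort("lambda_t > 0 requires a target similarity matrix",
                           class = "grmfc_validation_error")
    graph_operators(St, config$p)$L_norm
  }

  omega_mask <- Z == 1
  c0 <- sqrt(max(mean(Z), 1e-4) / k)
  init <- withr::with_seed(config$seed, list(
    X = matrix(runif(n * k, 0, c0), n, k),
    Y = matrix(runif(m * k, 0, c0), m, k)
  ))
  X <- init$X; Y <- init$Y
  U <- X; V <- t(Y)
  Lambda <- matrix(0, n, k); Pi <- matrix(0, k, m)
  M <- Z

  lam_d <- config$lambda_d; lam_t <- config$lambda_t
  alpha <- config$alpha; beta <- config$beta; gam <- config$gamma
  trace <- vector("list", config$max_iter)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    X <- update_X(M, Y, X, U, Lambda, L_d, lam_d, alpha)
    Y <- update_Y(M, X, Y, V, Pi, L_t, lam_t, beta)
    M_new <- update_M(X, Y, Z, omega_mask)
    U <- update_U(X, Lambda, alpha)
    V <- update_V(Y, Pi, beta)
    Lambda <- Lambda + gam * alpha * (X - U)
    Pi <- Pi + gam * beta * (t(Y) - V)
    if (!all(is.finite(M_new)) || !all(is.finite(X)) || !all(is.finite(Y))) {
      abort(sprintf("non-finite values in solver state at iteration %d", it),
            class = "grmfc_numerical_error")
    }
    rel <- norm(M_new - M, "F") / max(norm(M, "F"), 1)
    M <- M_new
    trace[[it]] <- c(
      objective = grmfc_objective(X, Y, M, L_d, L_t, lam_d, lam_t),
      rel_change = rel,
      resid_x = sqrt(sum((X - U)^2)),
      resid_v = sqrt(sum((t(Y) - V)^2))
    )
    if (rel < config$epsilon) {
      converged <- TRUE
      break
    }
  }
  trace <- dplyr::bind_rows(lapply(trace[seq_len(it)], as.list))
  trace <- tibble::add_column(trace, iteration = seq_len(it), .before = 1)
  if (!converged) {
    warn(sprintf("solver did not converge within %d iterations (last relative change %.3g)",
                 config$max_iter, trace$rel_change[it]))
  }
  config$k <- k
  structure(
    list(M = M, X = X, Y = Y, U = U, V = V, Lambda = Lambda, Pi = Pi,
         trace = trace, converged = converged, iterations = it,
         config = config, drug_ids = data$drug_ids,
         target_ids = data$target_ids, omega = data$omega),
    class = "grmfc_fit"
  )
}

#' @export
print.grmfc_fit <- function(x, ...) {
  cat(sprintf(
    "<grmfc_fit> %d drugs x %d targets, k = %d; %d iterations, %s\n",
    nrow(x$M), ncol(x$M), x$config$k, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  final objective %.4g, primal residuals %.3g / %.3g\n",
              x$trace$objective[x$iterations],
              x$trace$resid_x[x$iterations],
              x$trace$resid_v[x$iterations]))
  invisible(x)
}

#' Tidy prediction scores from a fitted factorization
#'
#' Returns one row per drug-target pair with its prediction score (the entry
#' of `M`). By default known interactions are dropped so the table ranks
#' candidate novel interactions, sorted by descending score. Scores are
#' relative ranks, not probabilities; entries outside the known set may be
#' negative.
#'
#' @param x A `grmfc_fit`.
#' @param include_known Keep the pinned known-interaction pairs (default
#'   `FALSE`).
#' @param ... Unused.
#' @return A tibble with columns `drug_id`, `target_id`, `score`, `known`.
#' @method tidy grmfc_fit
#' @export
tidy.grmfc_fit <- function(x, include_known = FALSE, ...) {
  known <- matrix(FALSE, nrow(x$M), ncol(x$M))
  if (NROW(x$omega)) known[x$omega] <- TRUE
  out <- tibble(
    drug_id = rep(x$drug_ids, times = length(x$target_ids)),
    target_id = rep(x$target_ids, each = length(x$drug_ids)),
    score = as.vector(x$M),
    known = as.vector(known)
  )
  if (!include_known) out <- dplyr::filter(out, !.data$known)
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' One-row summary of a fitted factorization
#'
#' @param x A `grmfc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: rank, iterations, convergence flag, final
#'   objective, last relative change, and final primal residuals.
#' @method glance grmfc_fit
#' @export
glance.grmfc_fit <- function(x, ...) {
  last <- x$trace[x$iterations, ]
  tibble(
    k = x$config$k,
    iterations = x$iterations,
    converged = x$converged,
    objective = last$objective,
    rel_change = last$rel_change,
    resid_x = last$resid_x,
    resid_v = last$resid_v
  )
}

#' Convergence diagnostics plot
#'
#' Plots the per-iteration relative change of the prediction matrix and the
#' primal residuals of the two split constraints on a log scale.
#'
#' @param object A `grmfc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grmfc_fit
#' @export
autoplot.grmfc_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trace,
    c("rel_change", "resid_x", "resid_v"),
    names_to = "quantity", values_to = "value"
  )
  long <- dplyr::filter(long, .data$value > 0)
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = NULL, colour = NULL,
                  title = "Alternating-direction solver diagnostics") +
    ggplot2::theme_minimal()
}

#' @export
predict.grmfc_fit <- function(object, ...) {
  tidy.grmfc_fit(object, ...)
}
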