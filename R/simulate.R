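#' Simulate an interaction dataset with planted low-rank structure
#'
#' Generates the triple the factorization model assumes: a binary interaction
#' matrix obtained by thresholding a planted non-negative low-rank score
#' matrix, plus drug and target similarity matrices correlated with the
#' planted latent factors. Latent factors `A` (`n x k_true`) and `B`
#' (`m x k_true`) are drawn i.i.d. Exponential(1), giving a skewed,
#' non-negative score distribution whose top `density` fraction becomes the
#' known interactions. Similarities are the cosine similarity of latent factor
#' rows, perturbed by Gaussian noise of scale `noise_sd`, re-symmetrized,
#' clipped to `[0, 1]`, with unit diagonal — so the similarity graphs carry
#' real (but imperfect) information about the planted structure, as assumed by
#' graph regularization.
#'
#' The function is a pure function of its arguments: the same `seed` yields
#' bit-identical output, and the caller's RNG state is untouched.
#'
#' @param n,m Numbers of drugs and targets. Defaults (60, 40) give a problem
#'   of the same order as the smallest public benchmark.
#' @param k_true Planted latent rank (default 4).
#' @param density Fraction of drug-target pairs set to 1 (default 0.08,
#'   matching the denser end of the public benchmarks).
#' @param noise_sd Standard deviation of the similarity perturbation
#'   (default 0.1).
#' @param seed Integer seed.
#' @return A list of class `dti_sim`: `data` ([interaction_data]),
#'   `drug_sim`, `target_sim` ([similarity_matrix]), `truth`
#'   (the planted `n x m` score matrix `A %*% t(B)`), and the planted
#'   factors `drug_factors` (`A`) and `target_factors` (`B`).
#' @examples
#' sim <- simulate_dti(n = 20, m = 15, k_true = 3, density = 0.1, seed = 1)
#' nrow(sim$data$omega)  # round(0.1 * 300) = 30
#' @export
simulate_dti <- function(n = 60, m = 40, k_true = 4, density = 0.08,
                         noise_sd = 0.1, seed = 1) {
  if (k_true > min(n, m)) {
    abort("k_true must not exceed min(n, m)", class = "grmfc_domain_error")
  }
  if (density <= 0 || density >= 1) {
    abort("density must lie strictly between 0 and 1",
          class = "grmfc_domain_error")
  }
  n_pos <- round(density * n * m)
  if (n_pos < 1 || n_pos >= n * m) {
    abort("density infeasible for this matrix size",
          class = "grmfc_domain_error")
  }
  withr::with_seed(seed, {
    A <- matrix(rexp(n * k_true), n, k_true)
    B <- matrix(rexp(m * k_true), m, k_true)
    truth <- A %*% t(B)
    Z <- matrix(0, n, m)
    Z[order(truth, decreasing = TRUE)[seq_len(n_pos)]] <- 1
    drug_ids <- sprintf("D%03d", seq_len(n))
    target_ids <- sprintf("T%03d", seq_len(m))
    dimnames(Z) <- list(drug_ids, target_ids)
    dimnames(truth) <- dimnames(Z)
    Sd <- noisy_cosine(A, noise_sd)
    St <- noisy_cosine(B, noise_sd)
    structure(
      list(
        data = interaction_data(Z),
        drug_sim = similarity_matrix(Sd, drug_ids),
        target_sim = similarity_matrix(St, target_ids),
        truth = truth,
        drug_factors = A,
        target_factors = B
      ),
      class = "dti_sim"
    )
  })
}

# cosine similarity of the rows of A, plus N(0, noise_sd) perturbation,
# re-symmetrized, clipped to [0,1], diagonal forced to 1
noisy_cosine <- function(A, noise_sd) {
  nrm <- sqrt(rowSums(A^2))
  nrm[nrm == 0] <- 1
  S <- (A / nrm) %*% t(A / nrm)
  if (noise_sd > 0) {
    E <- matrix(stats::rnorm(length(S), sd = noise_sd), nrow(S), ncol(S))
    S <- S + (E + t(E)) / 2
  }
  S <- pmin(pmax(S, 0), 1)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' @export
print.dti_sim <- function(x, ...) {
  cat(sprintf("<dti_sim> %d drugs x %d targets, %d planted interactions\n",
              nrow(x$data$Z), ncol(x$data$Z), nrow(x$data$omega)))
  invisible(x)
}
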