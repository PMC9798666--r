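test_that("projection onto the known-interaction set zeroes the complement", {
  A <- matrix(c(3, 5, 4, 6), 2, 2)
  all_pairs <- which(matrix(TRUE, 2, 2), arr.ind = TRUE)
  expect_equal(project_omega(A, all_pairs), A)
  expect_equal(project_omega(A, matrix(integer(0), 0, 2)), matrix(0, 2, 2))
  omega <- rbind(c(1, 1), c(2, 2))
  expect_equal(project_omega(A, omega), matrix(c(3, 0, 0, 6), 2, 2))
  expect_error(project_omega(A, matrix(TRUE, 3, 3)),
               class = "grmfc_domain_error")
})

test_that("non-negative projection clips elementwise", {
  expect_equal(project_nonneg(matrix(-1, 2, 3)), matrix(0, 2, 3))
  A <- matrix(runif(6), 2, 3)
  expect_equal(project_nonneg(A), A)
  expect_equal(project_nonneg(matrix(c(-1, 2), 1, 2)), matrix(c(0, 2), 1, 2))
})

test_that("objective and augmented Lagrangian match scalar-loop oracles", {
  set.seed(21)
  for (rep in 1:10) {
    st <- rand_state(5, 4, 2)
    ld <- runif(1, 0, 0.5); lt <- runif(1, 0, 0.5)
    al <- runif(1, 0.1, 2); be <- runif(1, 0.1, 2)
    expect_equal(
      grmfc_objective(st$X, st$Y, st$M, st$L_d, st$L_t, ld, lt),
      oracle_objective(st$X, st$Y, st$M, st$L_d, st$L_t, ld, lt),
      tolerance = 1e-12)
    expect_equal(
      grmfc_augmented_lagrangian(st$X, st$Y, st$M, st$U, st$V, st$Lambda,
                                 st$Pi, st$L_d, st$L_t, ld, lt, al, be),
      oracle_auglag(st$X, st$Y, st$M, st$U, st$V, st$Lambda, st$Pi,
                    st$L_d, st$L_t, ld, lt, al, be),
      tolerance = 1e-12)
  }
})

test_that("the augmented Lagrangian reduces to the objective at feasible points", {
  st <- rand_state(6, 5, 3)
  expect_equal(
    grmfc_augmented_lagrangian(st$X, st$Y, st$M, U = st$X, V = t(st$Y),
                               Lambda = st$Lambda, Pi = st$Pi,
                               st$L_d, st$L_t, 0.1, 0.2, 0.5, 0.01),
    grmfc_objective(st$X, st$Y, st$M, st$L_d, st$L_t, 0.1, 0.2))
  expect_equal(
    grmfc_augmented_lagrangian(st$X, st$Y, st$M, st$U, st$V,
                               Lambda = 0 * st$Lambda, Pi = 0 * st$Pi,
                               st$L_d, st$L_t, 0.1, 0.2,
                               alpha = 1e-300, beta = 1e-300),
    grmfc_objective(st$X, st$Y, st$M, st$L_d, st$L_t, 0.1, 0.2))
})

test_that("the unregularized X update satisfies its normal equations", {
  set.seed(22)
  st <- rand_state(6, 4, 3)
  alpha <- 0.7
  X_next <- grmfc:::update_X(st$M, st$Y, st$X, st$U, st$Lambda,
                             NULL, 0, alpha)
  resid <- X_next %*% (crossprod(st$Y) + diag(alpha, 3)) -
    (st$M %*% st$Y + alpha * st$U - st$Lambda)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("the X update minimizes its block objective (numeric optimizer check)", {
  set.seed(23)
  n <- 4; m <- 3; k <- 2
  M <- matrix(rnorm(n * m), n, m)
  Y <- matrix(rnorm(m * k), m, k)
  U <- matrix(abs(rnorm(n * k)), n, k)
  alpha <- 0.5
  X_next <- grmfc:::update_X(M, Y, matrix(0, n, k), U,
                             matrix(0, n, k), NULL, 0, alpha)
  fn <- function(x) {
    X <- matrix(x, n, k)
    0.5 * sum((M - X %*% t(Y))^2) + alpha / 2 * sum((X - U)^2)
  }
  opt <- optim(rnorm(n * k), fn, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(fn(as.vector(X_next)), opt$value, tolerance = 1e-8)
  expect_lte(fn(as.vector(X_next)), opt$value + 1e-10)
})

test_that("the Y update mirrors the X update with transposed roles", {
  set.seed(24)
  st <- rand_state(5, 6, 2)
  beta <- 0.3
  Y_next <- grmfc:::update_Y(st$M, st$X, st$Y, st$V, st$Pi, NULL, 0, beta)
  resid <- Y_next %*% (crossprod(st$X) + diag(beta, 2)) -
    (crossprod(st$M, st$X) + beta * t(st$V) - t(st$Pi))
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("the M update pins known interactions and copies the factorization elsewhere", {
  set.seed(25)
  Z <- matrix(as.double(rbinom(20, 1, 0.3)), 4, 5)
  X <- matrix(rnorm(8), 4, 2); Y <- matrix(rnorm(10), 5, 2)
  M <- grmfc:::update_M(X, Y, Z, Z == 1)
  expect_identical(M[Z == 1], Z[Z == 1])
  expect_identical(M[Z == 0], (X %*% t(Y))[Z == 0])
  # empty and full index sets
  expect_equal(grmfc:::update_M(X, Y, Z, matrix(FALSE, 4, 5)), X %*% t(Y))
  expect_equal(grmfc:::update_M(X, Y, Z, matrix(TRUE, 4, 5)), Z)
})

test_that("auxiliary and multiplier updates follow their closed forms", {
  set.seed(26)
  st <- rand_state(4, 3, 2)
  alpha <- 0.5; beta <- 0.01; gam <- 1.618
  U_next <- grmfc:::update_U(st$X, st$Lambda, alpha)
  expect_equal(U_next, pmax(st$X + st$Lambda / alpha, 0))
  expect_true(all(U_next >= 0))
  V_next <- grmfc:::update_V(st$Y, st$Pi, beta)
  expect_equal(V_next, pmax(t(st$Y) + st$Pi / beta, 0))
  # feasible points leave multipliers unchanged
  Lam2 <- st$Lambda + gam * alpha * (st$X - st$X)
  expect_equal(Lam2, st$Lambda)
  # one ascent step matches the hand formula
  Lam3 <- st$Lambda + gam * alpha * (st$X - U_next)
  expect_equal(Lam3 - st$Lambda, gam * alpha * (st$X - U_next))
})

test_that("rank-1 indicator completion converges and pins the support", {
  u <- c(1, 1, 0, 0, 1); v <- c(0, 1, 1, 0)
  Z <- outer(u, v)
  dat <- interaction_data(Z)
  fit <- grmfc_fit(dat, lambda_d = 0, lambda_t = 0, k = 2, seed = 3)
  expect_true(fit$converged)
  expect_identical(unname(fit$M[Z == 1]), rep(1, sum(Z)))
  expect_lt(fit$trace$rel_change[fit$iterations], 1e-6)
})

test_that("identical configuration and seed give identical traces", {
  sim <- simulate_dti(n = 20, m = 15, seed = 8)
  f1 <- suppressWarnings(grmfc_fit(sim$data, sim$drug_sim, sim$target_sim,
                                   k = 5, max_iter = 50, seed = 2))
  f2 <- suppressWarnings(grmfc_fit(sim$data, sim$drug_sim, sim$target_sim,
                                   k = 5, max_iter = 50, seed = 2))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$M, f2$M)
  f3 <- suppressWarnings(grmfc_fit(sim$data, sim$drug_sim, sim$target_sim,
                                   k = 5, max_iter = 50, seed = 4))
  expect_false(identical(f1$M, f3$M))
})

test_that("the rank is clamped to the smaller dimension with a warning", {
  sim <- simulate_dti(n = 12, m = 10, k_true = 2, seed = 14)
  fit <- NULL
  warnings_seen <- testthat::capture_warnings(
    fit <- grmfc_fit(sim$data, sim$drug_sim, sim$target_sim, k = 50,
                     max_iter = 20))
  expect_true(any(grepl("clamping", warnings_seen)))
  expect_equal(fit$config$k, 10)
  expect_equal(ncol(fit$X), 10)
})

test_that("factor copies stay non-negative and the constraint holds each sweep", {
  sim <- simulate_dti(n = 18, m = 14, seed = 15)
  fit <- suppressWarnings(grmfc_fit(sim$data, sim$drug_sim, sim$target_sim,
                                    k = 4, max_iter = 60))
  expect_true(all(fit$U >= 0))
  expect_true(all(fit$V >= 0))
  expect_identical(unname(fit$M[sim$data$omega]), rep(1, nrow(sim$data$omega)))
})

test_that("config validation rejects out-of-range hyperparameters", {
  expect_error(solver_config(k = 0), class = "grmfc_domain_error")
  expect_error(solver_config(alpha = 0), class = "grmfc_domain_error")
  expect_error(solver_config(gamma = 1.7), class = "grmfc_domain_error")
  expect_error(solver_config(epsilon = 0), class = "grmfc_domain_error")
  expect_error(solver_config(lambda_d = -1), class = "grmfc_domain_error")
  expect_error(grmfc_fit(simulate_dti(n = 10, m = 8, seed = 1)$data,
                         lambda_d = 0.1, lambda_t = 0, k = 3),
               class = "grmfc_validation_error")
})

test_that("tidy predictions exclude known pairs and sort by score", {
  sim <- simulate_dti(n = 15, m = 12, seed = 16)
  fit <- suppressWarnings(grmfc_fit(sim$data, sim$drug_sim, sim$target_sim,
                                    k = 4, max_iter = 40))
  tb <- tidy(fit)
  expect_equal(nrow(tb), 15 * 12 - nrow(sim$data$omega))
  expect_false(any(tb$known))
  expect_true(all(diff(tb$score) <= 0))
  expect_equal(nrow(tidy(fit, include_known = TRUE)), 15 * 12)
  g <- glance(fit)
  expect_equal(g$iterations, fit$iterations)
  expect_s3_class(autoplot(fit), "ggplot")
})
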