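#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, with ties counted one half — the normalized Mann-Whitney
#' U statistic. Invariant to any strictly increasing transform of the scores.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric vector of the same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
#' @export
auc_score <- function(labels, scores) {
  check_labels(labels, scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) integration: scores are swept from high to
#' low, tied scores are processed as one threshold block, and each recall
#' increment contributes `(recall_k - recall_{k-1}) * precision_k`. This is
#' the step convention (average precision); linearly interpolated or 11-point
#' variants give different numbers on the same ranking.
#'
#' @inheritParams auc_score
#' @return AUPR in `(0, 1]`.
#' @export
aupr_score <- function(labels, scores) {
  check_labels(labels, scores)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # threshold blocks: last index of each run of tied scores
  block_end <- which(!duplicated(sc, fromLast = TRUE))
  tp <- cumsum(lab)[block_end]
  npred <- block_end
  recall <- tp / sum(labels == 1)
  precision <- tp / npred
  sum(diff(c(0, recall)) * precision)
}

check_labels <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    abort("labels and scores must have equal length",
          class = "grmfc_domain_error")
  }
  if (!any(labels == 1) || !any(labels == 0)) {
    abort("need at least one positive and one negative label",
          class = "grmfc_metric_error")
  }
  invisible(TRUE)
}

#' Partition entities into cross-validation folds
#'
#' Seeded random partition of the given identifiers (or indices) into
#' `n_folds` disjoint folds whose sizes differ by at most one.
#'
#' @param ids Vector of entity identifiers or indices.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of `n_folds` vectors covering `ids`.
#' @export
make_folds <- function(ids, n_folds = 10, seed = 1) {
  n <- length(ids)
  if (n < n_folds) {
    abort("need at least as many entities as folds",
          class = "grmfc_domain_error")
  }
  shuffled <- withr::with_seed(seed, sample(ids))
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(shuffled, rep(seq_len(n_folds), times = sizes))
}

#' Mask the interactions of held-out entities
#'
#' Implements the cold-start masking of the two cross-validation scenarios:
#' under `cv_d` every row of `Z` belonging to a held-out drug is zeroed (the
#' drug enters the model with no known targets); under `cv_t` the columns of
#' held-out targets are zeroed. Test pairs are *all* pairs involving the
#' held-out entities; their labels come from the unmasked matrix.
#'
#' @param data An [interaction_data] object.
#' @param fold Vector of drug ids (for `cv_d`) or target ids (for `cv_t`),
#'   or integer indices.
#' @param scenario `"cv_d"` (mask drugs / rows) or `"cv_t"` (mask targets /
#'   columns).
#' @return A list with `train` (an [interaction_data] with the fold's
#'   interactions removed) and `test_pairs` (tibble of `drug`, `target`
#'   indices and the true `label`).
#' @export
mask_for_fold <- function(data, fold, scenario = c("cv_d", "cv_t")) {
  scenario <- match.arg(scenario)
  Z <- data$Z
  axis_ids <- if (scenario == "cv_d") data$drug_ids else data$target_ids
  idx <- if (is.character(fold)) match(fold, axis_ids) else as.integer(fold)
  if (anyNA(idx)) abort("unknown entity in fold", class = "grmfc_domain_error")
  Z_train <- Z
  if (scenario == "cv_d") {
    Z_train[idx, ] <- 0
    pairs <- tidyr::expand_grid(drug = idx, target = seq_len(ncol(Z)))
  } else {
    Z_train[, idx] <- 0
    pairs <- tidyr::expand_grid(drug = seq_len(nrow(Z)), target = idx)
  }
  pairs$label <- Z[cbind(pairs$drug, pairs$target)]
  list(train = interaction_data(Z_train, data$drug_ids, data$target_ids),
       test_pairs = pairs)
}

#' Default hyperparameter grid
#'
#' The reference search space: rank `k` in `{50, 100}` and each Laplacian
#' weight in `{0, 1e-4, 1e-3, 1e-2, 1e-1}`.
#'
#' @return A tibble with columns `k`, `lambda_d`, `lambda_t`.
#' @export
default_grid <- function() {
  tidyr::expand_grid(k = c(50, 100),
                     lambda_d = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
                     lambda_t = c(0, 1e-4, 1e-3, 1e-2, 1e-1))
}

#' Select hyperparameters on an inner hold-out split
#'
#' Exhaustively evaluates a grid of `(k, lambda_d, lambda_t)` combinations on
#' an inner cold-start split of the *training* entities — the same masking
#' scenario as the outer evaluation, so model selection never touches the
#' outer test entities — and returns the combination with the highest inner
#' AUPR. Ties are broken toward smaller `lambda_d`, then smaller `lambda_t`,
#' then smaller `k`.
#'
#' @param data Training [interaction_data] (outer test entities already
#'   masked).
#' @param drug_sim,target_sim Similarity matrices.
#' @param grid Tibble with columns `k`, `lambda_d`, `lambda_t` (see
#'   [default_grid]).
#' @param scenario Masking scenario, as in [mask_for_fold].
#' @param inner_frac Fraction of entities held out for the inner evaluation
#'   (default 0.1, mirroring one fold of a 10-fold split).
#' @param seed Integer seed for the inner split and fits.
#' @param config Base [solver_config]; the grid overrides its `k`,
#'   `lambda_d`, `lambda_t`.
#' @return A one-row tibble: the chosen `k`, `lambda_d`, `lambda_t` and the
#'   achieved `inner_aupr`.
#' @export
grmfc_grid_search <- function(data, drug_sim, target_sim, grid = default_grid(),
                              scenario = c("cv_d", "cv_t"), inner_frac = 0.1,
                              seed = 1, config = solver_config()) {
  scenario <- match.arg(scenario)
  if (!NROW(grid)) abort("empty hyperparameter grid",
                         class = "grmfc_domain_error")
  grid <- as_tibble(grid)
  if (nrow(grid) == 1L) {
    return(tibble::add_column(grid, inner_aupr = NA_real_))
  }
  n_ent <- if (scenario == "cv_d") length(data$drug_ids) else length(data$target_ids)
  n_inner <- max(1L, round(inner_frac * n_ent))
  inner <- withr::with_seed(seed, sample.int(n_ent, n_inner))
  masked <- mask_for_fold(data, inner, scenario)
  scored <- purrr::pmap_dbl(grid, function(k, lambda_d, lambda_t) {
    fit <- suppressWarnings(grmfc_fit(
      masked$train, drug_sim, target_sim, config,
      k = k, lambda_d = lambda_d, lambda_t = lambda_t, seed = seed))
    pairs <- masked$test_pairs
    tryCatch(
      aupr_score(pairs$label, fit$M[cbind(pairs$drug, pairs$target)]),
      grmfc_metric_error = function(e) NA_real_)
  })
  ord <- order(-scored, grid$lambda_d, grid$lambda_t, grid$k)
  chosen <- grid[ord[1L], ]
  tibble::add_column(chosen, inner_aupr = scored[ord[1L]])
}

#' Cold-start cross-validation of the factorization model
#'
#' Runs repeated k-fold cross-validation under one of the two cold-start
#' scenarios: `cv_d` partitions the drugs and masks every interaction of the
#' held-out drugs before fitting (testing target prediction for new drugs);
#' `cv_t` does the same with targets. Each repeat uses a fresh seeded
#' partition. Per fold, the model is fitted on the masked matrix and all
#' pairs involving held-out entities are scored from the prediction matrix
#' `M`; AUC and AUPR are computed against the unmasked labels. Folds whose
#' test pairs contain no positives (or no negatives) are skipped with a
#' warning and recorded as `NA`. Reported aggregates are means and standard
#' deviations across all repeat-fold cells; standard deviations across the
#' repeat means are also kept.
#'
#' @param data An [interaction_data] object.
#' @param drug_sim,target_sim Similarity matrices.
#' @param scenario `"cv_d"` or `"cv_t"`.
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Repeats (default 5).
#' @param seed Integer seed; repeat `r` partitions with `seed + r - 1`.
#' @param grid Optional hyperparameter grid for inner-split selection
#'   ([grmfc_grid_search]); `NULL` (default) uses `config` as-is.
#' @param config Base [solver_config].
#' @param ... Named overrides for `config` fields.
#' @return An object of class `grmfc_cv`: `folds` (tibble with one row per
#'   repeat-fold: metrics, iterations, chosen hyperparameters), `scenario`,
#'   and the aggregate statistics.
#' @examples
#' sim <- simulate_dti(n = 30, m = 20, seed = 3)
#' cv <- grmfc_cv(sim$data, sim$drug_sim, sim$target_sim, "cv_t",
#'                n_folds = 3, n_repeats = 1, k = 5, max_iter = 100)
#' glance(cv)
#' @export
grmfc_cv <- function(data, drug_sim, target_sim,
                     scenario = c("cv_d", "cv_t"),
                     n_folds = 10, n_repeats = 5, seed = 1,
                     grid = NULL, config = solver_config(), ...) {
  scenario <- match.arg(scenario)
  dots <- list(...)
  if (length(dots)) config <- do.call(solver_config, modifyList(
    config[setdiff(names(config), "")], dots))
  if (n_folds < 2) abort("need at least 2 folds", class = "grmfc_domain_error")
  entity_ids <- if (scenario == "cv_d") data$drug_ids else data$target_ids
  cells <- tidyr::expand_grid(repeat_ = seq_len(n_repeats),
                              fold = seq_len(n_folds))
  rows <- purrr::pmap(cells, function(repeat_, fold) {
    folds <- make_folds(entity_ids, n_folds, seed = seed + repeat_ - 1L)
    masked <- mask_for_fold(data, folds[[fold]], scenario)
    fit_seed <- seed + 1009L * repeat_ + 31L * fold
    params <- tibble(k = config$k, lambda_d = config$lambda_d,
                     lambda_t = config$lambda_t)
    if (!is.null(grid)) {
      params <- grmfc_grid_search(masked$train, drug_sim, target_sim, grid,
                                  scenario, seed = fit_seed, config = config)
    }
    out <- tibble(repeat_ = repeat_, fold = fold,
                  k = params$k, lambda_d = params$lambda_d,
                  lambda_t = params$lambda_t,
                  auc = NA_real_, aupr = NA_real_,
                  iterations = NA_integer_, note = NA_character_)
    pairs <- masked$test_pairs
    if (!any(pairs$label == 1) || !any(pairs$label == 0)) {
      warn(sprintf("repeat %d fold %d: degenerate test labels; fold skipped",
                   repeat_, fold))
      out$note <- "degenerate labels"
      return(out)
    }
    fit <- tryCatch(
      suppressWarnings(grmfc_fit(
        masked$train, drug_sim, target_sim, config,
        k = params$k, lambda_d = params$lambda_d,
        lambda_t = params$lambda_t, seed = fit_seed)),
      grmfc_numerical_error = function(e) e)
    if (inherits(fit, "error")) {
      warn(sprintf("repeat %d fold %d: %s", repeat_, fold,
                   conditionMessage(fit)))
      out$note <- conditionMessage(fit)
      return(out)
    }
    scores <- fit$M[cbind(pairs$drug, pairs$target)]
    out$auc <- auc_score(pairs$label, scores)
    out$aupr <- aupr_score(pairs$label, scores)
    out$iterations <- fit$iterations
    out
  })
  folds_tbl <- dplyr::bind_rows(rows)
  structure(
    list(folds = folds_tbl, scenario = scenario, n_folds = n_folds,
         n_repeats = n_repeats, seed = seed, config = config,
         grid_used = !is.null(grid)),
    class = "grmfc_cv"
  )
}

#' @export
print.grmfc_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<grmfc_cv> %s: %d x %d-fold; AUC %.3f (sd %.3f), AUPR %.3f (sd %.3f)\n",
              x$scenario, x$n_repeats, x$n_folds,
              g$mean_auc, g$sd_auc, g$mean_aupr, g$sd_aupr))
  invisible(x)
}

#' Per-fold cross-validation metrics
#'
#' @param x A `grmfc_cv`.
#' @param ... Unused.
#' @return The per repeat-fold tibble of metrics and chosen hyperparameters.
#' @method tidy grmfc_cv
#' @export
tidy.grmfc_cv <- function(x, ...) {
  x$folds
}

#' Aggregate cross-validation metrics
#'
#' Means and standard deviations of AUC and AUPR across all repeat-fold
#' cells, plus the standard deviation across the per-repeat means
#' (`sd_auc_repeats`, `sd_aupr_repeats`) since both conventions appear in the
#' literature.
#'
#' @param x A `grmfc_cv`.
#' @param ... Unused.
#' @return A one-row tibble of aggregates.
#' @method glance grmfc_cv
#' @export
glance.grmfc_cv <- function(x, ...) {
  f <- dplyr::filter(x$folds, !is.na(.data$auc))
  rep_means <- dplyr::summarise(dplyr::group_by(f, .data$repeat_),
                                auc = mean(.data$auc),
                                aupr = mean(.data$aupr))
  tibble(
    scenario = x$scenario,
    n_scored_folds = nrow(f),
    mean_auc = mean(f$auc), sd_auc = sd(f$auc),
    mean_aupr = mean(f$aupr), sd_aupr = sd(f$aupr),
    sd_auc_repeats = sd(rep_means$auc),
    sd_aupr_repeats = sd(rep_means$aupr)
  )
}

#' Cross-validation metrics plot
#'
#' Boxplots of per-fold AUC and AUPR across repeats.
#'
#' @param object A `grmfc_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grmfc_cv
#' @export
autoplot.grmfc_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object$folds, !is.na(.data$auc)),
    c("auc", "aupr"), names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Cold-start cross-validation (%s)",
                                  object$scenario)) +
    ggplot2::theme_minimal()
}
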