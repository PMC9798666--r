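#' Construct a validated drug-target interaction dataset
#'
#' Bundles a binary drug-by-target matrix `Z` with its identifier lists and
#' the index set of known interactions (the positions where `Z` is 1). Rows
#' are drugs, columns are targets; this is the canonical orientation used
#' throughout the package.
#'
#' @param Z Numeric matrix with entries in `{0, 1}`; rows are drugs, columns
#'   are targets.
#' @param drug_ids,target_ids Character vectors of unique identifiers; default
#'   to the dimnames of `Z` when present.
#' @return An object of class `interaction_data`: a list with elements
#'   `Z` (the 0/1 matrix, dimnames set), `drug_ids`, `target_ids`, and
#'   `omega` (a two-column integer matrix of `(i, j)` positions with
#'   `Z[i, j] == 1`).
#' @examples
#' Z <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 2)
#' dat <- interaction_data(Z, c("d1", "d2"), c("t1", "t2", "t3"))
#' nrow(dat$omega)
#' @export
interaction_data <- function(Z, drug_ids = rownames(Z), target_ids = colnames(Z)) {
  Z <- as.matrix(Z)
  if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(nrow(Z)))
  if (is.null(target_ids)) target_ids <- paste0("t", seq_len(ncol(Z)))
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (nrow(Z) < 2L || ncol(Z) < 2L) {
    abort("interaction matrix must be at least 2 x 2",
          class = "grmfc_validation_error")
  }
  if (length(drug_ids) != nrow(Z) || length(target_ids) != ncol(Z)) {
    abort("identifier lists must match the matrix dimensions",
          class = "grmfc_validation_error")
  }
  if (anyDuplicated(drug_ids) || anyDuplicated(target_ids)) {
    abort("identifiers must be unique within each axis",
          class = "grmfc_validation_error")
  }
  if (!all(is.finite(Z)) || !all(Z %in% c(0, 1))) {
    abort("every interaction entry must be exactly 0 or 1",
          class = "grmfc_validation_error")
  }
  storage.mode(Z) <- "double"
  dimnames(Z) <- list(drug_ids, target_ids)
  structure(
    list(Z = Z, drug_ids = drug_ids, target_ids = target_ids,
         omega = which(Z == 1, arr.ind = TRUE, useNames = FALSE)),
    class = "interaction_data"
  )
}

#' @export
print.interaction_data <- function(x, ...) {
  cat(sprintf("<interaction_data> %d drugs x %d targets, %d known interactions (sparseness %.2f%%)\n",
              nrow(x$Z), ncol(x$Z), nrow(x$omega), sparseness(x)))
  invisible(x)
}

#' @export
as_tibble.interaction_data <- function(x, ...) {
  tibble(
    drug_id = x$drug_ids[rep(seq_along(x$drug_ids), times = length(x$target_ids))],
    target_id = x$target_ids[rep(seq_along(x$target_ids), each = length(x$drug_ids))],
    interaction = as.vector(x$Z)
  )
}

#' Construct a validated similarity matrix
#'
#' A square symmetric matrix of pairwise similarities in `[0, 1]` for one side
#' of the interaction problem (drugs or targets). Symmetry is required within
#' `1e-8`; a diagonal different from 1 triggers a warning rather than an
#' error, since distributed similarity files do not always store exact
#' self-similarities.
#'
#' @param S Square numeric matrix with entries in `[0, 1]`.
#' @param ids Character vector of unique identifiers (defaults to rownames).
#' @return An object of class `similarity_matrix` with elements `S` and `ids`.
#' @export
similarity_matrix <- function(S, ids = rownames(S)) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) {
    abort("similarity matrix must be square", class = "grmfc_validation_error")
  }
  if (is.null(ids)) ids <- paste0("x", seq_len(nrow(S)))
  ids <- as.character(ids)
  if (length(ids) != nrow(S) || anyDuplicated(ids)) {
    abort("similarity identifiers must be unique and match the dimension",
          class = "grmfc_validation_error")
  }
  if (!all(is.finite(S)) || any(S < 0) || any(S > 1)) {
    abort("similarity values must lie in [0, 1]",
          class = "grmfc_validation_error")
  }
  if (max(abs(S - t(S))) > 1e-8) {
    abort("similarity matrix must be symmetric (tolerance 1e-8)",
          class = "grmfc_validation_error")
  }
  if (any(abs(diag(S) - 1) > 1e-8)) {
    warn("similarity diagonal is not identically 1; proceeding as-is")
  }
  S <- (S + t(S)) / 2
  storage.mode(S) <- "double"
  dimnames(S) <- list(ids, ids)
  structure(list(S = S, ids = ids), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, mean off-diagonal %.3f\n",
              nrow(x$S), ncol(x$S),
              mean(x$S[row(x$S) != col(x$S)])))
  invisible(x)
}

#' Sparseness of an interaction dataset
#'
#' Percentage of drug-target pairs that are *not* known interactions,
#' `100 * (1 - |omega| / (n * m))`, the figure conventionally reported for
#' interaction benchmarks.
#'
#' @param data An [interaction_data] object.
#' @param digits Decimals for rounding (display convention); default 2.
#' @return A single number (percentage).
#' @examples
#' Z <- matrix(0, 54, 26)
#' Z[seq_len(90)] <- 1
#' sparseness(interaction_data(Z))  # 93.59
#' @export
sparseness <- function(data, digits = 2) {
  stopifnot(inherits(data, "interaction_data"))
  round(100 * (1 - nrow(data$omega) / length(data$Z)), digits)
}

#' Normalized Smith-Waterman similarity score
#'
#' Normalizes a raw local-alignment score between two protein sequences by the
#' geometric mean of the self-alignment scores:
#' `sw_12 / (sqrt(sw_11) * sqrt(sw_22))`. The raw Smith-Waterman scores are
#' supplied by the user; this package does not run alignments.
#'
#' @param sw_12 Raw alignment score between the two sequences (`>= 0`).
#' @param sw_11,sw_22 Raw self-alignment scores (`> 0`).
#' @return The normalized score. Vectorized over all arguments.
#' @examples
#' normalized_sw_score(6, 4, 9)  # 1
#' @export
normalized_sw_score <- function(sw_12, sw_11, sw_22) {
  if (any(sw_11 <= 0) || any(sw_22 <= 0)) {
    abort("self-alignment scores must be strictly positive",
          class = "grmfc_domain_error")
  }
  if (any(sw_12 < 0)) {
    abort("cross-alignment score must be non-negative",
          class = "grmfc_domain_error")
  }
  sw_12 / (sqrt(sw_11) * sqrt(sw_22))
}
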