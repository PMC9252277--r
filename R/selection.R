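#' Trait weight vector
#'
#' Strictly positive per-trait weights expressing the relative importance of
#' the traits. For L-shaped selection on normalized values, a weight ratio
#' `w1/w2 = 4` reads as "one percentage point of trait 1 is worth four of
#' trait 2", independent of measurement units.
#'
#' @param w Numeric vector of strictly positive weights.
#' @param normalize If `TRUE`, rescale so the weights sum to one (selection is
#'   invariant to a common positive scaling of the weights either way).
#' @param trait_ids Optional names.
#' @return A named numeric vector of class `weight_vector`.
#' @export
weight_vector <- function(w, normalize = FALSE, trait_ids = names(w)) {
  w <- as.numeric(w)
  if (length(w) < 1L || any(!is.finite(w)) || any(w <= 0)) {
    stop("all weights must be strictly positive and finite")
  }
  if (normalize) w <- w / sum(w)
  if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_along(w))
  structure(stats::setNames(w, trait_ids), class = "weight_vector")
}

as_weights <- function(w, K) {
  if (!inherits(w, "weight_vector")) w <- weight_vector(w)
  if (length(w) != K) stop("weight vector length must equal number of traits")
  unclass(w)
}

#' Result of a parent-selection solve
#'
#' @param selected Integer indices of the selected individuals (sorted).
#' @param ids Their identifiers.
#' @param objective Objective value attained.
#' @param weights The [weight_vector()] used.
#' @param method `"index"` or `"lshaped"`.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(selected, ids, objective, weights, method) {
  selected <- as.integer(selected)
  if (anyDuplicated(selected)) stop("selected indices must be unique")
  ord <- order(selected)
  structure(list(selected = selected[ord],
                 ids = ids[ord],
                 objective = objective,
                 weights = weights,
                 method = match.arg(method, c("index", "lshaped"))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection: {%s}, objective = %g\n",
              x$method, paste(x$ids, collapse = ", "), x$objective))
  cat("  weights:", paste(format(unclass(x$weights), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Classical index selection (weighted-sum truncation)
#'
#' Selects the size-`S` subset maximizing the weighted sum of trait values,
#' `sum_k w_k sum_{i selected} v[i, k]`. The objective separates over
#' individuals, so the exact optimum is the top `S` individuals by the scalar
#' index `sum_k w_k v[i, k]`; score ties are broken lexicographically by
#' individual identifier for determinism.
#'
#' @param v [genetic_values()] (raw by classical convention; normalized values
#'   are also accepted).
#' @param w Strictly positive [weight_vector()] (or numeric vector).
#' @param S Number of parents to select, `S <= nrow(v)`.
#' @return A [selection_result()].
#' @export
index_select <- function(v, w, S) {
  m <- unclass(v)
  n <- nrow(m)
  if (S > n) stop("cannot select more individuals than the population holds")
  if (S < 1L) stop("S must be at least 1")
  wv <- as_weights(w, ncol(m))
  score <- as.vector(m %*% wv)
  ord <- order(-score, rownames(m))
  sel <- ord[seq_len(S)]
  selection_result(sel, rownames(m)[sel],
                   objective = sum(score[sel]),
                   weights = weight_vector(wv, trait_ids = colnames(m)),
                   method = "index")
}

#' L-shaped (max-min) selection objective of a given subset
#'
#' For a selected subset, the objective is
#' `min_k ( sum_{i selected} vtilde[i, k] / w_k )`: the smallest
#' weight-deflated normalized trait sum. Its level sets are L-shaped in two
#' dimensions, whence the method's name.
#'
#' @param selected Integer indices (or identifiers) of selected individuals.
#' @param vn Normalized [genetic_values()].
#' @param w Strictly positive weights.
#' @return The scalar objective value.
#' @export
lshaped_objective <- function(selected, vn, w) {
  if (!is_normalized(vn)) stop("L-shaped objective requires normalized values")
  m <- unclass(vn)
  if (is.character(selected)) selected <- match(selected, rownames(m))
  if (anyNA(selected)) stop("unknown individual in selected set")
  wv <- as_weights(w, ncol(m))
  sums <- colSums(m[selected, , drop = FALSE])
  min(sums / wv)
}

#' L-shaped (max-min) selection of breeding parents
#'
#' Finds a size-`S` subset maximizing the max-min objective of
#' [lshaped_objective()] by exact enumeration of all `choose(n, S)` subsets.
#' A max-min optimum can be weakly dominated, so ties on the objective are
#' broken first by the largest total normalized sum (which guarantees the
#' returned optimum is itself Pareto optimal) and then by the
#' lexicographically smallest index set, making solves reproducible.
#'
#' Because normalized values and therefore the whole solve are invariant under
#' per-trait positive affine rescaling of the raw values (when bounds use
#' relative padding), the selected set does not depend on measurement units --
#' unlike index selection on raw values.
#'
#' @param vn Normalized [genetic_values()].
#' @param w Strictly positive weights.
#' @param S Number of parents to select.
#' @param enumeration_cap Largest subset count solved by enumeration (default
#'   `1e6`; the classical two-parent case at population size 200 needs only
#'   19,900). Larger instances require an exact integer-programming backend;
#'   none is configured, so exceeding the cap is a capacity error rather than
#'   a silent heuristic.
#' @return A [selection_result()].
#' @export
lshaped_select <- function(vn, w, S, enumeration_cap = 1e6) {
  if (!is_normalized(vn)) stop("L-shaped selection requires normalized values")
  m <- unclass(vn)
  n <- nrow(m)
  K <- ncol(m)
  if (S > n) stop("cannot select more individuals than the population holds")
  if (S < 1L) stop("S must be at least 1")
  wv <- as_weights(w, K)
  n_subsets <- choose(n, S)
  if (n_subsets > enumeration_cap) {
    stop(sprintf(paste0(
      "instance too large for exact enumeration (%g subsets > cap %g) ",
      "and no exact integer-programming backend is configured"),
      n_subsets, enumeration_cap))
  }
  idx <- utils::combn(n, S)                    # S x m, lexicographic order
  sums <- vapply(seq_len(K),
                 function(k) colSums(matrix(m[, k][idx], nrow = S)),
                 numeric(ncol(idx)))
  sums <- matrix(sums, ncol = K)
  obj <- sums[, 1L] / wv[1L]
  if (K > 1L) for (k in 2L:K) obj <- pmin(obj, sums[, k] / wv[k])
  best <- which(obj == max(obj))
  if (length(best) > 1L) {
    tot <- rowSums(sums[best, , drop = FALSE])
    best <- best[tot == max(tot)]
  }
  pick <- best[1L]                             # combn order is lexicographic
  sel <- idx[, pick]
  selection_result(sel, rownames(m)[sel],
                   objective = obj[pick],
                   weights = weight_vector(wv, trait_ids = colnames(m)),
                   method = "lshaped")
}

#' Constructive weights under which a subset is max-min optimal
#'
#' For a Pareto-optimal subset, setting each trait weight equal to the
#' subset's own normalized trait sum, `w_k = sum_{i selected} vtilde[i, k]`,
#' makes that subset attain the maximal L-shaped objective (value exactly 1):
#' any subset with a strictly larger objective would have to exceed the
#' subset's sum on every trait, contradicting Pareto optimality. This is the
#' constructive guarantee that max-min selection can recover *every*
#' Pareto-optimal solution, including those unreachable by any weighted sum.
#'
#' @param selected Integer indices (or identifiers) of the subset.
#' @param vn Normalized [genetic_values()].
#' @return A [weight_vector()]; all entries are positive because normalized
#'   values lie in (0, 1).
#' @export
weights_for_solution <- function(selected, vn) {
  if (!is_normalized(vn)) stop("requires normalized values")
  m <- unclass(vn)
  if (is.character(selected)) selected <- match(selected, rownames(m))
  if (anyNA(selected) || length(selected) == 0L) stop("invalid selected set")
  weight_vector(colSums(m[selected, , drop = FALSE]), trait_ids = colnames(m))
}
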