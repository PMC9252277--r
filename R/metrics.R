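#' Evaluation set of individuals with provenance weights
#'
#' A set of individuals (trait vectors) to be compared with the Pareto
#' optimality gap and diversity measures. Each individual carries the weight
#' vector of the breeding project that produced it ("provenance weights"),
#' which is the weight used when measuring how badly that individual is
#' dominated. For external point sets without provenance, a uniform weight
#' vector is substituted with a warning.
#'
#' @param values Numeric matrix (individuals x traits) of trait values.
#' @param weights `NULL`, a single positive weight vector recycled to all
#'   individuals, or a matrix (individuals x traits) of strictly positive
#'   per-individual weights.
#' @param label Optional set label (e.g. `"I0"`).
#' @return An object of class `evaluation_set`.
#' @export
evaluation_set <- function(values, weights = NULL, label = "") {
  values <- as_points(values)
  K <- ncol(values)
  if (is.null(weights)) {
    warning("no provenance weights supplied; substituting uniform weights")
    weights <- matrix(1 / K, nrow(values), K)
  } else if (is.null(dim(weights))) {
    if (length(weights) != K) stop("weight vector length must match traits")
    weights <- matrix(as.numeric(weights), nrow(values), K, byrow = TRUE)
  } else {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(values))) {
      stop("per-individual weights must match the values dimensions")
    }
  }
  if (any(weights <= 0) || any(!is.finite(weights))) {
    stop("provenance weights must be strictly positive")
  }
  structure(list(values = values, weights = weights, label = label),
            class = "evaluation_set")
}

#' @export
print.evaluation_set <- function(x, ...) {
  cat(sprintf("evaluation_set%s: %d individual(s) x %d trait(s)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Combine evaluation sets
#' @param ... `evaluation_set` objects with matching trait dimension.
#' @param label Label for the pooled set.
#' @return An [evaluation_set()].
#' @export
bind_evaluation_sets <- function(..., label = "") {
  es <- list(...)
  evaluation_set(do.call(rbind, lapply(es, `[[`, "values")),
                 do.call(rbind, lapply(es, `[[`, "weights")),
                 label = label)
}

#' Pareto-optimal subset of an evaluation set
#'
#' The Pareto-optimal subset P(I) is the set of members attaining the maximum
#' of some strictly-positive-weighted sum of traits, i.e. the supported
#' (convex efficient) frontier of the set's trait vectors. Duplicate trait
#' vectors are collapsed first (keeping the first occurrence), so overlapping
#' progeny count once.
#'
#' @param es An [evaluation_set()].
#' @param include_boundary Passed to [supported_front()].
#' @return An [evaluation_set()] restricted to the Pareto-optimal members.
#' @export
pareto_subset <- function(es, include_boundary = FALSE) {
  stopifnot(inherits(es, "evaluation_set"))
  first <- !duplicated(es$values)
  vals <- es$values[first, , drop = FALSE]
  wts <- es$weights[first, , drop = FALSE]
  sf <- supported_front(vals, include_boundary = include_boundary)
  evaluation_set(vals[sf$indices, , drop = FALSE],
                 wts[sf$indices, , drop = FALSE],
                 label = es$label)
}

#' Pareto optimality gap between two Pareto sets
#'
#' Measures how far set `p0` is dominated by set `p1`:
#' `sum_{i in P0} min_{i' in P1 dominating i} min_k w[i, k] * max(v[i', k] - v[i, k], 0)`.
#' For each member `i` of `p0`, the competitor `i'` of `p1` that dominates `i`
#' by the least weighted amount determines `i`'s gap; a member not dominated
#' by any competitor contributes 0, as does weak dominance with equality in
#' some trait (an arbitrarily small improvement there would break the
#' dominance). The weights are each individual's provenance weights.
#'
#' The value returned is the raw sum over `p0` as in the defining formula; the
#' per-individual terms and their mean are attached as attributes
#' (`"per_individual"`, `"mean"`), since summaries of the gap are sometimes
#' reported as a per-individual average.
#'
#' @param p0,p1 [evaluation_set()]s, normally already reduced by
#'   [pareto_subset()].
#' @param auto_reduce If `TRUE`, apply [pareto_subset()] to both sets first.
#' @return Nonnegative scalar gap with attributes `per_individual` and `mean`.
#' @export
pareto_optimality_gap <- function(p0, p1, auto_reduce = FALSE) {
  stopifnot(inherits(p0, "evaluation_set"), inherits(p1, "evaluation_set"))
  if (ncol(p0$values) != ncol(p1$values)) {
    stop("trait dimensions of the two sets do not match")
  }
  if (auto_reduce) {
    p0 <- pareto_subset(p0)
    p1 <- pareto_subset(p1)
  }
  v0 <- p0$values
  v1 <- p1$values
  terms <- vapply(seq_len(nrow(v0)), function(i) {
    diff <- v1 - matrix(v0[i, ], nrow(v1), ncol(v1), byrow = TRUE)
    dom <- rowSums(diff >= 0) == ncol(v1) & rowSums(diff > 0) > 0
    if (!any(dom)) return(0)
    d <- pmax(diff[dom, , drop = FALSE], 0)
    wd <- sweep(d, 2L, p0$weights[i, ], `*`)
    min(apply(wd, 1L, min))
  }, numeric(1))
  structure(sum(terms), per_individual = terms, mean = mean(terms))
}

#' Diversity of a Pareto set
#'
#' Weighted spread of the trait vectors:
#' `sum_k w_k / n * sum_i sum_{i'} (v[i, k] - v[i', k])^2` over all ordered
#' pairs, with `n` the set size (`variant = "literal"`, the defining formula).
#' `variant = "mean"` divides by `n^2` instead (a per-pair average), and
#' `variant = "rms"` is the square root of the `"mean"` form; both alternates
#' address the formula's nominal "average Euclidean distance" wording and are
#' off by default.
#'
#' @param p0 An [evaluation_set()] (normally a Pareto subset).
#' @param w Strictly positive global weights, one per trait.
#' @param variant One of `"literal"`, `"mean"`, `"rms"`.
#' @return Nonnegative scalar.
#' @export
diversity <- function(p0, w, variant = c("literal", "mean", "rms")) {
  stopifnot(inherits(p0, "evaluation_set"))
  variant <- match.arg(variant)
  v <- p0$values
  n <- nrow(v)
  wv <- as_weights(w, ncol(v))
  # sum over ordered pairs of squared differences, per trait:
  # sum_{i,i'} (x_i - x_{i'})^2 = 2 * (n * sum x^2 - (sum x)^2)
  ssq <- vapply(seq_len(ncol(v)), function(k) {
    x <- v[, k]
    2 * (n * sum(x^2) - sum(x)^2)
  }, numeric(1))
  val <- switch(variant,
                literal = sum(wv * ssq / n),
                mean = sum(wv * ssq / n^2),
                rms = sqrt(sum(wv * ssq / n^2)))
  max(val, 0)   # guard tiny negative round-off
}
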