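#' Dominance between trait vectors
#'
#' Vector `a` dominates `b` when `a` is no worse in every trait and strictly
#' better in at least one: `all(a >= b) && any(a > b)`.
#'
#' @param a,b Numeric trait vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) all(a >= b) && any(a > b)

as_points <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("empty point set")
  storage.mode(points) <- "double"
  points
}

#' Frontier subset of a point set
#'
#' @param indices Integer indices of frontier members in the original set.
#' @param points Their trait-value vectors (rows).
#' @return An object of class `frontier_set`.
#' @export
frontier_set <- function(indices, points) {
  structure(list(indices = as.integer(indices), points = as_points(points)),
            class = "frontier_set")
}

#' @export
print.frontier_set <- function(x, ...) {
  cat(sprintf("frontier_set: %d point(s)\n", length(x$indices)))
  print(cbind(index = x$indices, x$points))
  invisible(x)
}

dominator_exists <- function(points, i) {
  p <- points[i, ]
  ge <- points >= matrix(p, nrow(points), ncol(points), byrow = TRUE)
  gt <- points > matrix(p, nrow(points), ncol(points), byrow = TRUE)
  any(rowSums(ge) == ncol(points) & rowSums(gt) > 0L)
}

#' Pareto frontier (non-dominated points)
#'
#' Returns exactly the points not dominated by any other point in the set.
#' Duplicate vectors are all retained: a copy never dominates its duplicate
#' (no strict improvement), though a third point may dominate both.
#'
#' @param points Numeric matrix of trait vectors (rows), or a list of vectors.
#' @return A [frontier_set()] of the non-dominated points.
#' @export
pareto_front <- function(points) {
  pts <- as_points(points)
  keep <- !vapply(seq_len(nrow(pts)),
                  function(i) dominator_exists(pts, i), logical(1))
  frontier_set(which(keep), pts[keep, , drop = FALSE])
}

# Indices (within `upts`, unique Pareto-optimal points sorted by first trait
# ascending) of the strict upper-convex-hull vertices. With
# include_boundary = TRUE, points lying on the interior of a hull segment are
# kept as well (weak weighted-sum maximizers).
upper_hull_2d <- function(upts, include_boundary = FALSE) {
  n <- nrow(upts)
  if (n <= 2L) return(seq_len(n))
  stack <- integer(0)
  for (i in seq_len(n)) {
    repeat {
      h <- length(stack)
      if (h < 2L) break
      a <- upts[stack[h - 1L], ]
      b <- upts[stack[h], ]
      p <- upts[i, ]
      cr <- (b[1L] - a[1L]) * (p[2L] - b[2L]) - (b[2L] - a[2L]) * (p[1L] - b[1L])
      pop <- if (include_boundary) cr > 0 else cr >= 0
      if (pop) stack <- stack[-h] else break
    }
    stack <- c(stack, i)
  }
  stack
}

# Strictly-positive-weight support test for point p against competitor rows q:
# feasibility of { w : w >= 1, (p - q) . w >= margin for all q } checked with
# a strictly convex quadratic program (minimize ||w||^2). margin = 1 tests
# strict maximization (feasible iff some w > 0 makes p the unique maximizer of
# the weighted sum, by homogeneity); margin = 0 tests weak maximization.
qp_supported <- function(p, competitors, margin = 1) {
  K <- length(p)
  A <- diag(K)
  b <- rep(1, K)
  if (nrow(competitors) > 0L) {
    D <- matrix(p, nrow(competitors), K, byrow = TRUE) - competitors
    A <- rbind(A, D)
    b <- c(b, rep(margin, nrow(competitors)))
  }
  ok <- tryCatch({
    quadprog::solve.QP(Dmat = diag(K), dvec = rep(0, K),
                       Amat = t(A), bvec = b)
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' Supported (convex efficient) frontier
#'
#' Returns the points attainable as maximizers of a strictly-positive-weighted
#' sum `sum_k w_k p_k` -- the part of the Pareto frontier a weighted-sum
#' (index) criterion can ever find. Pareto-optimal points inside a concavity
#' of the frontier are unsupported: no weights reach them.
#'
#' By default only *strict* maximizers count: points lying on the interior of
#' a hull segment (weakly supported) are excluded, since at their supporting
#' weights the segment endpoints do at least as well and any perturbation of
#' the weights abandons them. Set `include_boundary = TRUE` to keep them.
#'
#' For two traits the exact upper-right convex hull is used; for more traits
#' each Pareto-optimal candidate is tested exactly for existence of strictly
#' positive supporting weights via a small convex quadratic program.
#'
#' Supportedness is a property of the trait vector: if a supported vector is
#' duplicated, all indices carrying it are returned.
#'
#' @param points Numeric matrix of trait vectors (rows), or a list of vectors.
#' @param include_boundary Keep weakly supported points (default `FALSE`).
#' @return A [frontier_set()].
#' @export
supported_front <- function(points, include_boundary = FALSE) {
  pts <- as_points(points)
  K <- ncol(pts)
  upts <- unique(pts)
  # restrict to unique Pareto-optimal vectors; a supported point is Pareto
  # optimal, and dominated competitors never bind the support test
  pf <- pareto_front(upts)
  cand <- pf$points
  if (nrow(cand) == 1L) {
    sup <- cand
  } else if (K == 2L) {
    ord <- order(cand[, 1L], -cand[, 2L])
    srt <- cand[ord, , drop = FALSE]
    hull <- upper_hull_2d(srt, include_boundary = include_boundary)
    sup <- srt[hull, , drop = FALSE]
  } else {
    margin <- if (include_boundary) 0 else 1
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      qp_supported(cand[i, ], cand[-i, , drop = FALSE], margin = margin)
    }, logical(1))
    sup <- cand[keep, , drop = FALSE]
  }
  if (!include_boundary && nrow(sup) > 1L) {
    # strictness at the vector level: a duplicated vector is never a unique
    # maximizer, so vectors occurring more than once in the input are dropped
    counts <- vapply(seq_len(nrow(sup)), function(i) {
      sum(colSums(t(pts) == sup[i, ]) == K)
    }, integer(1))
    sup <- sup[counts == 1L, , drop = FALSE]
  }
  idx <- which(vapply(seq_len(nrow(pts)), function(i) {
    any(colSums(t(sup) == pts[i, ]) == K)
  }, logical(1)))
  frontier_set(idx, pts[idx, , drop = FALSE])
}

#' Weight-region decomposition of max-min selection for two traits
#'
#' Partitions the weight simplex `w1 in (0, 1), w2 = 1 - w1` into maximal
#' intervals, each mapped to the point that is L-shaped (max-min) optimal for
#' every weight inside it. Geometrically, max-min selection slides the corner
#' of an L-shaped level set along the ray through `(w1, w2)`; the boundary ray
#' between two adjacent Pareto-optimal points `p` (larger second trait) and
#' `q` (larger first trait) passes through the corner `(p1, q2)` where the L
#' touches both, so the breakpoint is `w1 / w2 = p1 / q2`. Every
#' Pareto-optimal point receives a nonempty interval -- the constructive
#' counterpart, over a weight continuum, of the guarantee that max-min
#' selection recovers the full Pareto frontier.
#'
#' @param points Numeric matrix of strictly positive 2-trait vectors (rows),
#'   e.g. normalized trait sums of candidate crosses.
#' @return A data frame with columns `w1_lo`, `w1_hi` (interval for `w1`),
#'   `index` (row of `points` optimal on the interval) and the point's two
#'   trait values.
#' @export
lshaped_weight_regions <- function(points) {
  pts <- as_points(points)
  if (ncol(pts) != 2L) stop("weight-region decomposition requires exactly 2 traits")
  if (any(pts <= 0)) stop("points must be strictly positive (normalized scale)")
  pf <- pareto_front(unique(pts))
  cand <- pf$points
  ord <- order(cand[, 1L])
  cand <- cand[ord, , drop = FALSE]            # second trait strictly decreasing
  m <- nrow(cand)
  # map back to first matching row of the input
  orig <- vapply(seq_len(m), function(i) {
    which(pts[, 1L] == cand[i, 1L] & pts[, 2L] == cand[i, 2L])[1L]
  }, integer(1))
  if (m == 1L) {
    return(data.frame(w1_lo = 0, w1_hi = 1, index = orig,
                      v1 = cand[, 1L], v2 = cand[, 2L]))
  }
  ratio <- cand[seq_len(m - 1L), 1L] / cand[2L:m, 2L]   # w1/w2 at each tie
  brk <- ratio / (1 + ratio)
  data.frame(w1_lo = c(0, brk), w1_hi = c(brk, 1), index = orig,
             v1 = cand[, 1L], v2 = cand[, 2L])
}
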