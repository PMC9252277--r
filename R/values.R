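#' Genetic values of individuals
#'
#' A matrix of additive genetic (breeding) values `v[i, k]` for individuals i and
#' traits k, optionally normalized to the open unit interval. Normalized values
#' must lie strictly in (0, 1).
#'
#' @param values Numeric matrix (individuals x traits).
#' @param normalized Logical flag; `TRUE` marks values as normalized.
#' @param individual_ids,trait_ids Identifiers; default to dimnames.
#' @return An object of class `genetic_values` (a classed numeric matrix with
#'   a `normalized` attribute).
#' @export
genetic_values <- function(values, normalized = FALSE,
                           individual_ids = NULL, trait_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("genetic values must be finite numeric values")
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(values)
    if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(values)))
  }
  if (is.null(trait_ids)) {
    trait_ids <- colnames(values)
    if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_len(ncol(values)))
  }
  dimnames(values) <- list(individual_ids, trait_ids)
  if (normalized && (any(values <= 0) || any(values >= 1))) {
    stop("normalized genetic values must lie strictly in (0, 1)")
  }
  structure(values, normalized = isTRUE(normalized),
            class = c("genetic_values", "matrix", "array"))
}

#' @rdname genetic_values
#' @param v Object to test.
#' @export
is_normalized <- function(v) isTRUE(attr(v, "normalized"))

#' @export
print.genetic_values <- function(x, ...) {
  cat(sprintf("genetic_values: %d individuals x %d trait(s)%s\n",
              nrow(x), ncol(x),
              if (is_normalized(x)) " (normalized)" else ""))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more individuals\n", nrow(x) - 6L))
  invisible(x)
}

#' Compute additive genetic values from genotypes and allele effects
#'
#' The genetic value of individual i on trait k is the dosage-weighted sum of
#' allele effects, `v[i, k] = sum_j G[i, j] * beta[j, k]`, where G is the
#' allele dosage (0/1/2) and beta the per-copy additive effect.
#'
#' @param g A [genotype_matrix()].
#' @param effects An [effect_matrix()] over the same loci (any order; aligned
#'   by locus identifier).
#' @return A raw (non-normalized) [genetic_values()] object.
#' @export
compute_genetic_values <- function(g, effects) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!setequal(rownames(effects), g$locus_ids)) {
    stop("locus sets of genotypes and effects do not align")
  }
  b <- effects[g$locus_ids, , drop = FALSE]
  v <- dosage(g) %*% unclass(b)
  genetic_values(v, normalized = FALSE,
                 individual_ids = g$individual_ids,
                 trait_ids = colnames(effects))
}

#' Orient all traits toward maximization
#'
#' Multitrait selection models here maximize every trait. A trait to be
#' minimized is oriented by negating its column of raw genetic values, which
#' turns its minimization into maximization.
#'
#' @param v Raw (non-normalized) [genetic_values()].
#' @param directions Character vector, one of `"maximize"`/`"minimize"` per
#'   trait (abbreviations `"max"`/`"min"` accepted).
#' @return [genetic_values()] with minimized traits negated.
#' @export
orient_traits <- function(v, directions) {
  if (is_normalized(v)) stop("orient_traits expects raw (non-normalized) values")
  directions <- tolower(directions)
  if (!all(directions %in% c("maximize", "minimize", "max", "min"))) {
    stop("directions must be 'maximize' or 'minimize' per trait")
  }
  directions <- ifelse(directions %in% c("minimize", "min"), "minimize", "maximize")
  if (length(directions) != ncol(v)) {
    stop("one direction flag required per trait")
  }
  out <- unclass(v)
  flip <- directions == "minimize"
  out[, flip] <- -out[, flip]
  genetic_values(out, normalized = FALSE)
}

#' Per-trait normalization bounds
#'
#' Bounds (lower, upper) per trait used to map raw genetic values into the
#' open unit interval. `epsilon_rel` records the relative padding fraction
#' used to construct them.
#'
#' @param lower,upper Numeric vectors of per-trait bounds, `lower < upper`.
#' @param epsilon_rel Positive padding fraction (dimensionless).
#' @param trait_ids Optional trait identifiers.
#' @return An object of class `trait_bounds`.
#' @export
trait_bounds <- function(lower, upper, epsilon_rel = 1e-6, trait_ids = NULL) {
  if (length(lower) != length(upper)) stop("lower/upper length mismatch")
  if (!all(is.finite(lower)) || !all(is.finite(upper))) stop("bounds must be finite")
  if (any(lower >= upper)) stop("lower bound must be strictly below upper bound")
  if (!is.numeric(epsilon_rel) || length(epsilon_rel) != 1L || epsilon_rel <= 0) {
    stop("epsilon_rel must be a positive scalar")
  }
  if (is.null(trait_ids)) trait_ids <- names(lower)
  if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_along(lower))
  structure(list(lower = stats::setNames(as.numeric(lower), trait_ids),
                 upper = stats::setNames(as.numeric(upper), trait_ids),
                 epsilon_rel = epsilon_rel,
                 trait_ids = trait_ids),
            class = "trait_bounds")
}

#' @export
print.trait_bounds <- function(x, ...) {
  cat("trait_bounds (epsilon_rel =", format(x$epsilon_rel), ")\n")
  print(rbind(lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Compute normalization bounds from a reference set of genetic values
#'
#' For each trait k the bounds are `lower_k = min_i v[i,k] - eps_k` and
#' `upper_k = max_i v[i,k] + eps_k`, where the padding
#' `eps_k = epsilon_rel * (max_i v[i,k] - min_i v[i,k])` is *relative* to the
#' observed per-trait range. The small positive padding guarantees that every
#' reference value maps strictly inside (0, 1); making it proportional to the
#' range keeps the whole normalization invariant under a change of measurement
#' units (per-trait positive affine rescaling).
#'
#' @param v_ref Reference [genetic_values()] (raw scale).
#' @param epsilon_rel Positive relative padding fraction (default `1e-6`).
#' @param fallback_range Optional positive scalar: an absolute range to
#'   substitute for a degenerate trait whose reference values are all
#'   identical. Without it a degenerate trait is an error.
#' @return A [trait_bounds()] object.
#' @export
compute_bounds <- function(v_ref, epsilon_rel = 1e-6, fallback_range = NULL) {
  if (!is.numeric(epsilon_rel) || length(epsilon_rel) != 1L || epsilon_rel <= 0) {
    stop("epsilon_rel must be a positive scalar")
  }
  v <- unclass(v_ref)
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  rng <- hi - lo
  if (any(rng == 0)) {
    if (is.null(fallback_range)) {
      bad <- colnames(v)[rng == 0]
      stop(sprintf("degenerate trait(s) with constant reference values: %s",
                   paste(bad, collapse = ", ")))
    }
    stopifnot(is.numeric(fallback_range), fallback_range > 0)
    rng[rng == 0] <- fallback_range
  }
  eps <- pad_eps(epsilon_rel, rng, lo, hi)
  trait_bounds(lo - eps, hi + eps, epsilon_rel = epsilon_rel,
               trait_ids = colnames(v))
}

# relative padding with a machine-precision floor: when a trait's range is
# vanishingly small relative to its magnitude, epsilon_rel * range would be
# absorbed by rounding and the padded bounds would coincide with the extremes
pad_eps <- function(epsilon_rel, rng, lo, hi) {
  pmax(epsilon_rel * rng, 4 * .Machine$double.eps * pmax(abs(lo), abs(hi)))
}

#' Normalize genetic values into the open unit interval
#'
#' Maps each value to `(v - lower) / (upper - lower)` per trait. Values of the
#' reference set that produced the bounds map strictly inside (0, 1) by
#' construction of the padding. A value outside its trait's `[lower, upper]`
#' interval is an error (never silently clamped), since clamping would corrupt
#' the max-min selection objective.
#'
#' @param v Raw [genetic_values()].
#' @param bounds A [trait_bounds()] object with one bound pair per trait.
#' @return Normalized [genetic_values()] (`is_normalized` set).
#' @export
normalize_values <- function(v, bounds) {
  stopifnot(inherits(bounds, "trait_bounds"))
  if (is_normalized(v)) stop("values are already normalized")
  m <- unclass(v)
  if (length(bounds$lower) != ncol(m)) stop("bounds/trait dimension mismatch")
  for (k in seq_len(ncol(m))) {
    bad <- which(m[, k] < bounds$lower[k] | m[, k] > bounds$upper[k])
    if (length(bad)) {
      stop(sprintf(
        "value outside reference bounds: individual '%s', trait '%s' (%g not in [%g, %g])",
        rownames(m)[bad[1]], colnames(m)[k], m[bad[1], k],
        bounds$lower[k], bounds$upper[k]))
    }
  }
  out <- sweep(sweep(m, 2L, bounds$lower, `-`), 2L,
               bounds$upper - bounds$lower, `/`)
  genetic_values(out, normalized = TRUE)
}

#' Bounds over every genotype attainable from a founder population
#'
#' Computes per-trait lower/upper bounds over the set of all individuals that
#' can ever arise by recurrent crossing within a founder population: descent
#' only recombines founder alleles, so at each locus the attainable dosage
#' range is determined by which alleles are present among the founders. The
#' per-trait extremes are the sums of the per-locus extreme dosage-by-effect
#' contributions, padded relatively as in [compute_bounds()]. Freezing these
#' bounds at generation 0 keeps normalized values comparable across all
#' generations and methods of a breeding experiment while guaranteeing every
#' future progeny stays inside them.
#'
#' @param g Founder [genotype_matrix()].
#' @param effects An [effect_matrix()] over the same loci.
#' @param epsilon_rel Positive relative padding fraction (default `1e-6`).
#' @return A [trait_bounds()] object.
#' @export
attainable_bounds <- function(g, effects, epsilon_rel = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!setequal(rownames(effects), g$locus_ids)) {
    stop("locus sets of genotypes and effects do not align")
  }
  b <- unclass(effects[g$locus_ids, , drop = FALSE])
  has1 <- colSums(g$hap1) + colSums(g$hap2) > 0
  has0 <- colSums(1L - g$hap1) + colSums(1L - g$hap2) > 0
  dmin <- ifelse(has0, 0L, 2L)
  dmax <- ifelse(has1, 2L, 0L)
  contrib_min <- pmin(dmin * b, dmax * b)
  contrib_max <- pmax(dmin * b, dmax * b)
  lo <- colSums(contrib_min)
  hi <- colSums(contrib_max)
  rng <- hi - lo
  if (any(rng == 0)) {
    stop("degenerate trait: no attainable variation from these founders")
  }
  eps <- pad_eps(epsilon_rel, rng, lo, hi)
  trait_bounds(lo - eps, hi + eps, epsilon_rel = epsilon_rel,
               trait_ids = colnames(effects))
}
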