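#' Specification of a synthetic multitrait genomic-selection data set
#'
#' Describes founder genotypes, pleiotropic additive effects and a
#' recombination map to be simulated. Founders are fully homozygous inbred
#' lines; allele frequencies are drawn per locus from a Beta distribution;
#' effects for the traits are drawn from a correlated zero-mean Gaussian; and
#' within-chromosome recombination frequencies come from a configurable
#' distribution truncated to \[0, 0.5\].
#'
#' @param n_founders Number of inbred founders (default 200).
#' @param n_chromosomes Number of linkage groups (default 10).
#' @param loci_per_chromosome Loci per chromosome (default 100, for 1,000
#'   total).
#' @param n_traits Number of traits (default 2).
#' @param freq_shape Two Beta shape parameters for per-locus allele-1
#'   frequencies (default `c(2, 2)`).
#' @param r_dist Within-chromosome recombination-frequency distribution:
#'   `list(type = "exponential", mean = 0.02)` (default; truncated at 0.5,
#'   emulating a dense SNP map on chromosomes of roughly two Morgans),
#'   `list(type = "uniform", min, max)` or `list(type = "fixed", value)`.
#' @param rho Target correlation between the two effect columns (or a full
#'   correlation matrix for `n_traits > 2`); must define a positive-definite
#'   correlation structure. Default 0.375.
#' @param effect_sd Standard deviation of the per-locus effects (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_founders = 200L, n_chromosomes = 10L,
                           loci_per_chromosome = 100L, n_traits = 2L,
                           freq_shape = c(2, 2),
                           r_dist = list(type = "exponential", mean = 0.02),
                           rho = 0.375, effect_sd = 1) {
  stopifnot(n_founders >= 1L, n_chromosomes >= 1L, loci_per_chromosome >= 1L,
            n_traits >= 1L, length(freq_shape) == 2L, all(freq_shape > 0),
            effect_sd > 0)
  if (is.matrix(rho)) {
    if (!identical(dim(rho), rep(as.integer(n_traits), 2L))) {
      stop("correlation matrix dimension must match n_traits")
    }
  } else if (n_traits == 2L) {
    if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_chromosomes = as.integer(n_chromosomes),
                 loci_per_chromosome = as.integer(loci_per_chromosome),
                 n_traits = as.integer(n_traits),
                 freq_shape = freq_shape, r_dist = r_dist,
                 rho = rho, effect_sd = effect_sd),
            class = "synthetic_spec")
}

#' Maize-like preset specification
#'
#' The default emulation scale: 200 inbred founders, 10 chromosomes x 100
#' SNPs, 2 pleiotropic traits with a genetic correlation of 0.375 between the
#' founder genetic values.
#'
#' @param ... Overrides passed to [synthetic_spec()].
#' @export
maize_like_spec <- function(...) synthetic_spec(...)

#' Simulate fully homozygous founder genotypes
#'
#' Each founder is a fully homozygous diploid (both haplotypes identical);
#' the allele-1 indicator at each locus is drawn with a locus-specific
#' frequency sampled from the spec's Beta distribution. Loci are assigned
#' contiguously to chromosomes. The drawn per-locus frequencies are attached
#' as attribute `"allele_freq"`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [genotype_matrix()].
#' @export
simulate_founders <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$n_chromosomes * spec$loci_per_chromosome
  n <- spec$n_founders
  p <- stats::rbeta(L, spec$freq_shape[1L], spec$freq_shape[2L])
  hap <- matrix(stats::rbinom(n * L, 1L, rep(p, each = n)), n, L)
  chrom <- rep(seq_len(spec$n_chromosomes), each = spec$loci_per_chromosome)
  g <- genotype_matrix(hap, hap,
                       individual_ids = sprintf("founder%03d", seq_len(n)),
                       locus_ids = sprintf("chr%d_snp%d", chrom,
                                           sequence(rep(spec$loci_per_chromosome,
                                                        spec$n_chromosomes))),
                       chrom = chrom)
  attr(g, "allele_freq") <- p
  g
}

chol_sigma <- function(rho, K, sd) {
  R <- if (is.matrix(rho)) rho else {
    m <- diag(K); m[m == 0] <- rho; m
  }
  ch <- tryCatch(chol(R), error = function(e) {
    stop("requested trait correlation matrix is not positive definite")
  })
  ch * sd
}

#' Simulate pleiotropic additive effects
#'
#' Draws per-locus effects for all traits jointly from a zero-mean Gaussian
#' with the spec's between-trait correlation and scale. With `founders` given
#' and a two-trait spec, the correlation realized between the founder genetic
#' values is attached as attribute `"realized_value_correlation"`; with
#' `target_value_correlation` also set, the effect-level correlation is tuned
#' by a one-dimensional root search (on a fixed set of underlying Gaussian
#' draws, so the search is deterministic given the RNG state) until the
#' founder genetic-value correlation matches the target. Founder allele
#' frequencies and linkage perturb the value-level correlation away from the
#' effect-level one, which is why the two readings are reported side by side.
#'
#' @param spec A [synthetic_spec()].
#' @param founders Optional founder [genotype_matrix()] used to measure (and
#'   optionally target) the value-level correlation.
#' @param target_value_correlation Optional target for the correlation of the
#'   two founder genetic-value columns (e.g. 0.375 for the maize-like preset).
#' @return An [effect_matrix()] with attributes `effect_correlation` and (when
#'   `founders` is given) `realized_value_correlation`.
#' @export
simulate_effects <- function(spec, founders = NULL,
                             target_value_correlation = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- spec$n_traits
  L <- spec$n_chromosomes * spec$loci_per_chromosome
  Z <- matrix(stats::rnorm(L * K), L, K)
  make_B <- function(rho) Z %*% chol_sigma(rho, K, spec$effect_sd)
  if (!is.null(target_value_correlation)) {
    if (K != 2L || is.null(founders)) {
      stop("value-correlation targeting requires 2 traits and founders")
    }
    D <- dosage(founders)
    realized <- function(rho) {
      V <- D %*% make_B(rho)
      stats::cor(V[, 1L], V[, 2L]) - target_value_correlation
    }
    lo <- -0.99; hi <- 0.99
    flo <- realized(lo); fhi <- realized(hi)
    rho <- if (flo * fhi <= 0) {
      stats::uniroot(realized, c(lo, hi), tol = 1e-6)$root
    } else {
      # no sign change: fall back to the closest endpoint
      if (abs(flo) < abs(fhi)) lo else hi
    }
  } else {
    rho <- spec$rho
  }
  B <- make_B(rho)
  locus_ids <- if (!is.null(founders)) founders$locus_ids else
    paste0("locus", seq_len(L))
  eff <- effect_matrix(B, locus_ids = locus_ids,
                       trait_ids = paste0("trait", seq_len(K)))
  if (K == 2L) {
    attr(eff, "effect_correlation") <- stats::cor(B[, 1L], B[, 2L])
    if (!is.null(founders)) {
      V <- dosage(founders) %*% B
      attr(eff, "realized_value_correlation") <- stats::cor(V[, 1L], V[, 2L])
    }
  }
  eff
}

#' Simulate a recombination map
#'
#' Within-chromosome interval frequencies are drawn from the spec's
#' distribution truncated to \[0, 0.5\]; chromosome-boundary intervals are set
#' to exactly 0.5.
#'
#' @param spec A [synthetic_spec()].
#' @param locus_ids Optional locus identifiers (default as in
#'   [simulate_founders()]).
#' @return A [recombination_map()].
#' @export
simulate_recomb_map <- function(spec, locus_ids = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$n_chromosomes * spec$loci_per_chromosome
  chrom <- rep(seq_len(spec$n_chromosomes), each = spec$loci_per_chromosome)
  if (is.null(locus_ids)) {
    locus_ids <- sprintf("chr%d_snp%d", chrom,
                         sequence(rep(spec$loci_per_chromosome,
                                      spec$n_chromosomes)))
  }
  d <- spec$r_dist
  n_int <- L - 1L
  r <- switch(d$type,
              exponential = {
                # inverse-CDF draw from Exp(mean) truncated to [0, 0.5]
                u <- stats::runif(n_int)
                -d$mean * log(1 - u * (1 - exp(-0.5 / d$mean)))
              },
              uniform = stats::runif(n_int, max(0, d$min), min(0.5, d$max)),
              fixed = rep(d$value, n_int),
              stop("unknown r_dist type"))
  boundary <- chrom[-L] != chrom[-1L]
  r[boundary] <- 0.5
  recombination_map(locus_ids, chrom, r)
}

#' Generate a complete maize-like data set
#'
#' Convenience wrapper: seeds the RNG, simulates founders, a recombination
#' map, and effects tuned so the founder genetic-value correlation matches the
#' preset target (0.375 by default).
#'
#' @param seed Integer seed.
#' @param spec A [synthetic_spec()] (default [maize_like_spec()]).
#' @param target_value_correlation Target founder genetic-value correlation
#'   (default `0.375`; `NULL` to skip tuning and use `spec$rho` at the effect
#'   level).
#' @return List with `founders`, `effects`, `map` and `spec`.
#' @export
maize_like_data <- function(seed = 1L, spec = maize_like_spec(),
                            target_value_correlation = 0.375) {
  set.seed(seed)
  founders <- simulate_founders(spec)
  map <- simulate_recomb_map(spec, locus_ids = founders$locus_ids)
  effects <- simulate_effects(spec, founders = founders,
                              target_value_correlation = target_value_correlation)
  list(founders = founders, effects = effects, map = map, spec = spec)
}

#' Worked four-individual example
#'
#' The printed two-trait example: four candidate individuals, the six
#' candidate biparental crosses with their trait sums, the expected supported
#' (convex efficient) frontier and the expected Pareto frontier. The four
#' value pairs already lie in (0, 1) and are used directly as normalized
#' values when solving the example.
#'
#' @return List with `values` (a normalized [genetic_values()] for i1..i4),
#'   `crosses` (data frame: cross id, the two parents, printed trait sums),
#'   `supported` (cross ids on the convex efficient frontier) and `pareto`
#'   (cross ids on the Pareto frontier).
#' @export
example1_fixture <- function() {
  vals <- matrix(c(0.05, 0.33,
                   0.22, 0.22,
                   0.30, 0.15,
                   0.44, 0.06),
                 ncol = 2L, byrow = TRUE,
                 dimnames = list(paste0("i", 1:4), c("trait1", "trait2")))
  crosses <- data.frame(
    cross = paste0("c", 1:6),
    parent1 = c("i1", "i1", "i1", "i2", "i2", "i3"),
    parent2 = c("i2", "i3", "i4", "i3", "i4", "i4"),
    sum1 = c(0.27, 0.35, 0.49, 0.52, 0.66, 0.74),
    sum2 = c(0.55, 0.48, 0.39, 0.37, 0.28, 0.21),
    stringsAsFactors = FALSE)
  list(values = genetic_values(vals, normalized = TRUE),
       crosses = crosses,
       supported = c("c1", "c5", "c6"),
       pareto = paste0("c", 1:6))
}

#' Candidate cross trait sums of a population
#'
#' Enumerates all size-`S` subsets and their per-trait value sums.
#'
#' @param v A [genetic_values()] object.
#' @param S Subset size (default 2: biparental crosses).
#' @return List with `subsets` (S x m index matrix, lexicographic order) and
#'   `sums` (m x traits matrix of subset trait sums).
#' @export
cross_sums <- function(v, S = 2L) {
  m <- unclass(v)
  idx <- utils::combn(nrow(m), S)
  sums <- vapply(seq_len(ncol(m)),
                 function(k) colSums(matrix(m[, k][idx], nrow = S)),
                 numeric(ncol(idx)))
  list(subsets = idx, sums = matrix(sums, ncol = ncol(m),
                                    dimnames = list(NULL, colnames(m))))
}
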