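# Independent brute-force oracles and small random-instance generators used
# across the suite. The oracles deliberately share no code with the package
# solvers: plain loops and all-pairs scans.

rand_values <- function(n, K, normalized = FALSE) {
  m <- matrix(stats::runif(n * K), n, K,
              dimnames = list(paste0("i", seq_len(n)),
                              paste0("trait", seq_len(K))))
  if (normalized) {
    m <- 0.02 + 0.96 * m        # keep strictly inside (0, 1)
  }
  genetic_values(m, normalized = normalized)
}

all_subsets <- function(n, S) utils::combn(n, S, simplify = FALSE)

# exact weighted-sum maximizers over all size-S subsets, by enumeration
oracle_index_optima <- function(v, w, S) {
  m <- unclass(v)
  subs <- all_subsets(nrow(m), S)
  obj <- vapply(subs, function(s) sum(colSums(m[s, , drop = FALSE]) * w),
                numeric(1))
  subs[abs(obj - max(obj)) < 1e-12]
}

# exact max-min optima over all size-S subsets, by enumeration
oracle_lshaped_optima <- function(vn, w, S, tol = 1e-12) {
  m <- unclass(vn)
  subs <- all_subsets(nrow(m), S)
  obj <- vapply(subs, function(s) min(colSums(m[s, , drop = FALSE]) / w),
                numeric(1))
  list(subsets = subs[obj >= max(obj) - tol], value = max(obj))
}

oracle_lshaped_value <- function(vn, w, s) {
  min(colSums(unclass(vn)[s, , drop = FALSE]) / w)
}

# all-pairs O(n^2) dominance scan
oracle_pareto <- function(points) {
  n <- nrow(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(points[j, ] >= points[i, ]) &&
          any(points[j, ] > points[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  which(keep)
}

# dense weight sweep with exact per-weight maximization; returns indices of
# points that are the unique maximizer for at least one strictly positive
# weight vector on the grid
oracle_supported_sweep <- function(points, n_grid = 4001L) {
  found <- integer(0)
  for (w1 in seq(1e-4, 1 - 1e-4, length.out = n_grid)) {
    sc <- points %*% c(w1, 1 - w1)
    top <- which(sc == max(sc))
    if (length(top) == 1L) found <- union(found, top)
  }
  sort(found)
}

# trait sums of all size-S subsets plus the subsets themselves
oracle_subset_sums <- function(v, S) {
  m <- unclass(v)
  subs <- all_subsets(nrow(m), S)
  sums <- t(vapply(subs, function(s) colSums(m[s, , drop = FALSE]),
                   numeric(ncol(m))))
  list(subsets = subs, sums = sums)
}

# small random genotype population; homozygous = fully inbred founders
random_genotypes <- function(n, L, n_chrom = 2L, homozygous = TRUE) {
  chrom <- sort(rep_len(seq_len(n_chrom), L))
  h1 <- matrix(stats::rbinom(n * L, 1L, 0.5), n, L)
  h2 <- if (homozygous) h1 else matrix(stats::rbinom(n * L, 1L, 0.5), n, L)
  genotype_matrix(h1, h2, chrom = chrom)
}

random_map <- function(g, r_max = 0.4) {
  L <- length(g$locus_ids)
  r <- stats::runif(L - 1L, 0, r_max)
  boundary <- g$chrom[-L] != g$chrom[-1L]
  r[boundary] <- 0.5
  recombination_map(g$locus_ids, g$chrom, r)
}

# founders encoding the printed four-individual example: one private
# "signature" locus per individual (homozygous dosage 2), effects = half the
# printed values, so dosage %*% effects reproduces the table exactly
example1_founders <- function() {
  ex <- example1_fixture()
  g <- genotype_matrix(diag(4L), diag(4L),
                       individual_ids = rownames(ex$values),
                       chrom = rep(1L, 4L))
  eff <- effect_matrix(unclass(ex$values) / 2,
                       locus_ids = g$locus_ids,
                       trait_ids = colnames(ex$values))
  map <- recombination_map(g$locus_ids, g$chrom, rep(0.5, 3L))
  list(founders = g, effects = eff, map = map)
}
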