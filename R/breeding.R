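#' Recombination map over ordered loci
#'
#' Per-interval recombination frequencies between adjacent loci. Within a
#' chromosome each `r` lies in \[0, 0.5\]; intervals spanning a chromosome
#' boundary are fixed at exactly 0.5 (independent assortment).
#'
#' @param locus_ids Ordered locus identifiers (length L).
#' @param chrom Integer chromosome label per locus (contiguous blocks).
#' @param r Numeric vector of length L - 1 of recombination frequencies.
#' @return An object of class `recomb_map`.
#' @export
recombination_map <- function(locus_ids, chrom, r) {
  L <- length(locus_ids)
  chrom <- as.integer(chrom)
  if (length(chrom) != L) stop("chrom must have one entry per locus")
  if (length(r) != L - 1L) stop("r must have length loci - 1")
  if (any(r < 0 | r > 0.5)) stop("recombination frequencies must lie in [0, 0.5]")
  if (anyDuplicated(rle(chrom)$values)) stop("loci of a chromosome must be contiguous")
  boundary <- chrom[-L] != chrom[-1L]
  if (any(r[boundary] != 0.5)) {
    stop("chromosome-boundary intervals must have r = 0.5 exactly")
  }
  structure(list(locus_ids = as.character(locus_ids), chrom = chrom,
                 r = as.numeric(r), boundary = boundary),
            class = "recomb_map")
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf("recomb_map: %d loci, %d chromosome(s), mean within-chromosome r = %.4g\n",
              length(x$locus_ids), length(unique(x$chrom)),
              mean(x$r[!x$boundary])))
  invisible(x)
}

# n gametes from one parent's two haplotypes under a no-interference
# (Haldane-style) crossover model: one uniform starting phase, then
# independent Bernoulli(r) phase switches per interval. Boundary intervals
# at r = 0.5 re-randomize the phase, which is exactly a fresh uniform start
# per chromosome.
gamete_rows <- function(h1, h2, map, n) {
  L <- length(h1)
  if (L != length(map$r) + 1L) stop("haplotype length does not match the map")
  start <- as.integer(stats::runif(n) < 0.5)
  if (L > 1L) {
    sw <- matrix(stats::runif(n * (L - 1L)) <
                   matrix(map$r, n, L - 1L, byrow = TRUE), n, L - 1L)
    phase <- cbind(start, sw)
    phase <- t(apply(phase, 1L, cumsum)) %% 2L
  } else {
    phase <- matrix(start, n, 1L)
  }
  out <- matrix(rep(h1, each = n), n, L)
  alt <- matrix(rep(h2, each = n), n, L)
  out[phase == 1L] <- alt[phase == 1L]
  storage.mode(out) <- "integer"
  out
}

#' Simulate one gamete by meiosis
#'
#' Draws a recombinant haplotype from a parent's two phased haplotypes under a
#' no-interference crossover model: the starting phase is uniform and phase
#' switches occur independently between adjacent loci with the map's
#' recombination frequency. Chromosomes assort independently through the
#' boundary intervals at r = 0.5.
#'
#' @param parent A single-individual [genotype_matrix()] or a list with
#'   elements `hap1` and `hap2` (0/1 vectors).
#' @param map A [recombination_map()] matching the loci.
#' @return Integer 0/1 haplotype vector.
#' @export
make_gamete <- function(parent, map) {
  hp <- parent_haplotypes(parent)
  drop(gamete_rows(hp$h1, hp$h2, map, 1L))
}

parent_haplotypes <- function(parent) {
  if (inherits(parent, "genotype_matrix")) {
    if (n_individuals(parent) != 1L) stop("parent must be a single individual")
    list(h1 = drop(parent$hap1[1L, ]), h2 = drop(parent$hap2[1L, ]))
  } else if (is.list(parent) && all(c("hap1", "hap2") %in% names(parent))) {
    list(h1 = as.integer(parent$hap1), h2 = as.integer(parent$hap2))
  } else stop("parent must be a genotype_matrix or a hap1/hap2 list")
}

#' Biparental cross
#'
#' Produces `n_progeny` offspring, each formed from one independent gamete of
#' each parent.
#'
#' @param parent_a,parent_b Single-individual [genotype_matrix()] objects (or
#'   `hap1`/`hap2` lists) over the same loci.
#' @param n_progeny Number of offspring.
#' @param map A [recombination_map()].
#' @param locus_ids,chrom Locus metadata, taken from `parent_a` when it is a
#'   `genotype_matrix`.
#' @param ids Optional progeny identifiers (default `prog1, prog2, ...`).
#' @return A [genotype_matrix()] of the progeny.
#' @export
cross <- function(parent_a, parent_b, n_progeny, map,
                  locus_ids = NULL, chrom = NULL, ids = NULL) {
  pa <- parent_haplotypes(parent_a)
  pb <- parent_haplotypes(parent_b)
  if (length(pa$h1) != length(pb$h1)) stop("parents have incompatible loci")
  if (inherits(parent_a, "genotype_matrix")) {
    if (is.null(locus_ids)) locus_ids <- parent_a$locus_ids
    if (is.null(chrom)) chrom <- parent_a$chrom
  }
  if (is.null(ids)) ids <- paste0("prog", seq_len(n_progeny))
  h1 <- gamete_rows(pa$h1, pa$h2, map, n_progeny)
  h2 <- gamete_rows(pb$h1, pb$h2, map, n_progeny)
  genotype_matrix(h1, h2, individual_ids = ids,
                  locus_ids = locus_ids, chrom = chrom)
}

#' Configuration of a recurrent breeding program
#'
#' @param S Parents selected per generation (the simulator crosses one
#'   biparental pair, so `S = 2`).
#' @param N Progeny per generation (default 200).
#' @param T Number of generations of selection and crossing (default 5).
#' @param method Selection method, `"lshaped"` or `"index"`.
#' @param weights Trait [weight_vector()].
#' @param seed Integer seed for the run.
#' @param epsilon_rel Relative padding for normalization bounds.
#' @param bounds_policy How normalization bounds for within-run selection are
#'   chosen. `"refresh"` (default): recomputed each generation from the
#'   current candidate population, so normalized values always span the open
#'   unit interval and the weights keep their percentage-point interpretation;
#'   `"attainable"`: frozen bounds over every genotype reachable from the
#'   founder alleles (comparable across generations, but observed values
#'   occupy a narrow central band, which blunts the weight semantics);
#'   `"generation0"`: frozen bounds from the observed founder values (errors
#'   if transgressive progeny exceed them).
#' @param index_normalize If `TRUE`, index selection runs on normalized rather
#'   than raw values (classical index selection uses raw values).
#' @param enumeration_cap Passed to [lshaped_select()].
#' @return An object of class `breeding_config`.
#' @export
breeding_config <- function(S = 2L, N = 200L, T = 5L,
                            method = c("lshaped", "index"),
                            weights = weight_vector(c(0.5, 0.5)),
                            seed = 1L,
                            epsilon_rel = 1e-6,
                            bounds_policy = c("refresh", "attainable", "generation0"),
                            index_normalize = FALSE,
                            enumeration_cap = 1e6) {
  method <- match.arg(method)
  bounds_policy <- match.arg(bounds_policy)
  if (S < 2L) stop("S must be at least 2")
  if (N < 1L || T < 1L) stop("N and T must be positive")
  structure(list(S = as.integer(S), N = as.integer(N), T = as.integer(T),
                 method = method, weights = weight_vector(weights),
                 seed = as.integer(seed), epsilon_rel = epsilon_rel,
                 bounds_policy = bounds_policy,
                 index_normalize = isTRUE(index_normalize),
                 enumeration_cap = enumeration_cap),
            class = "breeding_config")
}

#' Run a recurrent breeding program
#'
#' Starting from the founder population, each generation computes the current
#' population's genetic values, selects `S = 2` parents with the configured
#' method (L-shaped selection on normalized values under the configured
#' bounds policy; index selection on raw values unless `index_normalize`), and
#' crosses them to produce `N` progeny. The two parents are always distinct
#' individuals. Selection uses true genetic values (no phenotyping noise), and
#' candidates are the current generation only.
#'
#' @param founders Founder [genotype_matrix()].
#' @param effects An [effect_matrix()].
#' @param map A [recombination_map()].
#' @param config A [breeding_config()].
#' @return An object of class `breeding_result`: list with the final
#'   `population` (genotype_matrix), final raw `values`, per-generation raw
#'   value `trace` (generations 0..T), `parents` selected each generation,
#'   the normalization `bounds` and the `config`.
#' @export
run_breeding_program <- function(founders, effects, map, config) {
  stopifnot(inherits(config, "breeding_config"))
  if (!identical(founders$locus_ids, map$locus_ids)) {
    stop("founders and recombination map must share loci (same order)")
  }
  if (config$S != 2L) {
    stop("the simulator makes one biparental cross per generation; S must be 2")
  }
  if (n_individuals(founders) < config$S) stop("population smaller than S")
  set.seed(config$seed)
  v0 <- compute_genetic_values(founders, effects)
  # bounds are only needed when selection runs on normalized values
  bounds <- if (config$method == "lshaped" || config$index_normalize) {
    switch(config$bounds_policy,
           refresh = NULL,   # recomputed from each generation's candidates
           attainable = attainable_bounds(founders, effects,
                                          config$epsilon_rel),
           generation0 = compute_bounds(v0, config$epsilon_rel))
  } else NULL
  pop <- founders
  v <- v0
  trace <- list(v0)
  parents <- vector("list", config$T)
  for (t in seq_len(config$T)) {
    sel <- select_parents(v, bounds, config)
    parents[[t]] <- sel$ids
    pa <- subset_individuals(pop, sel$selected[1L])
    pb <- subset_individuals(pop, sel$selected[2L])
    pop <- cross(pa, pb, config$N, map,
                 ids = sprintf("g%d_%03d", t, seq_len(config$N)))
    v <- compute_genetic_values(pop, effects)
    trace[[t + 1L]] <- v
  }
  structure(list(population = pop, values = v, trace = trace,
                 parents = parents, bounds = bounds, config = config),
            class = "breeding_result")
}

select_parents <- function(v, bounds, config) {
  if (is.null(bounds) && (config$method == "lshaped" || config$index_normalize)) {
    # per-generation refresh; a trait fixed in the current candidates gets an
    # arbitrary unit fallback range (it cannot discriminate candidates anyway)
    bounds <- compute_bounds(v, config$epsilon_rel, fallback_range = 1)
  }
  if (config$method == "lshaped") {
    vn <- normalize_values(v, bounds)
    lshaped_select(vn, config$weights, config$S,
                   enumeration_cap = config$enumeration_cap)
  } else if (config$index_normalize) {
    index_select(normalize_values(v, bounds), config$weights, config$S)
  } else {
    index_select(v, config$weights, config$S)
  }
}

#' @export
print.breeding_result <- function(x, ...) {
  cat(sprintf("breeding_result: %s selection, T = %d, N = %d\n",
              x$config$method, x$config$T, x$config$N))
  means <- t(vapply(x$trace, colMeans, numeric(ncol(x$values))))
  rownames(means) <- paste0("gen", seq_len(nrow(means)) - 1L)
  cat("population mean genetic values by generation:\n")
  print(means)
  invisible(x)
}

#' Run the weight-grid breeding experiment
#'
#' Runs every method x weight x repetition combination as an independent
#' breeding program and pools the final-generation individuals of each method
#' into an [evaluation_set()], tagging every individual with its run's weight
#' vector (the provenance weights used by [pareto_optimality_gap()]). The
#' default grid is `w1 in {0.1, ..., 0.9}`, `w2 = 1 - w1`, with 10
#' repetitions per weight set.
#'
#' One child seed per (method, weight, repetition) is derived from
#' `master_seed` by seeding R's RNG with it and drawing the child seeds in
#' the fixed run order (methods outer, weights, repetitions inner), so the
#' whole experiment is reproducible while runs stay independent.
#'
#' Pooled final values are reported both raw and normalized; normalization
#' uses bounds over the union of all runs' final populations plus the
#' founders, so every compared individual shares one scale.
#'
#' @param founders,effects,map As in [run_breeding_program()].
#' @param methods Character vector of methods to run.
#' @param weight_grid Numeric vector of `w1` values (two-trait case) or a list
#'   of weight vectors.
#' @param reps Repetitions per method x weight combination.
#' @param config Base [breeding_config()]; its method/weights/seed are
#'   overridden per run.
#' @param master_seed Integer master seed.
#' @return List with `sets` (named list of normalized evaluation_sets per
#'   method), `raw_sets` (same on the raw scale), `runs` (data frame of run
#'   metadata) and `pool_bounds` (the shared normalization bounds).
#' @export
run_experiment_grid <- function(founders, effects, map,
                                methods = c("index", "lshaped"),
                                weight_grid = seq(0.1, 0.9, by = 0.1),
                                reps = 10L,
                                config = breeding_config(),
                                master_seed = 1L) {
  if (!is.list(weight_grid)) {
    weight_grid <- lapply(weight_grid, function(w1) c(w1, 1 - w1))
  }
  runs <- expand.grid(rep = seq_len(reps),
                      weight = seq_along(weight_grid),
                      method = methods,
                      stringsAsFactors = FALSE)
  set.seed(master_seed)
  runs$seed <- sample.int(.Machine$integer.max - 1L, nrow(runs))
  results <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    cfg <- config
    cfg$method <- runs$method[r]
    cfg$weights <- weight_vector(weight_grid[[runs$weight[r]]])
    cfg$seed <- runs$seed[r]
    results[[r]] <- run_breeding_program(founders, effects, map, cfg)
  }
  v0 <- compute_genetic_values(founders, effects)
  all_final <- do.call(rbind, c(list(unclass(v0)),
                                lapply(results, function(x) unclass(x$values))))
  pool_bounds <- compute_bounds(genetic_values(all_final),
                                epsilon_rel = config$epsilon_rel)
  sets <- raw_sets <- list()
  for (m in methods) {
    rows <- which(runs$method == m)
    vals <- do.call(rbind, lapply(results[rows], function(x) unclass(x$values)))
    wts <- do.call(rbind, lapply(rows, function(r) {
      matrix(weight_grid[[runs$weight[r]]], nrow(results[[r]]$values),
             ncol(vals), byrow = TRUE)
    }))
    vn <- normalize_values(genetic_values(vals), pool_bounds)
    raw_sets[[m]] <- evaluation_set(vals, wts, label = m)
    sets[[m]] <- evaluation_set(unclass(vn), wts, label = m)
  }
  list(sets = sets, raw_sets = raw_sets, runs = runs,
       pool_bounds = pool_bounds)
}

#' Gap and diversity comparison of pooled experiment sets
#'
#' For each method's pooled evaluation set, computes the Pareto-optimal
#' subset, its Pareto optimality gap against the Pareto subset of the union of
#' all methods' sets, and its diversity.
#'
#' @param grid Result of [run_experiment_grid()].
#' @param diversity_weights Global weights for [diversity()] (default
#'   uniform).
#' @param variant Diversity variant.
#' @return Data frame with one row per method: gap (sum), mean gap per
#'   Pareto-optimal individual, diversity, and Pareto-subset size.
#' @export
evaluate_experiment <- function(grid, diversity_weights = NULL,
                                variant = "literal") {
  sets <- grid$sets
  K <- ncol(sets[[1L]]$values)
  if (is.null(diversity_weights)) diversity_weights <- rep(1 / K, K)
  pooled <- do.call(bind_evaluation_sets, c(unname(sets), list(label = "union")))
  p_union <- pareto_subset(pooled)
  out <- lapply(names(sets), function(m) {
    p0 <- pareto_subset(sets[[m]])
    gap <- pareto_optimality_gap(p0, p_union)
    data.frame(method = m,
               gap = as.numeric(gap),
               gap_mean = attr(gap, "mean"),
               diversity = diversity(p0, diversity_weights, variant = variant),
               n_pareto = nrow(p0$values))
  })
  do.call(rbind, out)
}
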