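test_that("recombination maps validate ranges and chromosome boundaries", {
  expect_error(recombination_map(letters[1:3], c(1, 1, 1), c(0.1, 0.7)),
               "0, 0.5")
  expect_error(recombination_map(letters[1:3], c(1, 2, 2), c(0.1, 0.1)),
               "boundary")
  m <- recombination_map(letters[1:4], c(1, 1, 2, 2), c(0.1, 0.5, 0.2))
  expect_equal(m$boundary, c(FALSE, TRUE, FALSE))
})

test_that("without crossovers a gamete is one intact parental haplotype", {
  set.seed(51)
  h1 <- rep(1L, 10)
  h2 <- rep(0L, 10)
  map <- recombination_map(paste0("l", 1:10), rep(1L, 10), rep(0, 9))
  picks <- replicate(200, {
    gm <- make_gamete(list(hap1 = h1, hap2 = h2), map)
    expect_true(all(gm == 1L) || all(gm == 0L))
    gm[1]
  })
  # both parental haplotypes transmitted, roughly equally often
  expect_gt(mean(picks), 0.35)
  expect_lt(mean(picks), 0.65)
})

test_that("gametes of a homozygote equal the haplotype regardless of the map", {
  set.seed(52)
  h <- rbinom(20, 1, 0.5)
  map <- recombination_map(paste0("l", 1:20), rep(1L, 20), runif(19, 0, 0.5))
  for (i in 1:10) {
    expect_equal(make_gamete(list(hap1 = h, hap2 = h), map), as.integer(h))
  }
})

test_that("every gamete is a mosaic of the parent's two haplotypes", {
  set.seed(53)
  g <- random_genotypes(1, 40, n_chrom = 4, homozygous = FALSE)
  map <- random_map(g)
  for (i in 1:25) {
    gm <- make_gamete(subset_individuals(g, 1), map)
    expect_true(all(gm == g$hap1[1, ] | gm == g$hap2[1, ]))
  }
})

test_that("phase-switch rates over 10,000 meioses match the map frequencies", {
  set.seed(54)
  r <- c(0.05, 0.2, 0.35, 0.5, 0.01)
  map <- recombination_map(paste0("l", 1:6), rep(1L, 6), r)
  parent <- list(hap1 = rep(1L, 6), hap2 = rep(0L, 6))
  n <- 10000
  pa <- subset_individuals(
    genotype_matrix(matrix(parent$hap1, 1), matrix(parent$hap2, 1),
                    locus_ids = map$locus_ids), 1)
  prog <- cross(pa, pa, n, map)
  # the fully heterozygous parent exposes the phase directly in hap1
  switches <- prog$hap1[, -1, drop = FALSE] != prog$hap1[, -6, drop = FALSE]
  counts <- colSums(switches)
  for (j in seq_along(r)) {
    expect_gte(counts[j], qbinom(0.005, n, r[j]))
    expect_lte(counts[j], qbinom(0.995, n, r[j]))
  }
})

test_that("crossing two distinct homozygotes gives identical heterozygous F1", {
  g <- genotype_matrix(rbind(rep(1L, 8), rep(0L, 8)),
                       rbind(rep(1L, 8), rep(0L, 8)),
                       individual_ids = c("p1", "p2"))
  map <- recombination_map(g$locus_ids, g$chrom, runif(7, 0, 0.5))
  set.seed(55)
  f1 <- cross(subset_individuals(g, 1), subset_individuals(g, 2), 30, map)
  expect_true(all(dosage(f1) == 1L))
  # selfing a homozygote reproduces it exactly
  self <- cross(subset_individuals(g, 1), subset_individuals(g, 1), 10, map)
  expect_true(all(dosage(self) == 2L))
})

test_that("progeny dosage means approach the parental average", {
  set.seed(56)
  g <- random_genotypes(2, 25, n_chrom = 2, homozygous = FALSE)
  map <- random_map(g)
  prog <- cross(subset_individuals(g, 1), subset_individuals(g, 2), 10000, map)
  expected <- colMeans(dosage(g))
  observed <- colMeans(dosage(prog))
  expect_lt(max(abs(observed - expected)), 0.05)
})

test_that("a one-generation run on the worked example selects the printed cross", {
  fx <- example1_founders()
  cfg <- breeding_config(S = 2, N = 10, T = 1, method = "lshaped",
                         weights = c(0.5, 0.5), seed = 7,
                         bounds_policy = "generation0")
  res <- run_breeding_program(fx$founders, fx$effects, fx$map, cfg)
  expect_equal(res$parents[[1]], c("i1", "i4"))
  expect_equal(nrow(res$values), 10)
})

test_that("breeding without genetic variation reproduces the founders", {
  h <- matrix(rep(c(1L, 0L), each = 6), 2, 6, byrow = TRUE)
  g <- genotype_matrix(rbind(h[1, ], h[1, ]), rbind(h[1, ], h[1, ]),
                       individual_ids = c("a", "b"))
  eff <- effect_matrix(matrix(c(1, -1, 2, 0.5, 1, -2, 3, 1, 0.2, 0.3, 1, 1),
                              6, 2), locus_ids = g$locus_ids)
  map <- recombination_map(g$locus_ids, g$chrom, runif(5, 0, 0.5))
  cfg <- breeding_config(S = 2, N = 1, T = 1, method = "index",
                         weights = c(1, 1), seed = 3)
  res <- run_breeding_program(g, eff, map, cfg)
  expect_equal(unname(res$population$hap1[1, ]), unname(g$hap1[1, ]))
  expect_equal(unname(res$population$hap2[1, ]), unname(g$hap2[1, ]))
  # a second generation would need two parents from a single progeny
  cfg2 <- breeding_config(S = 2, N = 1, T = 2, method = "index",
                          weights = c(1, 1), seed = 3)
  expect_error(run_breeding_program(g, eff, map, cfg2), "more individuals")
})

test_that("population size is exactly N in every bred generation", {
  set.seed(57)
  g <- random_genotypes(6, 20, n_chrom = 2)
  eff <- effect_matrix(matrix(rnorm(40), 20, 2), locus_ids = g$locus_ids)
  map <- random_map(g)
  cfg <- breeding_config(S = 2, N = 17, T = 3, method = "lshaped",
                         weights = c(0.4, 0.6), seed = 9)
  res <- run_breeding_program(g, eff, map, cfg)
  for (t in 2:4) expect_equal(nrow(res$trace[[t]]), 17)
})

test_that("selected parents attain the exact max-min optimum each generation", {
  set.seed(58)
  g <- random_genotypes(8, 24, n_chrom = 2)
  eff <- effect_matrix(matrix(rnorm(48), 24, 2), locus_ids = g$locus_ids)
  map <- random_map(g)
  cfg <- breeding_config(S = 2, N = 12, T = 2, method = "lshaped",
                         weights = c(0.5, 0.5), seed = 10,
                         bounds_policy = "attainable")
  res <- run_breeding_program(g, eff, map, cfg)
  for (t in 1:2) {
    vn <- normalize_values(res$trace[[t]], res$bounds)
    oracle <- oracle_lshaped_optima(vn, unclass(cfg$weights), 2)
    sel <- match(res$parents[[t]], rownames(res$trace[[t]]))
    expect_equal(oracle_lshaped_value(vn, unclass(cfg$weights), sel),
                 oracle$value, tolerance = 1e-12)
  }
})

test_that("breeding runs are bit-reproducible under a fixed seed", {
  set.seed(59)
  g <- random_genotypes(5, 15)
  eff <- effect_matrix(matrix(rnorm(30), 15, 2), locus_ids = g$locus_ids)
  map <- random_map(g)
  cfg <- breeding_config(S = 2, N = 8, T = 2, weights = c(0.3, 0.7), seed = 123)
  r1 <- run_breeding_program(g, eff, map, cfg)
  r2 <- run_breeding_program(g, eff, map, cfg)
  expect_identical(r1$population$hap1, r2$population$hap1)
  expect_identical(unclass(r1$values), unclass(r2$values))
})

test_that("a degenerate one-run grid equals the plain breeding program", {
  set.seed(60)
  g <- random_genotypes(6, 12)
  eff <- effect_matrix(matrix(rnorm(24), 12, 2), locus_ids = g$locus_ids)
  map <- random_map(g)
  cfg <- breeding_config(S = 2, N = 5, T = 2)
  grid <- run_experiment_grid(g, eff, map, methods = "lshaped",
                              weight_grid = 0.5, reps = 1, config = cfg,
                              master_seed = 77)
  cfg1 <- cfg
  cfg1$method <- "lshaped"
  cfg1$weights <- weight_vector(c(0.5, 0.5))
  cfg1$seed <- grid$runs$seed[1]
  direct <- run_breeding_program(g, eff, map, cfg1)
  vn <- normalize_values(genetic_values(rbind(unclass(direct$values))),
                         grid$pool_bounds)
  expect_equal(unname(grid$sets$lshaped$values), unname(unclass(vn)))
})

test_that("pooled grid sets count methods x weights x reps x N individuals", {
  set.seed(61)
  g <- random_genotypes(6, 12)
  eff <- effect_matrix(matrix(rnorm(24), 12, 2), locus_ids = g$locus_ids)
  map <- random_map(g)
  cfg <- breeding_config(S = 2, N = 4, T = 1)
  grid <- run_experiment_grid(g, eff, map, methods = c("index", "lshaped"),
                              weight_grid = c(0.3, 0.7), reps = 2,
                              config = cfg, master_seed = 5)
  for (m in c("index", "lshaped")) {
    expect_equal(nrow(grid$sets[[m]]$values), 2 * 2 * 4)
  }
  # provenance weights match the run weights
  expect_setequal(unique(grid$sets$index$weights[, 1]), c(0.3, 0.7))
})
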