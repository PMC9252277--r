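#' Phased diploid genotype matrix
#'
#' Container for phased, biallelic SNP genotypes. Each individual carries two
#' haplotypes (allele arrays with values 0/1) over a common set of loci; every
#' locus is assigned to a chromosome, and loci belonging to one chromosome must
#' be contiguous and ordered consistently with any recombination map used with
#' the object. The allele dosage of individual `i` at locus `j` is the sum of
#' its two haplotype alleles, so dosages lie in \{0, 1, 2\} and fully
#' homozygous (inbred) individuals have dosages in \{0, 2\}.
#'
#' @param hap1,hap2 Integer/numeric matrices (individuals x loci) with entries
#'   0 or 1; the two phased haplotypes of each individual.
#' @param individual_ids Character vector of individual identifiers; defaults
#'   to `rownames(hap1)` or `ind1, ind2, ...`.
#' @param locus_ids Character vector of locus identifiers; defaults to
#'   `colnames(hap1)` or `locus1, locus2, ...`.
#' @param chrom Integer vector, one chromosome label per locus. Loci of a
#'   chromosome must form one contiguous block.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(hap1, hap2,
                            individual_ids = NULL,
                            locus_ids = NULL,
                            chrom = NULL) {
  hap1 <- as.matrix(hap1)
  hap2 <- as.matrix(hap2)
  if (!identical(dim(hap1), dim(hap2))) {
    stop("hap1 and hap2 must have identical dimensions")
  }
  if (!all(hap1 %in% c(0, 1)) || !all(hap2 %in% c(0, 1))) {
    stop("haplotype alleles must be 0 or 1")
  }
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  n <- nrow(hap1)
  L <- ncol(hap1)
  if (is.null(individual_ids)) {
    individual_ids <- rownames(hap1)
    if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  }
  if (is.null(locus_ids)) {
    locus_ids <- colnames(hap1)
    if (is.null(locus_ids)) locus_ids <- paste0("locus", seq_len(L))
  }
  if (is.null(chrom)) chrom <- rep(1L, L)
  chrom <- as.integer(chrom)
  if (length(individual_ids) != n) stop("individual_ids length mismatch")
  if (length(locus_ids) != L) stop("locus_ids length mismatch")
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids")
  if (anyDuplicated(locus_ids)) stop("duplicated locus ids")
  if (length(chrom) != L) stop("chrom must have one entry per locus")
  if (anyDuplicated(rle(chrom)$values)) {
    stop("loci of a chromosome must be contiguous")
  }
  dimnames(hap1) <- dimnames(hap2) <- list(individual_ids, locus_ids)
  structure(
    list(hap1 = hap1, hap2 = hap2,
         individual_ids = individual_ids,
         locus_ids = locus_ids,
         chrom = chrom),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci on %d chromosome(s)\n",
              nrow(x$hap1), ncol(x$hap1), length(unique(x$chrom))))
  inbred <- all(x$hap1 == x$hap2)
  cat(sprintf("  fully homozygous: %s\n", if (inbred) "yes" else "no"))
  invisible(x)
}

#' Allele dosage matrix
#'
#' @param g A [genotype_matrix()].
#' @return Integer matrix (individuals x loci) with entries in \{0, 1, 2\}.
#' @export
dosage <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  g$hap1 + g$hap2
}

#' Number of individuals / loci in a genotype matrix
#' @param g A [genotype_matrix()].
#' @export
n_individuals <- function(g) length(g$individual_ids)

#' @rdname n_individuals
#' @export
n_loci <- function(g) length(g$locus_ids)

#' Subset a genotype matrix by individuals
#'
#' @param g A [genotype_matrix()].
#' @param idx Integer indices or character identifiers of individuals to keep.
#' @return A [genotype_matrix()] restricted to the requested individuals.
#' @export
subset_individuals <- function(g, idx) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(idx)) idx <- match(idx, g$individual_ids)
  if (anyNA(idx)) stop("unknown individual identifier")
  genotype_matrix(g$hap1[idx, , drop = FALSE], g$hap2[idx, , drop = FALSE],
                  individual_ids = g$individual_ids[idx],
                  locus_ids = g$locus_ids, chrom = g$chrom)
}

#' Combine genotype matrices over the same loci
#' @param ... `genotype_matrix` objects sharing loci and chromosomes.
#' @return A [genotype_matrix()] stacking all individuals.
#' @export
bind_individuals <- function(...) {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(g$locus_ids, ref$locus_ids) ||
        !identical(g$chrom, ref$chrom)) {
      stop("genotype matrices must share loci and chromosomes")
    }
  }
  genotype_matrix(do.call(rbind, lapply(gs, `[[`, "hap1")),
                  do.call(rbind, lapply(gs, `[[`, "hap2")),
                  individual_ids = unlist(lapply(gs, `[[`, "individual_ids")),
                  locus_ids = ref$locus_ids, chrom = ref$chrom)
}

#' Per-locus per-trait additive effect matrix
#'
#' Additive allele effects `beta[j, k]`: the contribution of one copy of the
#' alternate (1) allele at locus j to trait k, so that the genetic value of an
#' individual is `dosage %*% effects`.
#'
#' @param effects Numeric matrix (loci x traits) of finite effects.
#' @param locus_ids,trait_ids Identifiers; default to dimnames.
#' @return An object of class `effect_matrix` (a classed numeric matrix).
#' @export
effect_matrix <- function(effects, locus_ids = NULL, trait_ids = NULL) {
  effects <- as.matrix(effects)
  if (!is.numeric(effects) || !all(is.finite(effects))) {
    stop("effects must be finite numeric values")
  }
  if (is.null(locus_ids)) {
    locus_ids <- rownames(effects)
    if (is.null(locus_ids)) locus_ids <- paste0("locus", seq_len(nrow(effects)))
  }
  if (is.null(trait_ids)) {
    trait_ids <- colnames(effects)
    if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_len(ncol(effects)))
  }
  if (anyDuplicated(locus_ids)) stop("duplicated locus ids")
  dimnames(effects) <- list(locus_ids, trait_ids)
  class(effects) <- c("effect_matrix", class(effects))
  effects
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat(sprintf("effect_matrix: %d loci x %d trait(s)\n", nrow(x), ncol(x)))
  invisible(x)
}
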