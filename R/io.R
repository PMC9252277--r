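#' @title File formats
#' @description
#' All tabular files are UTF-8, tab-separated, with a mandatory header row;
#' lines starting with `#` are comments. Dialects:
#' * genotypes: `locus  chrom  <ind1>_h1  <ind1>_h2  <ind2>_h1 ...`, one row
#'   per locus, alleles 0/1 (phased);
#' * effects: `locus  <trait1>  <trait2> ...`, real-valued;
#' * recombination map: `locus_left  locus_right  r`;
#' * values: `individual  <trait1> ...` (a `# normalized` comment marks
#'   normalized files).
#' Loci are identified by id and ordered; VCF input follows the VCF 4.x
#' standard (1-based positions, phased `GT` with `|`); internal indices are
#' 0-free R indices (1-based).
#' @name lshaped-formats
NULL

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "")
}

write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read phased genotypes as TSV
#'
#' @param g A [genotype_matrix()].
#' @param path File path.
#' @return `read_genotypes()` returns a validated [genotype_matrix()];
#'   `write_genotypes()` returns `path` invisibly.
#' @seealso [lshaped-formats]
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  cols <- list(locus = g$locus_ids, chrom = g$chrom)
  for (i in seq_along(g$individual_ids)) {
    id <- g$individual_ids[i]
    cols[[paste0(id, "_h1")]] <- g$hap1[i, ]
    cols[[paste0(id, "_h2")]] <- g$hap2[i, ]
  }
  write_tsv(as.data.frame(cols, check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_genotypes
#' @param format `"tsv"` (native dialect) or `"vcf"` (phased VCF 4.x; requires
#'   the vcfR package; unphased or non-biallelic records are errors).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path))
  df <- read_tsv(path)
  if (!identical(names(df)[1:2], c("locus", "chrom"))) {
    stop("genotype TSV must start with columns 'locus' and 'chrom'")
  }
  hapcols <- names(df)[-(1:2)]
  if (length(hapcols) == 0L || length(hapcols) %% 2L != 0L) {
    stop("genotype TSV needs paired <id>_h1/<id>_h2 columns")
  }
  ids1 <- sub("_h1$", "", hapcols[c(TRUE, FALSE)])
  ids2 <- sub("_h2$", "", hapcols[c(FALSE, TRUE)])
  if (!identical(ids1, ids2)) stop("haplotype columns must pair as <id>_h1, <id>_h2")
  if (anyDuplicated(df$locus)) {
    stop(sprintf("duplicated locus id at line %d",
                 which(duplicated(df$locus))[1L] + 1L))
  }
  h <- as.matrix(df[, hapcols, drop = FALSE])
  if (!is.numeric(h) || !all(h %in% c(0, 1))) {
    stop("genotype TSV alleles must be 0 or 1")
  }
  genotype_matrix(t(h[, c(TRUE, FALSE), drop = FALSE]),
                  t(h[, c(FALSE, TRUE), drop = FALSE]),
                  individual_ids = ids1,
                  locus_ids = as.character(df$locus),
                  chrom = df$chrom)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  alt <- fix[, "ALT"]
  bad <- which(is.na(alt) | grepl(",", alt))
  if (length(bad)) {
    stop(sprintf("non-biallelic VCF record at %s:%s",
                 fix[bad[1L], "CHROM"], fix[bad[1L], "POS"]))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  unphased <- which(!grepl("^[01]\\|[01]$", gt))
  if (length(unphased)) {
    rec <- (unphased[1L] - 1L) %% nrow(gt) + 1L
    stop(sprintf("unphased or invalid GT for record %s:%s",
                 fix[rec, "CHROM"], fix[rec, "POS"]))
  }
  chrom_chr <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ord <- order(match(chrom_chr, unique(chrom_chr)), pos)
  gt <- gt[ord, , drop = FALSE]
  fix <- fix[ord, , drop = FALSE]
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == ".")) {
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  }
  h1 <- t(matrix(as.integer(substr(gt, 1L, 1L)), nrow(gt), ncol(gt)))
  h2 <- t(matrix(as.integer(substr(gt, 3L, 3L)), nrow(gt), ncol(gt)))
  genotype_matrix(h1, h2,
                  individual_ids = colnames(gt),
                  locus_ids = as.character(ids),
                  chrom = match(fix[, "CHROM"], unique(fix[, "CHROM"])))
}

#' Write / read per-locus per-trait effects as TSV
#'
#' @param effects An [effect_matrix()].
#' @param path File path.
#' @param genotypes Optional [genotype_matrix()]; when given, the locus set is
#'   checked to align with it.
#' @seealso [lshaped-formats]
#' @export
write_effects <- function(effects, path) {
  df <- data.frame(locus = rownames(effects), unclass(effects),
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path, genotypes = NULL) {
  df <- read_tsv(path)
  if (names(df)[1L] != "locus") stop("effects TSV must start with column 'locus'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("effects TSV has non-numeric cells")
  eff <- effect_matrix(m, locus_ids = as.character(df$locus))
  if (!is.null(genotypes) && !setequal(rownames(eff), genotypes$locus_ids)) {
    stop("effects loci do not align with the genotype loci")
  }
  eff
}

#' Write / read a recombination map as TSV
#'
#' The TSV stores one row per adjacent-locus interval (`locus_left`,
#' `locus_right`, `r`). On reading, chromosome assignment is taken from
#' `genotypes` when given; otherwise intervals with r equal to exactly 0.5 are interpreted
#' as chromosome boundaries.
#'
#' @param map A [recombination_map()].
#' @param path File path.
#' @param genotypes Optional [genotype_matrix()] supplying locus order and
#'   chromosomes.
#' @seealso [lshaped-formats]
#' @export
write_recomb_map <- function(map, path) {
  stopifnot(inherits(map, "recomb_map"))
  L <- length(map$locus_ids)
  df <- data.frame(locus_left = map$locus_ids[-L],
                   locus_right = map$locus_ids[-1L],
                   r = map$r)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(path, genotypes = NULL) {
  df <- read_tsv(path)
  need <- c("locus_left", "locus_right", "r")
  if (!all(need %in% names(df))) {
    stop("recombination TSV must have columns locus_left, locus_right, r")
  }
  if (!is.numeric(df$r)) stop("recombination TSV has non-numeric r cells")
  lids <- c(df$locus_left[1L], df$locus_right)
  if (!identical(df$locus_left[-1L], df$locus_right[-nrow(df)])) {
    stop("misordered loci: intervals must chain locus_left -> locus_right")
  }
  if (!is.null(genotypes)) {
    if (!identical(as.character(lids), genotypes$locus_ids)) {
      stop("recombination map loci do not align with the genotype loci")
    }
    chrom <- genotypes$chrom
  } else {
    chrom <- cumsum(c(TRUE, df$r == 0.5))
  }
  recombination_map(as.character(lids), chrom, df$r)
}

#' Write / read genetic values as TSV
#'
#' @param v A [genetic_values()] object.
#' @param path File path.
#' @seealso [lshaped-formats]
#' @export
write_values <- function(v, path) {
  df <- data.frame(individual = rownames(v), unclass(v), check.names = FALSE)
  write_tsv(df, path,
            comments = if (is_normalized(v)) "normalized" else character(0))
  invisible(path)
}

#' @rdname write_values
#' @export
read_values <- function(path) {
  first <- readLines(path, n = 5L)
  normalized <- any(grepl("^#\\s*normalized", first))
  df <- read_tsv(path)
  if (names(df)[1L] != "individual") {
    stop("values TSV must start with column 'individual'")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("values TSV has non-numeric cells")
  rownames(m) <- df$individual
  genetic_values(m, normalized = normalized)
}

#' Write an evaluation set as TSV
#'
#' Columns: `individual`, one column per trait, and provenance weight columns
#' `w_<trait>`.
#'
#' @param es An [evaluation_set()].
#' @param path File path.
#' @export
write_evaluation_set <- function(es, path) {
  stopifnot(inherits(es, "evaluation_set"))
  traits <- colnames(es$values)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(es$values)))
  df <- data.frame(individual = if (is.null(rownames(es$values)))
    paste0("ind", seq_len(nrow(es$values))) else rownames(es$values))
  df[traits] <- es$values
  df[paste0("w_", traits)] <- es$weights
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_evaluation_set
#' @param label Label for the set read back.
#' @export
read_evaluation_set <- function(path, label = "") {
  df <- read_tsv(path)
  wcols <- grep("^w_", names(df)[-1L], value = TRUE)
  tcols <- setdiff(names(df)[-1L], wcols)
  vals <- as.matrix(df[tcols])
  rownames(vals) <- df$individual
  wts <- if (length(wcols)) as.matrix(df[wcols]) else NULL
  evaluation_set(vals, wts, label = label)
}

#' Run record
#'
#' A machine-readable record of a command execution: the command and full
#' configuration, all seeds, md5 digests of the input files, the package
#' version and the output manifest -- enough to re-execute the run
#' bit-identically.
#'
#' @param command Command name.
#' @param config Named list of configuration values.
#' @param seeds Named list or vector of seeds.
#' @param inputs Character vector of input file paths (digested).
#' @param outputs Character vector of output file paths.
#' @return A list of class `run_record`.
#' @export
run_record <- function(command, config = list(), seeds = list(),
                       inputs = character(0), outputs = character(0)) {
  digests <- if (length(inputs)) {
    as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
  } else list()
  structure(list(command = command,
                 config = config,
                 seeds = seeds,
                 input_digests = digests,
                 outputs = as.list(outputs),
                 package_version = as.character(utils::packageVersion("lshaped"))),
            class = "run_record")
}

#' @rdname run_record
#' @param record A `run_record`.
#' @param path Output JSON path.
#' @export
write_run_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
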