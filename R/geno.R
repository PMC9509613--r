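# The geno_matrix container: individuals x variants dosages plus variant map.

#' Construct a geno_matrix
#'
#' Container for a dosage matrix with its variant map and line labels.
#' Dosages are coded 0/2 for the two homozygotes and 1 for heterozygotes;
#' missing values are allowed only when genotype noise has been injected.
#'
#' @param dosages integer matrix, individuals x variants, entries in
#'   \{0, 1, 2, NA\}; must carry row and column names.
#' @param map data frame with columns `variant_id`, `chrom`, `pos`,
#'   `is_chip`, one row per dosage column, positions strictly increasing
#'   within chromosome.
#' @param line character vector of line labels, one per individual.
#' @param genome optional [genome_config()] used to generate the data.
#' @param haplotypes optional list of two haplotype matrices `h1`, `h2`.
#' @return an object of class `geno_matrix`.
#' @export
new_geno_matrix <- function(dosages, map, line, genome = NULL,
                            haplotypes = NULL) {
  if (!is.matrix(dosages) || is.null(rownames(dosages)) ||
      is.null(colnames(dosages))) {
    stop_seqgp("`dosages` must be a matrix with row and column names",
               "integrity_error")
  }
  if (nrow(map) != ncol(dosages) ||
      !all(map$variant_id == colnames(dosages))) {
    stop_seqgp("variant map does not match dosage columns", "integrity_error")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop_seqgp("dosages must lie in {0, 1, 2} or be missing",
               "integrity_error")
  }
  bad_pos <- vapply(split(map$pos, map$chrom),
                    function(p) any(diff(p) <= 0) || any(p < 1), logical(1))
  if (any(bad_pos)) {
    stop_seqgp("variant positions must be >= 1 and strictly increasing within chromosome",
               "integrity_error")
  }
  if (length(line) != nrow(dosages)) {
    stop_seqgp("`line` must have one label per individual", "integrity_error")
  }
  names(line) <- rownames(dosages)
  structure(list(dosages = dosages, map = map, line = line,
                 genome = genome, haplotypes = haplotypes),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d variants (%d chip), %d line(s)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$map$is_chip),
              length(unique(x$line))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a geno_matrix
#'
#' @param x a `geno_matrix`.
#' @param individuals individual ids (or logical/integer index) to keep.
#' @param variants variant ids (or logical/integer index) to keep.
#' @return the subset `geno_matrix`.
#' @export
subset_geno <- function(x, individuals = NULL, variants = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  ri <- if (is.null(individuals)) seq_len(nrow(x$dosages)) else individuals
  ci <- if (is.null(variants)) seq_len(ncol(x$dosages)) else variants
  if (is.character(ci)) ci <- match(ci, x$map$variant_id)
  d <- x$dosages[ri, ci, drop = FALSE]
  haps <- x$haplotypes
  if (!is.null(haps)) {
    haps <- list(h1 = haps$h1[ri, ci, drop = FALSE],
                 h2 = haps$h2[ri, ci, drop = FALSE])
  }
  new_geno_matrix(d, x$map[ci, , drop = FALSE],
                  x$line[rownames(d)], genome = x$genome, haplotypes = haps)
}

#' Per-variant allele frequency
#'
#' Frequency of the counted allele, `mean(dosage) / 2`, over all
#' individuals or per line.
#'
#' @param genotypes a `geno_matrix`.
#' @param by_line if `TRUE`, return a lines x variants matrix.
#' @return numeric vector (or matrix) of allele frequencies in \[0, 1\].
#' @export
allele_freq <- function(genotypes, by_line = FALSE) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!by_line) {
    return(colMeans(genotypes$dosages, na.rm = TRUE) / 2)
  }
  lines <- sort(unique(genotypes$line))
  out <- t(vapply(lines, function(l) {
    colMeans(genotypes$dosages[genotypes$line == l, , drop = FALSE],
             na.rm = TRUE) / 2
  }, numeric(ncol(genotypes$dosages))))
  rownames(out) <- lines
  out
}

#' Per-variant minor allele frequency
#'
#' @param genotypes a `geno_matrix`.
#' @return numeric vector of MAF values in \[0, 0.5\].
#' @export
variant_maf <- function(genotypes) {
  p <- allele_freq(genotypes)
  pmin(p, 1 - p)
}
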