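# Plain-text interchange: dosage-matrix TSV (canonical), VCF (optional),
# pedigree / trait / variant-set / GWAS tables. All tables may carry '#'
# header comments (config hash, seed) which readers skip.

# write a data frame as TSV with optional '#' comment lines
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  # fixed %.10g formatting for bit-exact round trips
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# read a TSV written by write_tsv, skipping '#' comment lines
read_tsv <- function(path, colClasses = NULL) {
  first <- readLines(path, n = 200L)
  skip <- sum(cumprod(startsWith(first, "#")))
  out <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = colClasses %||% NA)
  out
}

#' Write genotypes to disk
#'
#' `format = "dosage_tsv"` writes the canonical pair: `<path>` with columns
#' `id`, `line`, then one column per variant id, and `<path>.map` with the
#' variant map. `format = "vcf"` writes a single VCFv4.2 file with GT
#' fields (0/0, 0/1, 1/1, ./.), a `CHIP` INFO flag for chip membership and
#' `##seqgp_line` header lines carrying the line labels.
#'
#' @param genotypes a `geno_matrix`.
#' @param path output file path.
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @param comments optional character vector of header comments.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path,
                            format = c("dosage_tsv", "vcf"),
                            comments = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    df <- data.frame(id = rownames(genotypes$dosages),
                     line = unname(genotypes$line),
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(genotypes$dosages, check.names = FALSE))
    write_tsv(df, path, comments)
    write_tsv(genotypes$map, paste0(path, ".map"), comments)
    return(invisible(path))
  }
  # VCF
  con <- file(path, "w")
  on.exit(close(con))
  ids <- rownames(genotypes$dosages)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=seqgp",
    "##INFO=<ID=CHIP,Number=0,Type=Flag,Description=\"Marker-array panel member\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##seqgp_line=", ids, "=", unname(genotypes$line)),
    if (!is.null(comments)) paste0("##seqgp_comment=", comments),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  d <- genotypes$dosages
  for (j in seq_len(ncol(d))) {
    gt <- ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1L])
    writeLines(paste(c(genotypes$map$chrom[j], genotypes$map$pos[j],
                       genotypes$map$variant_id[j], "A", "B", ".", "PASS",
                       if (genotypes$map$is_chip[j]) "CHIP" else ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from disk
#'
#' Inverse of [write_genotypes()]: `read_genotypes(write_genotypes(x))`
#' recovers the dosage matrix, map and line labels exactly. VCF input must
#' be diploid and biallelic; multi-allelic records and non-diploid GT
#' fields are rejected with the offending site named.
#'
#' @param path input path.
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @return a `geno_matrix`.
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_seqgp(paste("no such file:", path),
                                     "input_error")
  if (format == "dosage_tsv") {
    df <- read_tsv(path)
    map <- read_tsv(paste0(path, ".map"))
    map$is_chip <- as.logical(map$is_chip)
    dos <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(dos) <- "integer"
    rownames(dos) <- df$id
    return(new_geno_matrix(dos, map, df$line))
  }
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr_i)) stop_seqgp("VCF has no #CHROM header line",
                                 "parse_error")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]

  line_meta <- sub("^##seqgp_line=", "", meta[startsWith(meta, "##seqgp_line=")])
  line_map <- stats::setNames(sub("^[^=]*=", "", line_meta),
                              sub("=.*$", "", line_meta))
  gt_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
              "./." = NA_integer_, ".|." = NA_integer_)

  n <- length(samples)
  m <- length(body)
  dos <- matrix(NA_integer_, n, m)
  map <- data.frame(variant_id = character(m), chrom = integer(m),
                    pos = integer(m), is_chip = logical(m),
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- strsplit(body[j], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + n) {
      stop_seqgp(sprintf("malformed VCF record at data line %d", j),
                 "parse_error")
    }
    if (grepl(",", f[5], fixed = TRUE)) {
      stop_seqgp(sprintf("multi-allelic site not supported: %s (line %d)",
                         f[3], j), "unsupported_input_error")
    }
    gt <- sub(":.*$", "", f[-(1:9)])
    val <- gt_map[gt]
    if (any(is.na(val) & !gt %in% c("./.", ".|."))) {
      stop_seqgp(sprintf("unsupported (non-diploid?) GT at site %s", f[3]),
                 "unsupported_input_error")
    }
    dos[, j] <- unname(val)
    map$variant_id[j] <- f[3]
    map$chrom[j] <- as.integer(f[1])
    map$pos[j] <- as.integer(f[2])
    map$is_chip[j] <- grepl("(^|;)CHIP(;|$)", f[8])
  }
  rownames(dos) <- samples
  colnames(dos) <- map$variant_id
  new_geno_matrix(dos, map, unname(line_map[samples]))
}

#' Write / read a pedigree table
#'
#' Six canonical columns (`id`, `sire`, `dam`, `line`, `generation`,
#' `birth_order`) plus `sex` when present; missing parents are stored as
#' `NA`.
#'
#' @param pedigree pedigree data frame.
#' @param path file path.
#' @param comments optional header comments.
#' @return `path` / the pedigree.
#' @export
write_pedigree <- function(pedigree, path, comments = NULL) {
  write_tsv(pedigree, path, comments)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- read_tsv(path, colClasses = "character")
  ped$generation <- as.integer(ped$generation)
  ped$birth_order <- as.integer(ped$birth_order)
  for (col in c("sire", "dam")) ped[[col]][ped[[col]] == "NA"] <- NA_character_
  validate_pedigree(ped)
}

#' Write / read a variant set
#'
#' TSV with columns `variant_id`, `provenance` plus a header comment
#' carrying name, window size and p threshold, so that a persisted GWAS +
#' variant-set pair reproduces selections exactly.
#'
#' @param set a `variant_set`.
#' @param path file path.
#' @return `path` / the `variant_set`.
#' @export
write_variant_set <- function(set, path) {
  stopifnot(inherits(set, "variant_set"))
  write_tsv(data.frame(variant_id = set$variant_ids,
                       provenance = set$provenance,
                       stringsAsFactors = FALSE),
            path,
            comments = c(paste0("name=", set$name),
                         paste0("window_size_bp=", set$window_size_bp),
                         paste0("p_threshold=",
                                format(set$p_threshold, digits = 17))))
  invisible(path)
}

#' @rdname write_variant_set
#' @export
read_variant_set <- function(path) {
  first <- readLines(path, n = 10L)
  cm <- sub("^# ", "", first[startsWith(first, "#")])
  get <- function(k) sub(paste0("^", k, "="), "", cm[startsWith(cm, paste0(k, "="))])
  df <- read_tsv(path)
  new_variant_set(get("name"), df$variant_id, df$provenance,
                  window_size_bp = suppressWarnings(as.integer(get("window_size_bp"))),
                  p_threshold = suppressWarnings(as.numeric(get("p_threshold"))))
}

#' Write / read a GWAS result table
#'
#' @param gwas a `gwas_result`.
#' @param path file path.
#' @param comments optional header comments.
#' @return `path` / the `gwas_result`.
#' @export
write_gwas <- function(gwas, path, comments = NULL) {
  write_tsv(as.data.frame(gwas), path, comments)
}

#' @rdname write_gwas
#' @export
read_gwas <- function(path) {
  out <- read_tsv(path)
  out$tested <- as.logical(out$tested)
  class(out) <- c("gwas_result", "data.frame")
  out
}
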