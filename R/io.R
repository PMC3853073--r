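#' Read a genotype matrix from TSV or VCF
#'
#' TSV input is samples-by-SNPs with a header row: the first column holds
#' sample identifiers and the remaining columns hold additive minor-allele
#' counts (0/1/2, `NA` for missing calls).  VCF input (v4.x) keeps
#' biallelic SNP sites only (others are skipped with a warning), treats
#' missing GT as a missing call, ignores phasing, and orients the coding
#' so that 2 is always the minor-allele homozygote: when the ALT allele
#' frequency exceeds 0.5 the dosage is flipped.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return Integer genotype matrix with sample row names and SNP column
#'   names; VCF input also carries a `snp_info` attribute (snp_id, chrom,
#'   pos, flipped).
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "tsv"
    }
  }
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       show_col_types = FALSE, name_repair = "minimal")
  ids <- as.character(d[[1]])
  raw <- as.matrix(d[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.integer(raw), nrow(raw), ncol(raw),
                               dimnames = list(ids, colnames(raw))))
  bad <- (is.na(m) & !(is.na(raw) | raw %in% c("NA", ""))) |
    (!is.na(m) & !(m %in% 0:2))
  if (any(bad)) {
    row <- which(rowSums(bad) > 0)[1]
    stop("malformed genotype values at data line ", row, " of ", path)
  }
  m
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning(sum(!bi), " non-biallelic site(s) skipped")
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  alt_freq <- rowMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  m <- t(dos)
  colnames(m) <- ids
  attr(m, "snp_info") <- tibble::tibble(
    snp_id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    flipped = flip
  )
  m
}

#' Write / read genotype and phenotype matrices as TSV
#'
#' Lossless round-trip formats: one header row, first column `sample_id`,
#' remaining columns SNPs (0/1/2/NA) or traits (reals).
#'
#' @param m matrix with sample row names.
#' @param path file path.
#' @return `path`, invisibly (writers); a matrix (readers).
#' @export
write_genotypes <- function(m, path) {
  d <- tibble::as_tibble(m, rownames = "sample_id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_phenotypes <- function(m, path) {
  d <- tibble::as_tibble(m, rownames = "sample_id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_phenotypes <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, name_repair = "minimal")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read gene intervals from a BED file
#'
#' Standard BED (3+ columns, 0-based half-open intervals, tab-separated,
#' optional fourth name column).  Intervals are kept in BED coordinates;
#' [map_snps_to_genes()] converts internally.
#'
#' @param path BED file path.
#' @return Tibble with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_bed <- function(path) {
  # BED rows may legitimately differ in column count (the name column is
  # optional), which readr would flag as a parsing problem
  d <- suppressWarnings(readr::read_tsv(
    path,
    col_names = FALSE, comment = "#", show_col_types = FALSE
  ))
  if (ncol(d) < 3) stop("BED file needs at least 3 columns: ", path)
  out <- tibble::tibble(
    chrom = as.character(d[[1]]),
    start = as.integer(d[[2]]),
    end = as.integer(d[[3]]),
    gene_id = if (ncol(d) >= 4) as.character(d[[4]]) else NA_character_
  )
  anon <- is.na(out$gene_id)
  out$gene_id[anon] <- paste0(out$chrom[anon], ":", out$start[anon], "-",
                              out$end[anon])
  out
}
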