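#' Assemble a paired genotype/phenotype data set
#'
#' Bundles an `N x P` additive-coded genotype matrix with an `N x Q`
#' real-valued phenotype matrix, after validating that both sides describe
#' the same samples in the same order.  Genotypes count minor alleles at a
#' biallelic SNP: 2 for the minor-allele homozygote, 1 for a heterozygote
#' and 0 for the major-allele homozygote.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns,
#'   entries in `{0, 1, 2}` (or `NA` for missing calls).  Row and column
#'   names are used as sample and SNP identifiers; defaults are generated
#'   when absent.
#' @param phenotypes numeric matrix of traits, samples in rows, traits in
#'   columns, finite entries, rows aligned with `genotypes`.
#' @param snp_info optional tibble with columns `snp_id`, `chrom`, `pos`
#'   (1-based base-pair position) used for SNP-to-gene mapping.
#' @return An object of class `mvrf_data`: a list with elements
#'   `genotypes`, `phenotypes` and `snp_info`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 0L, 1L), nrow = 3)
#' y <- matrix(rnorm(6), nrow = 3)
#' d <- mvrf_data(g, y)
#' d
#' @export
mvrf_data <- function(genotypes, phenotypes, snp_info = NULL) {
  genotypes <- validate_genotypes(genotypes)
  if (is.data.frame(phenotypes)) phenotypes <- as.matrix(phenotypes)
  if (!is.matrix(phenotypes) || !is.numeric(phenotypes)) {
    stop("`phenotypes` must be a numeric matrix (samples x traits)")
  }
  if (nrow(genotypes) != nrow(phenotypes)) {
    stop("genotypes and phenotypes must describe the same samples: ",
         nrow(genotypes), " vs ", nrow(phenotypes), " rows")
  }
  if (nrow(genotypes) < 2L) stop("at least 2 samples are required")
  if (!all(is.finite(phenotypes))) stop("phenotypes must be finite")
  if (is.null(rownames(phenotypes))) {
    rownames(phenotypes) <- rownames(genotypes)
  } else if (!identical(rownames(phenotypes), rownames(genotypes))) {
    stop("phenotype rows are not aligned with genotype rows")
  }
  if (is.null(colnames(phenotypes))) {
    colnames(phenotypes) <- paste0("trait_", seq_len(ncol(phenotypes)))
  }
  if (!is.null(snp_info)) {
    snp_info <- tibble::as_tibble(snp_info)
    stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snp_info)))
    if (!all(colnames(genotypes) %in% snp_info$snp_id)) {
      stop("`snp_info` does not cover all SNPs in `genotypes`")
    }
  }
  structure(
    list(genotypes = genotypes, phenotypes = phenotypes, snp_info = snp_info),
    class = "mvrf_data"
  )
}

validate_genotypes <- function(genotypes) {
  if (is.data.frame(genotypes)) genotypes <- as.matrix(genotypes)
  if (!is.matrix(genotypes)) stop("`genotypes` must be a matrix")
  storage.mode(genotypes) <- "integer"
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    stop("genotypes must be additive minor-allele counts in {0, 1, 2}; ",
         sum(bad), " offending entries")
  }
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("sample_", seq_len(nrow(genotypes)))
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("snp_", seq_len(ncol(genotypes)))
  }
  if (anyDuplicated(rownames(genotypes))) stop("sample ids must be unique")
  if (anyDuplicated(colnames(genotypes))) stop("snp ids must be unique")
  genotypes
}

#' @method print mvrf_data
#' @export
print.mvrf_data <- function(x, ...) {
  cat("<mvrf_data> ", nrow(x$genotypes), " samples, ",
      ncol(x$genotypes), " SNPs, ", ncol(x$phenotypes), " traits\n", sep = "")
  n_miss <- sum(is.na(x$genotypes))
  if (n_miss > 0) cat("  ", n_miss, " missing genotype calls\n", sep = "")
  invisible(x)
}

#' Squared pairwise phenotype distances
#'
#' Precomputes the symmetric `N x N` matrix of squared inter-sample
#' phenotype distances that backs the distance-based node-splitting
#' criterion.  Under `"standardized"` every trait is first divided by its
#' whole-sample standard deviation, so the distance matches a diagonal
#' covariance weighting estimated once at the root.
#'
#' @param phenotypes numeric matrix, samples in rows.
#' @param metric `"euclidean"` or `"standardized"`.
#' @param var_floor lower bound applied to per-trait variances before
#'   standardization, guarding constant traits.
#' @return Squared-distance matrix with attribute `metric_name`.
#' @export
pairwise_phenotype_distance <- function(phenotypes,
                                        metric = c("euclidean", "standardized"),
                                        var_floor = 1e-8) {
  metric <- match.arg(metric)
  y <- as.matrix(phenotypes)
  if (metric == "standardized") {
    v <- pmax(apply(y, 2, var), var_floor)
    y <- sweep(y, 2, sqrt(v), "/")
  }
  g <- tcrossprod(y)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2 <- (d2 + t(d2)) / 2
  attr(d2, "metric_name") <- if (metric == "euclidean") {
    "euclidean"
  } else {
    "standardized-euclidean"
  }
  d2
}
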