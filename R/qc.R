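#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts
#' against the `p^2, 2pq, q^2` expectations computed from the observed
#' allele frequency.  Monomorphic SNPs return `p = 1`.  Vectorised over
#' SNPs; invariant to swapping the allele labels.
#'
#' @param n_aa,n_ab,n_bb counts of the three genotype classes.
#' @return Tibble with columns `chisq` and `p_value`.
#' @examples
#' hwe_test(50, 30, 20)
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (any(n <= 0)) stop("each SNP needs at least one called genotype")
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  e <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  o <- cbind(n_aa, n_ab, n_bb)
  chisq <- rowSums(ifelse(e > 0, (o - e)^2 / e, 0))
  mono <- p == 0 | p == 1
  chisq[mono] <- 0
  tibble::tibble(chisq = chisq, p_value = pchisq(chisq, df = 1,
                                                 lower.tail = FALSE))
}

#' SNP quality-control filtering
#'
#' Removes SNPs with a genotyping call rate below `call_rate_min`, a
#' Hardy-Weinberg equilibrium p-value below `hwe_p_min`, or a minor allele
#' frequency below `maf_min` (all strict inequalities, matching the usual
#' "< 95%", "< 0.1" phrasing).  Filters are evaluated in the order call
#' rate, HWE, MAF, and each removal is attributed to the first filter that
#' fails, so removed + surviving = input.  With `autosomes_only = TRUE`
#' (requires `snp_info`), non-autosomal SNPs are removed first.
#'
#' @param genotypes genotype matrix (may contain `NA`).
#' @param snp_info optional tibble with `snp_id`, `chrom` (needed for the
#'   autosome filter).
#' @param call_rate_min,hwe_p_min,maf_min filter thresholds.
#' @param autosomes_only keep autosomal SNPs (chromosomes named 1-22,
#'   optionally "chr"-prefixed) only.
#' @return List with `genotypes` (surviving columns) and `report` (list:
#'   `per_snp` tibble of call_rate/hwe_p/maf/removed_by, `summary` tibble
#'   of removal counts per filter).
#' @export
qc_filter <- function(genotypes, snp_info = NULL, call_rate_min = 0.95,
                      hwe_p_min = 5e-7, maf_min = 0.1,
                      autosomes_only = FALSE) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, maf_min >= 0, maf_min <= 0.5)
  n <- nrow(genotypes)
  call_rate <- colMeans(!is.na(genotypes))
  n_aa <- colSums(genotypes == 0L, na.rm = TRUE)
  n_ab <- colSums(genotypes == 1L, na.rm = TRUE)
  n_bb <- colSums(genotypes == 2L, na.rm = TRUE)
  called <- n_aa + n_ab + n_bb
  hwe_p <- rep(NA_real_, ncol(genotypes))
  ok <- called > 0
  hwe_p[ok] <- hwe_test(n_aa[ok], n_ab[ok], n_bb[ok])$p_value
  f <- ifelse(called > 0, (2 * n_bb + n_ab) / (2 * called), NA_real_)
  maf <- pmin(f, 1 - f)
  removed_by <- rep(NA_character_, ncol(genotypes))
  if (autosomes_only) {
    if (is.null(snp_info)) stop("`autosomes_only` requires `snp_info`")
    chrom <- sub("^chr", "", snp_info$chrom[
      match(colnames(genotypes), snp_info$snp_id)
    ])
    removed_by[!chrom %in% as.character(1:22)] <- "non_autosomal"
  }
  miss <- is.na(removed_by)
  removed_by[miss & (called == 0 | call_rate < call_rate_min)] <- "call_rate"
  miss <- is.na(removed_by)
  removed_by[miss & hwe_p < hwe_p_min] <- "hwe"
  miss <- is.na(removed_by)
  removed_by[miss & maf < maf_min] <- "maf"
  keep <- is.na(removed_by)
  if (!any(keep)) stop("all SNPs removed by QC filters")
  per_snp <- tibble::tibble(
    snp_id = colnames(genotypes), call_rate = call_rate, hwe_p = hwe_p,
    maf = maf, removed_by = removed_by
  )
  filters <- c("non_autosomal", "call_rate", "hwe", "maf")
  summary <- tibble::tibble(
    filter = c(filters, "surviving"),
    n = c(vapply(filters, function(f) sum(removed_by == f, na.rm = TRUE),
                 integer(1)),
          sum(keep))
  )
  list(
    genotypes = genotypes[, keep, drop = FALSE],
    report = list(per_snp = per_snp, summary = summary)
  )
}

#' Impute missing genotypes by the per-SNP mode
#'
#' Every missing call is replaced by the SNP's most frequent genotype,
#' with ties broken towards the smaller value, so the result is
#' deterministic.  Trees require complete genotypes; call-rate QC should
#' run first, and a SNP with no observed call is an error.
#'
#' @param genotypes genotype matrix (0/1/2/`NA`).
#' @return The matrix with all `NA` replaced.
#' @export
impute_missing <- function(genotypes) {
  miss_col <- which(colSums(is.na(genotypes)) > 0)
  if (length(miss_col) == 0L) return(genotypes)
  for (j in miss_col) {
    g <- genotypes[, j]
    obs <- g[!is.na(g)]
    if (length(obs) == 0L) {
      stop("SNP ", colnames(genotypes)[j],
           " is entirely missing; it should have failed call-rate QC")
    }
    counts <- tabulate(obs + 1L, nbins = 3L)
    mode_g <- which.max(counts) - 1L # which.max takes the first maximum
    genotypes[is.na(g), j] <- mode_g
  }
  genotypes
}
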