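#' Allele frequencies of the counted allele
#'
#' Per-marker frequency p = mean(dosage)/2 over non-missing calls; the
#' quantity that centers and scales the VanRaden genomic relationship
#' matrix.
#'
#' @param panel A `genotype_panel` or dosage matrix.
#' @return Named numeric vector of frequencies.
#' @export
allele_frequencies <- function(panel) {
  M <- dosage_matrix(panel)
  nonmiss <- colSums(!is.na(M))
  if (any(nonmiss == 0L)) {
    stop("marker(s) with no non-missing calls: ",
         paste(colnames(M)[nonmiss == 0L], collapse = ", "))
  }
  colMeans(M, na.rm = TRUE) / 2
}

# 1-df chi-square Hardy-Weinberg test on genotype counts (no continuity
# correction). Returns NA for fixed markers (p in {0,1}); the MAF filter
# removes those before the HWE p-value is ever consulted.
hwe_pvalues <- function(panel) {
  M <- dosage_matrix(panel)
  n0 <- colSums(M == 0L, na.rm = TRUE)
  n1 <- colSums(M == 1L, na.rm = TRUE)
  n2 <- colSums(M == 2L, na.rm = TRUE)
  N <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * N)
  e0 <- N * (1 - p)^2
  e1 <- N * 2 * p * (1 - p)
  e2 <- N * p^2
  chi2 <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  pv <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  pv[p <= 0 | p >= 1] <- NA_real_
  names(pv) <- colnames(M)
  pv
}

#' Marker quality control
#'
#' Removes a marker when its minor allele frequency, call rate, or
#' Hardy-Weinberg chi-square p-value falls below the thresholds
#' (defaults follow the usual 50K-chip practice: MAF < 0.05, call rate
#' < 0.90, HWE p < 1e-7). Surviving markers keep their order; the filter
#' is idempotent. No per-individual filtering is done.
#'
#' @param panel A `genotype_panel`.
#' @param maf_min Minimum minor allele frequency.
#' @param call_min Minimum per-marker call rate.
#' @param hwe_p_min Minimum HWE p-value.
#' @return List with `panel` (filtered `genotype_panel`) and `report`, a
#'   list holding the per-marker table (`maf`, `call_rate`, `hwe_p`,
#'   `removed`, `reason`) and counts `n_input`, `n_removed`, `n_retained`.
#' @export
qc_filter <- function(panel, maf_min = 0.05, call_min = 0.90,
                      hwe_p_min = 1e-7) {
  stopifnot(inherits(panel, "genotype_panel"))
  M <- panel$dosage
  if (ncol(M) == 0L) stop("empty genotype panel")
  call_rate <- colMeans(!is.na(M))
  counted <- colSums(!is.na(M))
  p <- ifelse(counted > 0L, colMeans(M, na.rm = TRUE) / 2, NA_real_)
  maf <- pmin(p, 1 - p)
  hwe <- hwe_pvalues(panel)
  fail_maf <- is.na(maf) | maf < maf_min
  fail_call <- call_rate < call_min
  fail_hwe <- !is.na(hwe) & hwe < hwe_p_min
  removed <- fail_maf | fail_call | fail_hwe
  reason <- rep(NA_character_, ncol(M))
  reason[fail_hwe] <- "hwe"
  reason[fail_call] <- "call_rate"
  reason[fail_maf] <- "maf"
  tab <- data.frame(marker = colnames(M), maf = maf, call_rate = call_rate,
                    hwe_p = hwe, removed = removed, reason = reason,
                    row.names = NULL, stringsAsFactors = FALSE)
  keep <- which(!removed)
  out <- genotype_panel(M[, keep, drop = FALSE],
                        panel$map[keep, , drop = FALSE])
  list(panel = out,
       report = list(table = tab,
                     n_input = ncol(M),
                     n_removed = sum(removed),
                     n_retained = length(keep)))
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing call by the marker's mean dosage 2p rounded to
#' the nearest of 0/1/2. Deterministic, linkage-agnostic filling intended
#' for panels with little missingness after QC.
#'
#' @param panel A `genotype_panel`.
#' @return A complete `genotype_panel`; non-missing entries untouched.
#' @export
naive_impute <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  M <- panel$dosage
  if (!anyNA(M)) return(panel)
  p <- allele_frequencies(panel)   # errors on all-missing markers
  fill <- as.integer(pmin(pmax(round(2 * p), 0), 2))
  miss <- which(is.na(M), arr.ind = TRUE)
  M[miss] <- fill[miss[, 2L]]
  genotype_panel(M, panel$map)
}
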