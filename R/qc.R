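# Marker quality control on locus NSS records.

#' Marker quality-control filter
#'
#' Removes loci that are non-biallelic, have minor allele frequency below
#' `maf_min`, call rate below `callrate_min`, or (when `hom_min` is given)
#' homozygote fraction below `hom_min` — the homozygosity screen used for
#' inbred-line panels, off by default for outbred data. All comparisons are
#' strict (`<`), so a locus sitting exactly on a threshold is kept. Each
#' removed locus carries the first failing reason, checked in the order
#' `non-biallelic`, `maf`, `callrate`, `homozygosity`. The filter is
#' idempotent.
#'
#' @param loci An `nss` object or its `loci` data frame.
#' @param maf_min,callrate_min Thresholds in `[0, 1]` (defaults 0.05 and
#'   0.998, the conventional dense-panel settings).
#' @param hom_min Optional homozygosity threshold in `[0, 1]` (e.g. 0.99
#'   for inbred lines); requires a `hom_rate` column, which the `.lnss`
#'   exchange format does not carry — apply this filter at encode time.
#' @return A list with `kept` (same shape as the input) and `removed`
#'   (data frame with a `reason` column).
#' @export
qc_filter <- function(loci, maf_min = 0.05, callrate_min = 0.998,
                      hom_min = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1, callrate_min >= 0, callrate_min <= 1)
  if (!is.null(hom_min)) stopifnot(hom_min >= 0, hom_min <= 1)
  if (inherits(loci, "nss")) {
    res <- qc_filter(loci$loci, maf_min, callrate_min, hom_min)
    kept <- loci
    kept$loci <- res$kept
    return(list(kept = kept, removed = res$removed))
  }
  if (nrow(loci) == 0L)
    return(list(kept = loci, removed = cbind(loci, reason = character(0))))
  biallelic <- if (!is.null(loci$biallelic)) loci$biallelic else TRUE
  maf <- pmin(loci$freq_a1, 1 - loci$freq_a1)
  reason <- rep(NA_character_, nrow(loci))
  reason[is.na(reason) & !biallelic] <- "non-biallelic"
  reason[is.na(reason) & maf < maf_min] <- "maf"
  reason[is.na(reason) & loci$call_rate < callrate_min] <- "callrate"
  if (!is.null(hom_min)) {
    if (is.null(loci$hom_rate))
      stop("hom_min given but loci carry no hom_rate column", call. = FALSE)
    reason[is.na(reason) & !is.na(loci$hom_rate) &
             loci$hom_rate < hom_min] <- "homozygosity"
  }
  removed <- loci[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = loci[is.na(reason), , drop = FALSE], removed = removed)
}
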