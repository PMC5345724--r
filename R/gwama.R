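# Consortium-style meta-analysis on per-cohort NSS: allele alignment,
# per-cohort OATH fits for a chosen covariate subset, inverse-variance
# fixed-effects pooling. Because each cohort ships its full NSS once, the
# central hub can switch the covariate subset freely without asking the
# cohorts to re-export anything.

.palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Align a locus record onto reference alleles
#'
#' If the cohort's allele pair matches the reference exactly the record is
#' returned unchanged; if it is the swapped pair, the effect allele is
#' flipped: `cov_xy` and every `cov_xz` are negated, `freq_a1` becomes
#' `1 - freq_a1`, `var_x` is unchanged and the alleles are swapped. Any
#' other pair is incompatible (strand flips are **not** inferred).
#'
#' @param locus A [locus_nss()] or one-row loci-table slice.
#' @param ref_a1,ref_a2 Reference effect / other allele.
#' @return List with `locus` (aligned record or `NULL`), `flipped`
#'   (logical) and `status` (`"match"`, `"flipped"` or
#'   `"allele-mismatch"`).
#' @export
align_alleles <- function(locus, ref_a1, ref_a2) {
  locus <- as_locus_nss(locus)
  if (identical(locus$a1, ref_a1) && identical(locus$a2, ref_a2))
    return(list(locus = locus, flipped = FALSE, status = "match"))
  if (identical(locus$a1, ref_a2) && identical(locus$a2, ref_a1)) {
    locus$a1 <- ref_a1
    locus$a2 <- ref_a2
    locus$freq_a1 <- 1 - locus$freq_a1
    locus$cov_xy <- -locus$cov_xy
    locus$cov_xz <- -locus$cov_xz
    return(list(locus = locus, flipped = TRUE, status = "flipped"))
  }
  list(locus = NULL, flipped = NA, status = "allele-mismatch")
}

# Vectorised allele alignment of a loci table against a reference map.
# Returns the table with flipped rows negated plus status/flip columns.
.align_loci_table <- function(loci, ref) {
  idx <- match(loci$snp_id, ref$snp_id)
  stopifnot(!anyNA(idx))
  r1 <- ref$a1[idx]
  r2 <- ref$a2[idx]
  same <- loci$a1 == r1 & loci$a2 == r2
  swap <- loci$a1 == r2 & loci$a2 == r1
  status <- ifelse(same, "match", ifelse(swap, "flipped", "allele-mismatch"))
  covcols <- c("cov_xy", grep("^cov_xz", names(loci), value = TRUE))
  if (any(swap)) {
    for (cc in covcols) loci[[cc]][swap] <- -loci[[cc]][swap]
    loci$freq_a1[swap] <- 1 - loci$freq_a1[swap]
    loci$a1[swap] <- r1[swap]
    loci$a2[swap] <- r2[swap]
  }
  loci$flipped <- swap
  loci$align_status <- status
  loci
}

#' Inverse-variance fixed-effects pooling
#'
#' Weights `w_i = 1 / se_i^2`; pooled estimate `sum(w b) / sum(w)`, pooled
#' standard error `1 / sqrt(sum(w))`, Wald `z` against the standard normal
#' with the two-sided p computed in log space.
#'
#' @param betas,ses Equal-length vectors (>= 1 cohort); all `ses` must be
#'   positive.
#' @return List with `beta`, `se`, `z`, `mlog10p`, `n_cohorts`.
#' @examples
#' meta_fixed(c(0.2, 0.4), c(0.1, 0.2))  # pooled beta 0.24, se ~0.0894
#' @export
meta_fixed <- function(betas, ses) {
  betas <- as.numeric(betas)
  ses <- as.numeric(ses)
  if (length(betas) != length(ses) || length(betas) < 1L)
    stop("betas and ses must be equal-length vectors of length >= 1",
         call. = FALSE)
  if (any(is.na(ses)) || any(ses <= 0))
    stop("all standard errors must be positive", call. = FALSE)
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  mlog10p <- -(log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
  list(beta = beta, se = se, z = z, mlog10p = mlog10p,
       n_cohorts = length(betas))
}

#' Fixed-effects meta-analysis across cohorts' NSS
#'
#' Intersects the SNP ids of all cohorts, aligns every cohort onto the
#' first cohort's effect alleles (incompatible allele pairs are excluded
#' with reason `"allele-mismatch"`; palindromic A/T and C/G variants are
#' aligned by allele labels only and listed in a warning), runs an OATH
#' scan per cohort under the covariate subset `s` (each cohort's own
#' covariates — typically its own ancestry eigenvectors), and pools the
#' per-cohort SNP estimates by inverse-variance fixed effects.
#'
#' @param cohorts Named list of `nss` objects (>= 1).
#' @param s Covariate subset, applied within every cohort.
#' @param alpha Family-wise error rate for the reported threshold.
#' @param df_convention See [oath_fit()].
#' @return Object of class `oath_meta`: list with `table` (per locus:
#'   `snp_id, n_cohorts, beta_meta, se_meta, z, mlog10p` plus per-cohort
#'   beta/se columns), `threshold`, `subset`, `excluded`.
#' @export
meta_scan <- function(cohorts, s = NULL, alpha = 0.05,
                      df_convention = c("centered", "ols")) {
  df_convention <- match.arg(df_convention)
  stopifnot(is.list(cohorts), length(cohorts) >= 1L,
            all(vapply(cohorts, inherits, logical(1), "nss")))
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  ids <- Reduce(intersect, lapply(cohorts, function(co) co$loci$snp_id))
  if (length(ids) == 0L)
    stop("no shared snp_ids across cohorts", call. = FALSE)
  ref <- cohorts[[1]]$loci[match(ids, cohorts[[1]]$loci$snp_id),
                           c("snp_id", "a1", "a2")]
  excluded <- character(0)
  aligned <- lapply(cohorts, function(co) {
    loci <- co$loci[match(ids, co$loci$snp_id), , drop = FALSE]
    loci <- .align_loci_table(loci, ref)
    bad <- loci$snp_id[loci$align_status == "allele-mismatch"]
    excluded <<- union(excluded, bad)
    co$loci <- loci
    co
  })
  keep <- setdiff(ids, excluded)
  if (length(excluded))
    message("meta_scan: excluded ", length(excluded),
            " locus/loci with reason allele-mismatch")
  pal <- .palindromic(ref$a1, ref$a2) & ref$snp_id %in% keep
  if (any(pal))
    warning("palindromic variant(s) aligned by allele labels only: ",
            paste(utils::head(ref$snp_id[pal], 5), collapse = ", "),
            if (sum(pal) > 5) ", ..." else "", call. = FALSE)
  scans <- lapply(aligned, function(co) {
    co$loci <- co$loci[match(keep, co$loci$snp_id), , drop = FALSE]
    oath_scan(co, s = s, df_convention = df_convention)
  })
  per_beta <- vapply(scans, function(sc) sc$records$beta,
                     numeric(length(keep)))
  per_se <- vapply(scans, function(sc) sc$records$se,
                   numeric(length(keep)))
  per_ok <- vapply(scans, function(sc) !sc$records$degenerate,
                   logical(length(keep)))
  if (length(keep) == 1L) {  # vapply drops to vectors
    per_beta <- matrix(per_beta, nrow = 1)
    per_se <- matrix(per_se, nrow = 1)
    per_ok <- matrix(per_ok, nrow = 1)
  }
  pooled <- t(vapply(seq_along(keep), function(i) {
    ok <- per_ok[i, ] & !is.na(per_se[i, ]) & per_se[i, ] > 0
    if (!any(ok)) return(c(NA_real_, NA_real_, NA_real_, NA_real_, 0))
    mf <- meta_fixed(per_beta[i, ok], per_se[i, ok])
    c(mf$beta, mf$se, mf$z, mf$mlog10p, mf$n_cohorts)
  }, numeric(5)))
  tab <- data.frame(snp_id = keep, n_cohorts = as.integer(pooled[, 5]),
                    beta_meta = pooled[, 1], se_meta = pooled[, 2],
                    z = pooled[, 3], mlog10p = pooled[, 4],
                    stringsAsFactors = FALSE)
  for (j in seq_along(scans)) {
    tab[[paste0("beta_", names(cohorts)[j])]] <- per_beta[, j]
    tab[[paste0("se_", names(cohorts)[j])]] <- per_se[, j]
  }
  structure(list(table = tab,
                 threshold = bonferroni_threshold(alpha, length(keep)),
                 alpha = alpha, subset = scans[[1]]$subset,
                 excluded = excluded),
            class = "oath_meta")
}

#' @export
print.oath_meta <- function(x, ...) {
  cat("OATH meta-analysis, subset {", paste(x$subset, collapse = ","),
      "}:", nrow(x$table), "loci, threshold", round(x$threshold, 2), "\n")
  invisible(x)
}
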