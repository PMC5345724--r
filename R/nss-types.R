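#' @keywords internal
"_PACKAGE"

# Relative symmetry tolerance for covariance blocks.
.sym_tol <- 1e-12
# Relative PSD tolerance: smallest eigenvalue >= -psd_tol * largest.
.psd_tol <- 1e-8

.default_znames <- function(m)
  if (m > 0) paste0("z", seq_len(m)) else character(0)

.check_symmetric <- function(M, what, tol = .sym_tol) {
  scale <- max(1, max(abs(M)))
  if (max(abs(M - t(M))) > tol * scale)
    stop(what, " is not symmetric within tolerance", call. = FALSE)
  (M + t(M)) / 2
}

#' Generic naive summary statistics
#'
#' The generic block of the sufficient statistics shared by every locus in a
#' scan: the sample size `n` together with the sample covariance matrix `C`
#' of `[phenotype, covariate_1, ..., covariate_m]` (phenotype first,
#' denominator `n - 1`).
#'
#' @param n Sample count; must satisfy `n >= m + 3` so the saturated model
#'   retains at least one residual degree of freedom.
#' @param C Symmetric `(m+1) x (m+1)` covariance matrix with a strictly
#'   positive diagonal.
#' @param covariate_names Optional length-`m` character vector; defaults to
#'   `z1..zm`.
#' @return An object of class `generic_nss` with fields `n`,
#'   `covariate_names` and `C`.
#' @seealso [encode_generic()] to build one from individual-level data,
#'   [assemble_phi()] to combine it with a locus record.
#' @export
generic_nss <- function(n, C, covariate_names = NULL) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || nrow(C) < 1L)
    stop("C must be a square matrix of order >= 1", call. = FALSE)
  m <- nrow(C) - 1L
  C <- .check_symmetric(C, "covariance matrix C")
  d <- diag(C)
  if (any(d <= 0)) {
    who <- c("phenotype", covariate_names %||% .default_znames(m))
    stop("zero or negative variance for: ",
         paste(who[d <= 0], collapse = ", "), call. = FALSE)
  }
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < m + 3L)
    stop("insufficient sample size: need n >= m + 3 (n = ", n,
         ", m = ", m, ")", call. = FALSE)
  if (is.null(covariate_names)) covariate_names <- .default_znames(m)
  covariate_names <- as.character(covariate_names)
  if (length(covariate_names) != m)
    stop("covariate_names must have length m = ", m, call. = FALSE)
  dimnames(C) <- rep(list(c("y", covariate_names)), 2)
  structure(list(n = n, covariate_names = covariate_names, C = C),
            class = "generic_nss")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.generic_nss <- function(x, ...) {
  cat("Generic NSS: n =", x$n, ", m =", length(x$covariate_names),
      "covariate(s)\n")
  print(round(x$C, 6))
  invisible(x)
}

#' Per-locus naive summary statistics
#'
#' The locus-specific row of the sufficient statistics for one SNP: allele
#' metadata, effect-allele frequency, call rate, genotype variance and the
#' genotype-phenotype / genotype-covariate covariances (denominator `n - 1`,
#' consistent with [generic_nss()]).
#'
#' A locus with `var_x = 0` is monomorphic: it is carried with
#' `monomorphic = TRUE` and is never fitted. `hom_rate` (fraction of
#' observed hard calls that are homozygous) is optional; it supports the
#' homozygosity filter of [qc_filter()] in inbred-line panels and is not
#' part of the NSS exchange format.
#'
#' @param snp_id,chrom,pos,a1,a2 Marker metadata; `pos` is 1-based, `a1` is
#'   the effect (counted) allele.
#' @param freq_a1 Effect-allele frequency in `[0, 1]` over observed calls.
#' @param call_rate Fraction of non-missing genotypes in `[0, 1]`.
#' @param var_x Genotype variance (>= 0).
#' @param cov_xy Genotype-phenotype covariance.
#' @param cov_xz Length-`m` numeric vector of genotype-covariate covariances.
#' @param hom_rate Optional homozygote fraction of observed calls (`NA` for
#'   dosage data).
#' @param biallelic Logical; `FALSE` marks a multi-allelic record destined
#'   for removal by [qc_filter()].
#' @return An object of class `locus_nss`.
#' @export
locus_nss <- function(snp_id, chrom = NA_character_, pos = NA_integer_,
                      a1 = "A1", a2 = "A2", freq_a1, call_rate = 1,
                      var_x, cov_xy, cov_xz = numeric(0),
                      hom_rate = NA_real_, biallelic = TRUE) {
  stopifnot(length(snp_id) == 1L, length(var_x) == 1L, length(cov_xy) == 1L)
  if (!is.na(freq_a1) && (freq_a1 < 0 || freq_a1 > 1))
    stop("freq_a1 must lie in [0, 1]", call. = FALSE)
  if (!is.na(call_rate) && (call_rate < 0 || call_rate > 1))
    stop("call_rate must lie in [0, 1]", call. = FALSE)
  if (var_x < 0) {
    if (var_x < -1e-12) stop("var_x must be non-negative", call. = FALSE)
    var_x <- 0
  }
  structure(list(snp_id = as.character(snp_id), chrom = as.character(chrom),
                 pos = as.integer(pos), a1 = as.character(a1),
                 a2 = as.character(a2), freq_a1 = as.numeric(freq_a1),
                 call_rate = as.numeric(call_rate), var_x = as.numeric(var_x),
                 cov_xy = as.numeric(cov_xy), cov_xz = as.numeric(cov_xz),
                 hom_rate = as.numeric(hom_rate),
                 biallelic = isTRUE(biallelic),
                 monomorphic = var_x == 0),
            class = "locus_nss")
}

#' @export
print.locus_nss <- function(x, ...) {
  cat(sprintf("Locus NSS %s (%s:%s %s/%s) freq=%.4g var_x=%.4g cov_xy=%.4g%s\n",
              x$snp_id, x$chrom, x$pos, x$a1, x$a2, x$freq_a1, x$var_x,
              x$cov_xy, if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

#' Assembled sufficient-statistic matrix for one locus
#'
#' The symmetric `(m+2) x (m+2)` covariance matrix of
#' `[phenotype, genotype, covariates]` (order `y, x, z1..zm`) plus the
#' sample size: everything least squares needs for any covariate subset at
#' this locus.
#'
#' @param M Symmetric matrix with non-negative diagonal, positive
#'   semi-definite within numerical tolerance.
#' @param n Sample count.
#' @param var_names Optional row/column names (defaults to
#'   `y, x, z1..zm`).
#' @return An object of class `phi_matrix` with fields `M` and `n`.
#' @export
phi_matrix <- function(M, n, var_names = NULL) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || nrow(M) < 2L)
    stop("Phi must be square of order >= 2", call. = FALSE)
  M <- .check_symmetric(M, "Phi")
  if (any(diag(M) < -1e-12))
    stop("Phi has a negative diagonal entry", call. = FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -.psd_tol * max(abs(ev), 1e-300))
    stop("Phi is not positive semi-definite within tolerance ",
         "(min eigenvalue ", signif(min(ev), 3), ")", call. = FALSE)
  m <- nrow(M) - 2L
  if (is.null(var_names)) var_names <- c("y", "x", .default_znames(m))
  dimnames(M) <- rep(list(var_names), 2)
  n <- as.integer(n)
  if (is.na(n) || n < m + 3L)
    stop("insufficient sample size for Phi: n = ", n, call. = FALSE)
  structure(list(M = M, n = n), class = "phi_matrix")
}

#' @export
print.phi_matrix <- function(x, ...) {
  cat("Phi matrix (", nrow(x$M), "x", ncol(x$M), "), n =", x$n, "\n")
  print(round(x$M, 6))
  invisible(x)
}

#' Number of covariates carried by an NSS container
#'
#' @param x A `generic_nss`, `phi_matrix` or `nss` object.
#' @return Integer covariate count `m`.
#' @export
n_covariates <- function(x) UseMethod("n_covariates")
#' @export
n_covariates.generic_nss <- function(x) length(x$covariate_names)
#' @export
n_covariates.phi_matrix <- function(x) nrow(x$M) - 2L
#' @export
n_covariates.nss <- function(x) length(x$generic$covariate_names)
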