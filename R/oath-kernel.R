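# The OATH estimator: least squares reconstructed from the covariance
# matrix Phi of [y, x, z1..zm]. For a covariate subset s of size k the
# coefficient vector is
#     beta = Omega^{-1} Lambda b
# where Omega is Phi restricted to the predictors [x, z_s], Lambda its
# diagonal and b the marginal (single-predictor) coefficients
# b_j = cov(y, v_j) / var(v_j). The sampling covariance is
#     ((var_y - beta' Lambda b) / df) * Omega^{-1}
# with df = n - k - 1 under the "centered" convention or n - k - 2 matching
# with-intercept least squares. Because every entry of Phi carries the same
# n - 1 denominator, the estimator is invariant to that choice of
# denominator; it must only be consistent within one NSS set.

.rcond_min <- 1e-12

.validate_subset <- function(s, m) {
  if (is.null(s)) s <- integer(0)
  if (is.character(s)) s <- parse_subset(s, m)
  s <- as.integer(s)
  if (anyDuplicated(s)) stop("covariate subset has duplicates", call. = FALSE)
  if (length(s) && (min(s) < 1L || max(s) > m))
    stop("covariate subset indices must lie in 1..", m, call. = FALSE)
  s
}

#' Extract the subset blocks Omega, Lambda and b-hat from Phi
#'
#' @param phi A [phi_matrix()].
#' @param s Covariate subset: integer indices in `1..m`, a `+/-` mask
#'   string, or `integer(0)`/`NULL` for the naive (no-covariate) model.
#' @return List with `Omega` (`(k+1) x (k+1)` predictor covariance block),
#'   `Lambda` (its diagonal, as a vector) and `b_hat` (marginal
#'   coefficients, SNP first).
#' @export
split_phi <- function(phi, s = NULL) {
  stopifnot(inherits(phi, "phi_matrix"))
  m <- n_covariates(phi)
  s <- .validate_subset(s, m)
  idx <- c(2L, 2L + s)
  Omega <- phi$M[idx, idx, drop = FALSE]
  Lambda <- diag(Omega)
  b_hat <- ifelse(Lambda > 0, phi$M[1, idx] / Lambda, NA_real_)
  names(b_hat) <- names(Lambda) <- rownames(Omega)
  list(Omega = Omega, Lambda = Lambda, b_hat = b_hat, subset = s)
}

#' Fit one locus for one covariate subset from summary statistics
#'
#' Reconstructs the multiple-regression coefficient for the SNP and the
#' included covariates, their standard errors, t statistics and the SNP's
#' two-sided -log10 p, exactly as individual-level least squares would
#' produce them, using only the Phi matrix.
#'
#' @inheritParams split_phi
#' @param df_convention `"centered"` uses residual df `n - k - 1` (the
#'   centered-variable form); `"ols"` uses `n - k - 2`, matching `lm()`
#'   with an intercept. The two differ by `sqrt((n-k-1)/(n-k-2))` in the
#'   standard errors.
#' @return An object of class `oath_fit`: list with `subset`, `terms`,
#'   `beta`, `se`, `t`, `df`, `sigma2_resid`, `mlog10p` (SNP term),
#'   `b_hat`, `degenerate`.
#' @examples
#' phi <- worked_example_phi()
#' oath_fit(phi, s = c(1, 2, 3))
#' @export
oath_fit <- function(phi, s = NULL, df_convention = c("centered", "ols")) {
  df_convention <- match.arg(df_convention)
  stopifnot(inherits(phi, "phi_matrix"))
  if (phi$M[2, 2] <= 0)
    stop("monomorphic locus: var_x = 0, nothing to fit", call. = FALSE)
  sp <- split_phi(phi, s)
  k <- length(sp$subset)
  n <- phi$n
  df <- n - k - if (df_convention == "centered") 1L else 2L
  if (df < 1L)
    stop("no residual degrees of freedom (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  if (rcond(sp$Omega) <= .rcond_min)
    stop("collinear predictors for subset {",
         paste(sp$subset, collapse = ","), "}: Omega is numerically singular",
         call. = FALSE)
  rhs <- sp$Lambda * sp$b_hat   # = cov(predictor, y)
  R <- tryCatch(chol(sp$Omega), error = function(e) NULL)
  if (!is.null(R)) {
    beta <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    Oinv_diag <- diag(chol2inv(R))
  } else {
    # benign PSD borderline: pivoted fallback
    beta <- solve(sp$Omega, rhs)
    Oinv_diag <- diag(solve(sp$Omega))
  }
  sigma2_num <- phi$M[1, 1] - sum(beta * rhs)
  degenerate <- sigma2_num < 0
  sigma2 <- max(sigma2_num, 0)
  se <- sqrt(pmax(sigma2 / df * Oinv_diag, 0))
  t_stat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  names(beta) <- names(se) <- names(t_stat) <- names(sp$Lambda)
  structure(list(subset = sp$subset, terms = names(sp$Lambda),
                 beta = as.numeric(beta), se = as.numeric(se),
                 t = as.numeric(t_stat), df = df, sigma2_resid = sigma2,
                 mlog10p = unname(mlog10_p_from_t(t_stat[1], df)),
                 b_hat = as.numeric(sp$b_hat), degenerate = degenerate,
                 df_convention = df_convention),
            class = "oath_fit")
}

#' @export
print.oath_fit <- function(x, digits = 4, ...) {
  cat("OATH fit, subset {", paste(x$subset, collapse = ","), "}, df =",
      x$df, if (x$degenerate) "[degenerate]" else "", "\n")
  print(data.frame(term = x$terms, beta = signif(x$beta, digits),
                   se = signif(x$se, digits), t = signif(x$t, digits)),
        row.names = FALSE)
  cat(sprintf("SNP -log10(p) = %.*g (sigma2_resid = %.*g)\n", digits,
              x$mlog10p, digits, x$sigma2_resid))
  invisible(x)
}

#' Two-sided -log10 p from a t statistic
#'
#' Computed on the log scale from the t survival function, so very large
#' statistics give large finite values instead of underflowing to p = 0.
#' Vectorised over `t`.
#'
#' @param t Statistic(s).
#' @param df Residual degrees of freedom (>= 1).
#' @return `-log10` of the two-sided p-value; 0 at `t = 0`, monotone
#'   increasing in `|t|`.
#' @export
mlog10_p_from_t <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  -(log(2) + stats::pt(-abs(t), df, log.p = TRUE)) / log(10)
}

# chi-square (1 df) analogue, used by genomic-control adjustment.
mlog10_p_from_chisq1 <- function(chisq) {
  -stats::pchisq(chisq, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
}
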