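# Encoding naive summary statistics from individual-level data.

.cov_names <- function(m) if (m > 0) paste0("cov_xz", seq_len(m)) else character(0)

.as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  Z <- as.matrix(covariates)
  if (!is.numeric(Z)) stop("covariates must be numeric", call. = FALSE)
  if (nrow(Z) != n) stop("covariates must have one row per sample", call. = FALSE)
  if (ncol(Z) > 0 && is.null(colnames(Z)))
    colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  Z
}

#' Encode the generic NSS block
#'
#' Computes the sample covariance matrix (denominator `n - 1`) of the
#' phenotype and the covariates, the generic part of the sufficient
#' statistics shared by every locus. Rows with a missing phenotype or
#' covariate value are dropped first (with a message); callers that also
#' encode loci must drop the same rows, as [encode_nss()] does.
#'
#' @param phenotype Numeric length-`n` vector.
#' @param covariates Optional `n x m` numeric matrix or data frame; column
#'   order is preserved.
#' @return A [generic_nss()] object.
#' @examples
#' encode_generic(c(1, 2, 3), cbind(z1 = c(3, 2, 1)))
#' @export
encode_generic <- function(phenotype, covariates = NULL) {
  y <- as.numeric(phenotype)
  Z <- .as_covariate_matrix(covariates, length(y))
  keep <- stats::complete.cases(cbind(y, Z))
  if (!all(keep)) {
    message("encode_generic: dropped ", sum(!keep),
            " row(s) with missing phenotype/covariate values")
    y <- y[keep]
    Z <- Z[keep, , drop = FALSE]
  }
  m <- ncol(Z)
  n <- length(y)
  if (n <= m + 2L)
    stop("insufficient sample size: need n >= m + 3 (n = ", n,
         ", m = ", m, ")", call. = FALSE)
  V <- cbind(y = y, Z)
  vars <- apply(V, 2, stats::var)
  if (any(vars <= 0)) {
    who <- c("phenotype", colnames(Z))
    stop("zero variance for: ", paste(who[vars <= 0], collapse = ", "),
         call. = FALSE)
  }
  generic_nss(n, stats::cov(V), covariate_names = colnames(Z))
}

.check_genotype_values <- function(x, dosage) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0L) stop("all genotypes missing", call. = FALSE)
  if (any(obs < 0 | obs > 2))
    stop("genotype values outside [0, 2]", call. = FALSE)
  if (!dosage && any(obs != round(obs)))
    stop("non-integer genotype calls; set dosage = TRUE for dosage data",
         call. = FALSE)
  invisible(TRUE)
}

#' Encode the locus-specific NSS record for one SNP
#'
#' Missing genotypes are mean-imputed before the covariance computation so
#' that one shared `n` serves the generic block and every locus; the call
#' rate and the observed-call allele frequency are recorded beforehand.
#' Phenotype and covariates must be complete (pre-clean with the same row
#' drop as [encode_generic()]; [encode_nss()] does this jointly).
#'
#' @param genotype Length-`n` vector of effect-allele counts in
#'   `{0, 1, 2, NA}`, or dosages in `[0, 2]` when `dosage = TRUE`.
#' @param phenotype,covariates As in [encode_generic()], complete rows only.
#' @param snp_id,chrom,pos,a1,a2 Marker metadata ([locus_nss()]).
#' @param dosage Accept fractional dosages (hom_rate then `NA`).
#' @return A [locus_nss()] object.
#' @examples
#' encode_locus(c(0, 1, 2), c(1, 2, 3), snp_id = "rs1")
#' @export
encode_locus <- function(genotype, phenotype, covariates = NULL,
                         snp_id, chrom = NA, pos = NA, a1 = "A1", a2 = "A2",
                         dosage = FALSE) {
  x <- as.numeric(genotype)
  y <- as.numeric(phenotype)
  if (length(x) != length(y))
    stop("genotype and phenotype lengths differ", call. = FALSE)
  Z <- .as_covariate_matrix(covariates, length(y))
  if (anyNA(y) || anyNA(Z))
    stop("phenotype/covariates contain missing values; drop those rows ",
         "before locus encoding (see encode_nss)", call. = FALSE)
  .check_genotype_values(x, dosage)
  obs <- !is.na(x)
  call_rate <- mean(obs)
  freq_a1 <- mean(x[obs]) / 2
  hom_rate <- if (dosage) NA_real_ else mean(x[obs] %in% c(0, 2))
  x[!obs] <- mean(x[obs])
  n <- length(y)
  var_x <- stats::var(x)
  cov_xy <- stats::cov(x, y)
  cov_xz <- if (ncol(Z) > 0) as.numeric(stats::cov(x, Z)) else numeric(0)
  locus_nss(snp_id = snp_id, chrom = chrom, pos = pos, a1 = a1, a2 = a2,
            freq_a1 = freq_a1, call_rate = call_rate, var_x = var_x,
            cov_xy = cov_xy, cov_xz = cov_xz, hom_rate = hom_rate)
}

#' Encode a full NSS set from a genotype matrix
#'
#' Vectorised encoding of the generic block and one locus record per
#' column of the genotype matrix. Rows with missing phenotype or covariate
#' values are dropped globally (message with the count); missing genotypes
#' are then mean-imputed per locus.
#'
#' @param genotypes `n x L` numeric matrix of effect-allele counts (or
#'   dosages), columns named by SNP id unless `map` is supplied.
#' @param phenotype,covariates As in [encode_generic()].
#' @param map Optional data frame with columns
#'   `snp_id, chrom, pos, a1, a2` (one row per genotype column).
#' @param dosage Accept fractional dosages.
#' @return An object of class `nss`: a list with elements `generic`
#'   (a [generic_nss()]) and `loci` (a data frame with one row per locus,
#'   covariances in columns `cov_xz1..m`).
#' @export
encode_nss <- function(genotypes, phenotype, covariates = NULL, map = NULL,
                       dosage = FALSE) {
  G <- as.matrix(genotypes)
  y <- as.numeric(phenotype)
  if (nrow(G) != length(y))
    stop("genotype rows and phenotype length differ", call. = FALSE)
  Z <- .as_covariate_matrix(covariates, length(y))
  keep <- stats::complete.cases(cbind(y, Z))
  if (!all(keep)) {
    message("encode_nss: dropped ", sum(!keep),
            " row(s) with missing phenotype/covariate values")
    y <- y[keep]
    Z <- Z[keep, , drop = FALSE]
    G <- G[keep, , drop = FALSE]
  }
  generic <- encode_generic(y, Z)
  n <- length(y)
  L <- ncol(G)
  if (L == 0L) stop("no loci to encode", call. = FALSE)
  .check_genotype_values(as.vector(G), dosage)
  obs <- !is.na(G)
  n_obs <- colSums(obs)
  if (any(n_obs == 0L))
    stop("all genotypes missing at loci: ",
         paste(utils::head(which(n_obs == 0L), 5), collapse = ", "),
         call. = FALSE)
  call_rate <- n_obs / n
  freq_a1 <- colSums(G, na.rm = TRUE) / (2 * n_obs)
  hom_rate <- if (dosage) rep(NA_real_, L) else
    colSums((G == 0 | G == 2) & obs, na.rm = TRUE) / n_obs
  if (anyNA(G)) {
    mu <- colSums(G, na.rm = TRUE) / n_obs
    idx <- which(!obs, arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  Xc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  var_x <- colSums(Xc^2) / (n - 1)
  cov_xy <- as.numeric(crossprod(Xc, yc)) / (n - 1)
  m <- ncol(Z)
  cov_xz <- if (m > 0) {
    Zc <- sweep(Z, 2, colMeans(Z))
    crossprod(Xc, Zc) / (n - 1)
  } else matrix(numeric(0), nrow = L, ncol = 0)
  colnames(cov_xz) <- .cov_names(m)
  if (is.null(map)) {
    ids <- colnames(G) %||% paste0("snp", seq_len(L))
    map <- data.frame(snp_id = ids, chrom = NA_character_,
                      pos = seq_len(L), a1 = "A1", a2 = "A2",
                      stringsAsFactors = FALSE)
  }
  if (nrow(map) != L)
    stop("map must have one row per genotype column", call. = FALSE)
  loci <- data.frame(snp_id = as.character(map$snp_id),
                     chrom = as.character(map$chrom),
                     pos = as.integer(map$pos),
                     a1 = as.character(map$a1), a2 = as.character(map$a2),
                     freq_a1 = freq_a1, call_rate = call_rate,
                     var_x = var_x, cov_xy = cov_xy,
                     stringsAsFactors = FALSE, row.names = NULL)
  loci <- cbind(loci, as.data.frame(cov_xz))
  loci$hom_rate <- hom_rate
  loci$biallelic <- if (!is.null(map$biallelic)) as.logical(map$biallelic) else TRUE
  loci$monomorphic <- var_x <= 0
  structure(list(generic = generic, loci = loci), class = "nss")
}

#' @export
print.nss <- function(x, ...) {
  cat("NSS set: n =", x$generic$n, ",", length(x$generic$covariate_names),
      "covariate(s),", nrow(x$loci), "loci (",
      sum(x$loci$monomorphic), "monomorphic )\n")
  invisible(x)
}

# Coerce a row of an nss loci table to a locus_nss record.
as_locus_nss <- function(loci, i = 1L) {
  if (inherits(loci, "locus_nss")) return(loci)
  row <- loci[i, , drop = FALSE]
  m <- sum(grepl("^cov_xz", names(loci)))
  cz <- if (m > 0) as.numeric(row[1, .cov_names(m)]) else numeric(0)
  locus_nss(snp_id = row$snp_id, chrom = row$chrom, pos = row$pos,
            a1 = row$a1, a2 = row$a2, freq_a1 = row$freq_a1,
            call_rate = row$call_rate, var_x = row$var_x,
            cov_xy = row$cov_xy, cov_xz = cz,
            hom_rate = if (!is.null(row$hom_rate)) row$hom_rate else NA_real_,
            biallelic = if (!is.null(row$biallelic)) row$biallelic else TRUE)
}

#' Assemble the sufficient-statistic matrix for one locus
#'
#' Combines the generic covariance block with a locus record into the
#' symmetric `(m+2) x (m+2)` matrix ordered `[y, x, z1..zm]`. The
#' Cauchy-Schwarz bounds `|cov_xy| <= sqrt(var_x * var_y)` (and likewise per
#' covariate) are enforced with a `1e-9` slack: a violation means the two
#' blocks were not computed from the same sample.
#'
#' @param generic A [generic_nss()].
#' @param locus A [locus_nss()] or a one-row slice of an `nss` loci table.
#' @return A [phi_matrix()].
#' @export
assemble_phi <- function(generic, locus) {
  stopifnot(inherits(generic, "generic_nss"))
  locus <- as_locus_nss(locus)
  m <- n_covariates(generic)
  if (length(locus$cov_xz) != m)
    stop("covariate count mismatch: locus has ", length(locus$cov_xz),
         " covariances, generic block has ", m, call. = FALSE)
  lim <- sqrt(locus$var_x * diag(generic$C)) + 1e-9
  got <- abs(c(locus$cov_xy, locus$cov_xz))
  if (any(got > lim))
    stop("Cauchy-Schwarz violation at locus ", locus$snp_id,
         ": covariances inconsistent with the generic block", call. = FALSE)
  M <- matrix(0, m + 2L, m + 2L)
  M[-2, -2] <- generic$C
  M[2, 2] <- locus$var_x
  M[2, 1] <- M[1, 2] <- locus$cov_xy
  if (m > 0) {
    M[2, 3:(m + 2L)] <- locus$cov_xz
    M[3:(m + 2L), 2] <- locus$cov_xz
  }
  phi_matrix(M, generic$n,
             var_names = c("y", "x", generic$covariate_names))
}

#' Split a Phi matrix back into generic and locus parts
#'
#' Inverse of [assemble_phi()] up to marker metadata (which Phi does not
#' carry): `assemble_phi(phi_to_nss(phi)$generic, phi_to_nss(phi)$locus)`
#' reproduces the matrix bit-identically.
#'
#' @param phi A [phi_matrix()].
#' @param snp_id Id to stamp on the locus record.
#' @return List with elements `generic` and `locus`.
#' @export
phi_to_nss <- function(phi, snp_id = "locus") {
  stopifnot(inherits(phi, "phi_matrix"))
  M <- phi$M
  m <- nrow(M) - 2L
  generic <- generic_nss(phi$n, M[-2, -2, drop = FALSE],
                         covariate_names = colnames(M)[-(1:2)])
  locus <- locus_nss(snp_id = snp_id, freq_a1 = NA_real_,
                     call_rate = NA_real_, var_x = M[2, 2],
                     cov_xy = M[1, 2],
                     cov_xz = if (m > 0) M[2, 3:(m + 2L)] else numeric(0))
  list(generic = generic, locus = locus)
}
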