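# Seeded generators: structured genotypes (Balding-Nichols), genetic
# relationship matrices, eigenvector covariates, additive phenotypes, the
# worked single-locus fixture and a two-cohort meta-analysis design. Every
# stochastic generator takes an explicit seed and restores the caller's
# RNG state on exit.

with_seed <- function(seed, code) {
  if (is.null(seed)) stop("an explicit seed is required", call. = FALSE)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Simulate genotypes with optional population structure
#'
#' Per-locus ancestral allele frequencies are drawn uniformly from
#' `maf_range`. With `fst > 0`, each subpopulation receives its own
#' frequency from the Balding-Nichols model
#' `Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) / Fst)`; genotypes are
#' `Binomial(2, p_subpop)` counts of the effect allele, or (in inbred
#' mode, emulating inbred-line panels) a doubled haploid draw, so every
#' call is homozygous. Loci are independent (no linkage disequilibrium).
#'
#' @param n_samples,n_loci Dimensions.
#' @param maf_range Length-2 range within `(0, 0.5]`.
#' @param n_subpops Number of equal-sized subpopulations (assigned
#'   round-robin).
#' @param fst Differentiation parameter in `[0, 1)`; 0 = panmictic.
#' @param inbred Draw doubled haploids (genotypes in `{0, 2}`).
#' @param seed Mandatory RNG seed.
#' @return List with `genotypes` (`n x L` matrix, columns named by
#'   `map$snp_id`), `map` (snp_id, chrom, pos, a1, a2), `subpop` (integer
#'   labels) and `p_anc`.
#' @export
sim_genotypes <- function(n_samples, n_loci, maf_range = c(0.05, 0.5),
                          n_subpops = 1, fst = 0, inbred = FALSE, seed) {
  stopifnot(n_samples >= 1, n_loci >= 1, n_subpops >= 1)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5] with min <= max", call. = FALSE)
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)", call. = FALSE)
  with_seed(seed, {
    p_anc <- stats::runif(n_loci, maf_range[1], maf_range[2])
    subpop <- rep_len(seq_len(n_subpops), n_samples)
    p_sub <- if (fst > 0 && n_subpops > 1) {
      t(vapply(seq_len(n_subpops), function(k)
        stats::rbeta(n_loci, p_anc * (1 - fst) / fst,
                     (1 - p_anc) * (1 - fst) / fst),
        numeric(n_loci)))
    } else matrix(p_anc, nrow = n_subpops, ncol = n_loci, byrow = TRUE)
    P <- p_sub[subpop, , drop = FALSE]  # n x L frequency per sample
    X <- if (inbred)
      2 * matrix(stats::rbinom(n_samples * n_loci, 1, P),
                 n_samples, n_loci)
    else
      matrix(stats::rbinom(n_samples * n_loci, 2, P),
             n_samples, n_loci)
    map <- data.frame(snp_id = paste0("1_", seq_len(n_loci)),
                      chrom = "1", pos = seq_len(n_loci),
                      a1 = "A", a2 = "G", stringsAsFactors = FALSE)
    colnames(X) <- map$snp_id
    list(genotypes = X, map = map, subpop = subpop, p_anc = p_anc)
  })
}

#' Genetic relationship matrix from standardized genotypes
#'
#' `GRM = (1 / L) * W W'` where column `l` of `W` is the genotype vector
#' standardized by its observed mean `2 p-hat` and standard deviation
#' `sqrt(2 p-hat (1 - p-hat))`. Monomorphic loci are skipped (with a
#' message giving the count). Under Hardy-Weinberg data the mean diagonal
#' is close to 1.
#'
#' @param genotypes `n x L` matrix of allele counts (0/1/2, or 0/2 for
#'   inbred lines).
#' @return Symmetric `n x n` matrix with attribute `n_loci_used`.
#' @export
grm <- function(genotypes) {
  X <- as.matrix(genotypes)
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci", call. = FALSE)
  if (any(!poly))
    message("grm: skipped ", sum(!poly), " monomorphic locus/loci")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(W) / ncol(W)
  structure((K + t(K)) / 2, n_loci_used = ncol(W))
}

#' Leading eigenvectors of a relationship matrix
#'
#' Unit-norm, mutually orthogonal eigenvectors of the `k` largest
#' eigenvalues. The sign of each column is fixed by making its
#' largest-magnitude entry positive, so the output is deterministic (up to
#' the usual non-identifiability within a degenerate eigenvalue).
#'
#' @param K Symmetric `n x n` matrix (e.g. from [grm()]).
#' @param k Number of leading eigenvectors, `k <= n`.
#' @return `n x k` matrix with columns `EV1..EVk`; eigenvalues in
#'   attribute `values`.
#' @export
top_eigenvectors <- function(K, k) {
  K <- as.matrix(K)
  stopifnot(k >= 1, k <= nrow(K))
  e <- eigen(K, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("EV", seq_len(k))
  structure(V, values = e$values[seq_len(k)])
}

#' Simulate an additive phenotype
#'
#' `y = sum_c sqrt(h2_c) * w_c + Z b + e` with `w_c` the empirically
#' standardized genotype of causal locus `c`, so each causal locus's
#' marginal variance share matches its requested fraction up to sampling
#' error, and `e ~ N(0, 1 - sum(h2) - var(Zb))` so the total variance is
#' close to 1.
#'
#' @param genotypes `n x L` genotype matrix.
#' @param causal Data frame with columns `locus` (column index) and `h2`
#'   (variance fraction), or `NULL` for a null trait.
#' @param covariates,covariate_effects Optional `n x m` matrix and
#'   length-`m` effect vector.
#' @param seed Mandatory RNG seed.
#' @param standardize Return the phenotype scaled to mean 0, variance 1.
#' @return Numeric phenotype vector.
#' @export
sim_phenotype <- function(genotypes, causal = NULL, covariates = NULL,
                          covariate_effects = NULL, seed,
                          standardize = FALSE) {
  X <- as.matrix(genotypes)
  n <- nrow(X)
  g <- numeric(n)
  h2_total <- 0
  if (!is.null(causal) && nrow(as.data.frame(causal)) > 0) {
    causal <- as.data.frame(causal)
    stopifnot(all(c("locus", "h2") %in% names(causal)),
              all(causal$h2 >= 0))
    h2_total <- sum(causal$h2)
    for (r in seq_len(nrow(causal))) {
      x <- X[, causal$locus[r]]
      if (stats::sd(x) == 0)
        stop("causal locus ", causal$locus[r], " is monomorphic",
             call. = FALSE)
      g <- g + sqrt(causal$h2[r]) * as.numeric(scale(x))
    }
  }
  zpart <- numeric(n)
  var_z <- 0
  if (!is.null(covariates)) {
    Z <- .as_covariate_matrix(covariates, n)
    stopifnot(length(covariate_effects) == ncol(Z))
    zpart <- as.numeric(Z %*% covariate_effects)
    var_z <- stats::var(zpart)
  }
  var_e <- 1 - h2_total - var_z
  if (var_e <= 0)
    stop("infeasible variance budget: causal fractions plus covariate ",
         "variance reach ", signif(h2_total + var_z, 4), call. = FALSE)
  y <- with_seed(seed, g + zpart + stats::rnorm(n, sd = sqrt(var_e)))
  if (standardize) y <- as.numeric(scale(y))
  y
}

#' The printed single-locus sufficient-statistic fixture
#'
#' The 5x5 covariance matrix (order `y, x, z1, z2, z3`) of the published
#' single-locus worked example — a biallelic locus with MAF 0.23 and zero
#' true effect, three standard-normal covariates, `n = 200`. Entries are
#' the displayed (rounded) values; downstream quantities derived from
#' off-diagonal ratios are therefore only display-precision accurate.
#'
#' @return A [phi_matrix()] with `n = 200`.
#' @export
worked_example_phi <- function() {
  M <- matrix(c(
     1,      -0.005,  0.092,  -0.121,   0.113,
    -0.005,   0.338, -0.035,   0.0063, -0.0505,
     0.092,  -0.035,  1,       0.0608,  0.0506,
    -0.121,   0.0063, 0.0608,  1,       0.0083,
     0.113,  -0.0505, 0.0506,  0.0083,  1), 5, 5, byrow = TRUE)
  phi_matrix(M, 200, var_names = c("y", "x", "z1", "z2", "z3"))
}

#' Simulate a complete small-panel GWAS design
#'
#' Inbred-line panel with mild population structure: genotypes, GRM, top
#' eigenvector covariates, an additive phenotype and the encoded NSS —
#' everything a scan or enumeration needs, from one seed. Defaults emulate
#' a 295-line inbred panel with five eigenvector covariates.
#'
#' @param n_samples,n_loci Panel dimensions.
#' @param n_eigenvectors Number of GRM eigenvector covariates.
#' @param n_subpops,fst,inbred,maf_range Passed to [sim_genotypes()].
#' @param causal Causal spec as in [sim_phenotype()]; default: two loci at
#'   2% variance each.
#' @param seed Mandatory RNG seed.
#' @return List with `genotypes`, `map`, `subpop`, `grm`, `eigenvectors`,
#'   `phenotype`, `nss`, `causal`.
#' @export
sim_gwas <- function(n_samples = 295, n_loci = 2000, n_eigenvectors = 5,
                     n_subpops = 3, fst = 0.05, inbred = TRUE,
                     maf_range = c(0.05, 0.5), causal = NULL, seed) {
  sim <- sim_genotypes(n_samples, n_loci, maf_range = maf_range,
                       n_subpops = n_subpops, fst = fst, inbred = inbred,
                       seed = seed)
  if (is.null(causal)) {
    poly <- which(apply(sim$genotypes, 2, stats::sd) > 0)
    pick <- function(frac) poly[which.min(abs(poly - frac * n_loci))]
    causal <- data.frame(locus = c(pick(0.25), pick(0.75)),
                         h2 = c(0.02, 0.02))
  }
  K <- grm(sim$genotypes)
  V <- top_eigenvectors(K, n_eigenvectors)
  y <- sim_phenotype(sim$genotypes, causal = causal, seed = seed + 1L)
  nss <- encode_nss(sim$genotypes, y, covariates = V, map = sim$map)
  list(genotypes = sim$genotypes, map = sim$map, subpop = sim$subpop,
       grm = K, eigenvectors = V, phenotype = y, nss = nss,
       causal = causal)
}

#' Simulate a two-cohort consortium meta-analysis design
#'
#' Two cohorts drawn from shared ancestral allele frequencies, each with
#' mild two-subpopulation structure, one shared causal locus at the given
#' variance fraction, and each cohort's own top GRM eigenvectors as
#' covariates. Defaults are the consortium demonstration sizes: 3191 and
#' 2309 samples, 9124 shared loci, 5% causal variance, three covariates.
#' The individual-level data are encoded to NSS and discarded, exactly as
#' cohorts shipping summaries to a central hub would do.
#'
#' @param seed Mandatory RNG seed.
#' @param n1,n2 Cohort sizes.
#' @param n_loci Number of shared loci.
#' @param causal_h2 Variance fraction of the causal locus in each cohort.
#' @param n_covariates Eigenvector covariates per cohort.
#' @param fst Within-cohort structure (two subpopulations).
#' @return List with `cohorts` (named list of two `nss`), `causal_id` and
#'   `causal_index`.
#' @export
sim_two_cohorts <- function(seed, n1 = 3191, n2 = 2309, n_loci = 9124,
                            causal_h2 = 0.05, n_covariates = 3,
                            fst = 0.01) {
  p_anc <- with_seed(seed, stats::runif(n_loci, 0.05, 0.5))
  causal_index <- which.min(abs(p_anc - 0.3))
  map <- data.frame(snp_id = paste0("1_", seq_len(n_loci)), chrom = "1",
                    pos = seq_len(n_loci), a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  make_cohort <- function(n, sub_seed) {
    subpop <- rep_len(1:2, n)
    X <- with_seed(sub_seed, {
      ps <- if (fst > 0) rbind(
        stats::rbeta(n_loci, p_anc * (1 - fst) / fst,
                     (1 - p_anc) * (1 - fst) / fst),
        stats::rbeta(n_loci, p_anc * (1 - fst) / fst,
                     (1 - p_anc) * (1 - fst) / fst))
      else rbind(p_anc, p_anc)
      P <- ps[subpop, , drop = FALSE]
      matrix(stats::rbinom(n * n_loci, 2, P), n, n_loci,
             dimnames = list(NULL, map$snp_id))
    })
    if (stats::sd(X[, causal_index]) == 0)
      stop("causal locus came out monomorphic; change the seed",
           call. = FALSE)
    K <- grm(X)
    V <- top_eigenvectors(K, n_covariates)
    y <- sim_phenotype(X, causal = data.frame(locus = causal_index,
                                              h2 = causal_h2),
                       seed = sub_seed + 2L)
    encode_nss(X, y, covariates = V, map = map)
  }
  cohorts <- list(cohort1 = make_cohort(n1, seed + 101L),
                  cohort2 = make_cohort(n2, seed + 202L))
  list(cohorts = cohorts,
       causal_id = cohorts$cohort1$loci$snp_id[causal_index],
       causal_index = causal_index)
}
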