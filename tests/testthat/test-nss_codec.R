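test_that("encode_generic computes n-1 covariances in input order", {
  # identical phenotype and covariate: every cell is the common variance
  v <- c(0.5, 1.5, 2.5, 4)
  g <- encode_generic(v, cbind(z1 = v))
  expect_equal(g$C, matrix(var(v), 2, 2,
                           dimnames = rep(list(c("y", "z1")), 2)))
  # hand covariance with denominator n - 1 = 4: sum((y - 3)^2) / 4 = 2.5
  g2 <- encode_generic(1:5, cbind(z1 = 5:1))
  expect_equal(unname(g2$C), matrix(c(2.5, -2.5, -2.5, 2.5), 2, 2))
  # the same arithmetic at the locus level, denominator n - 1 = 2
  expect_equal(cov(c(1, 2, 3), c(3, 2, 1)), -1)
  # covariate order is preserved
  Z <- cbind(a = rnorm(10), b = rnorm(10))
  expect_identical(encode_generic(rnorm(10), Z)$covariate_names, c("a", "b"))
})

test_that("encode_generic rejects degenerate inputs by name", {
  y <- rnorm(10)
  expect_error(encode_generic(rep(1, 10), cbind(z1 = y)), "phenotype")
  expect_error(encode_generic(y, cbind(zz = rep(2, 10))), "zz")
  expect_error(encode_generic(rnorm(4), matrix(rnorm(8), 4, 2)),
               "insufficient sample size")
})

test_that("mutually orthogonal eigenvector covariates give a diagonal block", {
  sim <- sim_genotypes(80, 300, n_subpops = 2, fst = 0.1, seed = 11)
  V <- top_eigenvectors(grm(sim$genotypes), 5)
  g <- encode_generic(rnorm(80), V)
  offdiag <- g$C[-1, -1][upper.tri(diag(5))]
  expect_lt(max(abs(offdiag)), 1e-10)
})

test_that("encode_locus computes frequency, call rate and covariances", {
  # x = y: cov_xy = var_x = var(y)
  y <- c(0, 1, 2, 1, 0)
  l <- encode_locus(y, y, snp_id = "s")
  expect_equal(l$cov_xy, var(y))
  expect_equal(l$var_x, var(y))
  # hand case, denominator 2
  l2 <- encode_locus(c(0, 1, 2), c(1, 2, 3), snp_id = "s")
  expect_equal(l2$var_x, 1)
  expect_equal(l2$cov_xy, 1)
  expect_equal(l2$freq_a1, 0.5)
  # monomorphic: flagged, freq 1, never fitted
  l3 <- encode_locus(rep(2, 6), rnorm(6), snp_id = "mono")
  expect_true(l3$monomorphic)
  expect_equal(l3$var_x, 0)
  expect_equal(l3$freq_a1, 1)
})

test_that("missing genotypes are mean-imputed with call rate recorded", {
  x <- c(0, 1, 2, NA, 1, NA)
  y <- rnorm(6)
  l <- encode_locus(x, y, snp_id = "s")
  expect_equal(l$call_rate, 4 / 6)
  expect_equal(l$freq_a1, mean(x, na.rm = TRUE) / 2)
  xi <- ifelse(is.na(x), mean(x, na.rm = TRUE), x)
  expect_equal(l$var_x, var(xi))
  expect_equal(l$cov_xy, cov(xi, y))
})

test_that("encode_locus rejects contract violations", {
  expect_error(encode_locus(rep(NA_real_, 5), rnorm(5), snp_id = "s"),
               "all genotypes missing")
  expect_error(encode_locus(c(0, 1, 3), rnorm(3), snp_id = "s"),
               "outside")
  expect_error(encode_locus(c(0, 0.5, 1), rnorm(3), snp_id = "s"),
               "dosage")
  expect_silent(encode_locus(c(0, 0.5, 1.2), rnorm(3), snp_id = "s",
                             dosage = TRUE))
})

test_that("phenotype scaling and allele recoding act as expected on NSS", {
  set.seed(3)
  x <- rbinom(40, 2, 0.4)
  y <- rnorm(40)
  Z <- matrix(rnorm(80), 40, 2)
  c_scale <- 3.7
  g1 <- encode_generic(y, Z)
  g2 <- encode_generic(c_scale * y, Z)
  expect_equal(g2$C[1, 1], c_scale^2 * g1$C[1, 1])
  expect_equal(g2$C[1, -1], c_scale * g1$C[1, -1])
  l1 <- encode_locus(x, y, Z, snp_id = "s")
  l2 <- encode_locus(2 - x, y, Z, snp_id = "s")
  expect_equal(l2$cov_xy, -l1$cov_xy)
  expect_equal(l2$cov_xz, -l1$cov_xz)
  expect_equal(l2$var_x, l1$var_x)
  expect_equal(l2$freq_a1, 1 - l1$freq_a1)
  expect_equal(encode_locus(x, c_scale * y, Z, snp_id = "s")$cov_xy,
               c_scale * l1$cov_xy)
})

test_that("assemble_phi places blocks correctly and validates dimensions", {
  # m = 0: Phi = [[var_y, c], [c, v]]
  g0 <- encode_generic(c(1, 2, 3, 5))
  l0 <- locus_nss("s", freq_a1 = 0.5, var_x = 0.4, cov_xy = 0.1)
  phi0 <- assemble_phi(g0, l0)
  expect_equal(unname(phi0$M),
               matrix(c(var(c(1, 2, 3, 5)), 0.1, 0.1, 0.4), 2, 2))
  # mismatched covariate count
  g2 <- encode_generic(rnorm(20), matrix(rnorm(40), 20, 2))
  expect_error(assemble_phi(g2, l0), "covariate count mismatch")
  # inconsistent blocks are caught by Cauchy-Schwarz
  bad <- locus_nss("s", freq_a1 = 0.5, var_x = 0.01, cov_xy = 5,
                   cov_xz = c(0, 0))
  expect_error(assemble_phi(g2, bad), "Cauchy-Schwarz")
})

test_that("phi round-trips through its generic/locus split bit-identically", {
  phi <- worked_example_phi()
  parts <- phi_to_nss(phi)
  phi2 <- assemble_phi(parts$generic, parts$locus)
  expect_identical(phi2$M[], phi$M[])
  expect_identical(phi2$n, phi$n)
})

test_that("assembled Phi from real data with imputation is PSD", {
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(rbinom(200, 2, 0.3), 40, 5)
    X[sample(200, 20)] <- NA
    nss <- encode_nss(X, rnorm(40), matrix(rnorm(120), 40, 3))
    for (i in 1:5) {
      phi <- assemble_phi(nss$generic, nss$loci[i, ])
      ev <- eigen(phi$M, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(ev))
    }
  }
})

test_that("qc_filter applies the thresholds strictly with first-fail reasons", {
  mk <- function(freq, cr = 1, bi = TRUE, hom = 1) {
    data.frame(snp_id = sprintf("s%.2f", freq), chrom = "1", pos = 1L,
               a1 = "A", a2 = "G", freq_a1 = freq, call_rate = cr,
               var_x = 0.5, cov_xy = 0, hom_rate = hom, biallelic = bi,
               monomorphic = FALSE)
  }
  # below-threshold MAF removed with reason "maf"
  res <- qc_filter(mk(0.04))
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$removed$reason, "maf")
  # clean biallelic common locus kept
  expect_equal(nrow(qc_filter(mk(0.5))$kept), 1)
  # frequencies 0.00..0.45: only 0.00 removed (0.05 kept under strict <)
  grid <- do.call(rbind, lapply(seq(0, 0.45, by = 0.05), mk))
  res2 <- qc_filter(grid, maf_min = 0.05)
  expect_equal(nrow(res2$kept), 9)
  expect_equal(res2$removed$freq_a1, 0)
  # reason precedence and the other filters
  multi <- qc_filter(mk(0.04, bi = FALSE))
  expect_equal(multi$removed$reason, "non-biallelic")
  expect_equal(qc_filter(mk(0.3, cr = 0.9))$removed$reason, "callrate")
  expect_equal(qc_filter(mk(0.3, hom = 0.95), hom_min = 0.99)$removed$reason,
               "homozygosity")
  # hom filter off by default
  expect_equal(nrow(qc_filter(mk(0.3, hom = 0.5))$kept), 1)
  # idempotent; empty input passes through
  again <- qc_filter(res2$kept, maf_min = 0.05)
  expect_identical(again$kept, res2$kept)
  expect_equal(nrow(again$removed), 0)
  empty <- qc_filter(grid[0, ])
  expect_equal(nrow(empty$kept), 0)
})

test_that("NSS files round-trip losslessly and validate on read", {
  sim <- sim_genotypes(60, 1000, seed = 21)
  y <- sim_phenotype(sim$genotypes, seed = 22)
  Z <- matrix(rnorm(120), 60, 2)
  nss <- encode_nss(sim$genotypes, y, Z, map = sim$map)
  prefix <- file.path(tempdir(), "rt")
  write_nss(nss, prefix)
  # line count: one header plus one row per locus
  expect_length(readLines(paste0(prefix, ".lnss")), 1001)
  back <- read_nss(prefix)
  expect_equal(back$generic$n, nss$generic$n)
  expect_equal(back$generic$C, nss$generic$C, tolerance = 1e-9)
  num <- c("freq_a1", "call_rate", "var_x", "cov_xy", "cov_xz1", "cov_xz2")
  for (col in num)
    expect_equal(back$loci[[col]], nss$loci[[col]], tolerance = 1e-9)
  expect_identical(back$loci$snp_id, nss$loci$snp_id)

  # covariate-count mismatch between the two files
  nss3 <- encode_nss(sim$genotypes[, 1:5], y, matrix(rnorm(180), 60, 3))
  prefix2 <- file.path(tempdir(), "rt2")
  write_nss(nss3, prefix2)
  file.copy(paste0(prefix, ".lnss"), paste0(prefix2, ".lnss"),
            overwrite = TRUE)  # m=2 loci against m=3 generic
  expect_error(read_nss(prefix2), "covariate-count mismatch")

  # duplicate snp_id reported with its line number
  lines <- readLines(paste0(prefix, ".lnss"))
  writeLines(c(lines, lines[2]), paste0(prefix, ".lnss"))
  expect_error(read_nss(prefix), "duplicate snp_id.*line 1002")

  # malformed rows reported with line numbers
  writeLines(c(lines[1:3], "too\tfew\tfields"), paste0(prefix, ".lnss"))
  expect_error(read_nss(prefix), "line 4")
})

test_that("the printed worked-example fixture survives a file round-trip", {
  phi <- worked_example_phi()
  parts <- phi_to_nss(phi, snp_id = "demo")
  loci <- data.frame(snp_id = "demo", chrom = "1", pos = 1L, a1 = "A",
                     a2 = "G", freq_a1 = 0.23, call_rate = 1,
                     var_x = parts$locus$var_x, cov_xy = parts$locus$cov_xy,
                     cov_xz1 = parts$locus$cov_xz[1],
                     cov_xz2 = parts$locus$cov_xz[2],
                     cov_xz3 = parts$locus$cov_xz[3],
                     hom_rate = NA_real_, biallelic = TRUE,
                     monomorphic = FALSE)
  nss <- structure(list(generic = parts$generic, loci = loci),
                   class = "nss")
  prefix <- file.path(tempdir(), "demo")
  write_nss(nss, prefix)
  back <- read_nss(prefix)
  phi2 <- assemble_phi(back$generic, back$loci[1, ])
  expect_equal(unname(phi2$M), unname(phi$M), tolerance = 1e-9)
})
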