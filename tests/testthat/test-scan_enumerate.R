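make_nss <- function(seed, n = 120, L = 50, m = 3, structure = FALSE) {
  sim <- sim_genotypes(n, L, n_subpops = if (structure) 2 else 1,
                       fst = if (structure) 0.1 else 0, seed = seed)
  y <- sim_phenotype(sim$genotypes, seed = seed + 1)
  Z <- if (m > 0) top_eigenvectors(grm(sim$genotypes), m) else NULL
  encode_nss(sim$genotypes, y, Z, map = sim$map)
}

test_that("oath_scan is deterministic and carries degenerate loci flagged", {
  nss <- make_nss(31)
  s1 <- oath_scan(nss, 1:3)
  s2 <- oath_scan(nss, 1:3)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$lambda_gc, s2$lambda_gc)
  # single-locus input
  nss1 <- nss
  nss1$loci <- nss1$loci[1, , drop = FALSE]
  expect_equal(nrow(oath_scan(nss1, integer(0))$records), 1)
  # a monomorphic locus stays in the records, flagged
  nssm <- nss
  nssm$loci$var_x[3] <- 0
  nssm$loci$cov_xy[3] <- 0
  nssm$loci[3, c("cov_xz1", "cov_xz2", "cov_xz3")] <- 0
  sm <- oath_scan(nssm, 1:3)
  expect_equal(nrow(sm$records), nrow(nssm$loci))
  expect_true(sm$records$degenerate[3])
  expect_match(sm$records$reason[3], "monomorphic")
})

test_that("scan results match per-locus kernel fits", {
  nss <- make_nss(37, L = 20)
  sc <- oath_scan(nss, c(1, 3))
  for (i in c(1, 7, 20)) {
    phi <- assemble_phi(nss$generic, nss$loci[i, ])
    fit <- oath_fit(phi, c(1, 3))
    expect_equal(sc$records$beta[i], fit$beta[1])
    expect_equal(sc$records$mlog10p[i], fit$mlog10p)
  }
})

test_that("lambda_gc matches the chi-square(1) median definition", {
  med <- qchisq(0.5, 1)
  expect_equal(lambda_gc(rep(med, 10)), 1)
  x <- rexp(100)
  expect_equal(lambda_gc(2 * x), 2 * lambda_gc(x))
  set.seed(41)
  expect_equal(lambda_gc(rchisq(1e5, 1)), 1, tolerance = 0.02)
  expect_error(lambda_gc(numeric(0)), "empty")
  expect_error(lambda_gc(c(1, -1)), "non-negative")
})

test_that("a null unstructured scan has lambda_gc near 1", {
  sim <- sim_genotypes(200, 5000, seed = 43)
  y <- sim_phenotype(sim$genotypes, seed = 44)
  nss <- encode_nss(sim$genotypes, y, map = sim$map)
  sc <- oath_scan(nss, integer(0))
  expect_gt(sc$lambda_gc, 0.9)
  expect_lt(sc$lambda_gc, 1.1)
})

test_that("gc_adjust deflates only when lambda exceeds 1", {
  nss <- make_nss(47)
  sc <- oath_scan(nss, 1:3)
  # forced lambda = 1: untouched
  sc1 <- sc
  sc1$lambda_gc <- 1
  adj1 <- gc_adjust(sc1)
  expect_equal(adj1$records$mlog10p_gc, sc$records$mlog10p)
  # forced lambda = 2: chi-square tail of t^2 / 2
  sc2 <- sc
  sc2$lambda_gc <- 2
  adj2 <- gc_adjust(sc2)
  i <- which.max(abs(sc$records$t))
  expect_equal(adj2$records$chisq_gc[i], sc$records$t[i]^2 / 2)
  expect_equal(adj2$records$mlog10p_gc[i],
               -pchisq(sc$records$t[i]^2 / 2, 1, lower.tail = FALSE,
                       log.p = TRUE) / log(10))
  # t^2 = 10 under lambda 2 -> chi-square 5
  expect_equal(adj2$records$chisq_gc[which.min(abs(sc$records$t^2 - 10))],
               sc$records$t[which.min(abs(sc$records$t^2 - 10))]^2 / 2)
  # deflation: adjusted never above unadjusted for a clearly inflated lambda
  sc3 <- sc
  sc3$lambda_gc <- 1.5
  adj3 <- gc_adjust(sc3)
  ok <- !adj3$records$degenerate
  expect_true(all(adj3$records$mlog10p_gc[ok] <=
                    adj3$records$mlog10p[ok] + 1e-12))
})

test_that("enumeration covers every covariate subset exactly once", {
  nss5 <- make_nss(53, n = 100, L = 3, m = 5)
  enum5 <- enumerate_models(nss5$generic, nss5$loci[1, ])
  expect_equal(nrow(enum5$table), 32)
  expect_equal(length(unique(enum5$table$subset)), 32)
  nss3 <- make_nss(54, m = 3, L = 2)
  expect_equal(nrow(enumerate_models(nss3$generic, nss3$loci[1, ],
                                     include_empty = FALSE)$table), 7)
  nss0 <- make_nss(55, m = 0, L = 2)
  expect_equal(nrow(enumerate_models(nss0$generic, nss0$loci[1, ])$table), 1)
  g_wide <- generic_nss(100, diag(22))
  l <- locus_nss("s", freq_a1 = 0.5, var_x = 0.5, cov_xy = 0.1,
                 cov_xz = rep(0, 21))
  expect_error(enumerate_models(g_wide, l), "2\\^21")
})

test_that("each enumerated subset equals the matching scan, locus by locus", {
  nss <- make_nss(59, L = 10, m = 3)
  enum <- enumerate_scan(nss)
  for (s in list(integer(0), 2L, c(1L, 3L), 1:3)) {
    sc <- oath_scan(nss, s)
    mask <- subset_mask(s, 3)
    sub <- enum$models[enum$models$subset == mask, ]
    expect_equal(sub$beta, sc$records$beta, tolerance = 1e-12)
    expect_equal(sub$mlog10p, sc$records$mlog10p, tolerance = 1e-12)
  }
})

test_that("Bonferroni thresholds and hit calling follow the strict rule", {
  expect_equal(round(bonferroni_threshold(0.05, 156744), 2), 6.50)
  expect_equal(bonferroni_threshold(0.05, 1), -log10(0.05))
  expect_equal(bonferroni_threshold(0.05, 9124), -log10(0.05 / 9124))
  expect_equal(round(bonferroni_threshold(0.05, 9124), 2), 5.26)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  # strictness: a locus exactly at the threshold is not a hit
  tab <- data.frame(snp_id = c("a", "b"),
                    mlog10p = c(-log10(0.05 / 100), -log10(0.04 / 100)))
  h <- call_hits(tab, alpha = 0.05, n_tests = 100)
  expect_identical(h$hits$snp_id, "b")
  # raising n_tests never adds hits
  set.seed(61)
  tab2 <- data.frame(snp_id = paste0("s", 1:200),
                     mlog10p = rexp(200, 1 / 2))
  n_hits <- vapply(c(10, 100, 1000, 1e5), function(nt)
    nrow(call_hits(tab2, 0.05, nt)$hits), numeric(1))
  expect_true(all(diff(n_hits) <= 0))
  # enumeration input: any subset above threshold makes an OATH hit
  summ <- data.frame(snp_id = c("a", "b"), max_mlog10p = c(7.2, 3.0))
  he <- call_hits(summ, 0.05, 156744)
  expect_identical(he$hits$snp_id, "a")
})

test_that("partition_pvalues groups by strict unit gaps, order-invariantly", {
  # one tight group
  p1 <- partition_pvalues(c(7.01, 7.05, 7.14))
  expect_length(p1$groups, 1)
  # two groups: gap > 1 between 1.0 and 2.5
  p2 <- partition_pvalues(c(2.5, 1.0, 2.7))
  expect_equal(unname(lengths(p2$groups)), c(1, 2))
  expect_equal(unname(p2$groups[[1]]), 1.0)
  # a gap of exactly one unit stays in-group
  expect_length(partition_pvalues(c(1, 2, 3))$groups, 1)
  # concatenation reproduces the sorted input; neighbour gaps <= 1 in-group
  set.seed(67)
  for (rep in 1:50) {
    v <- runif(sample(2:40, 1), 0, 12)
    part <- partition_pvalues(v)
    expect_equal(unlist(part$groups, use.names = FALSE), sort(v))
    expect_true(all(vapply(part$groups, function(g)
      all(diff(g) <= 1), logical(1))))
    # O(n^2) connected-components oracle agrees
    oracle <- partition_oracle(v)
    expect_equal(unname(lapply(part$groups, unname)),
                 unname(lapply(oracle, unname)))
    # order invariance
    part2 <- partition_pvalues(sample(v))
    expect_equal(part2$group, part$group)
  }
})

test_that("anova_f reproduces the one-way F statistic", {
  # hand case: between SS 13.5, within MS 1
  res <- anova_f(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$f, 13.5)
  # textbook oracle on random grouped data
  set.seed(71)
  for (rep in 1:10) {
    g <- sample(2:5, 1)
    groups <- lapply(seq_len(g), function(i) rnorm(sample(3:10, 1), i))
    res <- anova_f(groups)
    v <- unlist(groups)
    fac <- factor(rep(seq_len(g), lengths(groups)))
    oracle <- anova(lm(v ~ fac))
    expect_equal(res$f, oracle$`F value`[1], tolerance = 1e-10)
    expect_equal(10^(-res$mlog10p), oracle$`Pr(>F)`[1], tolerance = 1e-8)
  }
  # zero within-group variance: infinite F, capped p
  degen <- anova_f(list(c(0, 0), c(1, 1)))
  expect_identical(degen$f, Inf)
  expect_equal(degen$mlog10p, 300)
  # single group or zero total variance: not applicable
  expect_true(is.na(anova_f(list(c(1, 2, 3)))$f))
  expect_true(is.na(anova_f(list(c(1, 1), c(1, 1)))$f))
  # accepts a partition object directly
  part <- partition_pvalues(c(1, 1.2, 4, 4.1))
  expect_equal(anova_f(part)$f, anova_f(part$groups)$f)
})

test_that("enumerate_scan summarises grouping and F per locus", {
  nss <- make_nss(73, L = 6, m = 3)
  es <- enumerate_scan(nss)
  expect_equal(nrow(es$summary), 6)
  expect_true(all(es$summary$min_mlog10p <= es$summary$max_mlog10p))
  expect_true(all(es$summary$n_groups >= 1))
  # per-locus recheck of one row
  enum <- enumerate_models(nss$generic, nss$loci[2, ])
  ev <- evaluate_enumeration(enum)
  expect_equal(es$summary$max_mlog10p[2], ev$max_mlog10p)
  expect_equal(es$summary$f_stat[2], ev$f_stat)
})
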