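# Independent oracles used across test files.

# Brute-force least squares on individual-level data for a covariate
# subset: lm() with an intercept, SNP term first.
ols_oracle <- function(y, x, Z, s) {
  Zs <- Z[, s, drop = FALSE]
  dat <- data.frame(y = y, x = x)
  fit <- if (length(s)) {
    colnames(Zs) <- paste0("z", seq_along(s))
    summary(lm(y ~ ., data = cbind(dat, Zs)))
  } else summary(lm(y ~ x, data = dat))
  co <- coef(fit)[-1, , drop = FALSE]  # drop intercept
  list(beta = co[, 1], se = co[, 2], t = co[, 3],
       df = fit$df[2], p = co[, 4])
}

# O(n^2) segmentation oracle: connected components of the graph joining
# any two values at distance <= gap, read off in sorted order.
partition_oracle <- function(v, gap = 1.0) {
  v <- sort(v)
  n <- length(v)
  adj <- abs(outer(v, v, "-")) <= gap
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- k
      frontier <- which(is.na(comp) &
                          apply(adj[, frontier, drop = FALSE], 1, any))
    }
  }
  split(v, comp)
}

# Small random individual-level dataset plus its encoded NSS.
random_dataset <- function(seed, n = 50, m = 3, maf = 0.3) {
  set.seed(seed)
  x <- rbinom(n, 2, maf)
  while (sd(x) == 0) x <- rbinom(n, 2, maf)
  Z <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("z", 1:m)))
  y <- 0.2 * x + drop(Z %*% runif(m, -0.3, 0.3)) + rnorm(n)
  nss <- encode_nss(cbind(snp1 = x), y, Z)
  phi <- assemble_phi(nss$generic, nss$loci[1, ])
  list(x = x, y = y, Z = Z, nss = nss, phi = phi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

all_subsets_of <- function(m) {
  masks <- 0:(2^m - 1)
  lapply(masks, function(b) which(bitwAnd(b, 2^(0:(m - 1))) > 0))
}
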