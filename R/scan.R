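# Genome-wide scanning, subset enumeration, hit calling, genomic control
# and the p-value grouping / one-way F in-depth evaluation.

# chi-square(1) median; divisor of the genomic-control lambda.
.chisq1_median <- stats::qchisq(0.5, df = 1)

# -log10 p reported for an infinite F (zero within-group variance).
.mlog10p_cap <- 300

#' Parse a covariate-subset specification
#'
#' Accepts a `+/-` inclusion mask (length `m`; the Unicode minus is
#' accepted alongside ASCII `-`), a comma-separated index list such as
#' `"1,3"`, or the words `"all"` / `"saturated"` and `"none"` / `"naive"`.
#'
#' @param spec Character scalar.
#' @param m Number of available covariates.
#' @return Sorted integer vector of 1-based covariate indices.
#' @examples
#' parse_subset("+-+--", 5)  # c(1, 3)
#' @export
parse_subset <- function(spec, m) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- gsub("−", "-", trimws(spec))
  if (spec %in% c("all", "saturated")) return(seq_len(m))
  if (spec %in% c("none", "naive", "")) return(integer(0))
  if (grepl("^[+-]+$", spec)) {
    glyphs <- strsplit(spec, "")[[1]]
    if (length(glyphs) != m)
      stop("subset mask '", spec, "' has length ", length(glyphs),
           " but there are ", m, " covariates", call. = FALSE)
    return(which(glyphs == "+"))
  }
  if (grepl("^[0-9]+(,[0-9]+)*$", spec)) {
    s <- sort(unique(as.integer(strsplit(spec, ",")[[1]])))
    if (length(s) && (min(s) < 1L || max(s) > m))
      stop("subset indices must lie in 1..", m, call. = FALSE)
    return(s)
  }
  stop("cannot parse subset specification '", spec, "'", call. = FALSE)
}

#' Render a covariate subset as a +/- inclusion mask
#'
#' @param s Integer indices.
#' @param m Number of covariates.
#' @return Character scalar such as `"+-+--"`.
#' @export
subset_mask <- function(s, m) {
  glyphs <- rep("-", m)
  glyphs[s] <- "+"
  paste(glyphs, collapse = "")
}

#' Genome-wide OATH scan for one covariate subset
#'
#' Fits every locus of an NSS set under the covariate subset `s` and
#' attaches the genomic-control lambda computed from the squared SNP t
#' statistics. Loci that cannot be fitted (monomorphic, collinear) are
#' carried in the output with `degenerate = TRUE` and a `reason`, never
#' silently dropped, and never abort the scan.
#'
#' @param nss An `nss` object.
#' @param s Covariate subset ([parse_subset()] forms accepted); default:
#'   all covariates (the saturated model).
#' @param df_convention See [oath_fit()].
#' @return An object of class `oath_scan`: list with `subset`, `records`
#'   (one data-frame row per locus: `snp_id, chrom, pos, a1, a2, freq_a1,
#'   beta, se, t, mlog10p, degenerate, reason`), `lambda_gc`, `df`, `n`.
#' @export
oath_scan <- function(nss, s = NULL, df_convention = c("centered", "ols")) {
  df_convention <- match.arg(df_convention)
  stopifnot(inherits(nss, "nss"))
  m <- n_covariates(nss)
  if (is.null(s)) s <- seq_len(m)
  s <- .validate_subset(if (is.character(s)) parse_subset(s, m) else s, m)
  loci <- nss$loci
  L <- nrow(loci)
  beta <- se <- t_stat <- mlp <- rep(NA_real_, L)
  degen <- rep(FALSE, L)
  reason <- rep(NA_character_, L)
  df <- NA_integer_
  for (i in seq_len(L)) {
    fit <- tryCatch({
      phi <- assemble_phi(nss$generic, as_locus_nss(loci, i))
      oath_fit(phi, s, df_convention)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      degen[i] <- TRUE
      reason[i] <- conditionMessage(fit)
      next
    }
    beta[i] <- fit$beta[1]
    se[i] <- fit$se[1]
    t_stat[i] <- fit$t[1]
    mlp[i] <- fit$mlog10p
    df <- fit$df
    if (fit$degenerate) {
      degen[i] <- TRUE
      reason[i] <- "zero residual variance"
    }
  }
  records <- data.frame(snp_id = loci$snp_id, chrom = loci$chrom,
                        pos = loci$pos, a1 = loci$a1, a2 = loci$a2,
                        freq_a1 = loci$freq_a1, beta = beta, se = se,
                        t = t_stat, mlog10p = mlp, degenerate = degen,
                        reason = reason, stringsAsFactors = FALSE)
  chisq <- t_stat[!degen & !is.na(t_stat)]^2
  lam <- if (length(chisq)) lambda_gc(chisq) else NA_real_
  structure(list(subset = s, records = records, lambda_gc = lam,
                 df = df, n = nss$generic$n,
                 df_convention = df_convention,
                 m = m),
            class = "oath_scan")
}

#' @export
print.oath_scan <- function(x, ...) {
  cat("OATH scan, subset {", paste(x$subset, collapse = ","), "}:",
      nrow(x$records), "loci,", sum(x$records$degenerate), "flagged,",
      "lambda_GC =", round(x$lambda_gc, 4), "\n")
  invisible(x)
}

#' Genomic-control inflation factor
#'
#' `lambda_GC = median(chisq) / qchisq(0.5, 1)` for a vector of 1-df
#' association statistics; values near 1 indicate a well-calibrated null,
#' values above 1 inflation such as uncorrected population stratification.
#'
#' @param chisq Non-empty vector of non-negative 1-df statistics.
#' @return The inflation factor (scalar).
#' @export
lambda_gc <- function(chisq) {
  chisq <- as.numeric(chisq)
  if (length(chisq) == 0L) stop("empty statistic vector", call. = FALSE)
  if (any(is.na(chisq)) || any(chisq < 0))
    stop("chisq statistics must be non-negative and non-missing",
         call. = FALSE)
  stats::median(chisq) / .chisq1_median
}

#' Genomic-control adjustment of a scan
#'
#' When `lambda_gc > 1`, each SNP statistic `t^2` is deflated to
#' `t^2 / lambda_gc` and the p-value recomputed from the 1-df chi-square
#' tail; when `lambda_gc <= 1` the statistics are left unchanged (genomic
#' control only ever deflates). Original columns are retained; the
#' adjusted ones are added as `chisq_gc` and `mlog10p_gc`.
#'
#' @param scan An `oath_scan`.
#' @return The scan with adjusted columns added and `gc_adjusted = TRUE`.
#' @export
gc_adjust <- function(scan) {
  stopifnot(inherits(scan, "oath_scan"))
  lam <- scan$lambda_gc
  if (is.na(lam)) stop("scan has no lambda_gc", call. = FALSE)
  rec <- scan$records
  if (lam > 1) {
    rec$chisq_gc <- rec$t^2 / lam
    rec$mlog10p_gc <- mlog10_p_from_chisq1(rec$chisq_gc)
  } else {
    rec$chisq_gc <- rec$t^2
    rec$mlog10p_gc <- rec$mlog10p
  }
  scan$records <- rec
  scan$gc_adjusted <- TRUE
  scan
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' `-log10(alpha / (n_tests * n_models * n_traits))`, the family-wise
#' threshold for a scan of `n_tests` markers, optionally widened for
#' multiple models and traits. Computed directly, never hard-coded.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of markers tested (>= 1).
#' @param n_models,n_traits Optional extra multiplicities.
#' @return The threshold on the `-log10(p)` scale.
#' @examples
#' bonferroni_threshold(0.05, 156744)  # 6.496... -> 6.50 at two decimals
#' @export
bonferroni_threshold <- function(alpha, n_tests, n_models = 1, n_traits = 1) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  -log10(alpha) + log10(n_tests) + log10(n_models) + log10(n_traits)
}

#' Call genome-wide significant hits
#'
#' A locus is a hit iff its `-log10(p)` strictly exceeds the Bonferroni
#' threshold `-log10(alpha / n_tests)`. For an enumeration summary (see
#' [enumerate_scan()]) a locus is an OATH hit iff **any** of its subset
#' models exceeds the threshold, i.e. `max_mlog10p > threshold`.
#'
#' @param x An `oath_scan`, an enumeration summary data frame with a
#'   `max_mlog10p` column, or `NULL` to compute the threshold alone.
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests; defaults to the number of non-degenerate
#'   records in `x`.
#' @return List of class `oath_hits` with `threshold`, `alpha`, `n_tests`
#'   and `hits` (the qualifying records).
#' @export
call_hits <- function(x = NULL, alpha = 0.05, n_tests = NULL) {
  if (is.null(n_tests)) {
    if (inherits(x, "oath_scan"))
      n_tests <- sum(!x$records$degenerate)
    else if (is.data.frame(x)) n_tests <- nrow(x)
    else stop("n_tests must be given when x is NULL", call. = FALSE)
  }
  thr <- bonferroni_threshold(alpha, n_tests)
  hits <- if (inherits(x, "oath_scan")) {
    rec <- x$records
    rec[!rec$degenerate & !is.na(rec$mlog10p) & rec$mlog10p > thr, ,
        drop = FALSE]
  } else if (is.data.frame(x) && "max_mlog10p" %in% names(x)) {
    x[!is.na(x$max_mlog10p) & x$max_mlog10p > thr, , drop = FALSE]
  } else if (is.data.frame(x) && "mlog10p" %in% names(x)) {
    x[!is.na(x$mlog10p) & x$mlog10p > thr, , drop = FALSE]
  } else NULL
  structure(list(threshold = thr, alpha = alpha, n_tests = n_tests,
                 hits = hits),
            class = "oath_hits")
}

#' @export
print.oath_hits <- function(x, ...) {
  cat(sprintf("Bonferroni threshold -log10(%g/%d) = %.2f; %s hit(s)\n",
              x$alpha, x$n_tests, x$threshold,
              if (is.null(x$hits)) "NA" else nrow(x$hits)))
  invisible(x)
}

# All covariate subsets of 1..m as a list, in bitmask order
# (bit j set <=> covariate j included).
.all_subsets <- function(m, include_empty = TRUE) {
  if (m > 20L)
    stop("refusing to enumerate 2^", m, " subsets; restrict the ",
         "covariate set to at most 20", call. = FALSE)
  masks <- if (include_empty) 0:(2^m - 1) else 1:(2^m - 1)
  lapply(masks, function(b) which(bitwAnd(b, bitwShiftL(1L, 0:(m - 1))) > 0))
}

#' Enumerate all covariate-subset models for one locus
#'
#' Fits every subset of the `m` covariates (`2^m` models, or `2^m - 1`
#' when the empty, covariate-free model is excluded). Subsets that cannot
#' be fitted are carried as flagged entries.
#'
#' @param generic A [generic_nss()].
#' @param locus A [locus_nss()] or one-row loci-table slice.
#' @param include_empty Include the naive (no-covariate) model.
#' @param df_convention See [oath_fit()].
#' @return Object of class `oath_enumeration`: list with `snp_id`, `fits`
#'   (named by `+/-` mask), and `table` (one row per subset: `subset`, `k`,
#'   `beta`, `se`, `t`, `mlog10p`, `degenerate`).
#' @export
enumerate_models <- function(generic, locus, include_empty = TRUE,
                             df_convention = c("centered", "ols")) {
  df_convention <- match.arg(df_convention)
  locus <- as_locus_nss(locus)
  m <- n_covariates(generic)
  subsets <- .all_subsets(m, include_empty)
  phi <- assemble_phi(generic, locus)
  masks <- vapply(subsets, subset_mask, character(1), m = m)
  fits <- vector("list", length(subsets))
  names(fits) <- masks
  tab <- data.frame(subset = masks,
                    k = vapply(subsets, length, integer(1)),
                    beta = NA_real_, se = NA_real_, t = NA_real_,
                    mlog10p = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(subsets)) {
    fit <- tryCatch(oath_fit(phi, subsets[[i]], df_convention),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tab$degenerate[i] <- TRUE
      fits[[i]] <- list(error = conditionMessage(fit))
      next
    }
    fits[[i]] <- fit
    tab$beta[i] <- fit$beta[1]
    tab$se[i] <- fit$se[1]
    tab$t[i] <- fit$t[1]
    tab$mlog10p[i] <- fit$mlog10p
    tab$degenerate[i] <- fit$degenerate
  }
  structure(list(snp_id = locus$snp_id, m = m, fits = fits, table = tab),
            class = "oath_enumeration")
}

#' @export
print.oath_enumeration <- function(x, ...) {
  cat("OATH enumeration for", x$snp_id, ":", nrow(x$table), "models\n")
  print(utils::head(x$table, 8), row.names = FALSE)
  if (nrow(x$table) > 8) cat("...\n")
  invisible(x)
}

#' In-depth evaluation of one enumerated locus
#'
#' Sorts the `-log10(p)` values of all subset models, partitions them into
#' groups wherever two neighbours differ by more than a unit
#' ([partition_pvalues()]) and, when more than one group emerges, computes
#' the one-way F statistic across groups ([anova_f()]): a locus whose
#' evidence depends strongly on the covariate combination shows several
#' well-separated groups and a large F.
#'
#' @param enumeration An `oath_enumeration`.
#' @param gap Group-break gap on the `-log10(p)` scale (default 1).
#' @return List with `min_mlog10p`, `max_mlog10p`, `n_groups`, `f_stat`,
#'   `mlog10p_f` and the `partition`.
#' @export
evaluate_enumeration <- function(enumeration, gap = 1.0) {
  stopifnot(inherits(enumeration, "oath_enumeration"))
  v <- enumeration$table$mlog10p
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    return(list(min_mlog10p = NA_real_, max_mlog10p = NA_real_,
                n_groups = NA_integer_, f_stat = NA_real_,
                mlog10p_f = NA_real_, partition = NULL))
  part <- partition_pvalues(v, gap = gap)
  aov1 <- anova_f(part$groups)
  list(min_mlog10p = min(v), max_mlog10p = max(v),
       n_groups = length(part$groups), f_stat = aov1$f,
       mlog10p_f = aov1$mlog10p, partition = part)
}

#' Enumerate all subset models across every locus of an NSS set
#'
#' Streams locus by locus (only the per-locus model map is held at a
#' time unless `keep_fits = TRUE`).
#'
#' @param nss An `nss` object.
#' @inheritParams enumerate_models
#' @param keep_fits Keep every per-locus `oath_enumeration` (memory grows
#'   with `loci x 2^m`).
#' @param gap Grouping gap for [evaluate_enumeration()].
#' @return Object of class `oath_enum_scan`: list with `summary` (one row
#'   per locus: `snp_id, min_mlog10p, max_mlog10p, n_groups, f_stat,
#'   mlog10p_f`), `models` (long data frame of all per-subset results) and
#'   optionally `fits`.
#' @export
enumerate_scan <- function(nss, include_empty = TRUE,
                           df_convention = c("centered", "ols"),
                           keep_fits = FALSE, gap = 1.0) {
  df_convention <- match.arg(df_convention)
  stopifnot(inherits(nss, "nss"))
  L <- nrow(nss$loci)
  summaries <- vector("list", L)
  models <- vector("list", L)
  fits <- if (keep_fits) vector("list", L) else NULL
  for (i in seq_len(L)) {
    enum <- tryCatch(
      enumerate_models(nss$generic, as_locus_nss(nss$loci, i),
                       include_empty, df_convention),
      error = function(e) e)
    id <- nss$loci$snp_id[i]
    if (inherits(enum, "error")) {
      summaries[[i]] <- data.frame(snp_id = id, min_mlog10p = NA_real_,
                                   max_mlog10p = NA_real_,
                                   n_groups = NA_integer_,
                                   f_stat = NA_real_, mlog10p_f = NA_real_,
                                   stringsAsFactors = FALSE)
      next
    }
    ev <- evaluate_enumeration(enum, gap = gap)
    summaries[[i]] <- data.frame(snp_id = id,
                                 min_mlog10p = ev$min_mlog10p,
                                 max_mlog10p = ev$max_mlog10p,
                                 n_groups = ev$n_groups,
                                 f_stat = ev$f_stat,
                                 mlog10p_f = ev$mlog10p_f,
                                 stringsAsFactors = FALSE)
    models[[i]] <- cbind(snp_id = id, enum$table, stringsAsFactors = FALSE)
    if (keep_fits) fits[[i]] <- enum
  }
  structure(list(summary = do.call(rbind, summaries),
                 models = do.call(rbind, models), fits = fits,
                 include_empty = include_empty),
            class = "oath_enum_scan")
}

#' Partition sorted -log10(p) values into gap-separated groups
#'
#' Values are sorted ascending; a new group starts exactly where the gap
#' to the previous value strictly exceeds `gap` (default one unit — a gap
#' of exactly 1 stays in-group). The concatenated groups reproduce the
#' sorted input, and the partition is invariant to the input order.
#'
#' @param mlog10p Non-empty numeric vector.
#' @param gap Break gap (default 1).
#' @return List with `values` (sorted), `group` (integer label per sorted
#'   value) and `groups` (list of numeric vectors).
#' @export
partition_pvalues <- function(mlog10p, gap = 1.0) {
  v <- as.numeric(mlog10p)
  if (length(v) == 0L || anyNA(v))
    stop("mlog10p must be non-empty and non-missing", call. = FALSE)
  v <- sort(v)
  id <- cumsum(c(1L, as.integer(diff(v) > gap)))
  list(values = v, group = id, groups = split(v, id))
}

#' One-way ANOVA F across p-value groups
#'
#' The between-group mean square over the within-group mean square for the
#' grouped `-log10(p)` values, with its p-value from `F(g - 1, N - g)`.
#' With a single group or zero total variance the statistic is not
#' applicable and `NA` is returned; with zero within-group but positive
#' between-group variance the F is `+Inf` and the `-log10 p` is reported
#' at the cap of 300.
#'
#' @param groups List of non-empty numeric vectors, or the result of
#'   [partition_pvalues()].
#' @return List with `f`, `df1`, `df2`, `mlog10p`.
#' @export
anova_f <- function(groups) {
  if (is.list(groups) && !is.null(groups$groups)) groups <- groups$groups
  stopifnot(is.list(groups), all(lengths(groups) > 0))
  g <- length(groups)
  v <- unlist(groups, use.names = FALSE)
  N <- length(v)
  if (g < 2L || N <= g)
    return(list(f = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                mlog10p = NA_real_))
  means <- vapply(groups, mean, numeric(1))
  sizes <- lengths(groups)
  grand <- mean(v)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  df1 <- g - 1L
  df2 <- N - g
  if (ssb <= 0 && ssw <= 0)
    return(list(f = NA_real_, df1 = df1, df2 = df2, mlog10p = NA_real_))
  if (ssw <= 0)
    return(list(f = Inf, df1 = df1, df2 = df2, mlog10p = .mlog10p_cap))
  f <- (ssb / df1) / (ssw / df2)
  mlp <- -stats::pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(f = f, df1 = df1, df2 = df2, mlog10p = min(mlp, .mlog10p_cap))
}
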