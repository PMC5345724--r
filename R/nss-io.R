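# The NSS exchange format.
#
# <prefix>.gnss : JSON {n, covariate_names, C} with C stored row-major —
#                 the generic block, shared genome-wide.
# <prefix>.lnss : TSV, one row per locus, header
#                 SNP CHR BP A1 A2 FREQ CALLRATE VAR_X COV_XY COV_XZ1..m
# Numbers are written at %.10g so a round trip is lossless to ~1e-9
# relative; both files are plain text and diff-able.

.lnss_header <- function(m)
  c("SNP", "CHR", "BP", "A1", "A2", "FREQ", "CALLRATE", "VAR_X", "COV_XY",
    if (m > 0) paste0("COV_XZ", seq_len(m)))

#' Write an NSS set to the exchange format
#'
#' @param nss An `nss` object ([encode_nss()]).
#' @param prefix Output path prefix; writes `<prefix>.gnss` and
#'   `<prefix>.lnss`.
#' @return The two paths, invisibly.
#' @seealso [read_nss()]
#' @export
write_nss <- function(nss, prefix) {
  stopifnot(inherits(nss, "nss"))
  g <- nss$generic
  gpath <- paste0(prefix, ".gnss")
  lpath <- paste0(prefix, ".lnss")
  jsonlite::write_json(
    list(format = "nss", version = 1L, n = g$n,
         covariate_names = as.list(g$covariate_names),
         C = as.numeric(t(g$C))),
    gpath, auto_unbox = TRUE, digits = NA)
  m <- n_covariates(g)
  loci <- nss$loci
  num <- function(v) sprintf("%.10g", v)
  rows <- cbind(loci$snp_id, loci$chrom, as.character(loci$pos),
                loci$a1, loci$a2, num(loci$freq_a1), num(loci$call_rate),
                num(loci$var_x), num(loci$cov_xy))
  if (m > 0)
    rows <- cbind(rows, do.call(cbind, lapply(.cov_names(m),
                                              function(cn) num(loci[[cn]]))))
  con <- file(lpath, "w")
  on.exit(close(con))
  writeLines(paste(.lnss_header(m), collapse = "\t"), con)
  writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  invisible(c(gpath, lpath))
}

#' Read an NSS set from the exchange format
#'
#' Parse errors (malformed header, wrong field count, non-numeric values,
#' covariate-count mismatch between the generic and locus files, duplicate
#' SNP ids) are reported with the offending file and line number.
#'
#' @param prefix Path prefix used by [write_nss()].
#' @return An `nss` object. Loci read from disk carry `hom_rate = NA` and
#'   `biallelic = TRUE` (the format stores neither).
#' @export
read_nss <- function(prefix) {
  gpath <- paste0(prefix, ".gnss")
  lpath <- paste0(prefix, ".lnss")
  for (p in c(gpath, lpath))
    if (!file.exists(p)) stop("missing NSS file: ", p, call. = FALSE)
  gj <- tryCatch(jsonlite::read_json(gpath, simplifyVector = TRUE),
                 error = function(e) stop("malformed .gnss JSON in ", gpath,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(gj$n) || is.null(gj$C))
    stop("malformed .gnss header in ", gpath,
         ": fields n and C are required", call. = FALSE)
  cn <- as.character(unlist(gj$covariate_names))
  m <- length(cn)
  C <- matrix(as.numeric(gj$C), m + 1L, m + 1L, byrow = TRUE)
  generic <- generic_nss(gj$n, C, covariate_names = cn)

  lines <- readLines(lpath)
  if (length(lines) == 0L)
    stop("empty .lnss file: ", lpath, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  n_cov_cols <- sum(grepl("^COV_XZ", header))
  expected <- .lnss_header(n_cov_cols)
  if (!identical(header, expected))
    stop("malformed .lnss header at ", lpath, " line 1", call. = FALSE)
  if (n_cov_cols != m)
    stop("covariate-count mismatch: ", lpath, " has ", n_cov_cols,
         " COV_XZ column(s) but ", gpath, " declares m = ", m,
         call. = FALSE)
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(expected)))
    stop("wrong field count at ", lpath, " line ",
         which(nf != length(expected))[1] + 1L, call. = FALSE)
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- expected
  num_cols <- expected[-(1:5)]
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- is.na(v) & !(tab[[col]] %in% c("NA", "nan"))
    if (any(bad))
      stop("non-numeric ", col, " at ", lpath, " line ",
           which(bad)[1] + 1L, call. = FALSE)
    tab[[col]] <- v
  }
  if (anyDuplicated(tab$SNP)) {
    dup <- tab$SNP[duplicated(tab$SNP)][1]
    stop("duplicate snp_id '", dup, "' at ", lpath, " line ",
         which(tab$SNP == dup)[2] + 1L, call. = FALSE)
  }
  loci <- data.frame(snp_id = tab$SNP, chrom = tab$CHR,
                     pos = suppressWarnings(as.integer(tab$BP)),
                     a1 = tab$A1, a2 = tab$A2, freq_a1 = tab$FREQ,
                     call_rate = tab$CALLRATE, var_x = tab$VAR_X,
                     cov_xy = tab$COV_XY, stringsAsFactors = FALSE)
  if (m > 0)
    for (j in seq_len(m))
      loci[[paste0("cov_xz", j)]] <- tab[[paste0("COV_XZ", j)]]
  loci$hom_rate <- NA_real_
  loci$biallelic <- TRUE
  loci$monomorphic <- loci$var_x <= 0
  structure(list(generic = generic, loci = loci), class = "nss")
}
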