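# Individual-level genotype input: PLINK binary (.bed/.bim/.fam,
# SNP-major), plain dosage TSV, and (optionally, via vcfR) VCF. Genotypes
# are returned as counts of the A1 / effect allele.

# 2-bit PLINK codes, LSB-first within a byte:
# 00 -> 2 copies of A1, 01 -> missing, 10 -> het, 11 -> 0 copies of A1.
.bed_decode_table <- local({
  code <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  t(vapply(0:255, function(b)
    code[as.character(bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L))],
    numeric(4)))
})

#' Read a PLINK binary fileset
#'
#' Reads `<prefix>.bed` (SNP-major), `<prefix>.bim` and `<prefix>.fam`.
#' Genotypes are counts of the `.bim` A1 allele; missing calls become
#' `NA`.
#'
#' @param prefix Path prefix of the fileset.
#' @return List with `genotypes` (`n x L` matrix, rows named by IID,
#'   columns by SNP id), `map` (snp_id, chrom, pos, a1, a2) and `fam`.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths)
    if (!file.exists(p)) stop("missing PLINK file: ", p, call. = FALSE)
  bim <- utils::read.table(paths[2], stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  fam <- utils::read.table(paths[3], stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  n <- nrow(fam)
  L <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = 3 + L * bytes_per_snp)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", paths[1], call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported", call. = FALSE)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != L * bytes_per_snp)
    stop("truncated .bed file: expected ", L * bytes_per_snp,
         " data bytes, found ", length(body), call. = FALSE)
  # decode all bytes at once, then reshape: per SNP, 4 samples per byte
  geno <- .bed_decode_table[body + 1L, , drop = FALSE]  # (L*bps) x 4
  G <- matrix(t(geno), nrow = 4 * bytes_per_snp)[seq_len(n), , drop = FALSE]
  dimnames(G) <- list(fam$iid, bim$snp_id)
  list(genotypes = G, map = bim[, c("snp_id", "chrom", "pos", "a1", "a2")],
       fam = fam)
}

#' Read a plain dosage matrix
#'
#' TSV with one row per sample: the first column is the sample id, the
#' remaining (header-named) columns are per-SNP dosages in `[0, 2]`,
#' missing coded `NA`.
#'
#' @param path File path.
#' @return List with `genotypes` (rows named by sample id) and `map`
#'   (ids from the header; chrom/pos/alleles filled with placeholders).
#' @export
read_dosage_tsv <- function(path) {
  if (!file.exists(path)) stop("missing dosage file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("dosage file needs a sample-id column plus >= 1 SNP column",
         call. = FALSE)
  ids <- as.character(tab[[1]])
  G <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(G) <- "double"
  rownames(G) <- ids
  map <- data.frame(snp_id = colnames(G), chrom = NA_character_,
                    pos = seq_len(ncol(G)), a1 = "A1", a2 = "A2",
                    stringsAsFactors = FALSE)
  list(genotypes = G, map = map)
}

#' Read a phenotype or covariate table
#'
#' TSV whose first column is the sample id; remaining columns are numeric,
#' missing coded `NA`.
#'
#' @param path File path.
#' @return Data frame with rownames set to the sample id.
#' @export
read_pheno_tsv <- function(path) {
  if (!file.exists(path)) stop("missing table: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("table needs a sample-id column plus >= 1 value column",
         call. = FALSE)
  rownames(tab) <- as.character(tab[[1]])
  tab[, -1, drop = FALSE]
}

#' Read genotypes from a VCF (biallelic records only)
#'
#' Uses the `vcfR` package (Suggests). Genotypes are counts of the REF
#' allele from the GT field. Multi-allelic records are rejected: they are
#' dropped from the genotype matrix and listed in the `removed` element
#' with reason `"non-biallelic"`.
#'
#' @param path Path to an (optionally compressed) VCF.
#' @return List with `genotypes`, `map` (REF as a1, ALT as a2) and
#'   `removed` (excluded records with their reason).
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  bi <- vcfR::is.biallelic(v)
  fix <- vcfR::getFIX(v)
  count_ref <- function(s) {
    if (is.na(s)) return(NA_real_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "0")
  }
  G <- apply(gt, c(1, 2), count_ref)
  ids <- fix[, "ID"]
  anon <- is.na(ids) | ids == "."
  ids[anon] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[anon]
  map <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), a1 = fix[, "REF"],
                    a2 = fix[, "ALT"], stringsAsFactors = FALSE)
  removed <- cbind(map[!bi, , drop = FALSE], reason = "non-biallelic")
  G <- t(G[bi, , drop = FALSE])  # samples x biallelic loci
  map <- map[bi, , drop = FALSE]
  colnames(G) <- map$snp_id
  list(genotypes = G, map = map, removed = removed)
}
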