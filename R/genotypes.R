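#' Simulate unlinked biallelic genotypes
#'
#' Draws additive dosages at `n_snps` mutually independent SNPs for
#' `n_individuals` individuals. Each SNP's allele frequency is drawn
#' uniformly from `maf_range` and dosages are Binomial(2, p), i.e.
#' Hardy-Weinberg genotypes without linkage disequilibrium. This is the
#' desk-scale stand-in for a pruned genome-wide SNP panel.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param n_snps number of SNPs (>= 1).
#' @param maf_range length-2 numeric, allele-frequency interval within
#'   (0, 0.5].
#' @param seed integer seed for reproducibility.
#' @return a `genotype_matrix`: list with `dosages` (n x m integer matrix of
#'   0/1/2 counts), `allele_freqs`, `snp_ids`, `individual_ids`.
#' @examples
#' g <- simulate_genotypes(100, 50, maf_range = c(0.1, 0.5), seed = 1)
#' dim(g$dosages)
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5), seed = NULL) {
  n_individuals <- check_count(n_individuals, "n_individuals", lower = 2L)
  n_snps <- check_count(n_snps, "n_snps", lower = 1L)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(is.na(maf_range)) || maf_range[1L] > maf_range[2L] ||
      maf_range[1L] <= 0 || maf_range[2L] > 0.5) {
    stop_param("`maf_range` must be an interval within (0, 0.5]")
  }
  with_seed(seed, {
    p <- stats::runif(n_snps, maf_range[1L], maf_range[2L])
    dos <- matrix(
      stats::rbinom(n_individuals * n_snps, size = 2L,
                    prob = rep(p, each = n_individuals)),
      nrow = n_individuals, ncol = n_snps
    )
    genotype_matrix(dos, allele_freqs = p)
  })
}

#' Construct a genotype matrix object
#'
#' @param dosages n x m matrix of additive allele counts in \{0, 1, 2\}.
#' @param allele_freqs per-SNP generating allele frequency; defaults to the
#'   empirical frequency.
#' @param snp_ids,individual_ids identifiers; generated when missing.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, allele_freqs = NULL, snp_ids = NULL,
                            individual_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages) || !all(dosages %in% 0:2)) {
    stop_param("`dosages` must be complete with entries in {0, 1, 2}")
  }
  storage.mode(dosages) <- "integer"
  m <- ncol(dosages)
  n <- nrow(dosages)
  if (is.null(allele_freqs)) allele_freqs <- colMeans(dosages) / 2
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(m))
  if (is.null(individual_ids)) individual_ids <- sprintf("id%d", seq_len(n))
  stopifnot(length(allele_freqs) == m, length(snp_ids) == m,
            length(individual_ids) == n)
  structure(
    list(dosages = dosages, allele_freqs = as.numeric(allele_freqs),
         snp_ids = as.character(snp_ids),
         individual_ids = as.character(individual_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  allele freq range: [%.3f, %.3f]\n",
              min(x$allele_freqs), max(x$allele_freqs)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# ---- PLINK binary (.bed/.bim/.fam) I/O -------------------------------------
# Minimal SNP-major codec for the standard PLINK 1 binary triple. Two-bit
# codes per genotype: 00 = 2 copies of allele 1, 10 = 1 copy, 11 = 0 copies,
# 01 = missing. Missing genotypes are rejected on write (the synthetic
# generator never produces them).

#' Write genotypes as a PLINK .bed/.bim/.fam triple
#'
#' @param genotypes a `genotype_matrix`.
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` are written.
#' @return invisibly, the prefix.
#' @export
write_plink <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  n <- nrow(dos)
  m <- ncol(dos)
  # dosage -> 2-bit code (count of allele 1, here the ALT/effect allele)
  code <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(m)) {
    g <- code[as.character(dos[, j])]
    if (n %% 4 != 0) g <- c(g, rep(0L, 4 - n %% 4))
    gm <- matrix(g, nrow = 4)
    packed <- gm[1, ] + gm[2, ] * 4L + gm[3, ] * 16L + gm[4, ] * 64L
    stopifnot(length(packed) == bytes_per_snp)
    writeBin(as.raw(packed), con)
  }
  bim <- data.frame(chr = 1L, id = genotypes$snp_ids, cm = 0,
                    pos = seq_len(m), a1 = "A", a2 = "G")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = genotypes$individual_ids,
                    iid = genotypes$individual_ids,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam triple
#'
#' @param prefix path prefix of the triple.
#' @return a `genotype_matrix` with dosages counting copies of allele 1
#'   (the .bim A1 allele).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (!identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))) {
    stop_param("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  }
  body <- as.integer(raw[-(1:3)])
  bytes_per_snp <- ceiling(n / 4)
  # decode 2-bit fields: code -> dosage of allele 1
  decode <- c(2L, NA_integer_, 1L, 0L) # codes 0,1,2,3
  dos <- matrix(NA_integer_, nrow = n, ncol = m)
  shifts <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    b <- body[((j - 1L) * bytes_per_snp + 1L):(j * bytes_per_snp)]
    codes <- as.vector(vapply(shifts, function(s) (b %/% s) %% 4L,
                              integer(bytes_per_snp)))
    # vapply above gives byte-major ordering per shift; interleave properly
    codes <- as.vector(t(matrix(codes, nrow = bytes_per_snp)))
    dos[, j] <- decode[codes[seq_len(n)] + 1L]
  }
  if (anyNA(dos)) {
    stop_param("missing genotypes are not supported in this codec")
  }
  genotype_matrix(dos, snp_ids = bim$id, individual_ids = as.character(fam$iid))
}
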