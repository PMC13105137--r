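#' Reference genotype panel
#'
#' Wraps an individuals-by-SNPs dosage matrix (counts of the `a1` allele,
#' 0/1/2, `NA` allowed) together with SNP metadata. Allele frequencies are
#' computed from the non-missing dosages; monomorphic SNPs (frequency 0 or
#' 1) are dropped, since they carry no LD information and break genotype
#' standardization.
#'
#' @param genotypes n x M numeric matrix of a1-allele dosages.
#' @param bim data.frame with columns `chrom, snp_id, pos, a1, a2`
#'   (one row per genotype column).
#' @return A list of class `ref_panel` with elements `genotypes`, `freq`,
#'   `bim`.
#' @export
ref_panel <- function(genotypes, bim) {
  stopifnot(is.matrix(genotypes), nrow(bim) == ncol(genotypes))
  req <- c("chrom", "snp_id", "pos", "a1", "a2")
  if (!all(req %in% names(bim))) {
    stop("bim must have columns: ", paste(req, collapse = ", "))
  }
  freq <- colMeans(genotypes, na.rm = TRUE) / 2
  poly <- freq > 0 & freq < 1 & !is.na(freq)
  if (!all(poly)) {
    message("ref_panel: dropping ", sum(!poly), " monomorphic SNP(s)")
    genotypes <- genotypes[, poly, drop = FALSE]
    bim <- bim[poly, , drop = FALSE]
    freq <- freq[poly]
  }
  if (ncol(genotypes) == 0L) stop("no polymorphic SNPs in panel")
  colnames(genotypes) <- bim$snp_id
  rownames(bim) <- NULL
  structure(list(genotypes = genotypes, freq = unname(freq), bim = bim),
            class = "ref_panel")
}

#' Restrict a reference panel to a SNP subset
#'
#' @param panel A `ref_panel`.
#' @param snp_ids SNP ids to keep, in the desired order (must all be
#'   present).
#' @return A `ref_panel` with the requested SNP columns.
#' @export
subset_panel <- function(panel, snp_ids) {
  idx <- match(snp_ids, panel$bim$snp_id)
  if (anyNA(idx)) {
    stop("panel lacks SNP(s): ",
         paste(head(snp_ids[is.na(idx)], 5), collapse = ", "))
  }
  structure(list(genotypes = panel$genotypes[, idx, drop = FALSE],
                 freq = panel$freq[idx],
                 bim = panel$bim[idx, , drop = FALSE]),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("ref_panel:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "SNPs\n")
  invisible(x)
}

#' Read a PLINK bed/bim/fam fileset into a reference panel
#'
#' Minimal reader for the PLINK 1 binary format (SNP-major). Dosages count
#' copies of the bim file's first allele (A1); the 2-bit codes are
#' 00 = hom A1 (2), 10 = het (1), 11 = hom A2 (0), 01 = missing (`NA`).
#'
#' @param prefix Path prefix; `<prefix>.bed/.bim/.fam` must exist.
#' @return A `ref_panel`; the fam table is attached as attribute `fam`.
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           data.table = FALSE)
  names(bim) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           data.table = FALSE)
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  n <- nrow(fam); m <- nrow(bim)
  con <- file(bed_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK bed file: ", bed_path)
  }
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) < bytes_per_snp * m) stop("truncated bed file")
  # decode 2-bit genotype codes; lookup over the 4 codes per byte position
  mat_int <- matrix(as.integer(raw), nrow = bytes_per_snp, ncol = m)
  geno <- matrix(NA_real_, nrow = n, ncol = m)
  code_map <- c(2, NA, 1, 0)  # codes 0b00, 0b01, 0b10, 0b11 -> A1 dosage
  for (k in 0:3) {
    rows <- seq.int(k + 1L, n, by = 4L)
    if (length(rows) == 0L) next
    byte_rows <- ((rows - 1L) %/% 4L) + 1L
    codes <- (mat_int[byte_rows, , drop = FALSE] %/% (4L^k)) %% 4L
    geno[rows, ] <- code_map[codes + 1L]
  }
  panel <- ref_panel(geno, bim[, c("chrom", "snp_id", "pos", "a1", "a2")])
  attr(panel, "fam") <- fam
  panel
}

#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' @param genotypes n x M matrix of A1-allele dosages (0/1/2, `NA` allowed).
#' @param bim data.frame with `chrom, snp_id, pos, a1, a2`.
#' @param prefix Output path prefix.
#' @param iid Optional individual ids (default `ind1..indN`).
#' @return Invisibly, `prefix`.
#' @export
write_plink <- function(genotypes, bim, prefix, iid = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  stopifnot(nrow(bim) == m)
  if (is.null(iid)) iid <- paste0("ind", seq_len(n))
  fam <- data.frame(fid = iid, iid = iid, pat = 0, mat = 0, sex = 0, pheno = -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  bim_out <- data.frame(chrom = bim$chrom, snp_id = bim$snp_id, cm = 0,
                        pos = bim$pos, a1 = bim$a1, a2 = bim$a2)
  data.table::fwrite(bim_out, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  code_of <- function(g) {
    out <- integer(length(g))
    out[is.na(g)] <- 1L
    out[!is.na(g) & g == 2] <- 0L
    out[!is.na(g) & g == 1] <- 2L
    out[!is.na(g) & g == 0] <- 3L
    out
  }
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- bytes_per_snp * 4L - n
  for (j in seq_len(m)) {
    codes <- c(code_of(genotypes[, j]), rep(0L, pad))
    dim(codes) <- c(4L, bytes_per_snp)
    bytes <- codes[1L, ] + 4L * codes[2L, ] + 16L * codes[3L, ] + 64L * codes[4L, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
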