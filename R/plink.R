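# PLINK 1 binary genotype input/output.
#
# The BED format stores genotypes SNP-major, two bits per call:
#   00 = homozygous first allele (A1/A1, dosage 2)
#   01 = missing
#   10 = heterozygous (dosage 1)
#   11 = homozygous second allele (A2/A2, dosage 0)
# Dosages count copies of the A1 allele in the .bim file.  Allele identity is
# irrelevant downstream because columns are standardized.

bed_lut <- local({
  lut <- matrix(NA_real_, 256, 4)
  map <- c(2, NA, 1, 0)
  for (v in 0:255) {
    for (i in 0:3) lut[v + 1L, i + 1L] <- map[bitwAnd(bitwShiftR(v, 2L * i), 3L) + 1L]
  }
  lut
})

read_bed_columns <- function(path, N_file, row_keep, snp_idx) {
  bpf <- ceiling(N_file / 4)
  con <- file(path, "rb")
  on.exit(close(con))
  out <- matrix(NA_real_, length(row_keep), length(snp_idx))
  for (k in seq_along(snp_idx)) {
    seek(con, 3 + (snp_idx[k] - 1) * bpf)
    bytes <- readBin(con, "integer", n = bpf, size = 1L, signed = FALSE)
    g <- as.vector(t(bed_lut[bytes + 1L, , drop = FALSE]))[seq_len(N_file)]
    out[, k] <- g[row_keep]
  }
  out
}

#' Read genotypes from a PLINK BED/BIM/FAM fileset
#'
#' Builds a streamed [genotype source][genotype_matrix] over a PLINK 1
#' binary fileset.  A first pass computes per-SNP means and scales (missing
#' calls are mean-imputed per SNP); blocks are then standardized on the fly
#' as they are fetched, so the full matrix is never held in memory.
#' Monomorphic and all-missing SNPs are dropped with a warning.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @param sample_keep optional character vector of individual IDs (FAM column
#'   2).  The source is subset *and ordered* to match, so it can align the
#'   genotypes to a phenotype table; IDs absent from the FAM file raise an
#'   error listing the offenders.
#' @param snp_keep optional character vector of SNP IDs to retain.
#' @param block_size SNPs per streamed block.
#' @return an object of class `genotype_source` with `$sample_ids`,
#'   `$snp_ids`, `$N`, `$M`.
#' @seealso [write_plink()]
#' @export
read_plink <- function(prefix, sample_keep = NULL, snp_keep = NULL,
                       block_size = 1000L) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing PLINK file(s): ", paste(missing, collapse = ", "))

  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(fam[[2]])
  N_file <- nrow(fam)

  con <- file(paths[1], "rb")
  magic <- readBin(con, "integer", n = 3, size = 1L, signed = FALSE)
  close(con)
  if (!identical(magic[1:2], c(108L, 27L))) stop("not a PLINK BED file: ", paths[1])
  if (magic[3] != 1L) stop("only SNP-major BED files are supported")

  if (is.null(sample_keep)) {
    row_keep <- seq_len(N_file)
  } else {
    row_keep <- match(as.character(sample_keep), ids)
    if (anyNA(row_keep)) {
      stop("sample ID(s) not present in ", paths[3], ": ",
           paste(utils::head(sample_keep[is.na(row_keep)], 10L), collapse = ", "))
    }
  }
  snp_ids <- as.character(bim[[2]])
  if (is.null(snp_keep)) {
    col_map <- seq_len(nrow(bim))
  } else {
    col_map <- match(as.character(snp_keep), snp_ids)
    if (anyNA(col_map)) {
      stop("SNP ID(s) not present in ", paths[2], ": ",
           paste(utils::head(snp_keep[is.na(col_map)], 10L), collapse = ", "))
    }
  }

  N <- length(row_keep)
  # stats pass
  M0 <- length(col_map)
  mu <- numeric(M0); sd_n <- numeric(M0)
  chunk <- 2000L
  for (lo in seq(1L, M0, by = chunk)) {
    sel <- lo:min(lo + chunk - 1L, M0)
    raw <- read_bed_columns(paths[1], N_file, row_keep, col_map[sel])
    m <- colMeans(raw, na.rm = TRUE)
    mu[sel] <- m
    for (k in seq_along(sel)) {
      xj <- raw[, k]; xj[is.na(xj)] <- m[k]
      sd_n[sel[k]] <- sqrt(sum((xj - m[k])^2) / N)
    }
  }
  keep <- !is.nan(mu) & sd_n > 0
  if (!all(keep)) {
    warning(sum(!keep), " monomorphic or all-missing SNP(s) dropped")
  }
  src <- new_genotype_source("bed", N, sum(keep), ids[row_keep],
                             snp_ids[col_map][keep], mu[keep], sd_n[keep],
                             block_size)
  src$bed_path <- paths[1]
  src$N_file <- N_file
  src$row_keep <- row_keep
  src$col_map <- col_map[keep]
  src
}

#' Write genotypes to a PLINK BED/BIM/FAM fileset
#'
#' Writes a dosage matrix (counts of the A1 allele; `NA` = missing) as a
#' SNP-major PLINK 1 binary fileset with a dummy chromosome/position grid.
#'
#' @param prefix output path prefix.
#' @param G numeric `N x M` matrix of dosages in \{0, 1, 2, `NA`\}.
#' @param sample_ids,snp_ids identifiers; defaults are generated.
#' @param chr,pos,a1,a2 BIM fields, recycled across SNPs.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(prefix, G, sample_ids = NULL, snp_ids = NULL,
                        chr = 1L, pos = NULL, a1 = "A", a2 = "B") {
  G <- as.matrix(G)
  N <- nrow(G); M <- ncol(G)
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(N))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(M))
  if (is.null(pos)) pos <- seq_len(M) * 1000L
  bad <- !(G %in% c(0, 1, 2) | is.na(G))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")

  fam <- data.frame(fid = sample_ids, iid = sample_ids, pat = 0L, mat = 0L,
                    sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = rep_len(chr, M), id = snp_ids, cm = 0L,
                    pos = rep_len(pos, M), a1 = rep_len(a1, M),
                    a2 = rep_len(a2, M))
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, N, M)
  code[G == 2] <- 0L
  code[is.na(G)] <- 1L
  code[G == 1] <- 2L
  bpf <- ceiling(N / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bpf - N
  for (j in seq_len(M)) {
    cj <- c(code[, j], rep(0L, pad))
    dim(cj) <- c(4L, bpf)
    bytes <- cj[1L, ] + cj[2L, ] * 4L + cj[3L, ] * 16L + cj[4L, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
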