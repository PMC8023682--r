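#' Standardize a block of raw genotypes
#'
#' Mean-imputes missing calls, centers each column and scales it to unit
#' variance computed with denominator \eqn{N} (not \eqn{N-1}).  With this
#' convention a full standardized genotype matrix \eqn{X} satisfies
#' \eqn{\mathrm{tr}(XX^T)/M = N} exactly, which the trace identities used by
#' the estimators rely on.
#'
#' @param block numeric matrix of raw dosages (0/1/2, `NA` allowed).
#' @return numeric matrix of the same dimension; every column has mean 0 and
#'   variance 1.  Missing entries equal 0 after standardization (they are
#'   imputed at the column mean).
#' @examples
#' standardize_block(cbind(c(0, 1, 2, 1)))
#' @export
standardize_block <- function(block) {
  block <- as.matrix(block)
  n <- nrow(block)
  mu <- colMeans(block, na.rm = TRUE)
  if (anyNA(block)) {
    na_idx <- which(is.na(block), arr.ind = TRUE)
    block[na_idx] <- mu[na_idx[, 2L]]
  }
  xc <- sweep(block, 2L, mu, "-")
  sd_n <- sqrt(colSums(xc^2) / n)
  if (any(sd_n == 0)) {
    stop("zero-variance genotype column(s) at block position(s): ",
         paste(utils::head(which(sd_n == 0), 10L), collapse = ", "),
         " (monomorphic SNPs must be filtered before standardization)")
  }
  sweep(xc, 2L, sd_n, "/")
}

new_genotype_source <- function(backend, N, M, sample_ids, snp_ids,
                                means, sds, block_size) {
  block_size <- max(1L, as.integer(block_size))
  n_blocks <- ceiling(M / block_size)
  structure(
    list(backend = backend, N = N, M = M,
         sample_ids = sample_ids, snp_ids = snp_ids,
         means = means, sds = sds,
         block_size = block_size, n_blocks = n_blocks),
    class = "genotype_source")
}

#' Wrap an in-memory dosage matrix as a genotype source
#'
#' Genotype sources present genotypes as a stream of standardized
#' \eqn{N \times m} column blocks; both [memma()] and [gplemma()] consume
#' this interface so that file-backed and in-memory genotypes are handled
#' identically.  Monomorphic SNPs are dropped with a warning.
#'
#' @param G numeric matrix of dosages, samples in rows (`NA` allowed;
#'   missing calls are mean-imputed per SNP).
#' @param sample_ids,snp_ids optional identifier vectors.
#' @param block_size number of SNPs per streamed block.
#' @return an object of class `genotype_source`.
#' @seealso [read_plink()], [geno_block()]
#' @export
genotype_matrix <- function(G, sample_ids = NULL, snp_ids = NULL,
                            block_size = 1000L) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  N <- nrow(G)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(N))
  if (is.null(snp_ids)) snp_ids <- colnames(G) %||% paste0("snp", seq_len(ncol(G)))
  mu <- colMeans(G, na.rm = TRUE)
  keep <- !is.nan(mu)  # all-missing columns
  sd_n <- rep(0, ncol(G))
  for (j in which(keep)) {
    xj <- G[, j]
    xj[is.na(xj)] <- mu[j]
    sd_n[j] <- sqrt(sum((xj - mu[j])^2) / N)
  }
  keep <- keep & sd_n > 0
  if (!all(keep)) {
    warning(sum(!keep), " monomorphic or all-missing SNP(s) dropped")
    G <- G[, keep, drop = FALSE]
    mu <- mu[keep]; sd_n <- sd_n[keep]; snp_ids <- snp_ids[keep]
  }
  src <- new_genotype_source("matrix", N, ncol(G), sample_ids, snp_ids,
                             mu, sd_n, block_size)
  src$data <- G
  src
}

`%||%` <- function(a, b) if (is.null(a)) b else a

block_cols <- function(src, j) {
  lo <- (j - 1L) * src$block_size + 1L
  hi <- min(j * src$block_size, src$M)
  lo:hi
}

#' Fetch one standardized genotype block
#'
#' @param src a `genotype_source`.
#' @param j block index in `1:src$n_blocks`.
#' @return standardized `N x m` numeric matrix (column mean 0, variance 1
#'   with denominator N; missing calls imputed at the mean, i.e. 0 after
#'   standardization).
#' @export
geno_block <- function(src, j) {
  cols <- block_cols(src, j)
  raw <- fetch_raw_block(src, cols)
  if (anyNA(raw)) {
    na_idx <- which(is.na(raw), arr.ind = TRUE)
    raw[na_idx] <- src$means[cols][na_idx[, 2L]]
  }
  xc <- sweep(raw, 2L, src$means[cols], "-")
  sweep(xc, 2L, src$sds[cols], "/")
}

fetch_raw_block <- function(src, cols) {
  switch(src$backend,
    matrix = src$data[, cols, drop = FALSE],
    bed = read_bed_columns(src$bed_path, src$N_file, src$row_keep,
                           src$col_map[cols]),
    stop("unknown genotype backend"))
}

# Fetch a few standardized columns by SNP index (used by the simulators for
# causal SNPs without materializing the whole matrix).
geno_columns <- function(src, idx) {
  raw <- fetch_raw_block(src, idx)
  if (anyNA(raw)) {
    na_idx <- which(is.na(raw), arr.ind = TRUE)
    raw[na_idx] <- src$means[idx][na_idx[, 2L]]
  }
  xc <- sweep(raw, 2L, src$means[idx], "-")
  sweep(xc, 2L, src$sds[idx], "/")
}

# Accumulate XX^T A (and optionally crossprod of X^T Ay) in one pass over
# blocks; the workhorse behind every kernel-vector product.
stream_xxt <- function(src, A, Ay = NULL) {
  A <- as.matrix(A)
  R <- matrix(0, src$N, ncol(A))
  CT <- if (!is.null(Ay)) matrix(0, ncol(Ay), ncol(Ay)) else NULL
  for (j in seq_len(src$n_blocks)) {
    Xj <- geno_block(src, j)
    S <- crossprod(Xj, if (is.null(Ay)) A else cbind(A, Ay))
    R <- R + Xj %*% S[, seq_len(ncol(A)), drop = FALSE]
    if (!is.null(Ay)) {
      Sy <- S[, ncol(A) + seq_len(ncol(Ay)), drop = FALSE]
      CT <- CT + crossprod(Sy)
    }
  }
  list(R = R, CT = CT)
}

#' @export
print.genotype_source <- function(x, ...) {
  cat("Genotype source (", x$backend, "): ", x$N, " samples x ", x$M,
      " SNPs, block size ", x$block_size, "\n", sep = "")
  invisible(x)
}

#' Coerce a genotype source to a dense standardized matrix
#'
#' Intended for small fixtures and dense-oracle computations; avoid on large
#' inputs.
#'
#' @param x a `genotype_source`.
#' @param ... unused.
#' @return standardized `N x M` numeric matrix.
#' @export
as.matrix.genotype_source <- function(x, ...) {
  do.call(cbind, lapply(seq_len(x$n_blocks), function(j) geno_block(x, j)))
}
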