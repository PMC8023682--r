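# Internal helpers shared across modules.

# Column standardization with denominator-N variance, so that a standardized
# genotype matrix X satisfies tr(XX^T)/M = N exactly.
std_cols <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  sd_n <- sqrt(colSums(xc^2) / n)
  if (any(sd_n == 0)) {
    stop("zero-variance column(s): ", paste(which(sd_n == 0), collapse = ", "))
  }
  sweep(xc, 2L, sd_n, "/")
}

# Residualize the columns of x against the column space of `basis`
# (always including an intercept), used to make simulated phenotype
# components empirically orthogonal.
resid_on <- function(x, basis = NULL) {
  n <- NROW(x)
  b <- cbind(rep(1, n), basis)
  qr.resid(qr(b), as.matrix(x))
}

# Deterministic derived seeds, kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1103 + 7) %% 2147483629) + 1L
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
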