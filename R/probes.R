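#' Draw Hutchinson probe vectors
#'
#' Generates `B` i.i.d. standard-Gaussian probe vectors \eqn{z_b \sim
#' N(0, I_N)} for stochastic trace estimation,
#' \eqn{\mathrm{tr}(A) \approx \frac{1}{B}\sum_b z_b^T A z_b}.  One probe set
#' is shared across every trace term of an analysis, which positively
#' correlates the Monte-Carlo errors of the moment-system entries and
#' stabilizes the subsequent solve.
#'
#' @param N vector length (sample count).
#' @param B number of probes (default 100; the standard error of a trace
#'   estimate scales as \eqn{\sqrt{2/B}}).
#' @param seed integer seed; the same seed reproduces the same probes.
#' @return object of class `probe_set` with elements `Z` (`N x B`), `B`,
#'   `seed`.
#' @export
draw_probes <- function(N, B = 100L, seed = 1L) {
  stopifnot(B >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Z <- matrix(stats::rnorm(N * B), N, B)
  structure(list(Z = Z, B = as.integer(B), seed = as.integer(seed)),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("Probe set: B =", x$B, "Gaussian probes of length", nrow(x$Z),
      "(seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Apply a composed linear operator to vectors
#'
#' Evaluates \eqn{A v} exactly (no randomization) where \eqn{A} is a product
#' of the primitive operators used throughout the package, applied
#' right-to-left like a matrix product.  Supported tokens:
#'
#' * `"I"` — identity;
#' * `"K"` — the genomic relationship kernel \eqn{XX^T/M}, applied by
#'   streaming genotype blocks;
#' * `"W"` — the covariate projection \eqn{I - C(C^TC)^{-1}C^T};
#' * `"E<l>"` (e.g. `"E2"`) — `diag(E_l)` for environment column `l`;
#' * `"dWy"` — `diag(Wy)`.
#'
#' Primarily a testing and verification utility: every randomized trace used
#' by [memma()] and [gplemma()] can be cross-checked against
#' [estimate_trace()] with the corresponding operator word.
#'
#' @param word character vector of tokens, leftmost token applied last.
#' @param v numeric vector or matrix with `N` rows.
#' @param geno [genotype source][genotype_matrix]; required when the word
#'   contains `"K"`.
#' @param design [`gxe_design`][assemble_design]; required for `"W"`,
#'   `"E<l>"` and `"dWy"`.
#' @param y phenotype vector; required for `"dWy"`.
#' @return `A v`, same shape as `v`.
#' @export
apply_operator <- function(word, v, geno = NULL, design = NULL, y = NULL) {
  v <- as.matrix(v)
  for (tok in rev(word)) {
    if (tok == "I") {
      next
    } else if (tok == "K") {
      if (is.null(geno)) stop("token 'K' requires a genotype source")
      v <- stream_xxt(geno, v)$R / geno$M
    } else if (tok == "W") {
      if (is.null(design)) stop("token 'W' requires a design")
      v <- project_out(design, v)
    } else if (grepl("^E[0-9]+$", tok)) {
      if (is.null(design)) stop("token '", tok, "' requires a design")
      l <- as.integer(sub("^E", "", tok))
      if (l < 1 || l > design$L) stop("environment index out of range in '", tok, "'")
      v <- design$E[, l] * v
    } else if (tok == "dWy") {
      if (is.null(design) || is.null(y)) stop("token 'dWy' requires design and y")
      wy <- project_out(design, y - mean(y))
      v <- as.vector(wy) * v
    } else {
      stop("malformed operator token: '", tok, "'")
    }
  }
  v
}

#' Hutchinson trace estimate of a composed operator
#'
#' Returns \eqn{\frac{1}{B}\sum_b z_b^T (A z_b)} with \eqn{A} built by
#' [apply_operator()] from `word`.  Unbiased for \eqn{\mathrm{tr}(A)}.  The
#' trace of the bare projection `"W"` is returned analytically as
#' \eqn{N - D} without using the probes.
#'
#' @inheritParams apply_operator
#' @param probes a [`probe_set`][draw_probes].
#' @return scalar trace estimate.
#' @export
estimate_trace <- function(word, probes, geno = NULL, design = NULL, y = NULL) {
  if (identical(word, "W")) {
    if (is.null(design)) stop("token 'W' requires a design")
    return(design$N - design$D)
  }
  AZ <- apply_operator(word, probes$Z, geno = geno, design = design, y = y)
  mean(colSums(probes$Z * AZ))
}
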