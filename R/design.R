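#' Assemble the environment and covariate design
#'
#' Standardizes the environment matrix \eqn{E} (mean 0, variance 1 per
#' column, denominator \eqn{N}) and builds the covariate matrix
#' \eqn{C = [\mathbf{1} \,|\, \mathrm{covariates} \,|\, E]}.  Every column of
#' \eqn{E} is always included in \eqn{C}, so covariate projection removes all
#' linear (main) environmental effects before the interaction kernels are
#' formed; only the interaction signal remains for the GxE components.
#' Duplicate or collinear covariate columns are dropped with a warning so
#' \eqn{C} always has full column rank.
#'
#' @param env numeric `N x L` matrix (or data frame) of environmental
#'   variables, `L >= 2`.  Constant columns are an error.
#' @param covar optional numeric matrix of additional covariates (standardized
#'   internally).
#' @param add_intercept include an intercept column (default `TRUE`; the
#'   intercept is exempt from standardization).
#' @return an object of class `gxe_design` with elements `E` (`N x L`,
#'   standardized), `C` (`N x D`, full rank), `D`, `L`, `N`, and a cached
#'   orthonormal basis `Q` of the column space of `C` used by [project_out()].
#' @examples
#' E <- matrix(rnorm(300), 100, 3)
#' d <- assemble_design(E, covar = matrix(rnorm(100), 100, 1))
#' d$D  # 1 intercept + 1 covariate + 3 environments
#' @export
assemble_design <- function(env, covar = NULL, add_intercept = TRUE) {
  env <- as.matrix(env)
  N <- nrow(env)
  L <- ncol(env)
  if (L < 2) stop("at least 2 environmental variables are required")
  sds <- apply(env, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant environment column(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  env_names <- colnames(env) %||% paste0("env", seq_len(L))
  E <- std_cols(env)
  colnames(E) <- env_names

  C <- if (add_intercept) matrix(1, N, 1, dimnames = list(NULL, "intercept")) else NULL
  if (!is.null(covar)) {
    covar <- as.matrix(covar)
    if (nrow(covar) != N) stop("covariate rows do not match environment rows")
    cn <- colnames(covar) %||% paste0("covar", seq_len(ncol(covar)))
    csd <- apply(covar, 2L, stats::sd)
    if (any(csd == 0)) {
      warning("constant covariate column(s) dropped: ", paste(cn[csd == 0], collapse = ", "))
      covar <- covar[, csd > 0, drop = FALSE]; cn <- cn[csd > 0]
    }
    if (ncol(covar)) {
      covar <- std_cols(covar)
      colnames(covar) <- cn
      C <- cbind(C, covar)
    }
  }
  C <- cbind(C, E)

  # drop duplicated / collinear columns (e.g. an environment repeated in the
  # covariate file), keeping the first occurrence
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    keep <- sort(qrC$pivot[seq_len(qrC$rank)])
    dropped <- colnames(C)[setdiff(seq_len(ncol(C)), keep)]
    warning("rank-deficient covariate matrix; dropped column(s): ",
            paste(dropped, collapse = ", "))
    C <- C[, keep, drop = FALSE]
    qrC <- qr(C)
  }
  D <- ncol(C)
  if (N <= D) stop("need more samples than covariate columns (N = ", N,
                   ", D = ", D, ")")
  structure(
    list(E = E, C = C, D = D, L = L, N = N,
         Q = qr.Q(qrC), env_names = env_names),
    class = "gxe_design")
}

#' @export
print.gxe_design <- function(x, ...) {
  cat("GxE design: N =", x$N, ", L =", x$L, "environments, D =", x$D,
      "covariate columns\n")
  invisible(x)
}

#' Apply the covariate projection W = I - C (C'C)^-1 C'
#'
#' Projects vectors onto the orthogonal complement of the covariate column
#' space without ever forming the \eqn{N \times N} matrix \eqn{W}:
#' \eqn{Wv = v - Q(Q^T v)} where \eqn{Q} is the cached orthonormal basis of
#' \eqn{C}.  `W` is idempotent and annihilates every column of `C`;
#' \eqn{\mathrm{tr}(W) = N - D}.
#'
#' @param design a [`gxe_design`][assemble_design] (or any list with a `Q`
#'   basis matrix).
#' @param v numeric vector or matrix with `N` rows.
#' @return `W v`, same shape as `v`.
#' @export
project_out <- function(design, v) {
  v <- as.matrix(v)
  v - design$Q %*% crossprod(design$Q, v)
}

# Frisch-Waugh t-test of one extra regressor on top of the design's C.
ols_extra_t <- function(y, design, x) {
  rx <- project_out(design, x)
  vx <- sum(rx^2)
  if (vx < 1e-10 * length(x)) {
    return(c(estimate = NA, t = NA, p = NA))  # collinear with C
  }
  ry <- project_out(design, y)
  bhat <- sum(rx * ry) / vx
  res <- ry - bhat * rx
  df <- design$N - design$D - 1L
  se <- sqrt(sum(res^2) / df / vx)
  tval <- bhat / se
  c(estimate = bhat, t = tval, p = 2 * stats::pt(-abs(tval), df))
}

#' Pre-screen for squared environmental effects (+SQE)
#'
#' A phenotype that depends on the *square* of a heritable environmental
#' variable inflates GxE heritability estimates if unmodelled.  This screen
#' tests, for each environment \eqn{E_l}, the coefficient of \eqn{E_l^2} in
#' an ordinary least-squares fit of `y` on the existing covariates plus
#' \eqn{E_l^2} (two-sided t-test, so linear effects already in \eqn{C} are
#' controlled for).  Squared terms with \eqn{p < \alpha / L} are standardized
#' and appended to the covariate matrix.
#'
#' The screen is monotone in `alpha_level`: shrinking it can only remove
#' columns.  `alpha_level = 0` returns the design unchanged.
#'
#' @param y numeric phenotype vector.
#' @param design a [`gxe_design`][assemble_design].
#' @param alpha_level family-wise level before the Bonferroni division by
#'   `L` (default 0.01).
#' @return list with `design` (augmented `gxe_design`), and `report`, a data
#'   frame with one row per environment: `environment`, `estimate`, `t`,
#'   `p_value`, `included`.
#' @export
squared_effect_screen <- function(y, design, alpha_level = 0.01) {
  y <- as.numeric(y)
  L <- design$L
  stats_mat <- t(vapply(seq_len(L), function(l) {
    ols_extra_t(y, design, design$E[, l]^2)
  }, numeric(3)))
  thr <- alpha_level / L
  included <- !is.na(stats_mat[, "p"]) & stats_mat[, "p"] < thr
  report <- data.frame(environment = design$env_names,
                       estimate = stats_mat[, "estimate"],
                       t = stats_mat[, "t"],
                       p_value = stats_mat[, "p"],
                       included = included,
                       row.names = NULL)
  out_design <- design
  if (any(included)) {
    sq <- std_cols(design$E[, included, drop = FALSE]^2)
    colnames(sq) <- paste0(design$env_names[included], "_sq")
    C_aug <- cbind(design$C, sq)
    qrC <- qr(C_aug)
    if (qrC$rank < ncol(C_aug)) {
      keep <- sort(qrC$pivot[seq_len(qrC$rank)])
      C_aug <- C_aug[, keep, drop = FALSE]
      qrC <- qr(C_aug)
    }
    out_design$C <- C_aug
    out_design$D <- ncol(C_aug)
    out_design$Q <- qr.Q(qrC)
    if (out_design$N <= out_design$D) {
      stop("screen produced D >= N; reduce the number of covariates")
    }
  }
  list(design = out_design, report = report, alpha_level = alpha_level)
}
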