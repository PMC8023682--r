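# Randomized linear-algebra core.
#
# Everything both estimators need is assembled from one pass over the
# genotypes.  With shared Gaussian probes z_b, the pass accumulates
#   u_b     = XX^T W z_b
#   v_{b,l} = XX^T (E_l o W z_b)
#   H_{l,m} = (E_l o Wy)^T XX^T (E_m o Wy)
#   q_K     = ||X^T W y||^2
# Per probe, a dictionary of projected operator-applied vectors is formed:
#   phi_b      = W K W z_b                 (K = XX^T/M)
#   chi_b      = W z_b
#   P_b^{l,m}  = W (F_l F_m^T / M) W z_b   (F_l = diag(E_l) X)
# and their Gram matrix G = (1/B) sum_b S_b^T S_b is stored.  Because W is
# idempotent, E[G] holds every projected kernel-product trace
# tr(W A_i^T W A_j W) the moment systems and the non-linear least-squares
# objective require, so MEMMA's moment matrix and GPLEMMA's S(theta), J^T J
# and J^T eps all become cheap algebraic reads of G.

pair_layout <- function(L, pairs) {
  if (pairs == "full") {
    list(l_idx = rep(seq_len(L), each = L), m_idx = rep(seq_len(L), times = L))
  } else {
    list(l_idx = seq_len(L), m_idx = seq_len(L))
  }
}

pair_pos <- function(pc, l, m) {
  if (pc$pairs == "full") 2L + (l - 1L) * pc$L + m
  else if (l == m) 2L + l
  else stop("off-diagonal kernel pair requested from a 'diag' precompute")
}

#' One-pass streamed precomputes for randomized Haseman-Elston estimation
#'
#' Streams standardized genotype blocks once and accumulates every quantity
#' the [memma()] and [gplemma()] estimators need: the exact data quadratic
#' forms \eqn{y^TWK_kWy} (via \eqn{q_K = \|X^TWy\|^2} and the matrix
#' \eqn{H_{l,m} = (E_l \odot Wy)^T XX^T (E_m \odot Wy)}), and a Gram matrix
#' of projected operator-applied probe vectors from which all Hutchinson
#' trace estimates \eqn{\mathrm{tr}(WK_kWK_lW)} are assembled.  Covariate
#' projections \eqn{W} are inserted wherever the projected trace expressions
#' demand, and the residual diagonal uses the exact \eqn{\mathrm{tr}(W) =
#' N - D}.
#'
#' With `exact = TRUE` the same structure is filled with dense-matrix traces
#' instead of randomized estimates (feasible only for small fixtures); the
#' downstream estimators are agnostic to which mode produced the object,
#' which is how the dense-oracle equivalence checks are run.
#'
#' @param geno a [genotype source][genotype_matrix].
#' @param design a [`gxe_design`][assemble_design]; samples must align with
#'   `geno` and `y`.
#' @param y numeric phenotype vector (centered internally).
#' @param B number of Hutchinson probes (ignored when `exact = TRUE` or
#'   `probes` is supplied).
#' @param seed probe seed.
#' @param probes optionally a [`probe_set`][draw_probes] to reuse.
#' @param pairs `"full"` stores all \eqn{L^2} interaction kernel pairs
#'   \eqn{F_lF_m^T} (required by [gplemma()]); `"diag"` stores only the
#'   \eqn{L} diagonal pairs, which suffices for [memma()] and scales better
#'   in `L`.
#' @param exact compute dense (non-randomized) traces instead.
#' @return an object of class `rhe_precompute`.
#' @export
rhe_precompute <- function(geno, design, y, B = 100L, seed = 1L, probes = NULL,
                           pairs = c("full", "diag"), exact = FALSE) {
  pairs <- match.arg(pairs)
  y <- as.numeric(y)
  N <- design$N; L <- design$L; D <- design$D
  stopifnot(length(y) == N, geno$N == N)
  M <- geno$M
  yp <- as.vector(project_out(design, y - mean(y)))
  lay <- pair_layout(L, pairs)
  P <- length(lay$l_idx)
  labels <- c("K", "probe", paste0("F", lay$l_idx, ".F", lay$m_idx))

  if (exact) {
    Xs <- as.matrix(geno)
    K <- tcrossprod(Xs) / M
    Wmat <- diag(N) - tcrossprod(design$Q)
    ops <- vector("list", P + 2L)
    ops[[1L]] <- Wmat %*% K %*% Wmat
    ops[[2L]] <- Wmat
    for (p in seq_len(P)) {
      l <- lay$l_idx[p]; m <- lay$m_idx[p]
      ops[[2L + p]] <- Wmat %*% (outer(design$E[, l], design$E[, m]) * K) %*% Wmat
    }
    G <- matrix(0, P + 2L, P + 2L)
    for (i in seq_len(P + 2L)) {
      for (j in i:(P + 2L)) {
        G[i, j] <- G[j, i] <- sum(ops[[i]] * ops[[j]])
      }
    }
    G[2L, 2L] <- N - D
    Ey <- design$E * yp
    KEy <- K %*% Ey
    Hs <- crossprod(Ey, KEy)
    qK <- drop(crossprod(yp, K %*% yp))
    B_used <- NA_integer_
  } else {
    if (is.null(probes)) probes <- draw_probes(N, B, seed)
    Z <- probes$Z
    B_used <- probes$B
    WZ <- project_out(design, Z)
    A <- cbind(WZ, do.call(cbind, lapply(seq_len(L), function(l) design$E[, l] * WZ)))
    Ay <- cbind(yp, design$E * yp)
    st <- stream_xxt(geno, A, Ay)
    if (!all(is.finite(st$R)) || !all(is.finite(st$CT))) {
      stop("non-finite values accumulated while streaming genotype blocks")
    }
    qK <- st$CT[1L, 1L] / M
    Hs <- st$CT[-1L, -1L, drop = FALSE] / M
    G <- matrix(0, P + 2L, P + 2L)
    for (b in seq_len(B_used)) {
      Vb <- st$R[, B_used * seq_len(L) + b, drop = FALSE]
      Pb <- design$E[, lay$l_idx, drop = FALSE] * Vb[, lay$m_idx, drop = FALSE]
      pr <- project_out(design, cbind(st$R[, b], Pb)) / M
      stack <- cbind(pr[, 1L], WZ[, b], pr[, -1L, drop = FALSE])
      G <- G + crossprod(stack)
    }
    G <- G / B_used
    G[2L, 2L] <- N - D
    seed <- probes$seed
  }
  dimnames(G) <- list(labels, labels)
  dimnames(Hs) <- list(design$env_names, design$env_names)
  structure(
    list(method = if (exact) "dense" else "hutchinson",
         G = G, labels = labels, pairs = pairs,
         l_idx = lay$l_idx, m_idx = lay$m_idx,
         Hs = Hs, qK = qK, yWy = sum(yp^2), trW = N - D,
         N = N, M = M, L = L, D = D, B = B_used, seed = seed,
         env_names = design$env_names),
    class = "rhe_precompute")
}

#' Reuse a precompute for additional phenotypes on the same data
#'
#' The probe Gram matrix of an [rhe_precompute()] depends only on the
#' genotypes, environments and covariates — not on the phenotype.  Given a
#' matrix of phenotypes measured on the same samples, this recomputes the
#' phenotype-dependent quadratic forms (\eqn{q_K}, \eqn{H}, \eqn{y^TWy}) for
#' every column in a single streaming pass and returns one precompute object
#' per phenotype, all sharing the Gram.  Useful for replicate analyses
#' (e.g. null calibration) at a fraction of the cost of rebuilding the
#' precompute.
#'
#' @param pc an existing [`rhe_precompute`][rhe_precompute].
#' @param geno,design the same genotype source and design used to build
#'   `pc`.
#' @param Y numeric `N x R` matrix of phenotypes (columns centered
#'   internally).
#' @param chunk phenotypes per streaming pass.
#' @return list of `R` `rhe_precompute` objects.
#' @export
rhe_refit_phenotypes <- function(pc, geno, design, Y, chunk = 40L) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == pc$N)
  L <- pc$L
  R <- ncol(Y)
  out <- vector("list", R)
  for (lo in seq(1L, R, by = chunk)) {
    sel <- lo:min(lo + chunk - 1L, R)
    YP <- project_out(design, sweep(Y[, sel, drop = FALSE], 2L,
                                    colMeans(Y[, sel, drop = FALSE])))
    Ay <- do.call(cbind, lapply(seq_along(sel), function(i) {
      cbind(YP[, i], design$E * YP[, i])
    }))
    st <- stream_xxt(geno, matrix(0, pc$N, 0L), Ay)
    for (i in seq_along(sel)) {
      cols <- (i - 1L) * (L + 1L) + seq_len(L + 1L)
      CT <- st$CT[cols, cols]
      pr <- pc
      pr$qK <- CT[1L, 1L] / pc$M
      pr$Hs <- CT[-1L, -1L, drop = FALSE] / pc$M
      dimnames(pr$Hs) <- list(pc$env_names, pc$env_names)
      pr$yWy <- sum(YP[, i]^2)
      out[[sel[i]]] <- pr
    }
  }
  out
}

#' @export
print.rhe_precompute <- function(x, ...) {
  cat("RHE precompute (", x$method, "): N = ", x$N, ", M = ", x$M,
      ", L = ", x$L, ", D = ", x$D,
      if (!is.na(x$B)) paste0(", B = ", x$B), ", pairs = ", x$pairs, "\n",
      sep = "")
  invisible(x)
}
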