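# Multi-environment variance-component estimation (MEMMA).
#
# Model: y = C alpha + X beta + sum_l (E_l o X) lambda_l + eps, with
# independent Gaussian effect-size priors per environment.  Integrating out
# the effects gives the (L+2)-component covariance
#   sum_k theta_k K_k,  K_1 = XX^T/M, K_{l+1} = F_l F_l^T/M, K_{L+2} = I,
# and the method-of-moments normal equations T theta = c with
#   T_kl = tr(W K_k W K_l W),  c_k = y^T W K_k W y.

memma_system <- function(pc) {
  L <- pc$L
  idx <- c(1L, vapply(seq_len(L), function(l) pair_pos(pc, l, l), integer(1)), 2L)
  Tm <- pc$G[idx, idx]
  labels <- c("main", pc$env_names, "residual")
  dimnames(Tm) <- list(labels, labels)
  cv <- c(pc$qK, diag(pc$Hs), pc$yWy)
  bv <- pc$G[2L, idx]
  bv[L + 2L] <- pc$trW
  names(cv) <- names(bv) <- labels
  list(T = Tm, c = cv, b = bv, labels = labels)
}

solve_moments <- function(Tm, cv) {
  theta <- tryCatch(solve(Tm, cv), error = function(e) NULL)
  if (is.null(theta) || !all(is.finite(theta))) {
    warning("moment matrix numerically singular; using least-squares solution")
    theta <- qr.coef(qr(Tm, LAPACK = TRUE), cv)
    theta[is.na(theta)] <- 0
  }
  theta
}

#' MEMMA: per-environment GxE heritability by randomized Haseman-Elston
#' regression
#'
#' Fits a variance-component model in which every environmental variable
#' interacts independently with the genome: one genome-wide main-effect
#' component, one GxE component per environment, and a residual.  The
#' components are estimated analytically by solving the method-of-moments
#' normal equations \eqn{T\theta = c}, with the trace matrix \eqn{T}
#' estimated by Hutchinson probes shared across all entries and the
#' right-hand side computed exactly from data quadratic forms.  Estimates
#' are converted to per-component proportions of variance explained (PVE)
#' \deqn{\hat h^2_k = \hat\theta_k \mathrm{tr}(WK_kW) / \sum_j \hat\theta_j
#' \mathrm{tr}(WK_jW).}
#'
#' Method-of-moments variance estimates are unbiased but can be negative;
#' both the raw solution and a zero-truncated copy are reported, and the
#' headline PVE uses the truncated copy.  Because each environment enters
#' only through \eqn{\mathrm{diag}(E_l)} quadratically, the per-environment
#' components are invariant to the sign of \eqn{E_l}: MEMMA cannot recover
#' interaction-weight signs or an environmental score (use [gplemma()] for
#' that).
#'
#' @param y numeric phenotype vector (centered internally).
#' @param genotypes a [genotype source][genotype_matrix] or plain dosage
#'   matrix.
#' @param environments `N x L` matrix of environmental variables (`L >= 2`).
#' @param covariates optional additional covariates; an intercept and all
#'   environment columns are always included.
#' @param probes number of Hutchinson probes `B`.
#' @param seed probe seed.
#' @param design,precompute optionally a pre-built
#'   [`gxe_design`][assemble_design] / [`rhe_precompute`][rhe_precompute]
#'   (both must be supplied together with `y` consistent; `genotypes`,
#'   `environments` are then ignored).
#' @return an object of class `memma` with components `theta` (raw
#'   estimates), `theta_trunc`, `pve` (truncated, sums to 1), `pve_raw`
#'   (signed), `h2_G`, `h2_GxE_env`, `h2_GxE_total`, the moment `system`,
#'   and run metadata.
#' @examples
#' sim <- simulate_dataset(sim_config(N = 500, M = 400, L = 3, L_active = 2,
#'                                    M_G = 40, M_GxE = 20, seed = 1))
#' fit <- memma(sim$y, sim$geno, sim$E, sim$C, probes = 30, seed = 2)
#' fit$h2_GxE_total
#' @seealso [gplemma()] for the constrained single-score model.
#' @export
memma <- function(y, genotypes = NULL, environments = NULL, covariates = NULL,
                  probes = 100L, seed = 1L, design = NULL, precompute = NULL) {
  cl <- match.call()
  if (is.null(precompute)) {
    if (is.null(design)) design <- assemble_design(environments, covariates)
    if (!inherits(genotypes, "genotype_source")) genotypes <- genotype_matrix(genotypes)
    precompute <- rhe_precompute(genotypes, design, y, B = probes, seed = seed,
                                 pairs = "diag")
  }
  pc <- precompute
  sys <- memma_system(pc)
  theta <- solve_moments(sys$T, sys$c)
  names(theta) <- sys$labels
  theta_trunc <- pmax(theta, 0)
  vc_raw <- theta * sys$b
  vc_trunc <- theta_trunc * sys$b
  pve_raw <- vc_raw / sum(vc_raw)
  pve <- vc_trunc / sum(vc_trunc)
  L <- pc$L
  env_idx <- 1L + seq_len(L)
  structure(
    list(theta = theta, theta_trunc = theta_trunc,
         pve = pve, pve_raw = pve_raw,
         h2_G = unname(pve[1L]),
         h2_GxE_env = pve[env_idx],
         h2_GxE_total = sum(pve[env_idx]),
         system = sys,
         N = pc$N, M = pc$M, L = L, D = pc$D, B = pc$B, seed = pc$seed,
         method = pc$method, call = cl),
    class = "memma")
}

#' @export
print.memma <- function(x, digits = 4, ...) {
  cat("MEMMA randomized Haseman-Elston fit\n")
  cat("  N =", x$N, " M =", x$M, " L =", x$L, " D =", x$D,
      if (!is.na(x$B)) paste0(" B = ", x$B), "\n")
  cat("  h2 (main)      :", format(x$h2_G, digits = digits), "\n")
  cat("  h2 (GxE total) :", format(x$h2_GxE_total, digits = digits), "\n")
  cat("  residual       :", format(unname(x$pve["residual"]), digits = digits), "\n")
  invisible(x)
}

#' @export
summary.memma <- function(object, ...) {
  out <- data.frame(component = object$system$labels,
                    theta = unname(object$theta),
                    theta_trunc = unname(object$theta_trunc),
                    pve = unname(object$pve),
                    pve_raw = unname(object$pve_raw),
                    row.names = NULL)
  structure(list(table = out, h2_G = object$h2_G,
                 h2_GxE_total = object$h2_GxE_total),
            class = "summary.memma")
}

#' @export
print.summary.memma <- function(x, digits = 4, ...) {
  cat("Per-component variance estimates:\n")
  print(x$table, digits = digits)
  cat("\nTotal GxE PVE:", format(x$h2_GxE_total, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.memma <- function(object, ...) object$theta
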