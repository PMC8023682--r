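# GPLEMMA: joint estimation of a linear environmental score and its GxE
# heritability by non-linear least squares.
#
# Model: y ~ N(C alpha, sigma_b^2 K + K2(wt) + sigma_e^2 I) with
# K2(wt) = diag(E wt) K diag(E wt) = (1/M) sum_{l,m} wt_l wt_m F_l F_m^T,
# where the GxE effect scale sigma_gamma has been absorbed into the weight
# vector wt.  The squared Frobenius loss between observed and expected
# (covariate-projected) trait covariance,
#   S(theta) = || W y y^T W - (sb WKW + W K2(wt) W + se W) ||_F^2,
# is minimized over theta = (sb, wt, se) by Levenberg-Marquardt.  All traces
# in S, J^T J and J^T eps reduce to quadratic/quartic forms in wt over the
# precomputed Gram matrix of projected pair-kernel probe vectors (see
# precompute.R), so each LM iteration is O(L^4) independent of N and M.

# Extract the blocks of the Gram needed for the w-algebra.  Pair p = (l-1)L+m
# corresponds to the operator W F_l F_m^T W / M.
gp_parts <- function(pc) {
  if (pc$pairs != "full") {
    stop("gplemma requires a precompute with pairs = \"full\"")
  }
  L <- pc$L
  pidx <- 2L + seq_len(L * L)
  # vec layout matching pair index: Hsvec[(l-1)L+m] = Hs[l,m]
  list(L = L,
       gpp = pc$G[1L, 1L], gpc = pc$G[1L, 2L], trW = pc$trW,
       Gp_phi = pc$G[pidx, 1L], Gp_chi = pc$G[pidx, 2L],
       Gpp = pc$G[pidx, pidx],
       Hsvec = as.vector(t(pc$Hs)), Hs = pc$Hs,
       qK = pc$qK, yWy = pc$yWy)
}

gp_uvec <- function(w) as.vector(outer(w, w))

# Squared error S(theta); theta = (sigma_b2, w_tilde, sigma_e2).
gp_S <- function(theta, parts) {
  L <- parts$L
  sb <- theta[1L]; w <- theta[2L:(L + 1L)]; se <- theta[L + 2L]
  u <- gp_uvec(w)
  Yf <- sb * parts$qK + sum(u * parts$Hsvec) + se * parts$yWy
  q12 <- sum(u * parts$Gp_phi)
  q23 <- sum(u * parts$Gp_chi)
  q22 <- drop(crossprod(u, parts$Gpp %*% u))
  ff <- sb^2 * parts$gpp + se^2 * parts$trW + 2 * sb * se * parts$gpc +
    2 * sb * q12 + 2 * se * q23 + q22
  parts$yWy^2 - 2 * Yf + ff
}

# Coefficient matrix mapping the pair dictionary onto the analytic Jacobian
# of K2(wt): d K2/d wt_l = (1/M)(F_l F_wt^T + F_wt F_l^T), i.e. column l has
# weight w_m on pairs (l,m) and (m,l).  This carries the factor-2
# symmetrization of differentiating the quadratic form.
gp_amat <- function(w) {
  L <- length(w)
  A <- matrix(0, L * L, L)
  for (l in seq_len(L)) {
    A[(l - 1L) * L + seq_len(L), l] <- A[(l - 1L) * L + seq_len(L), l] + w
    A[(seq_len(L) - 1L) * L + l, l] <- A[(seq_len(L) - 1L) * L + l, l] + w
  }
  A
}

# J^T J and J^T eps at theta.  The (se, se) entry is the exact tr(W) = N - D.
gp_jacobian <- function(theta, parts) {
  L <- parts$L
  sb <- theta[1L]; w <- theta[2L:(L + 1L)]; se <- theta[L + 2L]
  A <- gp_amat(w)
  JJ <- matrix(0, L + 2L, L + 2L)
  JJ[1L, 1L] <- parts$gpp
  JJ[1L, L + 2L] <- JJ[L + 2L, 1L] <- parts$gpc
  JJ[L + 2L, L + 2L] <- parts$trW
  Jwp <- drop(crossprod(A, parts$Gp_phi))
  Jwc <- drop(crossprod(A, parts$Gp_chi))
  JJ[1L, 2L:(L + 1L)] <- JJ[2L:(L + 1L), 1L] <- Jwp
  JJ[L + 2L, 2L:(L + 1L)] <- JJ[2L:(L + 1L), L + 2L] <- Jwc
  JJ[2L:(L + 1L), 2L:(L + 1L)] <- crossprod(A, parts$Gpp %*% A)
  JtY <- c(parts$qK, 2 * as.vector(parts$Hs %*% w), parts$yWy)
  Jtf <- drop(JJ %*% c(sb, w / 2, se))
  list(JJ = JJ, Jte = JtY - Jtf)
}

# Generic damped (Levenberg-Marquardt) least-squares driver over closures.
# S_fun(theta) returns the squared error; jac_fun(theta) returns
# list(JJ, Jte).  Steps solve (J^T J + mu I) delta = J^T eps; accepted steps
# divide mu by mu_down, rejected steps multiply by mu_up and retry.
lm_nls <- function(theta0, S_fun, jac_fun, tol = 1e-6, max_iter = 200L,
                   patience = 3L, mu0 = NULL, mu_up = 2, mu_down = 3,
                   max_inner = 50L, trace_S = FALSE) {
  theta <- theta0
  S <- S_fun(theta)
  if (!is.finite(S)) stop("non-finite squared error at the starting point")
  mu <- mu0
  n_small <- 0L
  accepted <- 0L
  reason <- "max_iter"
  S_path <- if (trace_S) S else NULL
  p <- length(theta)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    jp <- jac_fun(theta)
    if (is.null(mu)) mu <- 1e-3 * mean(diag(jp$JJ))
    step_ok <- FALSE
    for (inner in seq_len(max_inner)) {
      delta <- tryCatch(solve(jp$JJ + mu * diag(p), jp$Jte),
                        error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        S_new <- S_fun(theta + delta)
        if (is.finite(S_new) && S_new < S) {
          step_ok <- TRUE
          break
        }
      }
      mu <- mu * mu_up
    }
    if (!step_ok) {
      reason <- "no_improving_step"
      break
    }
    rel <- (S - S_new) / max(S, .Machine$double.eps)
    theta <- theta + delta
    S <- S_new
    if (trace_S) S_path <- c(S_path, S)
    mu <- mu / mu_down
    accepted <- accepted + 1L
    if (rel < tol) {
      n_small <- n_small + 1L
      if (n_small >= patience) {
        reason <- "tolerance"
        break
      }
    } else {
      n_small <- 0L
    }
  }
  list(theta = theta, S = S, iterations = it, accepted = accepted,
       converged = reason %in% c("tolerance", "no_improving_step"),
       reason = reason, mu = mu, S_path = S_path)
}

# Multistart initialization: wt_init ~ 1/L + N(0, 2/L^2) entrywise, then a
# 3-component moment solve with kernels {K, K2(wt_init), I} supplies the
# starting variance scales; the weights are scaled by sqrt(sigma_gamma2).
gp_init <- function(parts, restart, base_seed, eps = 1e-6) {
  L <- parts$L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(base_seed, restart))
  w0 <- 1 / L + stats::rnorm(L, 0, sqrt(2) / L)
  u0 <- gp_uvec(w0)
  q12 <- sum(u0 * parts$Gp_phi)
  q23 <- sum(u0 * parts$Gp_chi)
  q22 <- drop(crossprod(u0, parts$Gpp %*% u0))
  T3 <- matrix(c(parts$gpp, q12, parts$gpc,
                 q12, q22, q23,
                 parts$gpc, q23, parts$trW), 3L, 3L)
  c3 <- c(parts$qK, sum(u0 * parts$Hsvec), parts$yWy)
  th3 <- solve_moments(T3, c3)
  sg2 <- max(th3[2L], eps)
  c(max(th3[1L], eps), sqrt(sg2) * w0, max(th3[3L], eps))
}

#' GPLEMMA: environmental-score GxE heritability by randomized
#' Haseman-Elston non-linear regression
#'
#' Jointly estimates a linear environmental score (ES) \eqn{\eta = Ew} and
#' the proportion of phenotypic variance explained by its interaction with
#' genome-wide SNP effects.  The model
#' \deqn{y \sim N(C\alpha,\; \sigma_\beta^2 K + K_2(\tilde w) + \sigma_e^2 I),
#' \qquad K_2(\tilde w) = \mathrm{diag}(E\tilde w)\, K\,
#' \mathrm{diag}(E\tilde w),}
#' (the GxE effect scale absorbed into \eqn{\tilde w}) is fitted by
#' minimizing the squared Frobenius distance between observed and expected
#' covariate-projected trait covariance — a non-linear least-squares problem
#' solved by a damped Levenberg-Marquardt algorithm.  All required traces
#' are Hutchinson estimates assembled from one streaming pass over the
#' genotypes ([rhe_precompute()]).  `restarts` independent LM runs from
#' perturbed initializations are performed and the solution with the lowest
#' squared error is kept.
#'
#' The overall sign of \eqn{\tilde w} is unidentifiable
#' (\eqn{K_2(w) = K_2(-w)}); reported ES weights are unit-norm with the
#' largest-magnitude weight made positive, and `es_scale` carries
#' \eqn{\|\tilde w\|} (the implied GxE effect scale).
#'
#' @inheritParams memma
#' @param restarts number of LM restarts (default 10).
#' @param tol relative decrease of the squared error below which an accepted
#'   step counts toward convergence (default 1e-6, over a patience window of
#'   3 accepted steps).
#' @param max_iter maximum LM iterations per restart.
#' @return an object of class `gplemma` with components `theta`
#'   (\eqn{(\sigma_\beta^2, \tilde w, \sigma_e^2)}), `S` (squared error),
#'   `es_weights` (unit norm, canonical sign, named by environment),
#'   `es_scale`, `eta_hat` (fitted ES, `N`-vector), `varcomp`, `pve` (named
#'   `main`/`gxe`/`residual`, sums to 1), `h2_G`, `h2_GxE`, a per-restart
#'   diagnostics data frame `restarts`, and run metadata.
#' @examples
#' sim <- simulate_dataset(sim_config(N = 500, M = 400, L = 3, L_active = 2,
#'                                    M_G = 40, M_GxE = 20, seed = 1))
#' fit <- gplemma(sim$y, sim$geno, sim$E, sim$C, probes = 30, restarts = 3,
#'                seed = 2)
#' fit$pve
#' abs(cor(fit$eta_hat, sim$truth$eta_true))
#' @seealso [memma()] for per-environment components without an ES.
#' @export
gplemma <- function(y, genotypes = NULL, environments = NULL,
                    covariates = NULL, probes = 100L, restarts = 10L,
                    tol = 1e-6, max_iter = 200L, seed = 1L,
                    design = NULL, precompute = NULL) {
  cl <- match.call()
  if (is.null(design) && is.null(precompute)) {
    design <- assemble_design(environments, covariates)
  }
  if (is.null(precompute)) {
    if (!inherits(genotypes, "genotype_source")) genotypes <- genotype_matrix(genotypes)
    precompute <- rhe_precompute(genotypes, design, y, B = probes, seed = seed,
                                 pairs = "full")
  }
  pc <- precompute
  parts <- gp_parts(pc)
  L <- parts$L

  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    theta0 <- gp_init(parts, r, seed)
    runs[[r]] <- lm_nls(theta0,
                        S_fun = function(th) gp_S(th, parts),
                        jac_fun = function(th) gp_jacobian(th, parts),
                        tol = tol, max_iter = max_iter)
  }
  S_all <- vapply(runs, `[[`, numeric(1), "S")
  if (!any(is.finite(S_all))) {
    stop("all LM restarts diverged; restart squared errors: ",
         paste(format(S_all), collapse = ", "))
  }
  best <- which.min(S_all)
  fit <- runs[[best]]
  theta <- fit$theta
  sb <- theta[1L]; w_tilde <- theta[2L:(L + 1L)]; se <- theta[L + 2L]
  names(w_tilde) <- pc$env_names

  u <- gp_uvec(w_tilde)
  varcomp <- c(main = sb * parts$gpc,
               gxe = sum(u * parts$Gp_chi),
               residual = se * parts$trW)
  vc_pos <- pmax(varcomp, 0)
  pve <- vc_pos / sum(vc_pos)

  es_scale <- sqrt(sum(w_tilde^2))
  es_weights <- if (es_scale > 0) w_tilde / es_scale else w_tilde
  imax <- which.max(abs(es_weights))
  if (length(imax) && es_weights[imax] < 0) es_weights <- -es_weights
  eta_hat <- if (!is.null(design)) drop(design$E %*% es_weights) else NULL

  restart_df <- data.frame(
    restart = seq_len(restarts),
    S = S_all,
    iterations = vapply(runs, `[[`, integer(1), "iterations"),
    accepted = vapply(runs, `[[`, integer(1), "accepted"),
    converged = vapply(runs, `[[`, logical(1), "converged"),
    reason = vapply(runs, `[[`, character(1), "reason"))

  structure(
    list(theta = theta, sigma_b2 = sb, w_tilde = w_tilde, sigma_e2 = se,
         S = fit$S, es_weights = es_weights, es_scale = es_scale,
         eta_hat = eta_hat, varcomp = varcomp, pve = pve,
         h2_G = unname(pve["main"]), h2_GxE = unname(pve["gxe"]),
         restarts = restart_df, best_restart = best,
         converged = fit$converged, reason = fit$reason,
         N = pc$N, M = pc$M, L = L, D = pc$D, B = pc$B, seed = seed,
         tol = tol, max_iter = max_iter, method = pc$method, call = cl),
    class = "gplemma")
}

#' @export
print.gplemma <- function(x, digits = 4, ...) {
  cat("GPLEMMA non-linear randomized Haseman-Elston fit\n")
  cat("  N =", x$N, " M =", x$M, " L =", x$L, " D =", x$D,
      if (!is.na(x$B)) paste0(" B = ", x$B), "\n")
  cat("  h2 (main):", format(x$h2_G, digits = digits),
      "  h2 (GxE):", format(x$h2_GxE, digits = digits),
      "  residual:", format(unname(x$pve["residual"]), digits = digits), "\n")
  cat("  squared error S =", format(x$S, digits = digits),
      " (best of", nrow(x$restarts), "restarts,", x$reason, ")\n")
  invisible(x)
}

#' @export
summary.gplemma <- function(object, ...) {
  structure(list(pve = object$pve, es_weights = object$es_weights,
                 es_scale = object$es_scale, restarts = object$restarts),
            class = "summary.gplemma")
}

#' @export
print.summary.gplemma <- function(x, digits = 4, ...) {
  cat("Variance partition (PVE):\n")
  print(round(x$pve, digits))
  cat("\nEnvironmental score weights (unit norm, scale ",
      format(x$es_scale, digits = digits), "):\n", sep = "")
  print(round(x$es_weights, digits))
  cat("\nRestart diagnostics:\n")
  print(x$restarts, digits = digits)
  invisible(x)
}

#' @export
coef.gplemma <- function(object, ...) {
  stats::setNames(object$theta,
                  c("sigma_b2", paste0("w.", names(object$w_tilde)), "sigma_e2"))
}

#' @export
plot.gplemma <- function(x, ...) {
  graphics::barplot(x$es_weights, las = 2,
                    ylab = "ES weight (unit norm)",
                    main = "Estimated environmental score", ...)
  invisible(x)
}
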