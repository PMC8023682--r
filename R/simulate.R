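# Synthetic data with known ground truth.
#
# The generator produces independent-SNP genotypes, Gaussian or
# binomial-ordinal environments, and phenotypes of the form
#   y = C alpha + X beta + (eta o X) gamma + eps,   eta = E w,
# with spike-and-slab SNP effects.  Components are made empirically
# orthogonal and rescaled so the realized variance fractions hit their
# targets exactly, which keeps parameter-recovery tests sharp.

#' Simulation configuration
#'
#' Collects the generative parameters of the phenotype simulator.  The
#' defaults are the study conditions of the simulation design this package
#' validates against: N = 25000 samples, M = 100000 SNPs, L = 30
#' environments of which 6 carry interaction weights, 2500 main-effect and
#' 1250 interaction SNPs, main heritability 20%, GxE heritability 5%, and a
#' covariate explaining 1% of trait variance.  Pass smaller values for
#' desk-scale work (causal counts are usually scaled pro rata with M).
#'
#' @param N,M,L sample, SNP and environment counts.
#' @param L_active number of non-zero environmental-score weights.
#' @param M_G,M_GxE number of non-zero main-effect / interaction SNPs.
#' @param h2_g,h2_gxe,covar_frac target variance fractions of the main,
#'   interaction and covariate components; must sum to less than 1.
#' @param seed integer seed governing every random draw derived from this
#'   configuration.
#' @param env_kind `"continuous"` (standard Gaussian) or `"ordinal"`
#'   (binomial with 3-5 levels).
#' @param maf_low,maf_high allele-frequency range for simulated SNPs.
#' @param weight_form form of the interaction weight sequence, see
#'   [make_interaction_weights()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(N = 25000L, M = 100000L, L = 30L, L_active = 6L,
                       M_G = 2500L, M_GxE = 1250L, h2_g = 0.20,
                       h2_gxe = 0.05, covar_frac = 0.01, seed = 1L,
                       env_kind = c("continuous", "ordinal"),
                       maf_low = 0.05, maf_high = 0.5,
                       weight_form = c("linear", "sqrt")) {
  env_kind <- match.arg(env_kind)
  weight_form <- match.arg(weight_form)
  stopifnot(is_scalar_num(N), is_scalar_num(M), N >= 2, M >= 1,
            L >= 1, L_active >= 1, L_active <= L,
            M_G >= 0, M_G <= M, M_GxE >= 0, M_GxE <= M,
            h2_g >= 0, h2_gxe >= 0, covar_frac >= 0)
  if (h2_g + h2_gxe + covar_frac >= 1) {
    stop("h2_g + h2_gxe + covar_frac must be < 1")
  }
  structure(list(N = as.integer(N), M = as.integer(M), L = as.integer(L),
                 L_active = as.integer(L_active), M_G = as.integer(M_G),
                 M_GxE = as.integer(M_GxE), h2_g = h2_g, h2_gxe = h2_gxe,
                 covar_frac = covar_frac, seed = as.integer(seed),
                 env_kind = env_kind, maf_low = maf_low, maf_high = maf_high,
                 weight_form = weight_form),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: N =", x$N, " M =", x$M, " L =", x$L,
      "(", x$L_active, "active )\n")
  cat("  M_G =", x$M_G, " M_GxE =", x$M_GxE,
      " h2_g =", x$h2_g, " h2_gxe =", x$h2_gxe,
      " covar =", x$covar_frac, " env:", x$env_kind, "\n")
  invisible(x)
}

#' Simulate unlinked genotypes
#'
#' Draws dosages \eqn{G_{ij} \sim \mathrm{Binomial}(2, p_j)} with per-SNP
#' allele frequencies \eqn{p_j \sim U(\mathrm{maf\_low},
#' \mathrm{maf\_high})}.  Columns that come out monomorphic are redrawn so
#' the result never contains a zero-variance SNP.  No linkage
#' disequilibrium or population structure is simulated.
#'
#' @param N,M sample and SNP counts.
#' @param maf_low,maf_high allele-frequency range, `0 < maf_low <= maf_high
#'   <= 0.5`.
#' @param seed integer seed (same seed, same matrix).
#' @return list with `G` (integer `N x M` matrix of dosages 0/1/2) and
#'   `maf` (length-`M` vector of generating allele frequencies).
#' @export
simulate_genotypes <- function(N, M, maf_low = 0.05, maf_high = 0.5,
                               seed = 1L) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0 < maf_low <= maf_high <= 0.5")
  }
  set.seed(seed)
  maf <- stats::runif(M, maf_low, maf_high)
  G <- matrix(0L, N, M)
  chunk <- 2000L
  for (lo in seq(1L, M, by = chunk)) {
    sel <- lo:min(lo + chunk - 1L, M)
    G[, sel] <- matrix(as.integer(
      stats::rbinom(N * length(sel), 2L, rep(maf[sel], each = N))), N)
  }
  for (pass in 1:100) {
    mono <- integer(0)
    for (lo in seq(1L, M, by = chunk)) {
      sel <- lo:min(lo + chunk - 1L, M)
      Gc <- G[, sel, drop = FALSE]
      v <- colMeans(Gc * Gc) - colMeans(Gc)^2
      mono <- c(mono, sel[v == 0])
    }
    if (!length(mono)) break
    G[, mono] <- matrix(as.integer(
      stats::rbinom(N * length(mono), 2L, rep(maf[mono], each = N))),
      N)
  }
  list(G = G, maf = maf)
}

#' Simulate standardized environmental variables
#'
#' Continuous environments are standard Gaussian draws; ordinal environments
#' are binomial, \eqn{\mathrm{Bin}(n, p)} with the number of levels
#' \eqn{n \in \{3, 4, 5\}} drawn per column and \eqn{p \sim U(0, 0.5)}
#' (degenerate single-level columns are redrawn).  All columns are
#' standardized to mean 0, variance 1 (denominator `N`); for ordinal
#' columns the generating `n` and `p` are attached as attributes.
#'
#' @param N,L sample and environment counts.
#' @param env_kind `"continuous"` or `"ordinal"`.
#' @param seed integer seed.
#' @return standardized `N x L` matrix.
#' @export
simulate_environments <- function(N, L, env_kind = c("continuous", "ordinal"),
                                  seed = 1L) {
  env_kind <- match.arg(env_kind)
  stopifnot(L >= 1)
  set.seed(seed)
  if (env_kind == "continuous") {
    E <- matrix(stats::rnorm(N * L), N, L)
  } else {
    n_levels <- sample(3:5, L, replace = TRUE)
    p_col <- stats::runif(L, 0, 0.5)
    E <- matrix(0, N, L)
    for (l in seq_len(L)) {
      repeat {
        x <- stats::rbinom(N, n_levels[l] - 1L, p_col[l])
        if (length(unique(x)) > 1L) break
        p_col[l] <- stats::runif(1, 0, 0.5)
      }
      E[, l] <- x
    }
  }
  Es <- std_cols(E)
  colnames(Es) <- paste0("env", seq_len(L))
  if (env_kind == "ordinal") {
    attr(Es, "n_levels") <- n_levels
    attr(Es, "p") <- p_col
    attr(Es, "raw") <- E
  }
  Es
}

#' Interaction weight sequence
#'
#' Deterministic decreasing-magnitude, alternating-sign weights for the
#' simulated environmental score: active entries are
#' \deqn{w_i = (-1)^i \left(1 - \frac{i}{2 L_{active}}\right), \qquad i \le
#' L_{active},} and 0 elsewhere, so magnitudes decrease strictly from
#' \eqn{1 - 1/(2L_{active})} down to \eqn{1/2}.  `form = "sqrt"` applies a
#' square root to the decreasing factor instead, as an alternative reading
#' of the same decreasing-sequence recipe.
#'
#' @param L,L_active total and active environment counts,
#'   `1 <= L_active <= L`.
#' @param form `"linear"` (default) or `"sqrt"`.
#' @return numeric length-`L` weight vector with exactly `L_active`
#'   non-zeros.
#' @examples
#' make_interaction_weights(8, 4)
#' @export
make_interaction_weights <- function(L, L_active, form = c("linear", "sqrt")) {
  form <- match.arg(form)
  stopifnot(L_active >= 1, L_active <= L)
  i <- seq_len(L_active)
  fac <- 1 - i / (2 * L_active)
  if (form == "sqrt") fac <- sqrt(fac)
  w <- numeric(L)
  w[i] <- (-1)^i * fac
  w
}

# standardized causal columns from either a matrix or a genotype source
causal_cols <- function(X, idx) {
  if (inherits(X, "genotype_source")) {
    geno_columns(X, idx)
  } else {
    as.matrix(X)[, idx, drop = FALSE]
  }
}

# Orthogonalize-and-rescale assembly shared by the phenotype simulators:
# components are successively residualized (always against the intercept)
# and scaled so each explains exactly its target fraction of var(y), with
# the Gaussian noise absorbing the remainder.  Variances use denominator N.
assemble_phenotype <- function(parts, fracs, eps) {
  N <- length(eps)
  basis <- NULL
  out <- vector("list", length(parts))
  scales <- numeric(length(parts))
  for (i in seq_along(parts)) {
    if (fracs[i] > 0 && !is.null(parts[[i]])) {
      mi <- resid_on(parts[[i]], basis)
      v <- sum(mi^2) / N
      if (v == 0) stop("degenerate phenotype component ", names(parts)[i])
      scales[i] <- sqrt(fracs[i] / v)
      out[[i]] <- drop(scales[i] * mi)
      basis <- cbind(basis, mi)
    } else {
      out[[i]] <- numeric(N)
    }
  }
  fe <- 1 - sum(fracs)
  me <- resid_on(eps, basis)
  se <- sqrt(fe / (sum(me^2) / N))
  noise <- drop(se * me)
  y <- drop(Reduce(`+`, out) + noise)
  list(y = y, components = out, noise = noise, scales = scales,
       noise_scale = se)
}

#' Simulate the baseline GxE phenotype
#'
#' Generates \eqn{y = C\alpha + X\beta + (\eta \odot X)\gamma + \epsilon}
#' with \eqn{\eta = Ew}: spike-and-slab SNP effects (`M_G` non-zero main
#' effects, `M_GxE` non-zero interaction effects, positions uniform at
#' random, non-zero values standard Gaussian), the deterministic interaction
#' weight sequence of [make_interaction_weights()], and standard Gaussian
#' noise.  The covariate, main and interaction components are made
#' empirically orthogonal and rescaled so their realized variance fractions
#' equal `covar_frac`, `h2_g` and `h2_gxe` *exactly*; `var(y) = 1` by
#' construction.  A zero target heritability yields an exactly zero
#' coefficient vector.
#'
#' @param config a [sim_config()].
#' @param X standardized genotypes: a numeric matrix or a
#'   [genotype source][genotype_matrix].
#' @param E standardized `N x L` environment matrix.
#' @param C covariate matrix (e.g. the leading genetic principal
#'   component), or `NULL` when `covar_frac = 0`.
#' @return list with `y` and `truth`, an object of class `sim_truth`
#'   recording `beta`, `gamma`, `w_true`, `eta_true`, `alpha`, the realized
#'   component vectors and variance fractions.
#' @export
simulate_baseline <- function(config, X, E, C = NULL) {
  N <- config$N; M <- if (inherits(X, "genotype_source")) X$M else ncol(X)
  L <- config$L
  stopifnot(nrow(E) == N, ncol(E) == L)
  if (config$covar_frac > 0 && is.null(C)) {
    stop("covar_frac > 0 requires a covariate matrix C")
  }
  if (config$h2_g > 0 && config$M_G == 0) stop("h2_g > 0 requires M_G > 0")
  if (config$h2_gxe > 0 && config$M_GxE == 0) stop("h2_gxe > 0 requires M_GxE > 0")
  set.seed(derive_seed(config$seed, 101L))
  beta <- numeric(M); gamma <- numeric(M)
  supp_b <- supp_g <- integer(0)
  if (config$M_G > 0 && config$h2_g > 0) {
    supp_b <- sample.int(M, config$M_G)
    beta[supp_b] <- stats::rnorm(config$M_G)
  }
  if (config$M_GxE > 0 && config$h2_gxe > 0) {
    supp_g <- sample.int(M, config$M_GxE)
    gamma[supp_g] <- stats::rnorm(config$M_GxE)
  }
  w <- make_interaction_weights(L, config$L_active, config$weight_form)
  eta <- drop(E %*% w)
  g_main <- if (length(supp_b)) drop(causal_cols(X, supp_b) %*% beta[supp_b]) else NULL
  g_gxe <- if (length(supp_g)) eta * drop(causal_cols(X, supp_g) %*% gamma[supp_g]) else NULL
  alpha <- NULL
  cov0 <- NULL
  if (config$covar_frac > 0) {
    C <- as.matrix(C)
    alpha <- stats::rnorm(ncol(C))
    cov0 <- drop(C %*% alpha)
  }
  eps <- stats::rnorm(N)
  asm <- assemble_phenotype(list(covar = cov0, main = g_main, gxe = g_gxe),
                            c(config$covar_frac, config$h2_g, config$h2_gxe),
                            eps)
  truth <- structure(
    list(beta = beta * asm$scales[2], gamma = gamma * asm$scales[3],
         w_true = w, eta_true = eta,
         alpha = if (!is.null(alpha)) alpha * asm$scales[1] else NULL,
         components = list(covar = asm$components[[1]],
                           main = asm$components[[2]],
                           gxe = asm$components[[3]],
                           noise = asm$noise),
         var_frac = c(covar = config$covar_frac, main = config$h2_g,
                      gxe = config$h2_gxe,
                      noise = 1 - config$covar_frac - config$h2_g - config$h2_gxe),
         config = config),
    class = "sim_truth")
  list(y = asm$y, truth = truth)
}

#' Simulate a phenotype driven by three orthogonal environmental scores
#'
#' Generalizes the baseline model to \eqn{y = C\alpha + X\beta + \sum_{k}
#' (\eta_k \odot X)\gamma_k + \epsilon} with \eqn{\eta_k = EW_k}: the
#' \eqn{L \times K} weight matrix `W` has `L_active` non-zero rows (standard
#' Gaussian) and orthonormal columns, the supports of the \eqn{\gamma_k}
#' are disjoint (each of size `M_GxE`), and \eqn{\gamma_k} is scaled so the
#' singular values of the implied GxE effect matrix \eqn{\Lambda = \sum_k
#' W_k \gamma_k^T} are proportional to `singular_values` (decreasing).  The
#' total GxE component is then rescaled to the configured `h2_gxe`, which
#' preserves the singular-value ratios.
#'
#' @inheritParams simulate_baseline
#' @param singular_values length-`K` decreasing positive scales of the
#'   per-score GxE terms.
#' @return list with `y` and `truth`; `truth$W_true` is `L x K`,
#'   `truth$gamma` is `M x K`, `truth$per_es_scale` records the realized
#'   singular values, `truth$eta_true` is `N x K`.
#' @export
simulate_multi_es <- function(config, X, E, C = NULL,
                              singular_values = c(80, 60, 40)) {
  N <- config$N; M <- if (inherits(X, "genotype_source")) X$M else ncol(X)
  L <- config$L; K <- length(singular_values)
  if (K * config$M_GxE > M) {
    stop("disjoint supports need K * M_GxE <= M")
  }
  if (config$covar_frac > 0 && is.null(C)) {
    stop("covar_frac > 0 requires a covariate matrix C")
  }
  set.seed(derive_seed(config$seed, 202L))
  active <- sort(sample.int(L, config$L_active))
  W0 <- matrix(stats::rnorm(config$L_active * K), config$L_active, K)
  Wmat <- matrix(0, L, K)
  Wmat[active, ] <- qr.Q(qr(W0))
  eta <- E %*% Wmat

  beta <- numeric(M)
  supp_b <- integer(0)
  if (config$M_G > 0 && config$h2_g > 0) {
    supp_b <- sample.int(M, config$M_G)
    beta[supp_b] <- stats::rnorm(config$M_G)
  }
  supp_all <- sample.int(M, K * config$M_GxE)
  gamma <- matrix(0, M, K)
  gxe_k <- matrix(0, N, K)
  for (k in seq_len(K)) {
    sk <- supp_all[(k - 1L) * config$M_GxE + seq_len(config$M_GxE)]
    gk <- stats::rnorm(config$M_GxE)
    gk <- gk * singular_values[k] / sqrt(sum(gk^2))
    gamma[sk, k] <- gk
    gxe_k[, k] <- eta[, k] * drop(causal_cols(X, sk) %*% gk)
  }
  g_gxe <- rowSums(gxe_k)
  g_main <- if (length(supp_b)) drop(causal_cols(X, supp_b) %*% beta[supp_b]) else NULL
  alpha <- NULL; cov0 <- NULL
  if (config$covar_frac > 0) {
    C <- as.matrix(C)
    alpha <- stats::rnorm(ncol(C))
    cov0 <- drop(C %*% alpha)
  }
  eps <- stats::rnorm(N)
  asm <- assemble_phenotype(list(covar = cov0, main = g_main, gxe = g_gxe),
                            c(config$covar_frac, config$h2_g, config$h2_gxe),
                            eps)
  truth <- structure(
    list(beta = beta * asm$scales[2], gamma = gamma * asm$scales[3],
         W_true = Wmat, eta_true = eta,
         per_es_scale = singular_values * asm$scales[3],
         alpha = if (!is.null(alpha)) alpha * asm$scales[1] else NULL,
         components = list(covar = asm$components[[1]],
                           main = asm$components[[2]],
                           gxe = asm$components[[3]],
                           noise = asm$noise),
         var_frac = c(covar = config$covar_frac, main = config$h2_g,
                      gxe = config$h2_gxe,
                      noise = 1 - config$covar_frac - config$h2_g - config$h2_gxe),
         config = config),
    class = "sim_truth")
  list(y = asm$y, truth = truth)
}

#' Simulate a misspecified phenotype with a squared heritable environment
#'
#' Builds a heritable environmental variable `S` (genetic variance fraction
#' exactly 0.30, with 2500 causal SNPs at M = 100000 and pro-rata counts
#' otherwise), standardizes it, inserts it as the *first* column of `E`, and
#' returns \eqn{y = \alpha_s S^2 + y_{baseline}} where the baseline
#' phenotype is simulated on the modified environment matrix.  Squared
#' dependence on a heritable environment is exactly the misspecification
#' the (+SQE) pre-screen ([squared_effect_screen()]) is designed to absorb.
#'
#' @inheritParams simulate_baseline
#' @param alpha_s strength of the squared effect; `alpha_s = 0` reproduces
#'   the baseline phenotype.
#' @return list with `y`, `truth`, `S` (the standardized heritable
#'   environment) and `E` (the modified environment matrix actually used).
#' @export
simulate_misspecified <- function(config, X, E, C = NULL, alpha_s = 1) {
  N <- config$N; M <- if (inherits(X, "genotype_source")) X$M else ncol(X)
  set.seed(derive_seed(config$seed, 303L))
  mis_M <- max(1L, as.integer(round(2500 * M / 1e5)))
  supp_S <- sample.int(M, mis_M)
  bS <- stats::rnorm(mis_M)
  Sg <- drop(causal_cols(X, supp_S) %*% bS)
  epsS <- stats::rnorm(N)
  Sgc <- drop(resid_on(Sg))
  Sec <- drop(resid_on(epsS, Sgc))
  S_gen <- sqrt(0.30 / (sum(Sgc^2) / N)) * Sgc
  S <- S_gen + sqrt(0.70 / (sum(Sec^2) / N)) * Sec
  E2 <- E
  E2[, 1L] <- S
  base <- simulate_baseline(config, X, E2, C)
  base$truth$S_causal <- supp_S
  base$truth$S_genetic <- S_gen
  base$truth$S_h2 <- (sum(S_gen^2) / N) / (sum(S^2) / N)
  list(y = drop(alpha_s * S^2 + base$y), truth = base$truth, S = S, E = E2)
}

# leading genetic principal component by block power iteration (direction
# only; used as the default simulated covariate)
geno_pc1 <- function(src, seed = 1L, iters = 8L) {
  set.seed(seed)
  v <- stats::rnorm(src$N)
  for (i in seq_len(iters)) {
    v <- stream_xxt(src, v)$R / src$M
    v <- v - mean(v)
    v <- v / sqrt(sum(v^2))
  }
  v
}

#' Simulate a complete dataset
#'
#' Convenience wrapper drawing genotypes ([simulate_genotypes()]),
#' environments ([simulate_environments()]), the leading genetic principal
#' component as covariate, and one of the three phenotype classes.  All
#' randomness derives from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param phenotype `"baseline"`, `"multi_es"` or `"misspecified"`.
#' @param alpha_s squared-effect strength for `"misspecified"`.
#' @param singular_values per-score scales for `"multi_es"`.
#' @return list with `geno` (a [genotype source][genotype_matrix]), `E`,
#'   `C` (one-column matrix), `y`, `truth`, `config`, and for the
#'   misspecified phenotype `S`.
#' @export
simulate_dataset <- function(config,
                             phenotype = c("baseline", "multi_es",
                                           "misspecified"),
                             alpha_s = 1, singular_values = c(80, 60, 40)) {
  phenotype <- match.arg(phenotype)
  g <- simulate_genotypes(config$N, config$M, config$maf_low,
                          config$maf_high, derive_seed(config$seed, 1L))
  src <- genotype_matrix(g$G)
  src$maf <- g$maf
  E <- simulate_environments(config$N, config$L, config$env_kind,
                             derive_seed(config$seed, 2L))
  C <- matrix(geno_pc1(src, derive_seed(config$seed, 3L)),
              dimnames = list(NULL, "PC1"))
  sim <- switch(phenotype,
    baseline = simulate_baseline(config, src, E, C),
    multi_es = simulate_multi_es(config, src, E, C, singular_values),
    misspecified = simulate_misspecified(config, src, E, C, alpha_s))
  if (phenotype == "misspecified") E <- sim$E
  out <- list(geno = src, E = E, C = C, y = sim$y, truth = sim$truth,
              config = config)
  if (phenotype == "misspecified") out$S <- sim$S
  out
}

#' Write a simulated dataset to disk
#'
#' Writes PLINK BED/BIM/FAM genotypes, tab-separated phenotype, environment
#' and covariate tables (first column `id`, header row), and a JSON ground
#' truth file.
#'
#' @param sim result of [simulate_dataset()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
save_dataset <- function(sim, prefix) {
  src <- sim$geno
  if (src$backend != "matrix") stop("only in-memory simulated genotypes can be saved")
  write_plink(prefix, src$data, sample_ids = src$sample_ids,
              snp_ids = src$snp_ids)
  ids <- src$sample_ids
  tsv <- function(df, suffix) {
    utils::write.table(df, paste0(prefix, suffix), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(data.frame(id = ids, y = sim$y), ".pheno.tsv")
  tsv(data.frame(id = ids, sim$E, check.names = FALSE), ".env.tsv")
  tsv(data.frame(id = ids, sim$C, check.names = FALSE), ".covar.tsv")
  tr <- sim$truth
  jsonlite::write_json(
    list(config = unclass(tr$config), beta = tr$beta, gamma = tr$gamma,
         w_true = tr$w_true, eta_true = tr$eta_true, alpha = tr$alpha,
         var_frac = as.list(tr$var_frac)),
    paste0(prefix, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a delimited table keyed by sample ID
#'
#' Reads a whitespace- or tab-delimited text file whose first column holds
#' sample IDs (header row required) and returns a numeric matrix with the
#' IDs as row names, aligned to `ids` when given (error listing missing
#' IDs otherwise).
#'
#' @param path file path.
#' @param ids optional character vector giving the required row order.
#' @return numeric matrix with rownames.
#' @export
read_id_table <- function(path, ids = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  rn <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  if (!is.null(ids)) {
    idx <- match(as.character(ids), rn)
    if (anyNA(idx)) {
      stop("sample ID(s) missing from ", path, ": ",
           paste(utils::head(ids[is.na(idx)], 10L), collapse = ", "))
    }
    m <- m[idx, , drop = FALSE]
  }
  m
}
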