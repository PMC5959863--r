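#' Read and validate a phylogeny from a Newick file
#'
#' Wraps `ape::read.tree` with the validation the comparative analyses
#' require: branch lengths must be present, tip labels unique, and
#' zero-length terminal branches are inflated to a small epsilon
#' (`1e-8 * max root-to-tip depth`) with a warning so that the Brownian
#' covariance stays positive definite.
#'
#' @param path Path to a Newick file, or a Newick string.
#' @return An `ape` `phylo` object.
#' @export
read_newick_tree <- function(path) {
  tree <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tree)) stop("could not parse Newick input")
  validate_phylogeny(tree)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0)) {
    eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
    tree$edge.length[term & tree$edge.length == 0] <- eps
    warning("zero-length terminal branches inflated to ", signif(eps, 3))
  }
  tree
}

#' Prune a tree to the species present in a trait table
#'
#' Reports (as a warning) tips dropped from the tree and species missing
#' from it, before any model is fitted.
#'
#' @param tree A `phylo` object.
#' @param species Character vector of species IDs to keep.
#' @return The pruned tree.
#' @export
prune_to_species <- function(tree, species) {
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp))
    warning("species absent from the tree: ", paste(missing_sp, collapse = ", "))
  drop <- setdiff(tree$tip.label, species)
  if (length(drop)) {
    warning("pruning ", length(drop), " tip(s) absent from the trait table")
    tree <- ape::drop.tip(tree, drop)
  }
  tree
}

#' Brownian-motion covariance matrix of a phylogeny
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances. Under Brownian motion the
#' cross-species trait covariance is proportional to this matrix.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric S x S matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  tree <- validate_phylogeny(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` is pure Brownian motion; `lambda = 0` removes all
#' phylogenetic covariance (the OLS limit).
#'
#' @param C Covariance matrix from [bm_covariance()].
#' @param lambda Signal multiplier in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

# GLS machinery for a fixed covariance matrix. Returns coefficients,
# residual sums of squares (slope model and phylogenetically weighted
# intercept-only model) and both ML and REML log-likelihoods.
gls_profile <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  R <- tryCatch(chol(V), error = function(e)
    stop("phylogenetic covariance is singular; check for duplicated or zero-distance tips"))
  logdetV <- 2 * sum(log(diag(R)))
  w <- function(M) backsolve(R, M, transpose = TRUE)  # R^-T M
  yt <- w(y); Xt <- w(X)
  XtX <- crossprod(Xt)
  beta <- solve(XtX, crossprod(Xt, yt))
  resid <- yt - Xt %*% beta
  rss <- sum(resid^2)
  ones <- w(matrix(1, n, 1))
  mu0 <- sum(ones * yt) / sum(ones^2)
  rss0 <- sum((yt - ones * mu0)^2)
  sig2_ml <- rss / n
  ll_ml <- -0.5 * (n * log(2 * pi * sig2_ml) + logdetV + n)
  sig2_reml <- rss / (n - p)
  ll_reml <- -0.5 * ((n - p) * log(2 * pi * sig2_reml) + logdetV +
                       determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  list(beta = drop(beta), rss = rss, rss0 = rss0, XtX = XtX,
       loglik_ml = ll_ml, loglik_reml = as.numeric(ll_reml))
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y ~ x` by GLS under a lambda-scaled Brownian covariance, estimating
#' lambda by profiling the likelihood over `[0, 1]` (golden-section search
#' via `optimize`, tolerance 1e-6, with both endpoints evaluated explicitly
#' so boundary optima are exact). ML is the default objective for the lambda
#' profile; REML is available. Coefficient standard errors use the GLS
#' residual variance on `n - 2` degrees of freedom, and the adjusted R^2 is
#' computed from GLS residual and total (phylogenetically weighted
#' intercept-only) sums of squares, so it can be negative.
#'
#' @param y Named numeric response vector (names = tip labels).
#' @param x Named numeric predictor vector.
#' @param tree A `phylo` object containing all names of `y`.
#' @param lambda `"ML"` (estimate) or a fixed value in `[0, 1]`.
#' @param method Objective for the lambda profile, `"ML"` or `"REML"`.
#' @return A list of class `pgls_fit`: `beta` (intercept, slope), `se`, `t`,
#'   `p` (on `n - 2` df), `lambda_hat`, `adj_r2`, `r2`, `loglik`, `n`,
#'   `method`.
#' @export
pgls_fit <- function(y, x, tree, lambda = "ML", method = c("ML", "REML")) {
  method <- match.arg(method)
  if (is.null(names(y)) || is.null(names(x)))
    stop("y and x must be named by species")
  if (!setequal(names(y), names(x))) stop("y and x species sets differ")
  tree <- prune_to_species(validate_phylogeny(tree), names(y))
  if (!all(names(y) %in% tree$tip.label))
    stop("species missing from the tree: ",
         paste(setdiff(names(y), tree$tip.label), collapse = ", "))
  ord <- tree$tip.label
  y <- y[ord]; x <- x[names(y)]
  n <- length(y)
  if (n < 4L) stop("need at least 4 species")
  C <- bm_covariance(tree)[ord, ord]
  X <- cbind(intercept = 1, slope = x)
  ll_at <- function(lam) {
    g <- gls_profile(y, X, lambda_transform(C, lam))
    if (method == "ML") g$loglik_ml else g$loglik_reml
  }
  if (identical(lambda, "ML")) {
    opt <- stats::optimize(ll_at, interval = c(0, 1), maximum = TRUE,
                           tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    vals <- c(ll_at(0), opt$objective, ll_at(1))
    lambda_hat <- cand[which.max(vals)]
  } else {
    lambda_hat <- lambda
    if (!is.numeric(lambda_hat) || lambda_hat < 0 || lambda_hat > 1)
      stop("lambda must be \"ML\" or a value in [0, 1]")
  }
  g <- gls_profile(y, X, lambda_transform(C, lambda_hat))
  names(g$beta) <- colnames(X)
  sig2 <- g$rss / (n - 2)
  se <- sqrt(diag(sig2 * solve(g$XtX)))
  names(se) <- colnames(X)
  tval <- g$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  r2 <- 1 - g$rss / g$rss0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(list(beta = g$beta, se = se, t = tval, p = pval,
                 lambda_hat = lambda_hat, r2 = r2, adj_r2 = adj_r2,
                 loglik = if (method == "ML") g$loglik_ml else g$loglik_reml,
                 n = n, method = method),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s): lambda = %.3f, adj R2 = %.3f, n = %d\n",
              x$method, x$lambda_hat, x$adj_r2, x$n))
  print(data.frame(estimate = x$beta, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

#' Log-likelihood of bivariate traits under Brownian motion on a tree
#'
#' Matrix-normal log density of a p x S trait matrix with row (between-trait)
#' covariance `Sigma` and column (between-species) covariance equal to the
#' tree's Brownian matrix, centred on a common root state. Equivalent to the
#' dense `p*S`-dimensional multivariate normal with covariance
#' `Sigma %x% C`, but computed in O(S^3 + p^3).
#'
#' @param traits p x S numeric matrix, columns named by tip label.
#' @param tree A `phylo` object.
#' @param Sigma p x p positive-definite Brownian rate covariance.
#' @param root_state Numeric p-vector of root trait values.
#' @return The log density (a scalar).
#' @export
bm_loglik <- function(traits, tree, Sigma, root_state) {
  stopifnot(is.matrix(traits), is.matrix(Sigma),
            nrow(Sigma) == nrow(traits), length(root_state) == nrow(traits))
  tree <- validate_phylogeny(tree)
  C <- bm_covariance(tree)
  if (is.null(colnames(traits))) stop("traits columns must be named by tip")
  C <- C[colnames(traits), colnames(traits)]
  p <- nrow(traits); S <- ncol(traits)
  Rs <- tryCatch(chol(Sigma), error = function(e) stop("Sigma must be positive definite"))
  Rc <- chol(C)
  E <- traits - root_state
  # tr(Sigma^-1 E C^-1 E') via triangular solves
  A <- backsolve(Rs, E, transpose = TRUE)          # Rs^-T E
  B <- t(backsolve(Rc, t(A), transpose = TRUE))    # A Rc^-1... (C^-1 = Rc^-1 Rc^-T)
  quad <- sum(B^2)
  -0.5 * (p * S * log(2 * pi) + p * 2 * sum(log(diag(Rc))) +
            S * 2 * sum(log(diag(Rs))) + quad)
}

# Sufficient statistics for the root-marginalized bivariate BM model:
# GLS root estimate per trait and the 2x2 cross-product matrix
# A = (X - root 1') C^-1 (X - root 1')'.
bm_suffstats <- function(traits, tree) {
  tree <- validate_phylogeny(tree)
  C <- bm_covariance(tree)
  C <- C[colnames(traits), colnames(traits)]
  Rc <- chol(C)
  S <- ncol(traits)
  ones <- backsolve(Rc, rep(1, S), transpose = TRUE)
  Xt <- backsolve(Rc, t(traits), transpose = TRUE)   # S x p
  root <- as.numeric(crossprod(Xt, ones) / sum(ones^2))
  E <- Xt - outer(ones, root)
  list(A = crossprod(E), root = root, S = S)
}

log_iw_density <- function(Sigma, Psi, nu) {
  p <- nrow(Sigma)
  Rs <- chol(Sigma)
  -0.5 * ((nu + p + 1) * 2 * sum(log(diag(Rs))) +
            sum(diag(solve(Sigma, Psi))))
}

#' Bayesian Brownian-motion correlation between two traits on a fixed tree
#'
#' Posterior of the 2 x 2 Brownian rate covariance `Sigma` given two traits
#' evolving on a fixed dated phylogeny, with an inverse-Wishart prior on
#' `Sigma` and an improper flat prior on the root state (marginalized
#' analytically). Sampling is random-walk Metropolis on the log-Cholesky
#' parameterization of `Sigma`. The quantity of interest is the evolutionary
#' correlation `r = Sigma[1,2]/sqrt(Sigma[1,1]*Sigma[2,2])` and its
#' posterior probability of being positive, `pp = Pr(r > 0 | data)`: pp
#' close to 1 supports a positive association, close to 0 a negative one.
#' The run is only reported when the minimum effective sample size reaches
#' `ess_floor`; otherwise a diagnostic error carrying the trace is raised.
#'
#' @param traits 2 x S matrix (rows = traits, columns named by tip label),
#'   or a data.frame with `species` plus two trait columns.
#' @param tree A `phylo` object containing all species.
#' @param prior_df Inverse-Wishart degrees of freedom (default 4).
#' @param prior_scale Inverse-Wishart scale matrix (default identity).
#' @param cycles Total MCMC cycles (default 30000).
#' @param burn_in Cycles discarded as burn-in (default `cycles %/% 10`).
#' @param proposal_sd Random-walk proposal standard deviation on the
#'   log-Cholesky scale.
#' @param seed RNG seed; recorded in the result.
#' @param ess_floor Minimum effective sample size required to report
#'   (default 300).
#' @return A list of class `bm_posterior`: `r_samples`, `r_mean`, `pp`,
#'   `ess`, `acceptance_rate`, `sigma_mean`, and `config`.
#' @seealso [bm_correlation_exact()] for the conjugate direct sampler.
#' @export
bayes_bm_correlation <- function(traits, tree, prior_df = 4,
                                 prior_scale = diag(2), cycles = 30000L,
                                 burn_in = NULL, proposal_sd = 0.15,
                                 seed = 1L, ess_floor = 300) {
  traits <- as_trait_matrix(traits)
  if (is.null(burn_in)) burn_in <- cycles %/% 10L
  if (cycles <= burn_in) stop("cycles must exceed burn_in")
  ss <- bm_suffstats(traits, tree)
  A <- ss$A; S <- ss$S
  log_target <- function(theta) {
    L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
    Sigma <- L %*% t(L)
    ll <- -0.5 * ((S - 1) * log_det2(Sigma) + tr_solve2(Sigma, A))
    lp <- -0.5 * ((prior_df + 3) * log_det2(Sigma) + tr_solve2(Sigma, prior_scale))
    # Jacobian of Sigma = LL' with L11, L22 on the log scale
    ljac <- 3 * theta[1] + 2 * theta[3]
    list(lp = ll + lp + ljac, Sigma = Sigma)
  }
  out <- with_seed(seed, {
    theta <- c(0.5 * log(A[1, 1] / S + 1e-8), 0, 0.5 * log(A[2, 2] / S + 1e-8))
    cur <- log_target(theta)
    keep <- cycles - burn_in
    r_samples <- numeric(keep)
    sig_sum <- matrix(0, 2, 2)
    theta_keep <- matrix(0, keep, 3)
    acc <- 0L
    for (i in seq_len(cycles)) {
      prop_theta <- theta + stats::rnorm(3, 0, proposal_sd)
      prop <- log_target(prop_theta)
      if (log(stats::runif(1)) < prop$lp - cur$lp) {
        theta <- prop_theta; cur <- prop; acc <- acc + 1L
      }
      if (i > burn_in) {
        k <- i - burn_in
        Sg <- cur$Sigma
        r_samples[k] <- Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2])
        theta_keep[k, ] <- theta
        sig_sum <- sig_sum + Sg
      }
    }
    list(r_samples = r_samples, theta = theta_keep,
         acc_rate = acc / cycles, sigma_mean = sig_sum / keep)
  })
  ess <- c(r = as.numeric(coda::effectiveSize(out$r_samples)),
           apply(out$theta, 2, function(v) as.numeric(coda::effectiveSize(v))))
  names(ess) <- c("r", "log_l11", "l21", "log_l22")
  res <- structure(list(r_samples = out$r_samples,
                        r_mean = mean(out$r_samples),
                        pp = mean(out$r_samples > 0),
                        ess = ess,
                        acceptance_rate = out$acc_rate,
                        sigma_mean = out$sigma_mean,
                        config = list(cycles = cycles, burn_in = burn_in,
                                      proposal_sd = proposal_sd, seed = seed,
                                      prior_df = prior_df,
                                      ess_floor = ess_floor)),
                   class = "bm_posterior")
  if (min(ess) < ess_floor) {
    cond <- simpleError(sprintf(
      "MCMC did not converge: min ESS %.0f < floor %.0f; trace attached as $diagnostics",
      min(ess), ess_floor))
    cond$diagnostics <- res
    stop(cond)
  }
  res
}

#' @export
print.bm_posterior <- function(x, ...) {
  cat(sprintf("Brownian-motion correlation posterior: mean r = %.3f, pp = %.3f\n",
              x$r_mean, x$pp))
  cat(sprintf("  min ESS = %.0f, acceptance = %.2f, cycles = %d (seed %d)\n",
              min(x$ess), x$acceptance_rate, x$config$cycles, x$config$seed))
  invisible(x)
}

#' Exact conjugate posterior sampler for the Brownian rate correlation
#'
#' With the root state marginalized under a flat prior, the inverse-Wishart
#' prior on the Brownian rate covariance is conjugate: the posterior of
#' `Sigma` is inverse-Wishart with scale `prior_scale + A` and degrees of
#' freedom `prior_df + S - 1`, where `A` is the GLS cross-product of the
#' root-centred traits and `S` the number of tips. This draws from it
#' directly (no MCMC), which is useful as an independent check of
#' [bayes_bm_correlation()] and as a fast alternative.
#'
#' @inheritParams bayes_bm_correlation
#' @param n_draws Number of posterior draws.
#' @return A list with `r_samples`, `r_mean` and `pp`.
#' @export
bm_correlation_exact <- function(traits, tree, prior_df = 4,
                                 prior_scale = diag(2), n_draws = 10000L,
                                 seed = 1L) {
  traits <- as_trait_matrix(traits)
  ss <- bm_suffstats(traits, tree)
  Psi <- prior_scale + ss$A
  nu <- prior_df + ss$S - 1
  r_samples <- with_seed(seed, {
    W <- stats::rWishart(n_draws, df = nu, Sigma = solve(Psi))
    vapply(seq_len(n_draws), function(i) {
      Sg <- solve(W[, , i])
      Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2])
    }, numeric(1))
  })
  list(r_samples = r_samples, r_mean = mean(r_samples),
       pp = mean(r_samples > 0))
}

as_trait_matrix <- function(traits) {
  if (is.data.frame(traits)) {
    sp_col <- intersect(c("species", "species_id"), names(traits))[1]
    if (is.na(sp_col)) stop("trait data.frame needs a species column")
    num <- traits[, setdiff(names(traits), sp_col), drop = FALSE]
    if (ncol(num) != 2L) stop("exactly two trait columns required")
    m <- t(as.matrix(num))
    colnames(m) <- traits[[sp_col]]
    return(m)
  }
  if (!is.matrix(traits) || nrow(traits) != 2L)
    stop("traits must be a 2 x S matrix or a species + 2-column data.frame")
  traits
}

log_det2 <- function(M) log(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
tr_solve2 <- function(M, A) {
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  (M[2, 2] * A[1, 1] - 2 * M[1, 2] * A[1, 2] + M[1, 1] * A[2, 2]) / det
}
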