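test_that("Newick reading validates branch lengths and tip labels", {
  tr <- read_newick_tree("((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:3]), c(2, 2, 2))
  expect_error(read_newick_tree("((A,B),C);"), "branch lengths")
  expect_error(read_newick_tree("((A:1,A:1):1,C:2);"), "duplicate")
  expect_warning(read_newick_tree("((A:0,B:1):1,C:2);"), "zero-length")
  expect_warning(prune_to_species(read_newick_tree("((A:1,B:1):1,C:2);"),
                                  c("A", "B")), "pruning")
})

test_that("Brownian covariance matches path arithmetic and the brute-force oracle", {
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  Cs <- bm_covariance(star)
  expect_equal(Cs, diag(3, 4, 4), ignore_attr = TRUE)
  tr <- read_newick_tree("((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["A", "A"], 2)
  for (seed in c(2, 9)) {
    rt <- simulate_yule_tree(10, 1, seed = seed)
    Ci <- bm_covariance(rt)
    Co <- brute_bm_cov(rt)
    expect_equal(Ci[rownames(Co), colnames(Co)], Co, tolerance = 1e-12)
  }
})

test_that("lambda transform scales off-diagonals only", {
  tr <- read_newick_tree("((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr)
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  H <- lambda_transform(C, 0.5)
  expect_equal(diag(H), diag(C))
  expect_equal(H[upper.tri(H)], 0.5 * C[upper.tri(C)])
  expect_error(lambda_transform(C, 1.2), "lambda")
})

test_that("PGLS on a star tree equals OLS to machine precision", {
  set.seed(4)
  n <- 20
  star <- ape::read.tree(text = paste0("(", paste0("s", 1:n, ":1", collapse = ","), ");"))
  x <- setNames(rnorm(n), star$tip.label)
  y <- setNames(2 + 0.7 * x + rnorm(n), star$tip.label)
  fit <- pgls_fit(y, x, star, lambda = 0)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ols)))), tolerance = 1e-10)
  expect_equal(fit$adj_r2, summary(ols)$adj.r.squared, tolerance = 1e-10)
  # on a star tree every lambda gives the same independent covariance,
  # so the ML fit must coincide with OLS too
  fit_ml <- pgls_fit(y, x, star)
  expect_equal(unname(fit_ml$beta), unname(coef(ols)), tolerance = 1e-8)
})

test_that("a noiseless linear relationship is recovered exactly", {
  tr <- simulate_yule_tree(15, 1, seed = 6)
  x <- setNames(rnorm(15), tr$tip.label)
  y <- 1.5 - 2 * x
  fit <- pgls_fit(y, x, tr, lambda = 1)
  expect_equal(unname(fit$beta), c(1.5, -2), tolerance = 1e-9)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
})

test_that("fixed-lambda PGLS agrees with the GLS reference implementation", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule_tree(25, 1, seed = 13)
  d <- simulate_bm_traits(tr, matrix(c(1, 0.5, 0.5, 1), 2), seed = 14)
  for (lam in c(0.3, 1)) {
    fit <- pgls_fit(trait_vec(d, "y"), trait_vec(d, "x"), tr, lambda = lam)
    df <- data.frame(y = d$y, x = d$x, species = d$species)
    ref <- nlme::gls(y ~ x, data = df,
                     correlation = ape::corPagel(lam, tr, fixed = TRUE,
                                                 form = ~species),
                     method = "ML")
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(ref$varBeta))), tolerance = 1e-4)
  }
})

test_that("lambda ML lands on boundary optima exactly", {
  tr <- simulate_yule_tree(60, 1, seed = 21)
  d1 <- simulate_bm_traits(tr, diag(2), lambda_true = 1, seed = 22)
  f1 <- pgls_fit(trait_vec(d1, "y"), trait_vec(d1, "x"), tr)
  expect_true(f1$lambda_hat %in% c(0, 1) || abs(f1$lambda_hat - 1) < 0.2)
  d0 <- simulate_bm_traits(tr, diag(2), lambda_true = 0, seed = 23)
  f0 <- pgls_fit(trait_vec(d0, "y"), trait_vec(d0, "x"), tr)
  expect_lt(f0$lambda_hat, 0.2)
})

test_that("bm_loglik equals the dense Kronecker MVN oracle", {
  for (seed in 1:6) {
    tr <- simulate_yule_tree(sample(3:6, 1), 1, seed = seed)
    S <- length(tr$tip.label)
    Sigma <- rand_pd(2, seed + 100)
    set.seed(seed + 200)
    traits <- matrix(rnorm(2 * S), 2, S, dimnames = list(NULL, tr$tip.label))
    root <- rnorm(2)
    ll <- bm_loglik(traits, tr, Sigma, root)
    C <- brute_bm_cov(tr)[tr$tip.label, tr$tip.label]
    # vec of the 2 x S matrix stacks columns: covariance is C (x) Sigma
    V <- kronecker(C, Sigma)
    oracle <- dmvnorm_log(as.numeric(traits), rep(root, S), V)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
  expect_error(bm_loglik(matrix(0, 2, 3, dimnames = list(NULL, c("A", "B", "C"))),
                         read_newick_tree("((A:1,B:1):1,C:2);"),
                         matrix(c(1, 2, 2, 1), 2), c(0, 0)), "positive definite")
})

test_that("traits equal to the root state maximize the likelihood over roots", {
  tr <- read_newick_tree("((A:1,B:1):1,C:2);")
  traits <- matrix(1.7, 2, 3, dimnames = list(NULL, c("A", "B", "C")))
  at_root <- bm_loglik(traits, tr, diag(2), c(1.7, 1.7))
  expect_gt(at_root, bm_loglik(traits, tr, diag(2), c(2.7, 1.7)))
  expect_gt(at_root, bm_loglik(traits, tr, diag(2), c(1.7, 0.7)))
})

test_that("the Metropolis sampler agrees with the exact conjugate posterior", {
  tr <- simulate_yule_tree(40, 1, seed = 31)
  d <- simulate_bm_traits(tr, matrix(c(1, 0.6, 0.6, 1), 2), seed = 32)
  m <- trait_mat(d)
  mh <- bayes_bm_correlation(m, tr, cycles = 20000, seed = 33)
  ex <- bm_correlation_exact(m, tr, n_draws = 20000, seed = 34)
  expect_lt(abs(mh$r_mean - ex$r_mean), 0.03)
  expect_lt(abs(mh$pp - ex$pp), 0.05)
  expect_gte(min(mh$ess), 300)
})

test_that("posterior pp respects trait symmetry", {
  tr <- simulate_yule_tree(40, 1, seed = 41)
  d <- simulate_bm_traits(tr, matrix(c(1, 0.4, 0.4, 1), 2), seed = 42)
  m <- trait_mat(d)
  a <- bayes_bm_correlation(m, tr, cycles = 15000, seed = 43)
  # swapping which trait is x and which is y leaves the correlation alone
  b <- bayes_bm_correlation(m[c(2, 1), ], tr, cycles = 15000, seed = 43)
  expect_lt(abs(a$pp - b$pp), 0.05)
  expect_lt(abs(a$r_mean - b$r_mean), 0.05)
  # flipping the sign of one trait maps pp to 1 - pp
  mneg <- m; mneg[2, ] <- -mneg[2, ]
  cpost <- bayes_bm_correlation(mneg, tr, cycles = 15000, seed = 43)
  expect_lt(abs(cpost$pp - (1 - a$pp)), 0.05)
  expect_lt(abs(cpost$r_mean + a$r_mean), 0.05)
})

test_that("non-convergent chains refuse to report and attach their trace", {
  tr <- simulate_yule_tree(20, 1, seed = 51)
  d <- simulate_bm_traits(tr, diag(2), seed = 52)
  err <- tryCatch(
    bayes_bm_correlation(trait_mat(d), tr, cycles = 300, burn_in = 100,
                         seed = 53, ess_floor = 5000),
    error = function(e) e)
  expect_match(conditionMessage(err), "ESS")
  expect_s3_class(err$diagnostics, "bm_posterior")
})

test_that("a duplicated trait concentrates the posterior correlation near 1", {
  tr <- simulate_yule_tree(40, 1, seed = 61)
  d <- simulate_bm_traits(tr, diag(2), seed = 62)
  m <- trait_mat(d)
  set.seed(63)
  m[2, ] <- m[1, ] + rnorm(ncol(m), sd = 0.01)  # jittered copy
  post <- bayes_bm_correlation(m, tr, cycles = 40000, seed = 64)
  expect_gt(post$r_mean, 0.95)
  expect_equal(post$pp, 1)
})
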