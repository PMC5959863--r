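#' Spearman rank correlation with exact, Monte Carlo or asymptotic p-values
#'
#' The coefficient is the Pearson correlation of mid-ranks, which is the
#' tie-corrected form of Spearman's rho; for tie-free data it coincides with
#' the classical `1 - 6*sum(d^2)/(n*(n^2-1))`. The two-sided p-value is
#' computed by full enumeration of all `n!` permutations when
#' `n <= exact_threshold`, by seeded Monte Carlo permutation (`mc_draws`
#' draws, add-one estimator) when `exact_threshold < n <= mc_threshold`, and
#' otherwise by the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length. Pairs with a missing value in
#'   either vector are deleted.
#' @param exact_threshold Largest n for full permutation enumeration
#'   (default 8, i.e. at most 40320 permutations).
#' @param mc_threshold Largest n for Monte Carlo permutation.
#' @param mc_draws Number of Monte Carlo permutations.
#' @param seed Seed for the Monte Carlo permutations (ignored by the other
#'   two methods). The global RNG state is left untouched.
#' @return A list of class `spearman_cor`: `n`, `rho`, `p_value`,
#'   `p_method` (one of `"exact-permutation"`, `"mc-permutation"`,
#'   `"t-approximation"`) and `tie_note` (`TRUE` when either vector has
#'   ties).
#' @examples
#' spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_cor <- function(x, y, exact_threshold = 8L, mc_threshold = 12L,
                         mc_draws = 1e5L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tie_note <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L

  if (n <= exact_threshold) {
    perms <- perm_matrix(n)
    rho_perm <- perm_rho(perms, rx, ry)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else if (n <= mc_threshold) {
    rho_perm <- with_seed(seed, {
      vapply(seq_len(mc_draws),
             function(i) stats::cor(rx[sample.int(n)], ry), numeric(1))
    })
    p <- (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (mc_draws + 1)
    method <- "mc-permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
    method <- "t-approximation"
  }
  structure(list(n = n, rho = rho, p_value = p, p_method = method,
                 tie_note = tie_note),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %.4g (%s, n = %d%s)\n",
              x$rho, x$p_value, x$p_method, x$n,
              if (x$tie_note) ", ties present" else ""))
  invisible(x)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9 in practice).
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# Pearson correlation of (rx[perm], ry) for every row of a permutation
# matrix, vectorized through a single matrix product.
perm_rho <- function(perms, rx, ry) {
  n <- length(rx)
  R <- matrix(rx[perms], nrow(perms), n)
  sxy <- as.numeric(R %*% ry) - n * mean(rx) * mean(ry)
  denom <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  sxy / denom
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Rank correlations between Q/A ratios and traits across groups
#'
#' Runs [spearman_cor()] of the Q/A ratio against each requested trait
#' within each group of a combined dataset, mirroring the analysed-together /
#' analysed-separately design (all bats; all primates pooled; New World and
#' Old World monkeys separately).
#'
#' @param data Data.frame containing `qa_ratio`, the trait columns and the
#'   grouping columns (as produced by [load_qa_palate_data()]).
#' @param traits Trait column names to correlate against `qa_ratio`.
#' @param groups Named list of logical row filters, or `NULL` for the
#'   default bats / primates / NWM / OWM split based on `group` and
#'   `subgroup` columns.
#' @param ... Passed to [spearman_cor()].
#' @return Data.frame with columns `group`, `trait`, `n`, `rho`, `p`,
#'   `method`.
#' @export
qa_trait_correlations <- function(data,
                                  traits = c("palate_length_gm",
                                             "palate_width_gm",
                                             "zygomatic_gm"),
                                  groups = NULL, ...) {
  if (is.null(groups)) {
    groups <- list(bats = data$group == "bats",
                   primates = data$group == "primates",
                   NWM = data$subgroup == "NWM",
                   OWM = data$subgroup == "OWM")
  }
  rows <- list()
  for (g in names(groups)) {
    d <- data[groups[[g]], , drop = FALSE]
    for (tr in traits) {
      r <- spearman_cor(d$qa_ratio, d[[tr]], ...)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, trait = tr, n = r$n, rho = r$rho, p = r$p_value,
        method = r$p_method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
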