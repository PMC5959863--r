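#' Eigenvalue coefficient of variation (integration magnitude)
#'
#' The magnitude of morphological integration of a phenotypic covariance or
#' correlation matrix: the standard deviation of its eigenvalues divided by
#' their mean. Equal eigenvalues (no integration) give 0; a single dominant
#' axis gives large values. Depends on the spectrum only, so it is invariant
#' to rotation of the trait space. The population standard deviation
#' (divisor p) is the default convention; the sample convention (divisor
#' p - 1) is available by flag.
#'
#' @param M Symmetric positive semi-definite p x p matrix (p >= 2).
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @return The coefficient of variation of the eigenvalues (>= 0).
#' @examples
#' icv(diag(5))                      # 0
#' icv(matrix(1, 4, 4))              # sqrt(3)
#' @export
icv <- function(M, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  ev <- check_phen_matrix(M)
  m <- mean(ev)
  if (m <= 0) stop("matrix has zero mean eigenvalue")
  p <- length(ev)
  s2 <- sum((ev - m)^2) / if (sd_convention == "population") p else p - 1
  sqrt(s2) / m
}

check_phen_matrix <- function(M, tol = 1e-10) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), nrow(M) >= 2L)
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop("matrix is not symmetric")
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("matrix is not positive semi-definite")
  pmax(ev, 0)
}

# Random unit-norm selection gradients, p x n, column-normalized draws from
# the uniform distribution on the sphere. The draw protocol (set.seed(seed);
# matrix(rnorm(p * n), p, n); normalize columns) is part of the contract so
# a run is exactly reproducible.
random_skewers <- function(p, n_skewers, seed) {
  with_seed(seed, {
    B <- matrix(stats::rnorm(p * n_skewers), p, n_skewers)
    sweep(B, 2, sqrt(colSums(B^2)), "/")
  })
}

#' Evolutionary flexibility by random skewers
#'
#' Mean cosine between random unit-norm selection gradients `beta` (uniform
#' on the sphere, seeded) and the evolutionary response `M %*% beta`. A
#' matrix proportional to the identity responds exactly along every
#' gradient (flexibility 1); strong integration deflects responses toward
#' the main axis of variation and lowers the index. Invariant to scaling of
#' `M` since the response enters only through its direction.
#'
#' @param M Symmetric PSD phenotypic matrix.
#' @param n_skewers Number of random gradients (>= 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return Mean cosine, in `(0, 1]` for PSD matrices.
#' @export
random_skewers_flexibility <- function(M, n_skewers = 1000L, seed = 1L) {
  check_phen_matrix(M)
  if (n_skewers < 100L) stop("n_skewers must be >= 100")
  if (sum(abs(M)) == 0) stop("null matrix has no evolutionary response")
  B <- random_skewers(nrow(M), n_skewers, seed)
  Z <- M %*% B
  nz <- sqrt(colSums(Z^2))
  if (any(nz == 0)) stop("zero response to a selection gradient; matrix is rank 0 in sampled directions")
  mean(colSums(B * Z) / nz)
}

#' Evolutionary constraints by random skewers
#'
#' Mean absolute cosine between the response `M %*% beta` to random unit
#' selection gradients and the matrix's leading eigenvector (the line of
#' least resistance). A rank-1 matrix funnels every response along its
#' single axis (constraints 1); an identity matrix leaves responses
#' uniformly distributed, giving the expected |cosine| between independent
#' random directions in dimension p. The absolute value is used because the
#' eigenvector sign is arbitrary.
#'
#' @inheritParams random_skewers_flexibility
#' @return Mean absolute cosine, in `[0, 1]`.
#' @export
constraints_index <- function(M, n_skewers = 1000L, seed = 1L) {
  check_phen_matrix(M)
  if (n_skewers < 100L) stop("n_skewers must be >= 100")
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (length(eg$values) > 1 &&
      eg$values[1] - eg$values[2] < 1e-8 * max(eg$values[1], 1))
    warning("leading eigenvalue is not simple; constraints index is ill-defined")
  e1 <- eg$vectors[, 1]
  B <- random_skewers(nrow(M), n_skewers, seed)
  Z <- M %*% B
  nz <- sqrt(colSums(Z^2))
  if (any(nz == 0)) stop("zero response to a selection gradient")
  mean(abs(colSums(Z * e1)) / nz)
}

#' Integration indices for a set of species matrices
#'
#' Computes ICV, evolutionary flexibility and evolutionary constraints for
#' each species' phenotypic matrix, with the Monte Carlo settings recorded
#' per row. Correlation matrices are the recommended input kind for
#' cross-species comparability.
#'
#' @param matrices Named list of symmetric PSD matrices (names = species
#'   IDs), or a directory of square CSV files (one per species, header row
#'   of trait names).
#' @param n_skewers Number of random selection gradients.
#' @param seed RNG seed, shared across species.
#' @param sd_convention Passed to [icv()].
#' @return Data.frame: `species_id`, `icv`, `flexibility`, `constraints`,
#'   `p`, `n_skewers`, `seed`.
#' @export
integration_indices <- function(matrices, n_skewers = 1000L, seed = 1L,
                                sd_convention = "population") {
  if (is.character(matrices) && length(matrices) == 1L) {
    files <- list.files(matrices, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("no CSV matrices found in ", matrices)
    matrices <- lapply(files, read_phen_matrix)
    names(matrices) <- sub("\\.csv$", "", basename(files))
  }
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  rows <- lapply(names(matrices), function(id) {
    M <- matrices[[id]]
    data.frame(species_id = id,
               icv = icv(M, sd_convention),
               flexibility = random_skewers_flexibility(M, n_skewers, seed),
               constraints = constraints_index(M, n_skewers, seed),
               p = nrow(M), n_skewers = n_skewers, seed = seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a phenotypic matrix from a square CSV
#'
#' @param path CSV with a header row of trait names and one row per trait.
#' @return A numeric matrix with trait dimnames.
#' @export
read_phen_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(d)
  rownames(M) <- colnames(M)
  storage.mode(M) <- "double"
  M
}

#' Correlate integration indices with Q/A ratios
#'
#' Joins per-species integration indices with Q/A repeat calls and runs
#' [spearman_cor()] of each index against the Q/A ratio.
#'
#' @param indices Output of [integration_indices()].
#' @param qa Data.frame with `species_id` and `qa_ratio` (e.g. from
#'   [extract_qa()] or [load_qa_palate_data()]).
#' @param ... Passed to [spearman_cor()].
#' @return Data.frame with `index`, `n`, `rho`, `p`, `method`; the number
#'   of species lost in the join is attached as attribute `join_loss` and
#'   reported with a warning when non-zero.
#' @export
indices_vs_qa <- function(indices, qa, ...) {
  m <- merge(indices, qa[, c("species_id", "qa_ratio")], by = "species_id")
  loss <- nrow(indices) - nrow(m)
  if (loss > 0) warning(loss, " species lost in the join")
  rows <- lapply(c("icv", "flexibility", "constraints"), function(idx) {
    r <- spearman_cor(m[[idx]], m$qa_ratio, ...)
    data.frame(index = idx, n = r$n, rho = r$rho, p = r$p_value,
               method = r$p_method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "join_loss") <- loss
  out
}
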