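#' Simulate a Yule (pure-birth) tree
#'
#' Constant-rate pure-birth tree conditioned on `n_tips` extant species.
#' The interval during which k lineages exist is exponential with rate
#' `k * birth_rate`; the final interval (n lineages, until the next birth
#' would occur) is included, so every terminal branch is strictly positive
#' and the expected root-to-tip depth is `(1/birth_rate) * sum(1/k)` for
#' k = 2..n. The labelled topology is uniform over join orders. The result
#' is ultrametric and a pure function of `(n_tips, birth_rate, seed)`.
#'
#' @param n_tips Number of tips (>= 3). Tips are labelled `s1..sn`.
#' @param birth_rate Speciation rate per lineage per unit time.
#' @param seed RNG seed.
#' @return An ultrametric `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 3L) stop("n_tips must be >= 3")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  with_seed(seed, {
    # node heights above the present: most recent join first
    waits <- stats::rexp(n_tips - 1L, rate = birth_rate * seq(n_tips, 2L))
    heights <- cumsum(waits)
    labs <- paste0("s", seq_len(n_tips))
    str <- labs
    h <- rep(0, n_tips)
    for (i in seq_len(n_tips - 1L)) {
      pair <- sample.int(length(str), 2L)
      hn <- heights[i]
      merged <- sprintf("(%s:%.10g,%s:%.10g)",
                        str[pair[1]], hn - h[pair[1]],
                        str[pair[2]], hn - h[pair[2]])
      str <- c(str[-pair], merged)
      h <- c(h[-pair], hn)
    }
    ape::read.tree(text = paste0(str, ";"))
  })
}

#' Simulate bivariate Brownian traits on a tree
#'
#' Draws two traits from the matrix normal implied by a lambda-scaled
#' Brownian model: between-trait covariance `sigma` (the 2 x 2 rate matrix)
#' and between-species covariance equal to the lambda-transformed tree
#' covariance. The generating parameters, including the true evolutionary
#' correlation `r = sigma[1,2]/sqrt(sigma[1,1]*sigma[2,2])`, travel with
#' the data as the `"manifest"` attribute.
#'
#' @param tree A `phylo` object.
#' @param sigma 2 x 2 positive-definite Brownian rate covariance.
#' @param root_state Numeric 2-vector of root values.
#' @param lambda_true Pagel's lambda used to scale the tree covariance.
#' @param seed RNG seed.
#' @return Data.frame with `species`, `x`, `y`; attribute `manifest` holds
#'   the generating parameters.
#' @export
simulate_bm_traits <- function(tree, sigma, root_state = c(0, 0),
                               lambda_true = 1, seed = 1L) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == 2L))
  Ls <- tryCatch(t(chol(sigma)), error = function(e) stop("sigma must be positive definite"))
  tree <- validate_phylogeny(tree)
  C <- lambda_transform(bm_covariance(tree), lambda_true)
  Rc <- chol(C)
  S <- ncol(C)
  X <- with_seed(seed, {
    Z <- matrix(stats::rnorm(2L * S), 2L, S)
    root_state + Ls %*% Z %*% Rc
  })
  out <- data.frame(species = colnames(C), x = X[1, ], y = X[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "manifest") <- list(
    sigma = sigma, root_state = root_state, lambda_true = lambda_true,
    true_r = sigma[1, 2] / sqrt(sigma[1, 1] * sigma[2, 2]), seed = seed)
  out
}

#' Simulate specimen measurements with a known covariance structure
#'
#' Multivariate-normal specimen samples from a single-species factor model:
#' generating covariance `loadings %*% t(loadings) + noise_sd^2 * I`. Large
#' loadings along one axis produce a near-rank-1, strongly integrated
#' matrix; zero loadings give an identity-proportional (unintegrated)
#' matrix. Non-positive measurements are resampled (not clipped, preserving
#' the multivariate-normal shape) up to 100 attempts per specimen. The
#' exact generating matrix is returned so the integration indices have
#' known targets.
#'
#' @param factor_loadings Numeric p-vector of factor loadings (p = 5 for the
#'   standard craniofacial measurement set).
#' @param specimen_n Number of specimens.
#' @param seed RNG seed.
#' @param trait_means Mean vector (mm); defaults to 20 for every trait.
#' @param noise_sd Residual standard deviation per trait.
#' @param species_id Species label for the records.
#' @return List with `records` (a measurement data.frame compatible with
#'   [standardize_specimens()] when p = 5) and `true_matrix`.
#' @export
simulate_specimens <- function(factor_loadings, specimen_n, seed = 1L,
                               trait_means = NULL, noise_sd = 1,
                               species_id = "sp1") {
  p <- length(factor_loadings)
  stopifnot(p >= 2L, specimen_n >= 2L, noise_sd > 0)
  if (is.null(trait_means)) trait_means <- rep(20, p)
  stopifnot(length(trait_means) == p, all(trait_means > 0))
  M <- tcrossprod(factor_loadings) + noise_sd^2 * diag(p)
  L <- t(chol(M))
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, specimen_n, p)
    for (i in seq_len(specimen_n)) {
      for (attempt in seq_len(100L)) {
        v <- trait_means + as.numeric(L %*% stats::rnorm(p))
        if (all(v > 0)) break
        if (attempt == 100L) stop("could not draw positive measurements in 100 attempts")
      }
      out[i, ] <- v
    }
    out
  })
  cols <- if (p == 5L) measurement_cols else paste0("trait", seq_len(p))
  records <- data.frame(specimen_id = paste0(species_id, "_", seq_len(specimen_n)),
                        species_id = species_id, draws, adult = TRUE,
                        stringsAsFactors = FALSE)
  names(records)[2L + seq_len(p)] <- cols
  list(records = records, true_matrix = M,
       manifest = list(factor_loadings = factor_loadings,
                       specimen_n = specimen_n, noise_sd = noise_sd,
                       trait_means = trait_means, seed = seed))
}

# Fixed reverse codon table (one codon per residue) for back-translation of
# non-repeat residues; Q and A use seeded synonymous-codon choice.
rev_codon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAG", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

#' Synthesize repeat-bearing RUNX2-like sequences
#'
#' Builds `5' anchor + polyQ + linker + polyA + 3' anchor` amino-acid
#' sequences (optionally with flanking padding) for a table of specified
#' (Q, A) counts — the ground truth for round-trip tests of the extraction
#' pipeline. Nucleotide mode back-translates the protein: glutamines use a
#' seeded choice of CAG/CAA, alanines a seeded GCN codon, and all other
#' residues a fixed codon table.
#'
#' @param repeat_specs Data.frame with columns `species_id`, `q`, `a`
#'   (counts, each at least `cfg$min_run_length`).
#' @param cfg A [repeat_config()] supplying the anchors.
#' @param as_nucleotide Return a `DNAStringSet` of coding sequences instead
#'   of an `AAStringSet`.
#' @param linker Residues inserted between the polyQ and polyA tracts
#'   (default none, matching the adjacent tracts of the real protein).
#' @param pad Residues added outside the anchors (domain location must be
#'   invariant to them).
#' @param seed Seed for the synonymous-codon choices.
#' @return An `AAStringSet` or `DNAStringSet` named by `species_id`.
#' @export
synthesize_runx2_sequences <- function(repeat_specs, cfg = repeat_config(),
                                       as_nucleotide = FALSE, linker = "",
                                       pad = "MS", seed = 1L) {
  stopifnot(is.data.frame(repeat_specs),
            all(c("species_id", "q", "a") %in% names(repeat_specs)))
  if (any(repeat_specs$q < cfg$min_run_length) ||
      any(repeat_specs$a < cfg$min_run_length))
    stop("Q and A counts must be at least min_run_length")
  for (s in c(linker, pad)) {
    if (nzchar(s) && grepl("[QA]", toupper(s)))
      stop("linker and pad must not contain Q or A residues")
  }
  aa <- vapply(seq_len(nrow(repeat_specs)), function(i) {
    paste0(pad, cfg$five_prime_anchor,
           strrep("Q", repeat_specs$q[i]), linker,
           strrep("A", repeat_specs$a[i]),
           cfg$three_prime_anchor, pad)
  }, character(1))
  names(aa) <- repeat_specs$species_id
  if (!as_nucleotide) return(Biostrings::AAStringSet(aa))
  nt <- with_seed(seed, vapply(aa, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    codons <- vapply(res, function(r) {
      if (r == "Q") sample(c("CAG", "CAA"), 1L)
      else if (r == "A") paste0("GC", sample(c("A", "C", "G", "T"), 1L))
      else rev_codon[[r]]
    }, character(1))
    paste(codons, collapse = "")
  }, character(1)))
  Biostrings::DNAStringSet(nt)
}
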