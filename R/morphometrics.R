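#' Geometric mean
#'
#' Computed as the exponential of the mean natural log, which is numerically
#' stable for measurement-scale values.
#'
#' @param values Numeric vector of strictly positive values.
#' @return The geometric mean.
#' @examples
#' geometric_mean(c(2, 8))  # 4
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0L) stop("values must be non-empty")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be finite and strictly positive")
  exp(mean(log(values)))
}

measurement_cols <- c("palate_length", "palate_width", "skull_length",
                      "skull_width", "zygomatic_breadth")

#' Size-correct craniofacial measurements by the specimen geometric mean
#'
#' Each specimen's palate length, palate width and zygomatic breadth are
#' divided by the geometric mean (GM) of its five linear measurements
#' (palate length, palate width, skull length, skull width, zygomatic
#' breadth), removing isometric size. The divisor is fixed to exactly those
#' five measurements. Only adult specimens (fused basisphenoid-basioccipital
#' joint) are retained; non-adult rows are dropped with a message, not an
#' error. The arithmetic-mean/geometric-mean inequality is asserted on every
#' record as an internal sanity check.
#'
#' @param records Data.frame with columns `species_id`, the five measurement
#'   columns (`palate_length`, `palate_width`, `skull_length`, `skull_width`,
#'   `zygomatic_breadth`, all in mm, strictly positive), optionally
#'   `specimen_id` and logical `adult` (assumed `TRUE` when absent).
#' @return Data.frame with `specimen_id`, `species_id`, `gm` (mm) and the
#'   dimensionless ratios `palate_length_gm`, `palate_width_gm`,
#'   `zygomatic_gm`.
#' @export
standardize_specimens <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c("species_id", measurement_cols), names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(records$adult)) records$adult <- TRUE
  if (is.null(records$specimen_id))
    records$specimen_id <- paste0(records$species_id, "_", seq_len(nrow(records)))
  n_excluded <- sum(!records$adult)
  if (n_excluded > 0)
    message(n_excluded, " non-adult specimen(s) excluded")
  records <- records[records$adult, , drop = FALSE]
  if (nrow(records) == 0L) stop("no adult specimens to standardize")
  m <- as.matrix(records[, measurement_cols])
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all five measurements must be finite and strictly positive")
  gm <- exp(rowMeans(log(m)))
  stopifnot(all(gm <= rowMeans(m) + 1e-12))  # AM-GM
  data.frame(specimen_id = records$specimen_id,
             species_id = records$species_id,
             gm = gm,
             palate_length_gm = records$palate_length / gm,
             palate_width_gm = records$palate_width / gm,
             zygomatic_gm = records$zygomatic_breadth / gm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate standardized traits to species means
#'
#' Unweighted arithmetic mean of the GM-standardized traits over the adult
#' specimens of each species, with the specimen count reported.
#'
#' @param standardized Output of [standardize_specimens()].
#' @return Data.frame with one row per species: `species_id`, `n`, `gm` and
#'   the three mean standardized traits.
#' @export
species_means <- function(standardized) {
  stopifnot(is.data.frame(standardized), nrow(standardized) >= 1L)
  cols <- c("gm", "palate_length_gm", "palate_width_gm", "zygomatic_gm")
  sp <- split(standardized, standardized$species_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(species_id = d$species_id[1], n = nrow(d),
               as.list(colMeans(d[, cols])), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
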