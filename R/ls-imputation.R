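#' Reference haplotype panel
#'
#' Phased reference haplotypes over an ordered marker map, used as the
#' template set of the diploid Li-Stephens HMM. All haplotypes serve as
#' templates — no subsetting.
#'
#' @param haps Integer matrix `H x J` of alleles in `{0, 1}` (rows =
#'   haplotypes, columns = markers), without missing values.
#' @param positions Integer/numeric vector of strictly increasing base-pair
#'   positions, length `J`.
#' @param marker_ids Optional marker identifiers (default `m<j>`).
#' @param map Optional genetic map: data frame with columns `pos` (bp) and
#'   `cm`; if absent, a uniform rate is assumed when distances are needed.
#' @param rate_cm_per_mb Uniform rate used when `map` is `NULL` (cM/Mb).
#' @return An object of class `haplotype_panel` with elements `haps`,
#'   `positions`, `marker_ids`, `cm` (cumulative genetic position per
#'   marker), `n_haps`, `n_markers`.
#' @export
haplotype_panel <- function(haps, positions, marker_ids = NULL, map = NULL,
                            rate_cm_per_mb = 1) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (any(is.na(haps)) || any(!haps %in% 0:1)) {
    stop("panel haplotypes must be complete alleles in {0, 1}", call. = FALSE)
  }
  J <- ncol(haps)
  positions <- as.numeric(positions)
  if (length(positions) != J) stop("`positions` must match the marker count", call. = FALSE)
  if (J > 1 && any(diff(positions) <= 0)) {
    stop("marker positions must be strictly increasing", call. = FALSE)
  }
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(J))
  cm <- interpolate_genetic_map(positions, map = map, rate_cm_per_mb = rate_cm_per_mb)
  structure(
    list(haps = haps, positions = positions, marker_ids = as.character(marker_ids),
         cm = cm, n_haps = nrow(haps), n_markers = J),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", x$n_haps, "haplotypes x", x$n_markers, "markers\n")
  cat("  genetic length:", round(max(x$cm) - min(x$cm), 3), "cM\n")
  invisible(x)
}

#' Interpolate genetic map positions
#'
#' Linear interpolation of cM coordinates at the given bp positions within
#' the map range; outside the range, constant-rate extrapolation using the
#' slope of the nearest map interval. With no map, a uniform rate (default
#' 1 cM/Mb) is applied.
#'
#' @param positions Sorted bp positions.
#' @param map Data frame with columns `pos` (bp) and `cm`, or `NULL`.
#' @param rate_cm_per_mb Uniform rate when `map` is `NULL`.
#' @return Numeric vector of cM coordinates, one per position.
#' @examples
#' interpolate_genetic_map(c(0, 5e5, 1e6), map = data.frame(pos = c(0, 1e6), cm = c(1, 3)))
#' @export
interpolate_genetic_map <- function(positions, map = NULL, rate_cm_per_mb = 1) {
  positions <- as.numeric(positions)
  if (is.unsorted(positions, strictly = FALSE)) {
    stop("`positions` must be sorted in increasing order", call. = FALSE)
  }
  if (is.null(map)) {
    return(positions * rate_cm_per_mb / 1e6)
  }
  stopifnot(all(c("pos", "cm") %in% names(map)))
  map <- map[order(map$pos), ]
  if (nrow(map) < 2L) stop("genetic map needs at least two knots", call. = FALSE)
  out <- stats::approx(map$pos, map$cm, xout = positions, rule = 2)$y
  # constant-rate extrapolation beyond the map using the edge interval slopes
  lo <- positions < map$pos[1]
  hi <- positions > map$pos[nrow(map)]
  if (any(lo)) {
    slope <- (map$cm[2] - map$cm[1]) / (map$pos[2] - map$pos[1])
    out[lo] <- map$cm[1] + (positions[lo] - map$pos[1]) * slope
  }
  if (any(hi)) {
    n <- nrow(map)
    slope <- (map$cm[n] - map$cm[n - 1]) / (map$pos[n] - map$pos[n - 1])
    out[hi] <- map$cm[n] + (positions[hi] - map$pos[n]) * slope
  }
  out
}

#' HMM parameters for Li-Stephens imputation
#'
#' @param recomb_scale Population-scaled recombination factor `rho` (an
#'   effective-population-size surrogate, roughly `4 * Ne`); the per-interval
#'   template switch probability is
#'   `theta_j = 1 - exp(-rho * d_j / H)` with `d_j` the interval's genetic
#'   distance in Morgans and `H` the number of template haplotypes.
#' @param err Allele miscopy (emission error) rate `epsilon`, in (0, 0.5).
#' @param gl_floor log10 floor applied to input genotype likelihoods.
#' @param min_prob Internal cutoff for close-to-zero probabilities.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(recomb_scale = 4e4, err = 1e-4, gl_floor = -5,
                       min_prob = 1e-15) {
  stopifnot(recomb_scale > 0, err > 0, err < 0.5, gl_floor < 0, min_prob > 0)
  structure(list(recomb_scale = recomb_scale, err = err, gl_floor = gl_floor,
                 min_prob = min_prob),
            class = "hmm_params")
}

switch_probs <- function(panel, params) {
  if (panel$n_markers < 2L) return(numeric(0))
  d_morgan <- diff(panel$cm) / 100
  theta <- 1 - exp(-params$recomb_scale * d_morgan / panel$n_haps)
  pmin(pmax(theta, 1e-12), 1 - 1e-9)
}

#' Impute one sample with the GL-aware diploid Li-Stephens HMM
#'
#' Runs a single forward-backward pass over hidden states formed by ordered
#' pairs of template haplotypes, using **all** panel haplotypes as templates.
#' Transitions follow the Li-Stephens switch process driven by per-interval
#' genetic distance; the emission at each marker integrates the sample's
#' genotype likelihoods over the allele-miscopy model. Unassayed markers are
#' expressed as uniform GLs, so a single pass simultaneously phases assayed
#' markers and imputes missing ones.
#'
#' @param gl Numeric matrix `J x 3` of log10 genotype likelihoods aligned
#'   with the panel's marker order (use uniform rows for unassayed markers),
#'   or a data frame with columns `l0`, `l1`, `l2`.
#' @param panel A [haplotype_panel()].
#' @param params An [hmm_params()].
#' @return A tibble with one row per marker: `marker_id`, `pos`, `p0`, `p1`,
#'   `p2` (posterior genotype probabilities) and `gt` (best-guess genotype).
#' @export
impute_sample <- function(gl, panel, params = hmm_params()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.data.frame(gl)) gl <- as.matrix(gl[, c("l0", "l1", "l2")])
  gl <- as.matrix(gl)
  if (nrow(gl) != panel$n_markers || ncol(gl) != 3L) {
    stop("genotype likelihoods do not align with the panel marker set (need ",
         panel$n_markers, " x 3)", call. = FALSE)
  }
  if (any(is.na(gl))) stop("genotype likelihoods must not contain NA", call. = FALSE)
  gl[gl < params$gl_floor] <- params$gl_floor
  lik <- 10^gl
  theta <- switch_probs(panel, params)
  post <- .ls_forward_backward(panel$haps, lik, theta, params$err, params$min_prob)
  post <- post / rowSums(post)
  tibble::tibble(
    marker_id = panel$marker_ids,
    pos = panel$positions,
    p0 = post[, 1], p1 = post[, 2], p2 = post[, 3],
    gt = best_guess(post)
  )
}

#' Impute a study cohort sample-wise
#'
#' Each sample is phased and imputed independently with [impute_sample()]
#' (results do not depend on cohort order or composition).
#'
#' @param gl_tbl Long tibble of study genotype likelihoods with columns
#'   `sample_id`, `marker_id`, `l0`, `l1`, `l2`. Markers absent for a sample
#'   get uniform likelihoods.
#' @param panel A [haplotype_panel()].
#' @param params An [hmm_params()].
#' @param samples Optional subset of sample ids to impute (default all).
#' @return A long tibble with `sample_id`, `marker_id`, `pos`, `p0`, `p1`,
#'   `p2`, `gt`.
#' @export
impute_cohort <- function(gl_tbl, panel, params = hmm_params(), samples = NULL) {
  stopifnot(all(c("sample_id", "marker_id", "l0", "l1", "l2") %in% names(gl_tbl)))
  ids <- if (is.null(samples)) unique(gl_tbl$sample_id) else samples
  unknown <- setdiff(gl_tbl$marker_id, panel$marker_ids)
  if (length(unknown) > 0) {
    stop("study markers absent from the panel: ",
         paste(utils::head(unknown, 3), collapse = ", "),
         if (length(unknown) > 3) ", ...", call. = FALSE)
  }
  uniform <- log10(1 / 3)
  res <- lapply(ids, function(sid) {
    sub <- gl_tbl[gl_tbl$sample_id == sid, ]
    gl <- matrix(uniform, panel$n_markers, 3L)
    idx <- match(sub$marker_id, panel$marker_ids)
    gl[idx, ] <- as.matrix(sub[, c("l0", "l1", "l2")])
    out <- impute_sample(gl, panel, params)
    out$sample_id <- sid
    out
  })
  dplyr::bind_rows(res)[, c("sample_id", "marker_id", "pos", "p0", "p1", "p2", "gt")]
}
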