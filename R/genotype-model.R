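#' Genotype representations
#'
#' A diploid biallelic SNP genotype is handled in three equivalent
#' representations throughout the package:
#'
#' * **G** — an integer in `{-1, 0, 1, 2}`: `-1` missing, `0` homozygous for
#'   the reference (REF) allele, `1` heterozygous, `2` homozygous for the
#'   alternate (ALT) allele.
#' * **GP** — a probability simplex `(p0, p1, p2)` over the three zygosity
#'   categories.
#' * **GL** — `log10`-scaled genotype probabilities `(l0, l1, l2)`, floored at
#'   a configurable cutoff so that impossible genotypes never reach exactly
#'   `-Inf`.
#'
#' Internally the uniform (missing) GP is kept as exact thirds; the familiar
#' printed triple `(-0.481, -0.481, -0.481)` only appears when GLs are
#' serialized at 3 decimals.
#'
#' @name genotype-representations
NULL

GT_VALUES <- c(-1L, 0L, 1L, 2L)

#' Convert integer genotypes to genotype probabilities
#'
#' Determined genotypes map to one-hot simplices; missing genotypes (`-1`)
#' map to the uniform simplex `(1/3, 1/3, 1/3)`.
#'
#' @param g Integer vector of genotypes in `{-1, 0, 1, 2}`.
#' @return A numeric matrix with `length(g)` rows and columns `p0`, `p1`, `p2`.
#' @examples
#' gt_to_gp(c(0L, 1L, 2L, -1L))
#' @export
gt_to_gp <- function(g) {
  g <- as.integer(g)
  bad <- !g %in% GT_VALUES
  if (any(bad)) {
    stop("invalid genotype value(s): ", paste(unique(g[bad]), collapse = ", "),
         " (must be in {-1, 0, 1, 2})", call. = FALSE)
  }
  gp <- matrix(0, nrow = length(g), ncol = 3L,
               dimnames = list(NULL, c("p0", "p1", "p2")))
  for (k in 0:2) gp[g == k, k + 1L] <- 1
  gp[g == -1L, ] <- 1 / 3
  gp
}

#' Convert genotype probabilities to floored log10 likelihoods
#'
#' Componentwise `log10`, with components below `10^floor_log10` replaced by
#' `floor_log10`. The default floor of `-5` matches the evaluation cutoff used
#' for near-zero probabilities.
#'
#' @param gp Numeric matrix (n x 3) of genotype probabilities, or a length-3
#'   vector.
#' @param floor_log10 Negative scalar; log10 floor for small probabilities.
#' @return Numeric matrix (n x 3) with columns `l0`, `l1`, `l2`, all `<= 0`.
#' @examples
#' round(gp_to_gl(c(1 / 3, 1 / 3, 1 / 3)), 3)
#' @export
gp_to_gl <- function(gp, floor_log10 = -5) {
  # accept 2-decimal rounded simplices such as (0.33, 0.33, 0.33)
  gp <- as_gp_matrix(gp, sum_tol = 0.015)
  if (!is.numeric(floor_log10) || length(floor_log10) != 1L || floor_log10 >= 0) {
    stop("`floor_log10` must be a single negative number", call. = FALSE)
  }
  gl <- log10(pmax(gp, 10^floor_log10))
  gl[gl < floor_log10] <- floor_log10
  # log10(1) can come out as tiny positive fuzz; clamp
  gl[gl > 0] <- 0
  dimnames(gl) <- list(NULL, c("l0", "l1", "l2"))
  gl
}

#' Convert floored log10 likelihoods back to normalized probabilities
#'
#' @param gl Numeric matrix (n x 3) of log10 genotype likelihoods, or a
#'   length-3 vector.
#' @return Numeric matrix (n x 3) of normalized genotype probabilities.
#' @export
gl_to_gp <- function(gl) {
  gl <- as_gp_matrix(gl, check_simplex = FALSE)
  p <- 10^gl
  p <- p / rowSums(p)
  dimnames(p) <- list(NULL, c("p0", "p1", "p2"))
  p
}

#' Best-guess genotype from genotype probabilities
#'
#' Returns the arg-max genotype; ties are broken deterministically in favour of
#' the lowest genotype index, so repeated metric computations are reproducible.
#'
#' @param gp Numeric matrix (n x 3) of genotype probabilities, or a length-3
#'   vector.
#' @return Integer vector of genotypes in `{0, 1, 2}`.
#' @examples
#' best_guess(c(0.7, 0.28, 0.02))
#' @export
best_guess <- function(gp) {
  gp <- as_gp_matrix(gp)
  as.integer(max.col(gp, ties.method = "first") - 1L)
}

#' Allele dosage of a genotype
#'
#' @param g Integer genotype vector in `{0, 1, 2}` (missing not allowed).
#' @return Numeric vector of ALT-allele dosages, equal to `g`.
#' @keywords internal
gt_dosage <- function(g) {
  g <- as.integer(g)
  if (any(!g %in% 0:2)) stop("dosage requires determined genotypes in {0,1,2}", call. = FALSE)
  as.numeric(g)
}

# Coerce vector/matrix input to an n x 3 matrix, optionally validating that
# rows are probability simplices.
as_gp_matrix <- function(gp, check_simplex = TRUE, tol = 1e-9, sum_tol = 1e-6) {
  if (is.null(dim(gp))) {
    if (length(gp) %% 3L != 0L) stop("genotype probability input must have 3 components", call. = FALSE)
    gp <- matrix(gp, ncol = 3L, byrow = length(gp) == 3L)
  }
  gp <- as.matrix(gp)
  if (ncol(gp) != 3L) stop("genotype probability input must have 3 columns", call. = FALSE)
  storage.mode(gp) <- "double"
  if (check_simplex) {
    if (any(gp < -tol) || any(gp > 1 + tol)) {
      stop("invalid probability: components must lie in [0, 1]", call. = FALSE)
    }
    if (any(abs(rowSums(gp) - 1) > sum_tol)) {
      stop("invalid probability simplex: rows must sum to 1", call. = FALSE)
    }
  }
  gp
}

#' Half-call representation
#'
#' A half-call records one known allele of a diploid genotype, as produced by
#' pool decoding when a sample is known to carry at least one copy of an
#' allele: the VCF spellings are `./1` (carries ALT, genotype in `{1, 2}`) and
#' `0/.` (carries REF, genotype in `{0, 1}`).
#'
#' @param known_allele Character vector in `{"REF", "ALT", "none"}`.
#' @return A tibble with columns `known_allele` and the corresponding candidate
#'   genotype set (list-column `candidates`).
#' @export
half_call <- function(known_allele) {
  if (any(!known_allele %in% c("REF", "ALT", "none"))) {
    stop('`known_allele` must be "REF", "ALT" or "none"', call. = FALSE)
  }
  cand <- list(REF = c(0L, 1L), ALT = c(1L, 2L), none = c(0L, 1L, 2L))
  tibble::tibble(
    known_allele = known_allele,
    candidates = unname(cand[known_allele])
  )
}
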