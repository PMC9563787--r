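#' Genotype concordance with the half-mismatch rule
#'
#' Per-genotype discordance is `|dosage(true) - dosage(best-guess)| / 2`, so
#' a homozygote imputed as heterozygote (or conversely) counts as half a
#' mismatch and a homozygote imputed as the opposite homozygote as a full
#' mismatch. Concordance is `1 - mean(discordance)`.
#'
#' @param true_g Integer vector of true genotypes in `{0, 1, 2}`.
#' @param gp Numeric matrix `n x 3` of predicted genotype probabilities (or a
#'   vector of best-guess genotypes in `{0, 1, 2}`).
#' @param na_action `"error"` (default) fails on missing truth; `"drop"`
#'   excludes missing-truth entries and records how many were dropped
#'   (attribute `n_dropped`).
#' @return Concordance in `[0, 1]` (scalar), with attribute `n` (entries
#'   scored) and, for `"drop"`, `n_dropped`.
#' @examples
#' concordance(c(1L, 0L), rbind(c(0.7, 0.28, 0.02), c(1, 0, 0)))  # (1 - 0.25)
#' @export
concordance <- function(true_g, gp, na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  true_g <- as.integer(true_g)
  guess <- if (is.null(dim(gp)) && length(gp) == length(true_g) && all(gp %in% 0:2 | is.na(gp))) {
    as.integer(gp)
  } else {
    best_guess(gp)
  }
  if (length(guess) != length(true_g)) stop("series lengths differ", call. = FALSE)
  miss <- is.na(true_g) | true_g == -1L
  n_dropped <- 0L
  if (any(miss)) {
    if (na_action == "error") stop("missing true genotypes (use na_action = \"drop\")", call. = FALSE)
    true_g <- true_g[!miss]; guess <- guess[!miss]
    n_dropped <- sum(miss)
  }
  if (any(!true_g %in% 0:2)) stop("true genotypes must be determined (0, 1, 2)", call. = FALSE)
  disc <- abs(gt_dosage(true_g) - gt_dosage(guess)) / 2
  out <- 1 - mean(disc)
  attr(out, "n") <- length(true_g)
  if (na_action == "drop") attr(out, "n_dropped") <- n_dropped
  out
}

#' Cross-entropy of predicted genotype probabilities
#'
#' Mean (over individuals) negative natural log of the probability assigned
#' to the true genotype, with the predicted probability floored at `10^-5`
#' (so a confidently wrong prediction contributes at most `-log(10^-5)`).
#' Zero exactly when every true genotype has predicted probability 1.
#'
#' @inheritParams concordance
#' @param floor Probability floor (default `1e-5`).
#' @return Mean cross-entropy (scalar, natural-log units) with attribute `n`.
#' @examples
#' cross_entropy(1L, matrix(c(0.56, 0.42, 0.02), 1))  # -log(0.42)
#' @export
cross_entropy <- function(true_g, gp, floor = 1e-5, na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  true_g <- as.integer(true_g)
  gp <- as_gp_matrix(gp)
  if (nrow(gp) != length(true_g)) stop("series lengths differ", call. = FALSE)
  miss <- is.na(true_g) | true_g == -1L
  if (any(miss)) {
    if (na_action == "error") stop("missing true genotypes (use na_action = \"drop\")", call. = FALSE)
    gp <- gp[!miss, , drop = FALSE]; true_g <- true_g[!miss]
  }
  if (any(!true_g %in% 0:2)) stop("true genotypes must be determined (0, 1, 2)", call. = FALSE)
  p_true <- gp[cbind(seq_along(true_g), true_g + 1L)]
  p_true <- pmax(p_true, floor)
  out <- mean(-log(p_true))
  attr(out, "n") <- length(true_g)
  out
}

#' Per-marker accuracy metrics
#'
#' Computes concordance and cross-entropy marker by marker from a long table
#' of predictions against truth.
#'
#' @param data Long tibble with columns `marker_id`, `g_true`, `p0`, `p1`,
#'   `p2` (one row per sample x marker).
#' @return A tibble with one row per marker: `marker_id`, `n`, `concordance`,
#'   `cross_entropy`.
#' @export
marker_metrics <- function(data) {
  stopifnot(all(c("marker_id", "g_true", "p0", "p1", "p2") %in% names(data)))
  data |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      concordance = as.numeric(concordance(.data$g_true, cbind(.data$p0, .data$p1, .data$p2))),
      cross_entropy = as.numeric(cross_entropy(.data$g_true, cbind(.data$p0, .data$p1, .data$p2))),
      .groups = "drop"
    )
}

#' MAF-stratified metric summary
#'
#' Aggregates per-marker metric values into the minor-allele-frequency bins
#' `[0, 0.02, 0.04, 0.06, 0.1, 0.2, 0.4, 0.5]` (tighter towards rare
#' variants) and, optionally, computes a rolling mean over markers sorted by
#' ascending MAF with a symmetric window (`window` markers on each side,
#' truncated at the edges).
#'
#' @param metrics Tibble with one row per marker containing `marker_id`, a
#'   `maf` column in `[0, 0.5]`, and one or more numeric metric columns.
#' @param values Names of the metric columns to summarise (default: all
#'   numeric columns except `maf` and `n`).
#' @param window Half-width of the rolling window (markers on each side);
#'   `NULL` disables the rolling series.
#' @param boundaries Bin boundaries over the MAF range.
#' @return A list of class `maf_summary`: `bins` (tibble: `bin`, `maf_lo`,
#'   `maf_hi`, `n_markers`, one mean per metric) and `rolling` (tibble sorted
#'   by MAF with per-marker rolling means), plus attribute `window`.
#' @export
summarize_by_maf <- function(metrics, values = NULL, window = 500L,
                             boundaries = c(0, 0.02, 0.04, 0.06, 0.1, 0.2, 0.4, 0.5)) {
  stopifnot("maf" %in% names(metrics))
  if (any(metrics$maf < 0 | metrics$maf > 0.5)) {
    stop("MAF values must lie in [0, 0.5]", call. = FALSE)
  }
  if (is.null(values)) {
    values <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                      c("maf", "n", "pos"))
  }
  bin <- cut(metrics$maf, breaks = boundaries, include.lowest = TRUE, right = TRUE)
  bins <- metrics |>
    dplyr::mutate(.bin = bin) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      dplyr::across(dplyr::all_of(values), ~ mean(.x)),
      .groups = "drop"
    ) |>
    dplyr::rename(bin = ".bin") |>
    dplyr::mutate(
      maf_lo = boundaries[as.integer(.data$bin)],
      maf_hi = boundaries[as.integer(.data$bin) + 1L],
      .after = "bin"
    )
  rolling <- NULL
  if (!is.null(window)) {
    ord <- order(metrics$maf)
    sorted <- metrics[ord, ]
    n <- nrow(sorted)
    w <- as.integer(window)
    roll <- function(x) {
      cs <- cumsum(c(0, x))
      lo <- pmax(seq_len(n) - w, 1L)
      hi <- pmin(seq_len(n) + w, n)
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    rolling <- sorted
    for (v in values) rolling[[paste0(v, "_roll")]] <- roll(sorted[[v]])
  }
  structure(list(bins = bins, rolling = rolling),
            class = "maf_summary", window = if (is.null(window)) NA_integer_ else as.integer(window))
}

#' @export
print.maf_summary <- function(x, ...) {
  cat("MAF-stratified metric summary\n")
  print(x$bins)
  if (!is.null(x$rolling)) {
    cat("rolling window: +/-", attr(x, "window"), "markers,", nrow(x$rolling), "markers\n")
  }
  invisible(x)
}

#' @export
tidy.maf_summary <- function(x, ...) x$bins

#' Plot a MAF-stratified metric profile
#'
#' Rolling-mean metric against MAF rank, one line per metric, mirroring the
#' usual presentation of imputation accuracy against ascending MAF.
#'
#' @param object A `maf_summary` with a rolling series.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maf_summary <- function(object, ...) {
  if (is.null(object$rolling)) stop("summary has no rolling series", call. = FALSE)
  roll_cols <- grep("_roll$", names(object$rolling), value = TRUE)
  df <- object$rolling |>
    dplyr::mutate(maf_rank = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(roll_cols), names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = sub("_roll$", "", .data$metric))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$maf, y = .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "MAF (markers sorted ascending)", y = "rolling mean",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
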