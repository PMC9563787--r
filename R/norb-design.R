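#' Square NORB pooling design
#'
#' Constructs the design matrix of a nonadaptive overlapping repeated block
#' (NORB) scheme in its square transversal form: a block of `m = q^2` samples
#' is arranged on a `q x q` grid and assayed through `k = 2q` pools (the `q`
#' grid rows and the `q` grid columns). Every pool contains `q` samples (pool
#' degree `q`), every sample occurs in exactly 2 pools (sample weight 2), and
#' any two pools share at most one sample (pool intersection 1). The reduction
#' factor — samples assayed per physical test — is `rho = q^2 / (2q) = q / 2`.
#'
#' For the default `q = 4` this is the 8-pools-per-16-samples block scheme
#' with reduction factor 2.
#'
#' @param q Block dimension (`>= 2`); the block holds `q^2` samples.
#' @return An object of class `norb_design`: a list with the binary `k x m`
#'   design matrix `matrix` (rows = pools, columns = samples), `q`, and the
#'   derived constants `n_pools`, `n_samples`, `reduction_factor`. Pool `i`
#'   for `i <= q` is row-pool `i`; pool `q + j` is column-pool `j`. Sample
#'   index `s` sits at grid coordinates `row = ((s - 1) %/% q) + 1`,
#'   `col = ((s - 1) %% q) + 1`.
#' @examples
#' d <- norb_design(4)
#' d$n_pools            # 8
#' d$reduction_factor   # 2
#' @export
norb_design <- function(q = 4L) {
  q <- as.integer(q)
  if (length(q) != 1L || is.na(q) || q < 2L) {
    stop("`q` must be a single integer >= 2", call. = FALSE)
  }
  m <- q * q
  k <- 2L * q
  M <- matrix(0L, nrow = k, ncol = m)
  s <- seq_len(m)
  row_of <- ((s - 1L) %/% q) + 1L
  col_of <- ((s - 1L) %% q) + 1L
  M[cbind(row_of, s)] <- 1L
  M[cbind(q + col_of, s)] <- 1L
  rownames(M) <- c(paste0("R", seq_len(q)), paste0("C", seq_len(q)))
  colnames(M) <- paste0("S", s)
  structure(
    list(matrix = M, q = q, n_pools = k, n_samples = m,
         reduction_factor = m / k),
    class = "norb_design"
  )
}

#' @export
print.norb_design <- function(x, ...) {
  cat("Square NORB pooling design\n")
  cat("  block dimension q :", x$q, "\n")
  cat("  pools per block   :", x$n_pools, "\n")
  cat("  samples per block :", x$n_samples, "\n")
  cat("  reduction factor  :", x$reduction_factor, "\n")
  invisible(x)
}

#' Validate a pooling design matrix
#'
#' Report-style check of the square-design invariants: every row (pool) sums
#' to the pool degree `q`, every column (sample) sums to the sample weight 2,
#' and any two rows intersect in at most 1 sample.
#'
#' @param design A `norb_design` object or a binary pools x samples matrix.
#' @return A tibble with one row per invariant (`invariant`, `observed`,
#'   `expected`, `pass`), with attribute `pass` giving the overall result.
#' @export
validate_design <- function(design) {
  M <- if (inherits(design, "norb_design")) design$matrix else as.matrix(design)
  if (!all(M %in% c(0L, 1L))) stop("design matrix must be binary", call. = FALSE)
  k <- nrow(M)
  degree <- k / 2       # expected row sum for a square design (q = k/2)
  rs <- rowSums(M)
  cs <- colSums(M)
  inter <- M %*% t(M)
  diag(inter) <- 0
  max_int <- max(inter)
  report <- tibble::tibble(
    invariant = c("pool degree (row sums)", "sample weight (column sums)",
                  "pool intersection (max pairwise)"),
    observed = c(paste(sort(unique(rs)), collapse = ","),
                 paste(sort(unique(cs)), collapse = ","),
                 as.character(max_int)),
    expected = c(as.character(degree), "2", "<= 1"),
    pass = c(all(rs == degree), all(cs == 2), max_int <= 1)
  )
  attr(report, "pass") <- all(report$pass)
  report
}

#' Assign study samples to pooling blocks
#'
#' Randomly permutes the cohort (seeded) and partitions it into consecutive
#' blocks of `q^2` samples; within each block, samples fill the `q x q` grid
#' row by row, which fixes their (row-pool, column-pool) coordinates. The
#' cohort size must be a multiple of the block size — undersized cohorts are
#' rejected, not padded.
#'
#' @param sample_ids Character (or coercible) vector of distinct sample ids.
#' @param q Block dimension.
#' @param seed Integer seed controlling the permutation; identical seeds give
#'   identical assignments.
#' @return A tibble with columns `sample_id`, `block`, `row_pool`, `col_pool`
#'   (pool indices within the block, 1-based), and `cell` (position in the
#'   grid, row-major). Attribute `seed` records the seed, `q` the dimension.
#' @examples
#' assign_blocks(sprintf("s%03d", 1:32), q = 4, seed = 7)
#' @export
assign_blocks <- function(sample_ids, q = 4L, seed = 1L) {
  q <- as.integer(q)
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  nb <- q * q
  if (n %% nb != 0L) {
    stop("cohort size ", n, " is not divisible by the block size ", nb,
         " (remainder ", n %% nb, ")", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be distinct", call. = FALSE)
  perm <- local_seed(seed, sample.int(n))
  ord <- sample_ids[perm]
  cell <- rep(seq_len(nb), times = n %/% nb)
  out <- tibble::tibble(
    sample_id = ord,
    block = rep(seq_len(n %/% nb), each = nb),
    row_pool = ((cell - 1L) %/% q) + 1L,
    col_pool = ((cell - 1L) %% q) + 1L,
    cell = cell
  )
  attr(out, "seed") <- as.integer(seed)
  attr(out, "q") <- q
  out
}

#' Decodability bound on the minor allele frequency
#'
#' Upper bound on the MAF below which a block is near-certainly decodable:
#' with at most `d0` minor-allele carriers guaranteed identifiable per block
#' and `g1` copies carried each, the bound is `d0 * g1 / (2 * q^2)`. For the
#' default `q = 4` design this evaluates to `1 / 32`, i.e. about 3.1%.
#'
#' @param q Block dimension.
#' @param d0 Guaranteed number of identifiable carriers per block (default 1).
#' @param g1 Minor-allele copies per carrier (default 1, the heterozygous
#'   case that dominates rare variants under Hardy-Weinberg equilibrium).
#' @return The MAF bound as a proportion in (0, 0.5].
#' @examples
#' decodability_bound(4)            # 0.03125
#' round(100 * decodability_bound(4), 1)  # 3.1 (%)
#' @export
decodability_bound <- function(q = 4L, d0 = 1, g1 = 1) {
  q <- as.integer(q)
  if (q < 2L) stop("`q` must be >= 2", call. = FALSE)
  d0 * g1 / (2 * q^2)
}

#' Export / import a design matrix as headered CSV
#'
#' @param design A `norb_design` object.
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   `norb_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "norb_design"))
  utils::write.csv(design$matrix, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  M <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(M) <- "integer"
  q <- nrow(M) %/% 2L
  d <- norb_design(q)
  if (!identical(unname(d$matrix), unname(M))) {
    stop("file does not contain a square NORB design matrix", call. = FALSE)
  }
  d$matrix <- M
  d
}

#' @export
tidy.norb_design <- function(x, ...) {
  idx <- which(x$matrix == 1L, arr.ind = TRUE)
  tibble::tibble(
    pool = rownames(x$matrix)[idx[, 1]],
    sample = colnames(x$matrix)[idx[, 2]]
  ) |> dplyr::arrange(.data$sample, .data$pool)
}

#' @export
glance.norb_design <- function(x, ...) {
  v <- validate_design(x)
  tibble::tibble(
    q = x$q, n_pools = x$n_pools, n_samples = x$n_samples,
    reduction_factor = x$reduction_factor,
    decodability_bound = decodability_bound(x$q),
    valid = attr(v, "pass")
  )
}
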