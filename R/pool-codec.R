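#' Simulate pool genotyping of one block (encoding)
#'
#' A pool genotyped on a SNP chip reports which alleles are present among its
#' members: the pool genotype is 0 iff all members are homozygous REF, 2 iff
#' all members are homozygous ALT, and 1 otherwise (both alleles detected).
#' Assays are assumed error-free.
#'
#' @param x Integer `q x q` matrix of determined genotypes in `{0, 1, 2}`;
#'   rows are row-pools, columns are column-pools.
#' @return An object of class `block_observation`: list with `pools` (length
#'   `2q`, row-pools first), `pattern` (list `rows`, `cols`: counts of pools
#'   with genotype 0, 1, 2), and `q`.
#' @examples
#' x <- matrix(0L, 4, 4); x[3, 1] <- 1L
#' encode_block(x)$pattern
#' @export
encode_block <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("block must be square", call. = FALSE)
  storage.mode(x) <- "integer"
  if (any(is.na(x)) || any(!x %in% 0:2)) {
    stop("encoding requires determined genotypes in {0, 1, 2}", call. = FALSE)
  }
  q <- nrow(x)
  pool_g <- function(v) if (all(v == 0L)) 0L else if (all(v == 2L)) 2L else 1L
  rows <- vapply(seq_len(q), function(i) pool_g(x[i, ]), integer(1))
  cols <- vapply(seq_len(q), function(j) pool_g(x[, j]), integer(1))
  block_observation(c(rows, cols), q)
}

#' Construct a block observation from pool genotypes
#'
#' @param pools Integer vector of length `2q` of pool genotypes in
#'   `{0, 1, 2}`; the first `q` entries are row-pools.
#' @param q Block dimension; defaults to `length(pools) / 2`.
#' @return A `block_observation` (see [encode_block()]).
#' @export
block_observation <- function(pools, q = length(pools) %/% 2L) {
  pools <- as.integer(pools)
  if (length(pools) != 2L * q) stop("`pools` must have length 2q", call. = FALSE)
  if (any(!pools %in% 0:2)) stop("pool genotypes must be in {0, 1, 2}", call. = FALSE)
  rows <- pools[seq_len(q)]
  cols <- pools[q + seq_len(q)]
  structure(
    list(pools = pools, q = q,
         pattern = list(rows = tabulate3(rows), cols = tabulate3(cols))),
    class = "block_observation"
  )
}

tabulate3 <- function(g) {
  c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
}

#' @export
print.block_observation <- function(x, ...) {
  cat("Block observation (q =", x$q, ")\n")
  cat("  row-pools   :", x$pools[seq_len(x$q)], "\n")
  cat("  column-pools:", x$pools[x$q + seq_len(x$q)], "\n")
  cat("  pattern psi : (", paste(x$pattern$rows, collapse = ","), ") x (",
      paste(x$pattern$cols, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Decode the genotype candidates at one pool intersection
#'
#' Intersection table for a sample lying in a row-pool with genotype `r` and a
#' column-pool with genotype `c`: two homozygous pools determine the sample; a
#' homozygous pool forces its homozygous genotype regardless of the other
#' pool; two heterozygous pools leave the sample indeterminate. The pair
#' `(0, 2)` (and `(2, 0)`) is inconsistent with any genotype and raises an
#' error.
#'
#' @param r,c Pool genotypes in `{0, 1, 2}`.
#' @return Integer vector of candidate genotypes.
#' @examples
#' decode_pair(0, 1)  # 0
#' decode_pair(1, 1)  # 0 1 2
#' @export
decode_pair <- function(r, c) {
  r <- as.integer(r); c <- as.integer(c)
  if (!r %in% 0:2 || !c %in% 0:2) stop("pool genotypes must be in {0, 1, 2}", call. = FALSE)
  if ((r == 0L && c == 2L) || (r == 2L && c == 0L)) {
    stop("inconsistent pool pair (", r, ", ", c, "): not consistent with any genotype",
         call. = FALSE)
  }
  if (r == 1L && c == 1L) return(0:2)
  if (r == 0L || c == 0L) return(0L)
  2L
}

#' Decode a block observation with constraint propagation
#'
#' Initializes every cell's candidate genotype set from its pool pair (see
#' [decode_pair()]) and then propagates allele-presence constraints to a
#' fixpoint: a pool with genotype 1 detected both alleles, so at least one of
#' its members must carry REF (genotype in `{0, 1}`) and at least one must
#' carry ALT (genotype in `{1, 2}`); whenever only a single member can still
#' supply an allele, that member's candidates are restricted accordingly.
#' Conversely a pool with genotype 0 (resp. 2) pins all members to 0 (resp.
#' 2). Cells are then classified: a singleton candidate set is a full call;
#' `{1, 2}` is an ALT half-call (`./1`); `{0, 1}` a REF half-call (`0/.`);
#' `{0, 1, 2}` is missing.
#'
#' @param obs A `block_observation`, or an integer vector of `2q` pool
#'   genotypes.
#' @return An object of class `decoded_block`: list with `q`, `obs`,
#'   `candidates` (a `q x q` list-matrix of integer candidate sets), `gt`
#'   (`q x q` integer matrix, `-1` where not fully decoded), and `status`
#'   (`q x q` character matrix in `{"full", "half_ref", "half_alt",
#'   "missing"}`).
#' @examples
#' x <- matrix(0L, 4, 4); x[3, 1] <- 1L
#' d <- decode_block(encode_block(x))
#' d$status[3, 1]  # "half_alt"
#' @export
decode_block <- function(obs) {
  if (!inherits(obs, "block_observation")) obs <- block_observation(obs)
  q <- obs$q
  rows <- obs$pools[seq_len(q)]
  cols <- obs$pools[q + seq_len(q)]
  cand <- vector("list", q * q)
  dim(cand) <- c(q, q)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    cand[[i, j]] <- decode_pair(rows[i], cols[j])
  }

  # membership lists: pool p -> cells (i, j)
  pools <- c(lapply(seq_len(q), function(i) cbind(i, seq_len(q))),
             lapply(seq_len(q), function(j) cbind(seq_len(q), j)))
  pool_g <- c(rows, cols)

  repeat {
    changed <- FALSE
    for (p in seq_along(pools)) {
      if (pool_g[p] != 1L) next
      cells <- pools[[p]]
      sets <- lapply(seq_len(q), function(t) cand[[cells[t, 1], cells[t, 2]]])
      for (allele_set in list(c(0L, 1L), c(1L, 2L))) {
        can_supply <- vapply(sets, function(s) any(s %in% allele_set), logical(1))
        if (!any(can_supply)) {
          stop("inconsistent block observation: heterozygous pool with no possible ",
               if (allele_set[1] == 0L) "REF" else "ALT", " carrier", call. = FALSE)
        }
        if (sum(can_supply) == 1L) {
          t <- which(can_supply)
          s <- sets[[t]]
          forced <- s[s %in% allele_set]
          if (length(forced) < length(s)) {
            cand[[cells[t, 1], cells[t, 2]]] <- forced
            sets[[t]] <- forced
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }

  gt <- matrix(-1L, q, q)
  status <- matrix("missing", q, q)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    s <- cand[[i, j]]
    if (length(s) == 0L) stop("inconsistent block observation: empty candidate set", call. = FALSE)
    if (length(s) == 1L) {
      gt[i, j] <- s
      status[i, j] <- "full"
    } else if (identical(s, c(1L, 2L))) {
      status[i, j] <- "half_alt"
    } else if (identical(s, c(0L, 1L))) {
      status[i, j] <- "half_ref"
    }
  }
  structure(list(q = q, obs = obs, candidates = cand, gt = gt, status = status),
            class = "decoded_block")
}

#' @export
print.decoded_block <- function(x, ...) {
  cat("Decoded block (q =", x$q, ")\n")
  disp <- matrix(".", x$q, x$q)
  disp[x$status == "full"] <- as.character(x$gt[x$status == "full"])
  disp[x$status == "half_alt"] <- "./m"
  disp[x$status == "half_ref"] <- "M/."
  disp[x$status == "missing"] <- "./."
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
tidy.decoded_block <- function(x, ...) {
  q <- x$q
  grid <- expand.grid(row_pool = seq_len(q), col_pool = seq_len(q))
  tibble::tibble(
    row_pool = grid$row_pool,
    col_pool = grid$col_pool,
    status = x$status[cbind(grid$row_pool, grid$col_pool)],
    gt = x$gt[cbind(grid$row_pool, grid$col_pool)],
    candidates = lapply(seq_len(q * q), function(s) x$candidates[[grid$row_pool[s], grid$col_pool[s]]])
  )
}

#' Encode pooled genotypes for many markers at once
#'
#' Vectorized encoding of one block across markers: for each marker, computes
#' the `2q` pool genotypes of the block.
#'
#' @param G Integer matrix `n_markers x q^2` of determined genotypes; columns
#'   are the block cells in row-major grid order.
#' @param q Block dimension.
#' @return Integer matrix `n_markers x 2q` of pool genotypes.
#' @keywords internal
encode_block_markers <- function(G, q) {
  stopifnot(ncol(G) == q * q)
  if (any(is.na(G)) || any(!G %in% 0:2)) {
    stop("encoding requires determined genotypes in {0, 1, 2}", call. = FALSE)
  }
  pools <- matrix(0L, nrow(G), 2L * q)
  for (p in seq_len(q)) {
    rcells <- ((p - 1L) * q + 1L):(p * q)              # row p, row-major
    ccells <- seq(p, q * q, by = q)                    # column p
    rsub <- G[, rcells, drop = FALSE]
    csub <- G[, ccells, drop = FALSE]
    pools[, p] <- ifelse(rowSums(rsub == 0L) == q, 0L,
                         ifelse(rowSums(rsub == 2L) == q, 2L, 1L))
    pools[, q + p] <- ifelse(rowSums(csub == 0L) == q, 0L,
                             ifelse(rowSums(csub == 2L) == q, 2L, 1L))
  }
  pools
}

#' Pattern key string for a block observation
#'
#' Serializes the pooling pattern `psi` as `"n0,n1,n2|n0,n1,n2"` (rows then
#' columns); used to key posterior tables.
#'
#' @param obs A `block_observation`, or a pattern list with `rows`/`cols`.
#' @return Character scalar.
#' @export
pattern_key <- function(obs) {
  pat <- if (inherits(obs, "block_observation")) obs$pattern else obs
  paste(paste(pat$rows, collapse = ","), paste(pat$cols, collapse = ","), sep = "|")
}

parse_pattern_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  list(rows = as.integer(strsplit(parts[1], ",")[[1]]),
       cols = as.integer(strsplit(parts[2], ",")[[1]]))
}
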