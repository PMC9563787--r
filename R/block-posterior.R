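#' Block posterior estimation
#'
#' Given an observed pooling pattern `psi` (counts of row- and column-pools
#' per genotype) and the genotype pair `(r, c)` of a cell's two intersecting
#' pools, this module estimates the genotype probability simplex of that cell
#' by reasoning over the *valid layouts*: the complete genotype assignments of
#' the block whose re-encoding reproduces the observation. Three estimators
#' are provided: exact Bayesian conditioning under an explicit per-cell prior
#' ([posterior_exact()], the reference oracle), marginal maximum likelihood
#' over the layout space ([mmle_estimate()]), and the self-consistent EM-type
#' estimator with heterozygote-degeneracy reweighting
#' ([self_consistent_estimate()]) whose results are tabulated per design by
#' [build_posterior_table()] and attached to decoded study data as GP/GL
#' priors by [attach_priors()].
#'
#' @name block-posterior
NULL

# ---- pattern utilities -----------------------------------------------------

as_pattern <- function(pattern) {
  if (is.character(pattern)) pattern <- parse_pattern_key(pattern)
  if (inherits(pattern, "block_observation")) pattern <- pattern$pattern
  stopifnot(is.list(pattern), length(pattern$rows) == 3L, length(pattern$cols) == 3L)
  if (sum(pattern$rows) != sum(pattern$cols)) {
    stop("row and column pool counts disagree on the block dimension", call. = FALSE)
  }
  list(rows = as.integer(pattern$rows), cols = as.integer(pattern$cols))
}

# All (n0, n1, n2) with n0 + n1 + n2 = q
compositions3 <- function(q) {
  out <- expand.grid(n0 = 0:q, n1 = 0:q)
  out <- out[out$n0 + out$n1 <= q, ]
  cbind(n0 = out$n0, n1 = out$n1, n2 = q - out$n0 - out$n1)
}

# ---- DP engine over valid layouts -----------------------------------------
#
# Canonical block for a pattern: rows ordered (0-pools, 1-pools, 2-pools),
# columns likewise. All cells outside the het-row x het-column subgrid are
# fully determined (0-pool members are 0, 2-pool members are 2); the free
# subgrid has a = n1_rows x b = n1_cols cells. Validity constraints on free
# cells reduce to allele-presence requirements per het pool ("not all REF" /
# "not all ALT" once the determined members are accounted for). The DP sweeps
# het rows, enumerating per-row assignments (<= 3^b) and tracking, per het
# column, which required alleles are already supplied (2 bits per column).
block_dp <- function(pattern, budget_states = 4^8) {
  pat <- as_pattern(pattern)
  q <- sum(pat$rows)
  n0r <- pat$rows[1]; n1r <- pat$rows[2]; n2r <- pat$rows[3]
  n0c <- pat$cols[1]; n1c <- pat$cols[2]; n2c <- pat$cols[3]

  infeasible <- function() list(feasible = FALSE, pattern = pat, q = q)

  # a 0-pool row crossing a 2-pool column is impossible
  if ((n0r > 0 && n2c > 0) || (n2r > 0 && n0c > 0)) return(infeasible())

  a <- n1r; b <- n1c
  need_ref_row <- n0c == 0   # het row must get a REF carrier from free cells
  need_alt_row <- n2c == 0
  need_ref_col <- n0r == 0
  need_alt_col <- n2r == 0

  # het pools with no free cells must already be satisfied by determined cells
  if (a > 0 && b == 0 && (need_ref_row || need_alt_row)) return(infeasible())
  if (b > 0 && a == 0 && (need_ref_col || need_alt_col)) return(infeasible())

  det_counts <- c(n0r * q + a * n0c, 0L, n2r * q + a * n2c)

  if (a == 0L || b == 0L) {
    return(list(feasible = TRUE, pattern = pat, q = q, a = a, b = b,
                det_counts = det_counts, free = FALSE))
  }

  if (4^b > budget_states) {
    stop("pattern state space exceeds the DP budget (q too large)", call. = FALSE)
  }

  tuples <- as.matrix(expand.grid(rep(list(0:2), b)))[, b:1, drop = FALSE]
  colnames(tuples) <- NULL
  has_ref <- tuples <= 1L   # cell supplies REF allele
  has_alt <- tuples >= 1L
  ok <- rep(TRUE, nrow(tuples))
  if (need_ref_row) ok <- ok & rowSums(has_ref) > 0
  if (need_alt_row) ok <- ok & rowSums(has_alt) > 0
  tuples <- tuples[ok, , drop = FALSE]
  has_ref <- has_ref[ok, , drop = FALSE]
  has_alt <- has_alt[ok, , drop = FALSE]
  if (nrow(tuples) == 0L) return(infeasible())

  cnt <- cbind(rowSums(tuples == 0L), rowSums(tuples == 1L), rowSums(tuples == 2L))

  # column-satisfaction bitmask contributed by each tuple
  ref_bits <- 4^(seq_len(b) - 1L)        # bit 2j   (value 1 within column slot)
  alt_bits <- 2 * 4^(seq_len(b) - 1L)    # bit 2j+1 (value 2 within column slot)
  mask <- as.integer(has_ref %*% ref_bits + has_alt %*% alt_bits)

  n_states <- as.integer(4^b)
  s0 <- 0L
  if (!need_ref_col) s0 <- s0 + as.integer(sum(ref_bits))
  if (!need_alt_col) s0 <- s0 + as.integer(sum(alt_bits))
  states <- 0:(n_states - 1L)
  # ns[s + 1, t]: state after applying tuple t in state s
  ns <- matrix(0L, n_states, nrow(tuples))
  for (t in seq_len(nrow(tuples))) ns[, t] <- bitwOr(states, mask[t])

  list(feasible = TRUE, pattern = pat, q = q, a = a, b = b,
       det_counts = det_counts, free = TRUE,
       tuples = tuples, cnt = cnt, ns = ns, n_states = n_states,
       s0 = s0, accept = n_states - 1L)
}

# Sparse one-row transition operators for a given per-cell prior.
# Returns A (weight flow) and B[[k]] (weight x genotype-k-count flow).
dp_operators <- function(dp, prior, tuple_subset = NULL) {
  tt <- if (is.null(tuple_subset)) seq_len(nrow(dp$tuples)) else tuple_subset
  if (length(tt) == 0L) return(NULL)
  w <- prior[1]^dp$cnt[tt, 1] * prior[2]^dp$cnt[tt, 2] * prior[3]^dp$cnt[tt, 3]
  S <- dp$n_states
  i <- as.vector(dp$ns[, tt, drop = FALSE]) + 1L
  j <- rep(1:S, times = length(tt))
  A <- Matrix::sparseMatrix(i = i, j = j, x = rep(w, each = S), dims = c(S, S))
  B <- lapply(1:3, function(k) {
    Matrix::sparseMatrix(i = i, j = j, x = rep(w * dp$cnt[tt, k], each = S),
                         dims = c(S, S))
  })
  list(A = A, B = B)
}

# Run the DP. Returns total weight over valid layouts, expected genotype
# counts over free cells (weight-summed, not normalized), and optionally the
# per-genotype weight split of the first free cell (row 1, column 1 of the
# free subgrid).
dp_eval <- function(dp, prior, marginal = FALSE) {
  if (!dp$feasible) stop("inconsistent pattern: no valid layout exists", call. = FALSE)
  if (!dp$free) {
    return(list(total = 1, counts = c(0, 0, 0),
                marginal = if (marginal) stop("pattern has no free cells", call. = FALSE)))
  }
  ops <- dp_operators(dp, prior)
  run <- function(first_ops) {
    W <- numeric(dp$n_states); W[dp$s0 + 1L] <- 1
    C <- matrix(0, 3, dp$n_states)
    for (r in seq_len(dp$a)) {
      o <- if (r == 1L) first_ops else ops
      if (is.null(o)) return(list(total = 0, counts = c(0, 0, 0)))
      Cn <- matrix(0, 3, dp$n_states)
      for (k in 1:3) {
        Cn[k, ] <- as.numeric(o$A %*% C[k, ]) + as.numeric(o$B[[k]] %*% W)
      }
      W <- as.numeric(o$A %*% W)
      C <- Cn
    }
    list(total = W[dp$accept + 1L], counts = C[, dp$accept + 1L])
  }
  out <- run(ops)
  res <- list(total = out$total, counts = out$counts)
  if (marginal) {
    wg <- vapply(0:2, function(g) {
      sub <- which(dp$tuples[, 1] == g)
      run(dp_operators(dp, prior, tuple_subset = sub))$total
    }, numeric(1))
    res$marginal_weights <- wg
  }
  res
}

# ---- layout enumeration ----------------------------------------------------

#' Enumerate the valid layouts of a block observation
#'
#' Explicitly enumerates all complete genotype assignments of the block that
#' are consistent with the observed pool genotypes: assignments over the
#' undecoded cells (candidate sets from [decode_block()]) whose re-encoding
#' reproduces the observation. Each layout is annotated with its genotype
#' counts `(n0, n1, n2)` and its heterozygote degeneracy `2^n1` — the number
#' of phased micro-layouts collapsed into it.
#'
#' @param obs A `block_observation` (or pool genotype vector).
#' @param budget Maximum number of candidate combinations to enumerate.
#' @return A tibble with one row per valid layout: list-column `layout`
#'   (`q x q` integer matrix), `n0`, `n1`, `n2`, `degeneracy`.
#' @examples
#' x <- matrix(0L, 4, 4); x[3, 1] <- 1L
#' enumerate_valid_layouts(encode_block(x))   # 2 layouts
#' @export
enumerate_valid_layouts <- function(obs, budget = 2e5) {
  if (!inherits(obs, "block_observation")) obs <- block_observation(obs)
  dec <- decode_block(obs)
  q <- dec$q
  free <- which(lengths(dec$candidates) > 1L)
  base <- dec$gt
  base[base == -1L] <- 0L   # placeholder, overwritten below
  n_comb <- prod(lengths(dec$candidates)[free])
  if (length(free) > 0 && n_comb > budget) {
    stop("layout enumeration budget exceeded (", n_comb, " combinations); ",
         "use the posterior estimators, which do not enumerate explicitly",
         call. = FALSE)
  }
  combos <- if (length(free) == 0L) {
    matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    as.matrix(expand.grid(dec$candidates[free]))
  }
  keep <- logical(nrow(combos))
  layouts <- vector("list", nrow(combos))
  for (s in seq_len(nrow(combos))) {
    x <- base
    x[free] <- as.integer(combos[s, ])
    keep[s] <- identical(encode_block(x)$pools, obs$pools)
    layouts[[s]] <- x
  }
  layouts <- layouts[keep]
  if (length(layouts) == 0L) {
    stop("inconsistent block observation: no valid layout exists", call. = FALSE)
  }
  n1 <- vapply(layouts, function(x) sum(x == 1L), integer(1))
  tibble::tibble(
    layout = layouts,
    n0 = vapply(layouts, function(x) sum(x == 0L), integer(1)),
    n1 = n1,
    n2 = vapply(layouts, function(x) sum(x == 2L), integer(1)),
    degeneracy = 2^n1
  )
}

# ---- exact conditioning ----------------------------------------------------

check_key <- function(pat, r, c) {
  r <- as.integer(r); c <- as.integer(c)
  if ((r == 0L && c == 2L) || (r == 2L && c == 0L)) {
    stop("inconsistent key: pool pair (", r, ", ", c, ") is never observed", call. = FALSE)
  }
  if (pat$rows[r + 1L] == 0L || pat$cols[c + 1L] == 0L) {
    stop("inconsistent key: pool genotype (", r, ", ", c,
         ") does not occur in the pattern", call. = FALSE)
  }
  c(r, c)
}

#' Exact posterior genotype probabilities at a pool intersection
#'
#' Exact Bayesian conditioning over the valid layouts of the pattern: each
#' layout is weighted by the product of per-cell prior probabilities, and the
#' normalized marginal of a cell at an `(r, c)` pool intersection is returned.
#' This is the reference oracle against which the iterative estimators are
#' compared.
#'
#' @param pattern A pattern (list `rows`/`cols`, key string, or
#'   `block_observation`).
#' @param r,c Pool genotypes of the cell's row- and column-pool.
#' @param prior Length-3 per-cell prior simplex. The default
#'   `c(0.25, 0.5, 0.25)` is uniform over *phased* allele pairs, giving
#'   heterozygotes twice the prior mass of either homozygote.
#' @return Named numeric simplex `(p0, p1, p2)`.
#' @examples
#' posterior_exact(list(rows = c(3, 1, 0), cols = c(3, 1, 0)), 1, 1)
#' @export
posterior_exact <- function(pattern, r = 1L, c = 1L, prior = c(0.25, 0.5, 0.25)) {
  pat <- as_pattern(pattern)
  rc <- check_key(pat, r, c)
  prior <- as.numeric(prior)
  stopifnot(length(prior) == 3L, all(prior >= 0), abs(sum(prior) - 1) < 1e-6)
  if (rc[1] != 1L || rc[2] != 1L) {
    g <- if (rc[1] == 0L || rc[2] == 0L) 0L else 2L
    return(one_hot(g))
  }
  dp <- block_dp(pat)
  if (!dp$feasible) stop("inconsistent pattern: no valid layout exists", call. = FALSE)
  if (!dp$free) stop("inconsistent key: pattern has no heterozygous intersection", call. = FALSE)
  ev <- dp_eval(dp, prior, marginal = TRUE)
  w <- ev$marginal_weights
  if (sum(w) <= 0) stop("inconsistent pattern: no valid layout exists", call. = FALSE)
  simplex(w)
}

one_hot <- function(g) {
  p <- c(p0 = 0, p1 = 0, p2 = 0)
  p[g + 1L] <- 1
  p
}

simplex <- function(x, snap_tol = 1e-9) {
  p <- as.numeric(x) / sum(x)
  # snap components that are equal up to floating-point fuzz, so the
  # deterministic lowest-index tie-break of best_guess() applies
  for (i in 1:2) for (j in (i + 1):3) {
    if (p[i] != p[j] && abs(p[i] - p[j]) < snap_tol) {
      m <- (p[i] + p[j]) / 2
      p[i] <- m; p[j] <- m
    }
  }
  p <- p / sum(p)
  names(p) <- c("p0", "p1", "p2")
  p
}

# ---- self-consistent (EM-type) estimation ---------------------------------

#' Configuration for the self-consistent estimator
#'
#' @param prior Initial per-cell estimate for undetermined entries; default
#'   `c(0.25, 0.5, 0.25)`, uniform over phased allele pairs.
#' @param weights Rescaling weights `(w0, w1, w2)` applied in the M-step to
#'   account for heterozygote degeneracy (a layout with `n1` heterozygotes
#'   stands for `2^n1` phased micro-layouts). Default `c(1, 2, 1)`;
#'   `c(1, 1, 1)` disables the degeneracy correction.
#' @param max_iter Maximum EM iterations.
#' @param tol L-infinity convergence tolerance on the iterate.
#' @param damping `"ratio"` applies the update `w_k * p_k / p_k^(prev)`
#'   (the literal rescaling, dividing by the previous iterate); `"plain"`
#'   uses `w_k * p_k`.
#' @param final_rescale Apply the terminal compensating rescale
#'   `(p_k / w_k) / sum` that converts the internally degeneracy-weighted
#'   estimate back to the uniform-prior convention expected by downstream
#'   imputation.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(prior = c(0.25, 0.5, 0.25),
                             weights = c(1, 2, 1),
                             max_iter = 100L,
                             tol = 1e-6,
                             damping = c("ratio", "plain"),
                             final_rescale = TRUE) {
  prior <- as.numeric(prior)
  stopifnot(length(prior) == 3L, all(prior > 0), abs(sum(prior) - 1) < 1e-6,
            length(weights) == 3L, all(weights > 0))
  structure(
    list(prior = prior, weights = as.numeric(weights),
         max_iter = as.integer(max_iter), tol = tol,
         damping = match.arg(damping), final_rescale = isTRUE(final_rescale)),
    class = "estimator_config"
  )
}

#' Self-consistent estimate of the genotype probabilities at a key
#'
#' EM-type iteration over the valid layouts of a pattern. The E-step computes
#' the mixing proportion of every valid layout under the current per-cell
#' estimate; the M-step re-estimates the genotype frequencies of the
#' undetermined cells from the count-weighted layout expectations, then
#' rescales them with the degeneracy weights `w` (dividing by the previous
#' iterate under the default `"ratio"` damping) and renormalizes. On
#' convergence a final compensating rescale by `1/w` undoes the internal
#' heterozygote upweighting, yielding likelihoods on the uniform-prior scale
#' used by imputation. Determined keys return a one-hot simplex immediately.
#'
#' @inheritParams posterior_exact
#' @param cfg An [estimator_config()].
#' @return A list with `estimate` (named simplex), `internal` (the converged
#'   iterate before the final rescale), `iterations`, `converged`.
#' @examples
#' self_consistent_estimate(list(rows = c(3, 1, 0), cols = c(3, 1, 0)), 1, 1)$estimate
#' @export
self_consistent_estimate <- function(pattern, r = 1L, c = 1L, cfg = estimator_config()) {
  pat <- as_pattern(pattern)
  rc <- check_key(pat, r, c)
  stopifnot(inherits(cfg, "estimator_config"))
  if (rc[1] != 1L || rc[2] != 1L) {
    g <- if (rc[1] == 0L || rc[2] == 0L) 0L else 2L
    p <- one_hot(g)
    return(list(estimate = p, internal = p, iterations = 1L, converged = TRUE))
  }
  dp <- block_dp(pat)
  if (!dp$feasible) stop("inconsistent pattern: no valid layout exists", call. = FALSE)
  if (!dp$free) stop("inconsistent key: pattern has no heterozygous intersection", call. = FALSE)

  w <- cfg$weights
  pi_prev <- cfg$prior
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    ev <- dp_eval(dp, pi_prev)
    if (ev$total <= 0) stop("inconsistent pattern: no valid layout exists", call. = FALSE)
    p_mle <- ev$counts / sum(ev$counts)              # M-step (count-weighted MLE)
    p_resc <- if (cfg$damping == "ratio") {
      ifelse(pi_prev > 0, w * p_mle / pi_prev, 0)    # degeneracy resampling
    } else {
      w * p_mle
    }
    pi_new <- p_resc / sum(p_resc)
    if (max(abs(pi_new - pi_prev)) < cfg$tol) {
      pi_prev <- pi_new
      converged <- TRUE
      break
    }
    pi_prev <- pi_new
  }
  if (!converged) {
    warning("self-consistent estimation did not converge in ", cfg$max_iter,
            " iterations for pattern ", pattern_key(list(rows = pat$rows, cols = pat$cols)),
            call. = FALSE)
  }
  internal <- simplex(pi_prev)
  estimate <- if (cfg$final_rescale) simplex(pi_prev / w) else internal
  list(estimate = estimate, internal = internal, iterations = iter, converged = converged)
}

# ---- marginal maximum likelihood ------------------------------------------

#' Marginal maximum-likelihood estimate of the block genotype frequencies
#'
#' Maximizes the marginal likelihood of an observed pattern `psi` over the
#' genotype simplex: `L(pi) = sum over valid layouts of prod_k pi_k^(n_k)`
#' with `n_k` the genotype counts of the full layout (optionally weighted by
#' the heterozygote degeneracy `2^n1`). Numerical optimization on the
#' 2-simplex via a softmax parametrization (Nelder-Mead, deterministic
#' initialization at the uniform simplex).
#'
#' @inheritParams posterior_exact
#' @param degeneracy Weight layouts by their phased degeneracy `2^n1`.
#' @return A list with `estimate` (named simplex), `log_likelihood`,
#'   `converged`.
#' @examples
#' mmle_estimate(list(rows = c(4, 0, 0), cols = c(4, 0, 0)))$estimate
#' @export
mmle_estimate <- function(pattern, degeneracy = FALSE) {
  pat <- as_pattern(pattern)
  dp <- block_dp(pat)
  if (!dp$feasible) stop("inconsistent pattern: no valid layout exists", call. = FALSE)
  D <- dp$det_counts
  loglik <- function(pi) {
    pi_eff <- if (degeneracy) pi * c(1, 2, 1) else pi
    tot <- dp_eval(dp, pi_eff)$total
    det_part <- sum(D * ifelse(pi_eff > 0, log(pi_eff), -Inf) * (D > 0))
    if (tot <= 0) return(-Inf)
    det_part + log(tot)
  }
  # boundary-friendly closed forms first: fully determined patterns
  if (!dp$free && dp$a == 0 && dp$b == 0 && sum(D) == dp$q^2) {
    p <- simplex(D)
    return(list(estimate = p, log_likelihood = sum(D[D > 0] * log(p[D > 0])),
                converged = TRUE))
  }
  obj <- function(theta) {
    e <- exp(theta - max(theta))
    -loglik(e / sum(e))
  }
  opt <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (!is.finite(opt$value)) stop("marginal likelihood optimization failed", call. = FALSE)
  e <- exp(opt$par - max(opt$par))
  list(estimate = simplex(e), log_likelihood = -opt$value,
       converged = opt$convergence == 0L)
}

# ---- posterior table -------------------------------------------------------

#' Precompute the posterior table of a design
#'
#' Enumerates every consistent key `(psi, r, c)` of the `q x q` square design
#' and stores its genotype probability estimate: one-hot for determined keys
#' (any key with a homozygous pool), and the self-consistent estimate for
#' heterozygous intersections. The table depends only on `q` and the
#' estimator configuration, so it is computed once per design and reused for
#' every marker.
#'
#' @param q Block dimension.
#' @param cfg An [estimator_config()].
#' @param exact_oracle Also store the exact-conditioning oracle values
#'   (phased prior and uniform prior) alongside, for diagnostics.
#' @return A tibble of class `posterior_table` with columns `pattern`
#'   (key string `"rows|cols"`), `r`, `c`, `p0`, `p1`, `p2`, `status`
#'   (cell class implied by the key), `iterations`, `converged`, plus
#'   attributes `q`, `cfg`.
#' @export
build_posterior_table <- function(q = 4L, cfg = estimator_config(), exact_oracle = FALSE) {
  q <- as.integer(q)
  comps <- compositions3(q)
  out <- list()
  for (ri in seq_len(nrow(comps))) {
    for (ci in seq_len(nrow(comps))) {
      pat <- list(rows = as.integer(comps[ri, ]), cols = as.integer(comps[ci, ]))
      dp <- block_dp(pat)
      if (!dp$feasible) next
      # the pattern must be realizable: positive layout weight under a
      # strictly positive prior
      if (dp$free && dp_eval(dp, c(1 / 3, 1 / 3, 1 / 3))$total <= 0) next
      key <- pattern_key(list(rows = pat$rows, cols = pat$cols))
      for (r in 0:2) for (cc in 0:2) {
        if ((r == 0L && cc == 2L) || (r == 2L && cc == 0L)) next
        if (pat$rows[r + 1L] == 0L || pat$cols[cc + 1L] == 0L) next
        if (r == 1L && cc == 1L && !dp$free) next
        if (r != 1L || cc != 1L) {
          g <- if (r == 0L || cc == 0L) 0L else 2L
          p <- one_hot(g)
          row <- tibble::tibble(pattern = key, r = r, c = cc,
                                p0 = unname(p[1]), p1 = unname(p[2]), p2 = unname(p[3]),
                                status = "full", iterations = 1L, converged = TRUE)
        } else {
          est <- self_consistent_estimate(pat, 1L, 1L, cfg)
          p <- est$estimate
          status <- cell_status_from_simplex(dp, cfg)
          row <- tibble::tibble(pattern = key, r = 1L, c = 1L,
                                p0 = unname(p[1]), p1 = unname(p[2]), p2 = unname(p[3]),
                                status = status,
                                iterations = est$iterations, converged = est$converged)
        }
        if (exact_oracle && r == 1L && cc == 1L) {
          ex_ph <- posterior_exact(pat, 1L, 1L, prior = c(0.25, 0.5, 0.25))
          ex_un <- posterior_exact(pat, 1L, 1L, prior = rep(1 / 3, 3))
          row$exact_phased <- list(ex_ph)
          row$exact_uniform <- list(ex_un)
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  tbl <- dplyr::bind_rows(out)
  attr(tbl, "q") <- q
  attr(tbl, "cfg") <- cfg
  class(tbl) <- c("posterior_table", class(tbl))
  tbl
}

# status of the free cells implied by a pattern's candidate sets
cell_status_from_simplex <- function(dp, cfg) {
  m <- posterior_exact(dp$pattern, 1L, 1L, prior = rep(1 / 3, 3))
  if (m[1] == 0 && m[3] > 0) "half_alt"
  else if (m[3] == 0 && m[1] > 0) "half_ref"
  else "missing"
}

#' Serialize / load a posterior table as JSON
#'
#' The table round-trips bit-identically: simplices are written with full
#' double precision.
#'
#' @param table A `posterior_table`.
#' @param path File path.
#' @return `write_posterior_table` returns `path` invisibly;
#'   `read_posterior_table` returns the `posterior_table`.
#' @export
write_posterior_table <- function(table, path) {
  stopifnot(inherits(table, "posterior_table"))
  cfg <- attr(table, "cfg")
  payload <- list(
    q = attr(table, "q"),
    estimator = "self_consistent",
    config = list(prior = cfg$prior, weights = cfg$weights,
                  max_iter = cfg$max_iter, tol = cfg$tol,
                  damping = cfg$damping, final_rescale = cfg$final_rescale),
    keys = lapply(seq_len(nrow(table)), function(i) {
      list(pattern = table$pattern[i], r = table$r[i], c = table$c[i],
           gp = c(table$p0[i], table$p1[i], table$p2[i]),
           status = table$status[i],
           iterations = table$iterations[i], converged = table$converged[i])
    })
  )
  # I(17) significant digits so stored simplices reload bit-identically
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_posterior_table
#' @export
read_posterior_table <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  keys <- payload$keys
  tbl <- dplyr::bind_rows(lapply(keys, function(k) {
    tibble::tibble(pattern = k$pattern, r = as.integer(k$r), c = as.integer(k$c),
                   p0 = k$gp[[1]], p1 = k$gp[[2]], p2 = k$gp[[3]],
                   status = k$status, iterations = as.integer(k$iterations),
                   converged = as.logical(k$converged))
  }))
  cfgl <- payload$config
  attr(tbl, "q") <- as.integer(payload$q)
  attr(tbl, "cfg") <- estimator_config(
    prior = unlist(cfgl$prior), weights = unlist(cfgl$weights),
    max_iter = cfgl$max_iter, tol = cfgl$tol, damping = cfgl$damping,
    final_rescale = cfgl$final_rescale
  )
  class(tbl) <- c("posterior_table", class(tbl))
  tbl
}

#' @export
glance.posterior_table <- function(x, ...) {
  tibble::tibble(
    q = attr(x, "q"),
    n_keys = nrow(x),
    n_patterns = dplyr::n_distinct(x$pattern),
    n_undetermined = sum(x$r == 1L & x$c == 1L & x$status != "full"),
    all_converged = all(x$converged)
  )
}

#' Attach GP/GL priors to decoded study data
#'
#' Determined entries get one-hot genotype probabilities; half-called and
#' missing entries get the posterior-table estimate for their block's
#' `(psi, r, c)` key. Genotype likelihoods are emitted via [gp_to_gl()].
#'
#' @param decoded A long tibble of decoded study entries with columns
#'   `status` (`"full"`, `"half_ref"`, `"half_alt"`, `"missing"`), `gt`
#'   (genotype for `"full"` rows), `pattern`, `r`, `c`.
#' @param table A `posterior_table` for the design in use.
#' @param gl_floor log10 floor for GL emission.
#' @return The input tibble with columns `p0`, `p1`, `p2`, `l0`, `l1`, `l2`
#'   added.
#' @export
attach_priors <- function(decoded, table, gl_floor = -5) {
  stopifnot(inherits(table, "posterior_table"))
  need <- decoded$status != "full"
  keyed <- dplyr::distinct(decoded[need, c("pattern", "r", "c")])
  lk <- dplyr::left_join(keyed, table[, c("pattern", "r", "c", "p0", "p1", "p2")],
                         by = c("pattern", "r", "c"))
  if (any(is.na(lk$p0))) {
    miss <- lk[is.na(lk$p0), ]
    stop("posterior table is missing key(s): ",
         paste0(miss$pattern, " (", miss$r, ",", miss$c, ")", collapse = "; "),
         call. = FALSE)
  }
  out <- dplyr::left_join(
    decoded,
    lk,
    by = c("pattern", "r", "c")
  )
  det <- out$status == "full"
  if (any(det)) {
    oh <- gt_to_gp(out$gt[det])
    out$p0[det] <- oh[, 1]; out$p1[det] <- oh[, 2]; out$p2[det] <- oh[, 3]
  }
  gl <- gp_to_gl(cbind(out$p0, out$p1, out$p2), floor_log10 = gl_floor)
  out$l0 <- gl[, 1]; out$l1 <- gl[, 2]; out$l2 <- gl[, 3]
  out
}

# ---- Monte-Carlo conditioning cross-check ---------------------------------

#' Monte-Carlo conditioning over simulated blocks
#'
#' Samples blocks with i.i.d. per-cell genotypes from `prior`, pools them,
#' groups the true genotypes of cells at heterozygous intersections by their
#' observed key `(psi, r = 1, c = 1)`, and returns the empirical genotype
#' frequencies per key. This reproduces [posterior_exact()] within binomial
#' sampling error and serves as an independent cross-check of the layout
#' conditioning.
#'
#' @param q Block dimension.
#' @param prior Per-cell genotype simplex used to simulate blocks.
#' @param n_blocks Number of blocks to simulate.
#' @param seed Integer seed.
#' @return A tibble with `pattern`, `r`, `c`, counts `n0`, `n1`, `n2`, total
#'   `n`, and frequencies `p0`, `p1`, `p2`.
#' @export
mc_conditioning <- function(q = 4L, prior = c(0.25, 0.5, 0.25), n_blocks = 1e5,
                            seed = 1L) {
  q <- as.integer(q)
  nb <- q * q
  G <- local_seed(seed, {
    matrix(sample.int(3L, n_blocks * nb, replace = TRUE, prob = prior) - 1L,
           nrow = n_blocks, ncol = nb)
  })
  pools <- encode_block_markers(G, q)
  rows_part <- pools[, seq_len(q), drop = FALSE]
  cols_part <- pools[, q + seq_len(q), drop = FALSE]
  # integer-code each axis pattern as n0 * (q + 1) + n1
  code_of <- function(P) rowSums(P == 0L) * (q + 1L) + rowSums(P == 1L)
  K <- (q + 1L) * (q + 1L)
  pat_code <- code_of(rows_part) * K + code_of(cols_part)
  nbin <- K * K * 3L
  acc <- numeric(nbin)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    het <- rows_part[, i] == 1L & cols_part[, j] == 1L
    if (!any(het)) next
    cell <- (i - 1L) * q + j
    bins <- pat_code[het] * 3L + G[het, cell] + 1L
    acc <- acc + tabulate(bins, nbins = nbin)
  }
  m <- matrix(acc, ncol = 3L, byrow = TRUE)
  seen <- which(rowSums(m) > 0)
  decode_axis <- function(code) {
    n0 <- code %/% (q + 1L); n1 <- code %% (q + 1L)
    paste(n0, n1, q - n0 - n1, sep = ",")
  }
  codes <- seen - 1L
  tibble::tibble(
    pattern = paste(decode_axis(codes %/% K), decode_axis(codes %% K), sep = "|"),
    r = 1L, c = 1L,
    n0 = m[seen, 1], n1 = m[seen, 2], n2 = m[seen, 3],
    n = rowSums(m[seen, , drop = FALSE]),
    p0 = m[seen, 1] / rowSums(m[seen, , drop = FALSE]),
    p1 = m[seen, 2] / rowSums(m[seen, , drop = FALSE]),
    p2 = m[seen, 3] / rowSums(m[seen, , drop = FALSE])
  )
}
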