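# Independent oracles used across the suite. These deliberately avoid the
# package's DP / constraint-propagation code paths: encoding is re-derived
# from the pool rule, posteriors by exhaustive enumeration, and the HMM by
# summing over all hidden-state paths.

# pool genotype of a set of member genotypes (0 iff all 0, 2 iff all 2, else 1)
oracle_pool_g <- function(v) {
  if (all(v == 0L)) 0L else if (all(v == 2L)) 2L else 1L
}

# encode a q x q block (rows then columns)
oracle_encode <- function(x) {
  q <- nrow(x)
  c(vapply(seq_len(q), function(i) oracle_pool_g(x[i, ]), integer(1)),
    vapply(seq_len(q), function(j) oracle_pool_g(x[, j]), integer(1)))
}

# canonical block skeleton for a pattern: row/col pool genotypes ordered
# 0-pools, then 1-pools, then 2-pools
oracle_canonical <- function(pattern) {
  list(rows = rep(0:2, times = pattern$rows), cols = rep(0:2, times = pattern$cols))
}

# exhaustive enumeration of the valid layouts of a canonical block for a
# pattern: all 3^(q^2) assignments filtered by re-encoding (restricted to
# undetermined cells for tractability, with determined cells fixed by the
# pool pair rule)
oracle_layouts <- function(pattern) {
  can <- oracle_canonical(pattern)
  q <- length(can$rows)
  base <- matrix(NA_integer_, q, q)
  free <- NULL
  for (i in seq_len(q)) for (j in seq_len(q)) {
    r <- can$rows[i]; cc <- can$cols[j]
    if (r == 0L || cc == 0L) base[i, j] <- 0L
    else if (r == 2L || cc == 2L) base[i, j] <- 2L
    else free <- rbind(free, c(i, j))
  }
  target <- c(can$rows, can$cols)
  if (is.null(free)) {
    if (identical(oracle_encode(base), target)) return(list(base)) else return(list())
  }
  combos <- as.matrix(expand.grid(rep(list(0:2), nrow(free))))
  out <- list()
  for (s in seq_len(nrow(combos))) {
    x <- base
    x[free] <- as.integer(combos[s, ])
    if (identical(oracle_encode(x), target)) out[[length(out) + 1L]] <- x
  }
  out
}

# exact conditional marginal of a free (het x het) cell under an iid prior
oracle_cell_posterior <- function(pattern, prior) {
  can <- oracle_canonical(pattern)
  q <- length(can$rows)
  i <- which(can$rows == 1L)[1]
  j <- which(can$cols == 1L)[1]
  w <- c(0, 0, 0)
  for (x in oracle_layouts(pattern)) {
    lw <- prod(prior[x + 1L])
    w[x[i, j] + 1L] <- w[x[i, j] + 1L] + lw
  }
  w / sum(w)
}

# brute-force diploid Li-Stephens posterior by enumeration over all state
# paths (feasible for H <= 3, J <= 4)
oracle_ls_posterior <- function(haps, positions, gl, recomb_scale = 4e4,
                                err = 1e-4, gl_floor = -5, min_prob = 1e-15) {
  H <- nrow(haps); J <- ncol(haps)
  cm <- positions / 1e6
  theta <- if (J > 1) {
    pmin(pmax(1 - exp(-recomb_scale * (diff(cm) / 100) / H), 1e-12), 1 - 1e-9)
  } else numeric(0)
  lik <- 10^pmax(gl, gl_floor)
  e <- err; ne <- 1 - err
  Pe <- rbind(c(ne^2, 2 * e * ne, e^2),
              c(e * ne, ne^2 + e^2, e * ne),
              c(e^2, 2 * e * ne, ne^2))
  Tm <- function(t) (1 - t) * diag(H) + t / H
  pairs <- expand.grid(k = seq_len(H), l = seq_len(H))
  S <- nrow(pairs)
  u <- function(j, s) {
    gp <- haps[pairs$k[s], j] + haps[pairs$l[s], j]
    max(sum(lik[j, ] * Pe[gp + 1, ]), min_prob)
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), J)))
  post <- matrix(0, J, 3)
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    w <- 1 / S
    em <- vapply(seq_len(J), function(j) u(j, s[j]), numeric(1))
    if (J > 1) {
      for (j in 2:J) {
        tm <- Tm(theta[j - 1])
        w <- w * tm[pairs$k[s[j - 1]], pairs$k[s[j]]] *
          tm[pairs$l[s[j - 1]], pairs$l[s[j]]]
      }
    }
    w <- w * prod(em)
    for (j in seq_len(J)) {
      gp <- haps[pairs$k[s[j]], j] + haps[pairs$l[s[j]], j]
      contrib <- w / em[j] * lik[j, ] * Pe[gp + 1, ]
      post[j, ] <- post[j, ] + contrib
    }
  }
  post / rowSums(post)
}

# shared fixtures: a small seeded population reused by scenario tests
small_pop <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) {
      pop <<- simulate_population(sim_config(
        n_markers = 300L, n_panel = 60L, n_study = 32L, seed = 7L
      ))
    }
    pop
  }
})

small_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) tbl <<- build_posterior_table(4L)
    tbl
  }
})
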