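fig3a <- list(rows = c(3L, 1L, 0L), cols = c(3L, 1L, 0L))
fig3b <- list(rows = c(2L, 2L, 0L), cols = c(2L, 2L, 0L))
phased_prior <- c(0.25, 0.5, 0.25)
uniform_prior <- rep(1 / 3, 3)

test_that("layout enumeration matches exhaustive counting", {
  # one-carrier block: intersection cell is 1 or 2, everything else fixed
  x <- matrix(0L, 4, 4); x[3, 1] <- 1L
  lay <- enumerate_valid_layouts(encode_block(x))
  expect_identical(nrow(lay), 2L)
  expect_setequal(lay$n1, c(1L, 0L))
  expect_setequal(lay$degeneracy, c(2, 1))

  # all-zero pools: a single layout
  lay0 <- enumerate_valid_layouts(encode_block(matrix(0L, 4, 4)))
  expect_identical(nrow(lay0), 1L)
  expect_true(all(lay0$layout[[1]] == 0L))

  # two-diagonal-carrier observation: count verified against the oracle
  # enumeration over all 3^4 = 81 assignments of the free subgrid
  x2 <- matrix(0L, 4, 4); x2[1, 1] <- 1L; x2[2, 2] <- 1L
  lay2 <- enumerate_valid_layouts(encode_block(x2))
  expect_identical(nrow(lay2), length(oracle_layouts(fig3b)))
})

test_that("a layout with four heterozygotes has 2^4 phased micro-layouts", {
  x <- matrix(0L, 4, 4); x[1, 1] <- 1L; x[1, 2] <- 1L; x[2, 1] <- 1L; x[2, 2] <- 1L
  lay <- enumerate_valid_layouts(encode_block(x))
  i <- which(vapply(lay$layout, function(l) identical(l, x), logical(1)))
  expect_identical(lay$degeneracy[i], 2^4)
})

test_that("exact conditioning agrees with brute-force enumeration", {
  # determined pattern: single layout, one-hot
  expect_equal(posterior_exact(list(rows = c(4L, 0L, 0L), cols = c(4L, 0L, 0L)), 0, 0),
               c(p0 = 1, p1 = 0, p2 = 0))
  # one-carrier pattern under the phased prior: (0, 2/3, 1/3)
  expect_equal(posterior_exact(fig3a, 1, 1, phased_prior),
               c(p0 = 0, p1 = 2 / 3, p2 = 1 / 3))
  # several patterns and priors against the oracle
  pats <- list(fig3a, fig3b,
               list(rows = c(2L, 2L, 0L), cols = c(3L, 1L, 0L)),
               list(rows = c(1L, 3L, 0L), cols = c(1L, 3L, 0L)),
               list(rows = c(0L, 3L, 1L), cols = c(0L, 3L, 1L)))
  for (pat in pats) {
    for (prior in list(phased_prior, uniform_prior, c(0.6, 0.3, 0.1))) {
      expect_equal(unname(posterior_exact(pat, 1, 1, prior)),
                   oracle_cell_posterior(pat, prior), tolerance = 1e-12)
    }
  }
  expect_error(posterior_exact(fig3a, 0, 2), "never observed")
  expect_error(posterior_exact(fig3a, 2, 2), "does not occur")
})

test_that("self-consistent estimation behaves as specified on worked keys", {
  # fully determined key: one-hot in one iteration
  det <- self_consistent_estimate(fig3a, 0, 1)
  expect_equal(det$estimate, c(p0 = 1, p1 = 0, p2 = 0))
  expect_identical(det$iterations, 1L)
  expect_true(det$converged)

  # default weights (1,2,1): the converged iterate matches exact
  # conditioning under the phased prior; the compensated output matches the
  # uniform-prior oracle
  est <- self_consistent_estimate(fig3a, 1, 1)
  expect_true(est$converged)
  expect_equal(unname(est$internal), c(0, 2 / 3, 1 / 3), tolerance = 0.02)
  expect_equal(unname(est$estimate),
               unname(posterior_exact(fig3a, 1, 1, uniform_prior)), tolerance = 0.02)

  # weights (1,1,1): no degeneracy correction; matches the uniform-prior
  # oracle directly
  cfg1 <- estimator_config(weights = c(1, 1, 1))
  est1 <- self_consistent_estimate(fig3a, 1, 1, cfg1)
  expect_equal(unname(est1$estimate),
               unname(posterior_exact(fig3a, 1, 1, uniform_prior)), tolerance = 0.02)

  # the plain (undamped) update is available behind a flag
  cfgp <- estimator_config(damping = "plain", max_iter = 10)
  expect_warning(self_consistent_estimate(fig3a, 1, 1, cfgp), "converge")
})

test_that("estimator output is normalized and 0/2-flip equivariant", {
  pats <- list(fig3a, fig3b, list(rows = c(1L, 3L, 0L), cols = c(2L, 2L, 0L)))
  for (pat in pats) {
    est <- self_consistent_estimate(pat, 1, 1)$estimate
    expect_equal(sum(est), 1, tolerance = 1e-9)
    flipped <- list(rows = rev(pat$rows), cols = rev(pat$cols))
    estf <- self_consistent_estimate(flipped, 1, 1)$estimate
    expect_equal(unname(estf), unname(rev(est)), tolerance = 1e-9)
    exf <- posterior_exact(flipped, 1, 1, phased_prior)
    expect_equal(unname(exf), unname(rev(posterior_exact(pat, 1, 1, phased_prior))),
                 tolerance = 1e-12)
  }
})

test_that("marginal maximum likelihood recovers degenerate and generic optima", {
  expect_equal(mmle_estimate(list(rows = c(4L, 0L, 0L), cols = c(4L, 0L, 0L)))$estimate,
               c(p0 = 1, p1 = 0, p2 = 0))
  expect_equal(mmle_estimate(list(rows = c(0L, 0L, 4L), cols = c(0L, 0L, 4L)))$estimate,
               c(p0 = 0, p1 = 0, p2 = 1))
  # generic pattern: optimum at least as good as a dense simplex grid search
  grid_ll <- function(pat, degeneracy = FALSE) {
    best <- -Inf
    for (p0 in seq(0, 1, by = 0.01)) for (p1 in seq(0, 1 - p0, by = 0.01)) {
      pi <- c(p0, p1, 1 - p0 - p1)
      ll <- 0
      for (x in oracle_layouts(pat)) {
        n <- tabulate(x + 1L, 3L)
        w <- if (degeneracy) 2^n[2] else 1
        ll <- ll + w * prod(pi^n)
      }
      if (ll > best) best <- ll
    }
    log(best)
  }
  for (pat in list(fig3a, fig3b)) {
    fit <- mmle_estimate(pat)
    expect_gte(fit$log_likelihood, grid_ll(pat) - 1e-6)
  }
  fitd <- mmle_estimate(fig3a, degeneracy = TRUE)
  expect_gte(fitd$log_likelihood, grid_ll(fig3a, degeneracy = TRUE) - 1e-6)
})

test_that("the posterior table covers every consistent key of the design", {
  tbl <- small_table()
  expect_s3_class(tbl, "posterior_table")
  expect_true(all(abs(tbl$p0 + tbl$p1 + tbl$p2 - 1) < 1e-9))
  # keys with a homozygous pool are one-hot
  det <- tbl[tbl$r != 1L | tbl$c != 1L, ]
  expect_true(all(pmax(det$p0, det$p1, det$p2) == 1))
  expect_true(all(tbl$converged))

  # the stored patterns are exactly those realized by pooling: census from
  # simulated blocks must be covered
  mc <- mc_conditioning(4, prior = c(0.25, 0.5, 0.25), n_blocks = 2e4, seed = 5)
  expect_true(all(mc$pattern %in% tbl$pattern))

  # q = 2 table: every key checked against the exhaustive oracle census
  tbl2 <- build_posterior_table(2)
  for (i in which(tbl2$r == 1L & tbl2$c == 1L)) {
    pat <- list(rows = as.integer(strsplit(strsplit(tbl2$pattern[i], "|", fixed = TRUE)[[1]][1], ",")[[1]]),
                cols = as.integer(strsplit(strsplit(tbl2$pattern[i], "|", fixed = TRUE)[[1]][2], ",")[[1]]))
    expect_gt(length(oracle_layouts(pat)), 0)
  }
})

test_that("posterior tables serialize to JSON and reload bit-identically", {
  tbl <- small_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_posterior_table(tbl, path)
  tbl2 <- read_posterior_table(path)
  expect_identical(tbl2$pattern, tbl$pattern)
  expect_identical(tbl2$p0, tbl$p0)
  expect_identical(tbl2$p1, tbl$p1)
  expect_identical(tbl2$p2, tbl$p2)
  expect_identical(attr(tbl2, "q"), attr(tbl, "q"))
  expect_equal(attr(tbl2, "cfg"), attr(tbl, "cfg"))
})

test_that("Monte-Carlo conditioning reproduces the exact oracle", {
  mc <- mc_conditioning(4, prior = c(0.25, 0.5, 0.25), n_blocks = 5e4, seed = 42)
  big <- mc[mc$n >= 500, ]
  for (i in seq_len(nrow(big))) {
    ex <- posterior_exact(big$pattern[i], 1, 1, prior = c(0.25, 0.5, 0.25))
    p_hat <- c(big$p0[i], big$p1[i], big$p2[i])
    se <- sqrt(pmax(ex * (1 - ex), 1e-12) / big$n[i])
    expect_true(all(abs(p_hat - ex) <= pmax(4 * se, 0.02)),
                info = paste("pattern", big$pattern[i]))
  }
})

test_that("attach_priors assigns one-hot to decoded and table values to the rest", {
  tbl <- small_table()
  decoded <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    marker_id = "m1",
    status = c("full", "half_alt", "full"),
    pattern = pattern_key(fig3a),
    r = c(0L, 1L, 1L),
    c = c(0L, 1L, 0L),
    gt = c(0L, -1L, 0L)
  )
  out <- attach_priors(decoded, tbl)
  expect_equal(out$p0[1], 1)
  key_row <- tbl[tbl$pattern == pattern_key(fig3a) & tbl$r == 1L & tbl$c == 1L, ]
  expect_equal(out$p1[2], key_row$p1)
  expect_equal(out$p2[2], key_row$p2)
  # GLs come from the GP via the floored log10 map
  expect_equal(out$l1[2], max(log10(key_row$p1), -5))
  # unknown keys are named in the error
  bad <- decoded
  bad$pattern <- "9,9,9|9,9,9"
  expect_error(attach_priors(bad, tbl), "9,9,9")
})
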