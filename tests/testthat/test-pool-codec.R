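test_that("pool encoding follows the allele-detection rule", {
  x0 <- matrix(0L, 4, 4)
  obs0 <- encode_block(x0)
  expect_identical(obs0$pools, rep(0L, 8))
  expect_identical(obs0$pattern, list(rows = c(4L, 0L, 0L), cols = c(4L, 0L, 0L)))

  # one carrier: its row- and column-pool become heterozygous
  for (g in c(1L, 2L)) {
    x1 <- matrix(0L, 4, 4); x1[3, 1] <- g
    obs1 <- encode_block(x1)
    expect_identical(obs1$pools[3], 1L)
    expect_identical(obs1$pools[4 + 1], 1L)
    expect_identical(sum(obs1$pools == 1L), 2L)
    expect_identical(obs1$pattern, list(rows = c(3L, 1L, 0L), cols = c(3L, 1L, 0L)))
  }

  # two carriers in distinct rows and columns
  x2 <- matrix(0L, 4, 4); x2[1, 1] <- 1L; x2[2, 2] <- 1L
  expect_identical(encode_block(x2)$pattern,
                   list(rows = c(2L, 2L, 0L), cols = c(2L, 2L, 0L)))

  expect_error(encode_block(matrix(c(-1L, rep(0L, 15)), 4, 4)), "determined")
})

test_that("pairwise decoding matches the intersection table", {
  expect_identical(decode_pair(0, 0), 0L)
  expect_identical(decode_pair(2, 2), 2L)
  expect_identical(decode_pair(0, 1), 0L)
  expect_identical(decode_pair(1, 0), 0L)
  expect_identical(decode_pair(2, 1), 2L)
  expect_identical(decode_pair(1, 2), 2L)
  expect_identical(decode_pair(1, 1), 0:2)
  expect_error(decode_pair(0, 2), "not consistent")
  expect_error(decode_pair(2, 0), "not consistent")
})

test_that("block decoding reproduces the one- and two-carrier worked examples", {
  # one carrier: the intersection is an ALT half-call, everything else 0
  x1 <- matrix(0L, 4, 4); x1[3, 1] <- 1L
  d1 <- decode_block(encode_block(x1))
  expect_identical(d1$status[3, 1], "half_alt")
  expect_identical(d1$candidates[[3, 1]], c(1L, 2L))
  expect_identical(sum(d1$status == "full"), 15L)
  expect_true(all(d1$gt[d1$status == "full"] == 0L))

  # all-homozygous block: every call full
  d0 <- decode_block(encode_block(matrix(0L, 4, 4)))
  expect_true(all(d0$status == "full"))
  expect_true(all(d0$gt == 0L))

  # two diagonal carriers: exactly 4 fully indeterminate cells
  x2 <- matrix(0L, 4, 4); x2[1, 1] <- 1L; x2[2, 2] <- 1L
  d2 <- decode_block(encode_block(x2))
  expect_identical(sum(d2$status == "missing"), 4L)
  expect_identical(sum(d2$status == "full"), 12L)
  expect_true(all(d2$gt[d2$status == "full"] == 0L))
})

test_that("decoding is sound: calls never contradict the simulated truth", {
  set.seed(402)
  for (rep in 1:60) {
    p <- runif(3); p <- p / sum(p)
    x <- matrix(sample(0:2, 16, replace = TRUE, prob = p), 4, 4)
    d <- decode_block(encode_block(x))
    for (i in 1:4) for (j in 1:4) {
      expect_true(x[i, j] %in% d$candidates[[i, j]])
    }
    # full calls equal the truth; half-calls contain it
    full <- d$status == "full"
    expect_true(all(d$gt[full] == x[full]))
  }
})

test_that("re-encoding any valid completion reproduces the observed pools", {
  set.seed(77)
  for (rep in 1:20) {
    x <- matrix(sample(0:2, 16, replace = TRUE, prob = c(0.6, 0.3, 0.1)), 4, 4)
    obs <- encode_block(x)
    dec <- decode_block(obs)
    if (prod(lengths(dec$candidates)) > 2e5) next  # keep enumeration tractable
    lay <- enumerate_valid_layouts(obs, budget = 2e5)
    for (s in seq_len(min(nrow(lay), 10))) {
      expect_identical(encode_block(lay$layout[[s]])$pools, obs$pools)
    }
  }
})

test_that("a true heterozygote is never returned as a full call", {
  set.seed(88)
  for (rep in 1:80) {
    x <- matrix(sample(0:2, 16, replace = TRUE, prob = c(0.4, 0.35, 0.25)), 4, 4)
    d <- decode_block(encode_block(x))
    het_cells <- which(x == 1L)
    expect_true(all(d$status[het_cells] != "full"))
  }
})

test_that("decoding commutes with the REF/ALT allele flip", {
  set.seed(99)
  for (rep in 1:30) {
    x <- matrix(sample(0:2, 16, replace = TRUE), 4, 4)
    obs <- encode_block(x)
    obs_f <- encode_block(2L - x)
    expect_identical(obs_f$pools, 2L - obs$pools)
    expect_identical(obs_f$pattern$rows, rev(obs$pattern$rows))
    expect_identical(obs_f$pattern$cols, rev(obs$pattern$cols))
    d <- decode_block(obs); df <- decode_block(obs_f)
    swap <- c(full = "full", half_ref = "half_alt", half_alt = "half_ref",
              missing = "missing")
    expect_identical(df$status, matrix(swap[d$status], 4, 4))
    full <- d$status == "full"
    expect_identical(df$gt[full], 2L - d$gt[full])
  }
})

test_that("below the MAF bound, blocks decode to full or carrier calls", {
  # at most one carrier in the block guarantees full decoding up to the
  # carrier's zygosity; under Hardy-Weinberg well below the bound this holds
  # for nearly every genotype
  set.seed(123)
  n_cells <- 0L; n_informative <- 0L
  for (rep in 1:400) {
    maf <- runif(1, 0.001, 0.02)
    g <- sample(0:2, 16, replace = TRUE,
                prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
    x <- matrix(g, 4, 4)
    d <- decode_block(encode_block(x))
    if (sum(x != 0L) <= 1L) {
      expect_true(all(d$status %in% c("full", "half_alt", "half_ref")))
    }
    n_cells <- n_cells + 16L
    n_informative <- n_informative + sum(d$status != "missing")
  }
  expect_gt(n_informative / n_cells, 0.95)
})

test_that("inconsistent pool vectors are rejected", {
  expect_error(decode_block(block_observation(c(0L, 0L, 0L, 2L, 0L, 0L, 0L, 0L), 4)),
               "inconsistent")
  # a lone heterozygous row-pool with all column-pools homozygous REF cannot
  # be explained by any layout
  expect_error(decode_block(block_observation(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 4)),
               "inconsistent")
})
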