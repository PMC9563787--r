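test_that("genetic map interpolation is linear with constant-rate extrapolation", {
  map <- data.frame(pos = c(1e6, 2e6, 4e6), cm = c(1, 3, 4))
  # exact knots
  expect_equal(interpolate_genetic_map(c(1e6, 2e6, 4e6), map), c(1, 3, 4))
  # midpoint between knots (1 cM, 3 cM) -> 2 cM
  expect_equal(interpolate_genetic_map(1.5e6, map), 2)
  # constant-rate extrapolation outside the map
  expect_equal(interpolate_genetic_map(0.5e6, map), 1 - 0.5 * 2)
  expect_equal(interpolate_genetic_map(5e6, map), 4.5)
  # no map: uniform rate, 1 cM per Mb by default
  cm <- interpolate_genetic_map(c(0, 1e6))
  expect_equal(diff(cm), 1)
  expect_error(interpolate_genetic_map(c(2, 1)), "sorted")
})

test_that("panel construction validates its inputs", {
  h <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  p <- haplotype_panel(h, c(100, 200))
  expect_identical(p$n_haps, 2L)
  expect_identical(p$n_markers, 2L)
  expect_error(haplotype_panel(matrix(2L, 1, 1), 1), "alleles")
  expect_error(haplotype_panel(h, c(200, 100)), "strictly increasing")
})

test_that("forward-backward equals brute-force path enumeration", {
  set.seed(314)
  for (rep in 1:12) {
    H <- sample(2:3, 1)
    J <- sample(2:4, 1)
    haps <- matrix(sample(0:1, H * J, replace = TRUE), H, J)
    positions <- sort(sample.int(5e5, J))
    # mix of one-hot, soft and uniform likelihoods
    gp <- t(apply(matrix(rexp(J * 3), J, 3), 1, function(x) x / sum(x)))
    unif <- sample.int(J, max(1, J %/% 2))
    gp[unif, ] <- 1 / 3
    gl <- gp_to_gl(gp)
    panel <- haplotype_panel(haps, positions)
    pars <- hmm_params(recomb_scale = 4e4, err = 1e-4)
    got <- impute_sample(gl, panel, pars)
    want <- oracle_ls_posterior(haps, positions, gl)
    expect_equal(unname(as.matrix(got[, c("p0", "p1", "p2")])), want,
                 tolerance = 1e-10)
  }
})

test_that("a panel of identical haplotypes pins the posterior", {
  haps <- matrix(rep(c(0L, 1L, 0L, 1L), each = 4), nrow = 4)
  panel <- haplotype_panel(haps, positions = c(1, 2, 3, 4) * 1e3)
  gl <- matrix(log10(1 / 3), 4, 3)
  res <- impute_sample(gl, panel)
  expect_identical(res$gt, c(0L, 2L, 0L, 2L))
  expect_true(all(pmax(res$p0, res$p1, res$p2) > 0.999))
})

test_that("masked markers of a panel-recoverable sample are imputed correctly", {
  # a study sample whose two haplotypes are verbatim panel members, with
  # half the markers observed one-hot and the rest uniform
  set.seed(2718)
  J <- 60L; H <- 8L
  founders <- matrix(sample(0:1, 4 * J, replace = TRUE), 4, J)
  haps <- founders[rep(1:4, 2), ]
  panel <- haplotype_panel(haps, positions = seq_len(J) * 1e3)
  truth_pair <- founders[c(1, 2), ]
  truth_g <- truth_pair[1, ] + truth_pair[2, ]
  observed <- seq(1, J, by = 2)
  gp <- gt_to_gp(truth_g)
  gp[setdiff(seq_len(J), observed), ] <- 1 / 3
  res <- impute_sample(gp_to_gl(gp), panel, hmm_params(err = 1e-4))
  masked <- setdiff(seq_len(J), observed)
  expect_gte(mean(res$gt[masked] == truth_g[masked]), 0.99)
})

test_that("posterior mass at the truth grows as more markers are observed", {
  set.seed(555)
  J <- 10L
  haps <- matrix(sample(0:1, 6 * J, replace = TRUE), 6, J)
  panel <- haplotype_panel(haps, positions = seq_len(J) * 1e3)
  truth_g <- haps[1, ] + haps[2, ]
  target <- 4L   # unassayed marker under scrutiny
  masses <- vapply(c(0L, 2L, 4L, 6L), function(n_obs) {
    gp <- matrix(1 / 3, J, 3)
    if (n_obs > 0) {
      obs <- setdiff(seq_len(J), target)[seq_len(n_obs)]
      gp[obs, ] <- gt_to_gp(truth_g[obs])
    }
    res <- impute_sample(gp_to_gl(gp), panel, hmm_params(err = 1e-6))
    as.numeric(res[target, c("p0", "p1", "p2")][[truth_g[target] + 1L]])
  }, numeric(1))
  expect_true(all(diff(masses) >= -1e-9))
})

test_that("cohort imputation is sample-wise independent", {
  set.seed(99)
  J <- 20L
  haps <- matrix(sample(0:1, 10 * J, replace = TRUE), 10, J)
  panel <- haplotype_panel(haps, positions = seq_len(J) * 1e3)
  gl_tbl <- tidyr::expand_grid(sample_id = c("s1", "s2", "s3"),
                               marker_id = panel$marker_ids)
  gp <- t(apply(matrix(rexp(nrow(gl_tbl) * 3), ncol = 3), 1, function(x) x / sum(x)))
  gl <- gp_to_gl(gp)
  gl_tbl$l0 <- gl[, 1]; gl_tbl$l1 <- gl[, 2]; gl_tbl$l2 <- gl[, 3]

  res <- impute_cohort(gl_tbl, panel)
  res_perm <- impute_cohort(gl_tbl[sample.int(nrow(gl_tbl)), ], panel)
  for (s in c("s1", "s2", "s3")) {
    a <- res[res$sample_id == s, ]
    b <- res_perm[res_perm$sample_id == s, ]
    expect_equal(a$p1, b$p1[match(a$marker_id, b$marker_id)])
  }
  # a cohort of one equals the single-sample run
  one <- impute_cohort(gl_tbl[gl_tbl$sample_id == "s1", ], panel)
  direct <- impute_sample(as.matrix(gl_tbl[gl_tbl$sample_id == "s1", c("l0", "l1", "l2")]),
                          panel)
  expect_equal(one$p0, direct$p0)
  expect_error(impute_cohort(dplyr::mutate(gl_tbl, marker_id = "nope"), panel),
               "absent from the panel")
})
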