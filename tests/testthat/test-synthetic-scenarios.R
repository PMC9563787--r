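test_that("population simulation is deterministic and well-formed", {
  cfg <- sim_config(n_markers = 120L, n_panel = 30L, n_study = 16L, seed = 42L)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$panel$haps, p2$panel$haps)
  expect_identical(p1$study_truth, p2$study_truth)
  expect_identical(p1$markers$pos, p2$markers$pos)
  p3 <- simulate_population(sim_config(n_markers = 120L, n_panel = 30L,
                                       n_study = 16L, seed = 43L))
  expect_false(identical(p1$panel$haps, p3$panel$haps))

  expect_identical(dim(p1$panel$haps), c(60L, 120L))
  expect_identical(dim(p1$study_truth), c(16L, 120L))
  expect_true(all(p1$study_truth %in% 0:2))
  expect_true(all(diff(p1$markers$pos) > 0))
  expect_error(sim_config(maf_props = rep(0, 7)), "infeasible")
})

test_that("the realized MAF spectrum matches the configured proportions", {
  cfg <- sim_config(n_markers = 10000L, n_panel = 60L, n_study = 16L, seed = 9L)
  pop <- simulate_population(cfg)
  realized <- table(cut(pop$markers$maf_target, cfg$maf_bins, include.lowest = TRUE))
  props <- as.numeric(realized) / sum(realized)
  expect_true(all(abs(props - cfg$maf_props) < 0.02))
  # the population-wide allele frequency tracks the target
  full_maf <- pop$markers$maf_panel * (2 * cfg$n_panel) +
    pop$markers$maf_study * 0   # panel dominates; just sanity-check the panel
  expect_lt(mean(abs(pop$markers$maf_panel - pop$markers$maf_target)), 0.02)
})

test_that("the LDHD scenario masks exactly the non-LD markers", {
  pop <- small_pop()
  b <- build_ldhd_scenario(pop, ld_fraction = 0.4, seed = 3)
  expect_equal(sum(b$manifest$assayed), round(0.4 * 300))
  # assayed entries carry the truth as one-hot GLs
  kept <- b$manifest$marker_id[b$manifest$assayed]
  expect_setequal(unique(b$study_gl$marker_id), kept)
  one <- b$study_gl[1, ]
  sidx <- match(one$sample_id, pop$study_ids)
  midx <- match(one$marker_id, pop$markers$marker_id)
  g <- pop$study_truth[sidx, midx]
  expect_equal(unname(unlist(one[, c("l0", "l1", "l2")][g + 1L])), 0)
  expect_error(build_ldhd_scenario(pop, ld_fraction = 1.2), "between 0 and 1")
})

test_that("the pooled scenario decodes soundly and monotonically in MAF", {
  pop <- small_pop()
  bundle <- build_pooled_scenario(pop, q = 4, table = small_table(), seed = 7)
  expect_identical(nrow(bundle$manifest), 32L * 300L)

  # full calls never contradict the truth
  man <- bundle$manifest
  sidx <- match(man$sample_id, pop$study_ids)
  midx <- match(man$marker_id, pop$markers$marker_id)
  truth <- pop$study_truth[cbind(sidx, midx)]
  full <- man$status == "full"
  expect_true(all(man$gt[full] == truth[full]))
  # half-calls contain the truth
  expect_true(all(truth[man$status == "half_alt"] %in% 1:2))
  expect_true(all(truth[man$status == "half_ref"] %in% 0:1))

  # a monomorphic marker decodes fully to one-hot priors
  mono <- pop$markers$marker_id[pop$markers$maf_study == 0][1]
  if (!is.na(mono)) {
    sub <- bundle$study_gl[bundle$study_gl$marker_id == mono, ]
    expect_true(all(sub$status == "full"))
    expect_true(all(pmax(sub$p0, sub$p1, sub$p2) == 1))
  }

  # decoding rate decreases across ascending MAF bins
  man$maf <- pop$markers$maf_study[midx]
  rate <- tapply(man$status == "full",
                 cut(man$maf, c(0, 0.02, 0.1, 0.3, 0.5), include.lowest = TRUE),
                 mean)
  rate <- rate[!is.na(rate)]
  expect_true(all(diff(rate) < 0))

  # determinism given the seed
  b2 <- build_pooled_scenario(pop, q = 4, table = small_table(), seed = 7)
  expect_identical(b2$study_gl$p1, bundle$study_gl$p1)
})

test_that("per-marker reassignment is available for stress testing", {
  pop <- simulate_population(sim_config(n_markers = 15L, n_panel = 10L,
                                        n_study = 16L, seed = 5L))
  b <- build_pooled_scenario(pop, q = 4, table = small_table(), seed = 5,
                             reassign_per_marker = TRUE)
  expect_identical(nrow(b$manifest), 16L * 15L)
  man <- b$manifest
  sidx <- match(man$sample_id, pop$study_ids)
  midx <- match(man$marker_id, pop$markers$marker_id)
  truth <- pop$study_truth[cbind(sidx, midx)]
  full <- man$status == "full"
  expect_true(all(man$gt[full] == truth[full]))
})

test_that("priors attached by the pooled scenario are coherent simplices", {
  pop <- small_pop()
  bundle <- build_pooled_scenario(pop, q = 4, table = small_table(), seed = 7)
  gl <- bundle$study_gl
  expect_true(all(abs(gl$p0 + gl$p1 + gl$p2 - 1) < 1e-9))
  # half-ALT priors put no mass on hom-REF
  expect_true(all(gl$p0[gl$status == "half_alt"] == 0))
  expect_true(all(gl$p2[gl$status == "half_ref"] == 0))
})
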