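#' Simulation configuration
#'
#' Parameters of the synthetic population generator. The defaults emulate the
#' statistical structure assumed by the pooled-genotyping experiment at desk
#' scale: a phased reference panel about twice the study cohort, a study size
#' that is a multiple of the pooling block size, and a strongly rare-skewed
#' MAF spectrum (per-bin proportions of a dense genotyping chip, where almost
#' a quarter of markers have MAF < 2%).
#'
#' @param n_markers Number of biallelic SNPs `J`.
#' @param n_founders Number of founder haplotypes the population mosaics are
#'   built from.
#' @param n_panel Reference-panel individuals (each contributes 2 phased
#'   haplotypes).
#' @param n_study Study individuals; must be a multiple of `q^2` for the
#'   pooled scenario.
#' @param maf_bins Bin boundaries of the target MAF spectrum.
#' @param maf_props Per-bin marker proportions (summing to 1). The default is
#'   the dense-chip spectrum `(24.2, 9.9, 5.4, 9.0, 17.1, 23.9, 10.4)%` over
#'   bins `[0, .02, .04, .06, .1, .2, .4, .5]`.
#' @param switch_rate Per-interval probability that a haplotype mosaic
#'   switches founder between consecutive markers.
#' @param spacing_bp Mean marker spacing in base pairs.
#' @param seed Integer seed; the whole population is deterministic given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 2000L,
                       n_founders = 24L,
                       n_panel = 320L,
                       n_study = 160L,
                       maf_bins = c(0, 0.02, 0.04, 0.06, 0.1, 0.2, 0.4, 0.5),
                       maf_props = c(0.2424, 0.0993, 0.0536, 0.0904, 0.1710, 0.2394, 0.1039),
                       switch_rate = 3 / n_markers,
                       spacing_bp = 1000L,
                       seed = 1L) {
  stopifnot(n_markers >= 10, n_founders >= 2, n_panel >= 2, n_study >= 4,
            length(maf_props) == length(maf_bins) - 1L)
  if (any(maf_props < 0) || sum(maf_props) <= 0) {
    stop("infeasible MAF spectrum: proportions must be non-negative and not all zero",
         call. = FALSE)
  }
  maf_props <- maf_props / sum(maf_props)
  structure(
    list(n_markers = as.integer(n_markers), n_founders = as.integer(n_founders),
         n_panel = as.integer(n_panel), n_study = as.integer(n_study),
         maf_bins = maf_bins, maf_props = maf_props,
         switch_rate = switch_rate, spacing_bp = as.integer(spacing_bp),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a reference panel and study population
#'
#' Founder haplotypes carry the allelic variation; every population haplotype
#' is a seeded recombinant mosaic of founders (switching founder between
#' consecutive markers with probability `switch_rate`), so linkage
#' disequilibrium exists and imputation from the panel is learnable. Marker
#' alleles are then assigned to hit a target MAF drawn from the configured
#' spectrum: the ALT carriers at a marker are chosen by filling whole
#' founder-mosaic groups first, so common variants tag founder segments
#' (strong LD) while rare variants live on a subset of one founder's
#' descendants (partial LD) — mimicking recent mutations. The study cohort's
#' true genotypes are the unphased sums of its haplotype pairs.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `scenario_population`: `panel` (a
#'   [haplotype_panel()] of `2 * n_panel` phased haplotypes), `study_truth`
#'   (integer matrix `n_study x J` of true genotypes), `study_ids`,
#'   `markers` (tibble: `marker_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf_target`, `maf_study`, `maf_panel`), and `cfg`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  J <- cfg$n_markers
  n_hap <- 2L * (cfg$n_panel + cfg$n_study)
  local_seed(cfg$seed, {
    positions <- cumsum(pmax(1L, stats::rpois(J, cfg$spacing_bp)))

    # founder mosaic per haplotype: founder index at each marker
    founder_at <- matrix(0L, n_hap, J)
    founder_at[, 1] <- sample.int(cfg$n_founders, n_hap, replace = TRUE)
    switches <- matrix(stats::runif(n_hap * (J - 1)) < cfg$switch_rate, n_hap, J - 1L)
    for (j in 2:J) {
      sw <- switches[, j - 1L]
      founder_at[, j] <- ifelse(sw, sample.int(cfg$n_founders, n_hap, replace = TRUE),
                                founder_at[, j - 1L])
    }

    # target MAFs from the spectrum
    bin_idx <- sample.int(length(cfg$maf_props), J, replace = TRUE, prob = cfg$maf_props)
    lo <- cfg$maf_bins[bin_idx]; hi <- cfg$maf_bins[bin_idx + 1L]
    maf_target <- stats::runif(J, lo, hi)
    carriers_n <- pmax(1L, round(n_hap * maf_target))

    # assign ALT alleles: fill whole founder groups (randomly ordered), then
    # a random subset of the next group
    haps <- matrix(0L, n_hap, J)
    for (j in seq_len(J)) {
      grp <- founder_at[, j]
      ord <- sample.int(cfg$n_founders)
      need <- carriers_n[j]
      carriers <- integer(0)
      for (f in ord) {
        members <- which(grp == f)
        if (length(members) == 0L) next
        if (length(members) <= need) {
          carriers <- c(carriers, members)
          need <- need - length(members)
        } else {
          carriers <- c(carriers, sample(members, need))
          need <- 0L
        }
        if (need == 0L) break
      }
      haps[carriers, j] <- 1L
    }

    panel_haps <- haps[seq_len(2L * cfg$n_panel), , drop = FALSE]
    study_haps <- haps[2L * cfg$n_panel + seq_len(2L * cfg$n_study), , drop = FALSE]
    study_truth <- study_haps[seq(1, nrow(study_haps), by = 2), , drop = FALSE] +
      study_haps[seq(2, nrow(study_haps), by = 2), , drop = FALSE]

    maf_of <- function(m) {
      f <- colMeans(m)
      pmin(f, 1 - f)
    }
    marker_ids <- sprintf("snp%05d", seq_len(J))
    markers <- tibble::tibble(
      marker_id = marker_ids,
      chrom = "1",
      pos = positions,
      ref = "A", alt = "G",
      maf_target = maf_target,
      maf_panel = maf_of(panel_haps),
      maf_study = maf_of(rbind(study_haps))
    )
    structure(
      list(
        panel = haplotype_panel(panel_haps, positions, marker_ids = marker_ids),
        study_truth = study_truth,
        study_ids = sprintf("stu%04d", seq_len(cfg$n_study)),
        markers = markers,
        cfg = cfg
      ),
      class = "scenario_population"
    )
  })
}

#' @export
print.scenario_population <- function(x, ...) {
  cat("Synthetic population:", x$cfg$n_panel, "panel +", x$cfg$n_study,
      "study individuals,", x$cfg$n_markers, "markers\n")
  invisible(x)
}

#' Build the classical low-density-to-high-density scenario
#'
#' Retains full genotypes at a seeded random low-density subset of markers
#' in the study cohort and masks all remaining markers completely (uniform
#' genotype likelihoods), mirroring imputation from a sparse chip to a dense
#' one.
#'
#' @param pop A `scenario_population`.
#' @param ld_fraction Fraction of markers kept at full density, in (0, 1).
#' @param seed Integer seed for the marker subset.
#' @return A list of class `scenario_bundle`: `study_gl` (long tibble
#'   `sample_id`, `marker_id`, `l0`, `l1`, `l2`), `manifest` (tibble
#'   `marker_id`, `assayed`), `scenario = "ldhd"`, and `pop`.
#' @export
build_ldhd_scenario <- function(pop, ld_fraction = 1 / 3, seed = 1L) {
  stopifnot(inherits(pop, "scenario_population"))
  if (!is.numeric(ld_fraction) || ld_fraction <= 0 || ld_fraction >= 1) {
    stop("`ld_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  J <- pop$cfg$n_markers
  n_ld <- max(1L, round(ld_fraction * J))
  ld_idx <- sort(local_seed(seed, sample.int(J, n_ld)))
  assayed <- seq_len(J) %in% ld_idx
  uniform_gl <- gp_to_gl(c(1, 1, 1) / 3)

  grid <- tidyr::expand_grid(sample = seq_len(nrow(pop$study_truth)), marker = ld_idx)
  g <- pop$study_truth[cbind(grid$sample, grid$marker)]
  gl <- gp_to_gl(gt_to_gp(g))
  study_gl <- tibble::tibble(
    sample_id = pop$study_ids[grid$sample],
    marker_id = pop$markers$marker_id[grid$marker],
    l0 = gl[, 1], l1 = gl[, 2], l2 = gl[, 3]
  )
  structure(
    list(study_gl = study_gl,
         manifest = tibble::tibble(marker_id = pop$markers$marker_id, assayed = assayed),
         scenario = "ldhd", pop = pop,
         uniform_gl = uniform_gl),
    class = "scenario_bundle"
  )
}

#' Build the pooled high-density scenario
#'
#' Assigns the study cohort to pooling blocks once (a chip genotypes all
#' markers simultaneously, so one assignment is shared across markers unless
#' `reassign_per_marker` is set for combinatorial stress-testing), simulates
#' pool genotyping and decoding at every marker, and attaches genotype
#' probabilities: one-hot for fully decoded entries, posterior-table
#' estimates for half-calls and missing entries.
#'
#' @param pop A `scenario_population`.
#' @param q Block dimension (study size must be a multiple of `q^2`).
#' @param table A `posterior_table` for `q` (built if `NULL`).
#' @param seed Integer seed for the block assignment.
#' @param reassign_per_marker Draw a fresh block assignment per marker
#'   (stress-testing only; defaults to the chip-realistic shared assignment).
#' @return A list of class `scenario_bundle`: `study_gl` (long tibble with
#'   `sample_id`, `marker_id`, `status`, `pattern`, `r`, `c`, `gt`, `p0`,
#'   `p1`, `p2`, `l0`, `l1`, `l2`), `manifest` (the same without the GP/GL
#'   columns), `assignment` (from [assign_blocks()]), `scenario = "pooled"`,
#'   and `pop`.
#' @export
build_pooled_scenario <- function(pop, q = 4L, table = NULL, seed = 1L,
                                  reassign_per_marker = FALSE) {
  stopifnot(inherits(pop, "scenario_population"))
  q <- as.integer(q)
  n_stu <- nrow(pop$study_truth)
  if (n_stu %% (q * q) != 0L) {
    stop("study size ", n_stu, " is not a multiple of the block size ", q * q,
         call. = FALSE)
  }
  if (is.null(table)) table <- build_posterior_table(q)
  stopifnot(identical(attr(table, "q"), q))
  J <- pop$cfg$n_markers
  n_blocks <- n_stu %/% (q * q)

  assignment <- assign_blocks(pop$study_ids, q = q, seed = seed)
  decode_one_assignment <- function(assignment, marker_subset = seq_len(J)) {
    entries <- vector("list", n_blocks)
    ord <- order(assignment$block, assignment$cell)
    sample_idx <- match(assignment$sample_id[ord], pop$study_ids)
    for (b in seq_len(n_blocks)) {
      cells <- sample_idx[(b - 1L) * q * q + seq_len(q * q)]
      G <- t(pop$study_truth[cells, marker_subset, drop = FALSE])  # J' x q^2
      pools <- encode_block_markers(G, q)
      res <- decode_pools_markers(pools, q)          # cell-major within marker
      res$sample_id <- pop$study_ids[cells][res$cell]
      res$marker_id <- pop$markers$marker_id[marker_subset][res$marker]
      entries[[b]] <- res
    }
    dplyr::bind_rows(entries)
  }
  if (reassign_per_marker) {
    decoded <- dplyr::bind_rows(lapply(seq_len(J), function(m) {
      decode_one_assignment(assign_blocks(pop$study_ids, q = q,
                                          seed = child_seed(seed, m)),
                            marker_subset = m)
    }))
  } else {
    decoded <- decode_one_assignment(assignment)
  }
  decoded <- decoded[, c("sample_id", "marker_id", "status", "pattern", "r", "c", "gt")]
  decoded <- attach_priors(decoded, table)
  manifest <- decoded[, c("sample_id", "marker_id", "status", "pattern", "r", "c", "gt")]
  structure(
    list(study_gl = decoded, manifest = manifest, assignment = assignment,
         scenario = "pooled", pop = pop, q = q),
    class = "scenario_bundle"
  )
}

# Vectorized decoding of one block across markers. Returns a data frame with
# one row per marker x cell: marker, cell, status, pattern key, r, c, gt.
decode_pools_markers <- function(pools, q) {
  J <- nrow(pools)
  rows_part <- pools[, seq_len(q), drop = FALSE]
  cols_part <- pools[, q + seq_len(q), drop = FALSE]
  key_axis <- function(P) {
    paste(rowSums(P == 0L), rowSums(P == 1L), rowSums(P == 2L), sep = ",")
  }
  keys <- paste(key_axis(rows_part), key_axis(cols_part), sep = "|")

  nb <- q * q
  cell <- rep(seq_len(nb), each = J)
  cell_row <- ((cell - 1L) %/% q) + 1L
  cell_col <- ((cell - 1L) %% q) + 1L
  r <- as.integer(rows_part[cbind(rep(seq_len(J), nb), cell_row)])
  cc <- as.integer(cols_part[cbind(rep(seq_len(J), nb), cell_col)])

  gt <- rep(-1L, J * nb)
  status <- rep(NA_character_, J * nb)
  det0 <- (r == 0L) | (cc == 0L)
  det2 <- !det0 & ((r == 2L) | (cc == 2L))
  gt[det0] <- 0L; gt[det2] <- 2L
  status[det0 | det2] <- "full"

  het <- r == 1L & cc == 1L
  if (any(het)) {
    # classify heterozygous intersections per marker via full block decoding,
    # memoized on the pool-genotype vector (few distinct vectors in practice)
    upool <- unique(pools[rowSums(rows_part == 1L) > 0 & rowSums(cols_part == 1L) > 0, ,
                          drop = FALSE])
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(upool))) {
      pv <- upool[i, ]
      dec <- decode_block(block_observation(pv, q))
      assign(paste(pv, collapse = ""), dec$status, envir = cache)
    }
    pool_key <- apply(pools, 1, paste, collapse = "")
    mk <- rep(seq_len(J), nb)
    for (idx in which(het)) {
      st <- get(pool_key[mk[idx]], envir = cache)
      status[idx] <- st[cell_row[idx], cell_col[idx]]
    }
  }
  data.frame(
    marker = rep(seq_len(J), nb), cell = cell,
    status = status, pattern = keys[rep(seq_len(J), nb)],
    r = r, c = cc, gt = gt,
    stringsAsFactors = FALSE
  )
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("Scenario bundle:", x$scenario, "\n")
  if (x$scenario == "pooled") {
    cat("  entries by status:\n")
    print(table(x$manifest$status))
  } else {
    cat("  assayed markers:", sum(x$manifest$assayed), "of", nrow(x$manifest), "\n")
  }
  invisible(x)
}

#' @export
glance.scenario_bundle <- function(x, ...) {
  if (x$scenario == "pooled") {
    st <- table(factor(x$manifest$status, levels = c("full", "half_ref", "half_alt", "missing")))
    tibble::tibble(
      scenario = "pooled",
      n_entries = nrow(x$manifest),
      prop_full = as.numeric(st["full"]) / nrow(x$manifest),
      prop_half = as.numeric(st["half_ref"] + st["half_alt"]) / nrow(x$manifest),
      prop_missing = as.numeric(st["missing"]) / nrow(x$manifest)
    )
  } else {
    tibble::tibble(
      scenario = "ldhd",
      n_entries = nrow(x$study_gl),
      prop_assayed = mean(x$manifest$assayed)
    )
  }
}
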