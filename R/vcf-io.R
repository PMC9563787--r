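#' Write study genotype data as VCF 4.2
#'
#' Serializes a long tibble of per-sample, per-marker genotype records to a
#' plain-text VCF with FORMAT fields drawn from `GT:GP:GL`. Full calls are
#' written unphased (`0/0`, `0/1`, `1/1`), half-calls with the known allele
#' (`0/.`, `./1`) and missing as `./.`; GP in probability space, GL in log10
#' space at 3 decimals (so a uniform entry prints as `-0.481`).
#'
#' @param geno Long tibble with `sample_id`, `marker_id` and, depending on
#'   `fields`: `gt` (+ optional `status` for half-calls), `p0`..`p2`,
#'   `l0`..`l2`.
#' @param markers Marker metadata tibble with `marker_id`, `chrom`, `pos`,
#'   `ref`, `alt` (output order follows this table).
#' @param path Output file path.
#' @param fields Character subset of `c("GT", "GP", "GL")`.
#' @param meta Named list written as `##poolgt_<name>=<value>` header lines
#'   (e.g. tool version, seed, design q); parseable back by [read_vcf()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, markers, path, fields = c("GT", "GP", "GL"),
                      meta = list()) {
  fields <- match.arg(fields, c("GT", "GP", "GL"), several.ok = TRUE)
  stopifnot(all(c("sample_id", "marker_id") %in% names(geno)),
            all(c("marker_id", "chrom", "pos", "ref", "alt") %in% names(markers)))
  samples <- unique(geno$sample_id)
  J <- nrow(markers)

  fmt_parts <- list()
  if ("GT" %in% fields) {
    stopifnot("gt" %in% names(geno))
    status <- if ("status" %in% names(geno)) geno$status else rep("full", nrow(geno))
    gt_str <- dplyr::case_when(
      status == "half_alt" ~ "./1",
      status == "half_ref" ~ "0/.",
      is.na(geno$gt) | geno$gt == -1L ~ "./.",
      geno$gt == 0L ~ "0/0",
      geno$gt == 1L ~ "0/1",
      geno$gt == 2L ~ "1/1"
    )
    fmt_parts$GT <- gt_str
  }
  if ("GP" %in% fields) {
    stopifnot(all(c("p0", "p1", "p2") %in% names(geno)))
    fmt_parts$GP <- sprintf("%.5g,%.5g,%.5g", geno$p0, geno$p1, geno$p2)
  }
  if ("GL" %in% fields) {
    # GL serialization follows the printed convention of rounding the
    # probabilities to 2 decimals first, so a uniform entry prints as
    # (-0.481, -0.481, -0.481); raw l-columns are used when GPs are absent
    if (all(c("p0", "p1", "p2") %in% names(geno))) {
      gl <- log10(pmax(round(cbind(geno$p0, geno$p1, geno$p2), 2), 1e-5))
    } else {
      stopifnot(all(c("l0", "l1", "l2") %in% names(geno)))
      gl <- cbind(geno$l0, geno$l1, geno$l2)
    }
    fmt_parts$GL <- sprintf("%.3f,%.3f,%.3f", gl[, 1], gl[, 2], gl[, 3])
  }
  entry <- do.call(paste, c(fmt_parts, sep = ":"))

  # entries laid out markers x samples
  mi <- match(geno$marker_id, markers$marker_id)
  si <- match(geno$sample_id, samples)
  if (any(is.na(mi))) stop("genotype records reference unknown markers", call. = FALSE)
  body <- matrix(paste(rep(".", length(fields)), collapse = ":"), J, length(samples))
  body[cbind(mi, si)] <- entry

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolgt",
    sprintf("##poolgt_%s=%s", names(meta), vapply(meta, as.character, character(1))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype probabilities">',
    '##FORMAT=<ID=GL,Number=G,Type=Float,Description="Log10 genotype likelihoods">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t")
  )
  if (length(meta) == 0) hdr <- hdr[hdr != ""]
  fixed <- paste(markers$chrom, markers$pos, markers$marker_id, markers$ref,
                 markers$alt, ".", "PASS", ".", paste(fields, collapse = ":"),
                 sep = "\t")
  lines <- c(hdr, paste(fixed, apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into long genotype records
#'
#' Parses a (plain or gzipped) VCF via the `vcfR` package. GT supports
#' half-calls and missing entries; GP/GL are parsed as numeric triples.
#' Multi-allelic records are rejected and counted.
#'
#' @param path VCF file path.
#' @param fields FORMAT fields to extract, subset of `c("GT", "GP", "GL")`.
#' @return A list with `markers` (tibble `marker_id`, `chrom`, `pos`, `ref`,
#'   `alt`), `data` (long tibble `sample_id`, `marker_id` + requested
#'   fields: `gt`/`status`, `p0`..`p2`, `l0`..`l2`), `meta` (named list of
#'   `##poolgt_*` header entries), `n_rejected` (multi-allelic count).
#' @export
read_vcf <- function(path, fields = c("GT", "GP", "GL")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  fields <- match.arg(fields, c("GT", "GP", "GL"), several.ok = TRUE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  n_rejected <- sum(multi)
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  markers <- tibble::tibble(
    marker_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  have <- strsplit(v@gt[1, "FORMAT"], ":")[[1]]
  miss_f <- setdiff(fields, have)
  if (length(miss_f) > 0) {
    stop("FORMAT field(s) absent from VCF: ", paste(miss_f, collapse = ", "),
         call. = FALSE)
  }
  samples <- colnames(v@gt)[-1]
  out <- tidyr::expand_grid(marker_id = markers$marker_id, sample_id = samples)
  if ("GT" %in% fields) {
    gtm <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    gtv <- as.vector(t(gtm))   # sample-fastest to match expand_grid order
    gtv <- gsub("|", "/", gtv, fixed = TRUE)
    status <- dplyr::case_when(
      gtv %in% c("0/0", "0/1", "1/0", "1/1") ~ "full",
      gtv %in% c("./1", "1/.") ~ "half_alt",
      gtv %in% c("0/.", "./0") ~ "half_ref",
      TRUE ~ "missing"
    )
    gt <- dplyr::case_when(
      gtv == "0/0" ~ 0L,
      gtv %in% c("0/1", "1/0") ~ 1L,
      gtv == "1/1" ~ 2L,
      TRUE ~ -1L
    )
    out$gt <- gt
    out$status <- status
  }
  parse_triplet <- function(el, prefix) {
    m <- vcfR::extract.gt(v, element = el)[keep, , drop = FALSE]
    vals <- strsplit(as.vector(t(m)), ",", fixed = TRUE)
    num <- matrix(as.numeric(unlist(vals)), ncol = 3L, byrow = TRUE)
    colnames(num) <- paste0(prefix, 0:2)
    num
  }
  if ("GP" %in% fields) out <- dplyr::bind_cols(out, tibble::as_tibble(parse_triplet("GP", "p")))
  if ("GL" %in% fields) out <- dplyr::bind_cols(out, tibble::as_tibble(parse_triplet("GL", "l")))
  meta_lines <- grep("^##poolgt_", v@meta, value = TRUE)
  meta <- list()
  if (length(meta_lines) > 0) {
    kv <- sub("^##poolgt_", "", meta_lines)
    meta <- stats::setNames(as.list(sub("^[^=]*=", "", kv)), sub("=.*$", "", kv))
  }
  list(markers = markers, data = out[, c("sample_id", "marker_id",
                                         setdiff(names(out), c("sample_id", "marker_id")))],
       meta = meta, n_rejected = n_rejected)
}

#' Write a phased haplotype panel as VCF
#'
#' @param panel A [haplotype_panel()].
#' @param markers Marker metadata tibble (as in [write_vcf()]); defaults to
#'   generic metadata from the panel.
#' @param path Output file path.
#' @param meta Named list of `##poolgt_*` header entries.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, markers = NULL, meta = list()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (panel$n_haps %% 2L != 0L) stop("panel must hold haplotype pairs", call. = FALSE)
  if (is.null(markers)) {
    markers <- tibble::tibble(marker_id = panel$marker_ids, chrom = "1",
                              pos = panel$positions, ref = "A", alt = "G")
  }
  n_ind <- panel$n_haps %/% 2L
  ids <- sprintf("pnl%04d", seq_len(n_ind))
  h1 <- panel$haps[seq(1, panel$n_haps, 2), , drop = FALSE]
  h2 <- panel$haps[seq(2, panel$n_haps, 2), , drop = FALSE]
  body <- matrix(paste0(t(h1), "|", t(h2)), nrow = panel$n_markers)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolgt",
    sprintf("##poolgt_%s=%s", names(meta), vapply(meta, as.character, character(1))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            ids), collapse = "\t")
  )
  fixed <- paste(markers$chrom, markers$pos, markers$marker_id, markers$ref,
                 markers$alt, ".", "PASS", ".", "GT", sep = "\t")
  writeLines(c(hdr, paste(fixed, apply(body, 1, paste, collapse = "\t"), sep = "\t")),
             path)
  invisible(path)
}

#' Read a phased panel VCF into a haplotype panel
#'
#' @param path VCF path with phased GT (`a|b`).
#' @param map,rate_cm_per_mb Passed to [haplotype_panel()].
#' @return A [haplotype_panel()].
#' @export
read_panel_vcf <- function(path, map = NULL, rate_cm_per_mb = 1) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gtm <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("|", gtm, fixed = TRUE))) {
    stop("panel VCF must contain phased genotypes (a|b)", call. = FALSE)
  }
  a1 <- substr(gtm, 1, 1); a2 <- substr(gtm, 3, 3)
  J <- nrow(gtm); n <- ncol(gtm)
  haps <- matrix(0L, 2L * n, J)
  haps[seq(1, 2 * n, 2), ] <- t(matrix(as.integer(a1), J, n))
  haps[seq(2, 2 * n, 2), ] <- t(matrix(as.integer(a2), J, n))
  haplotype_panel(haps, positions = as.integer(v@fix[, "POS"]),
                  marker_ids = v@fix[, "ID"], map = map,
                  rate_cm_per_mb = rate_cm_per_mb)
}

#' Write pool pseudo-samples as VCF
#'
#' One pseudo-sample per pool, named `<block>_R<i>` / `<block>_C<j>`, with
#' the pool's encoded genotype in GT.
#'
#' @param pool_gt Long tibble with `block`, `pool` (e.g. `"R1"`), `marker_id`,
#'   `gt` (pool genotype in 0/1/2).
#' @param markers Marker metadata tibble.
#' @param path Output file path.
#' @param meta Named list of header entries.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(pool_gt, markers, path, meta = list()) {
  stopifnot(all(c("block", "pool", "marker_id", "gt") %in% names(pool_gt)))
  geno <- tibble::tibble(
    sample_id = paste0("B", pool_gt$block, "_", pool_gt$pool),
    marker_id = pool_gt$marker_id,
    gt = pool_gt$gt
  )
  write_vcf(geno, markers, path, fields = "GT", meta = meta)
}

#' Read a 2-column genetic map file
#'
#' Plain text, whitespace- or tab-separated, columns `pos` (bp) and `cm`;
#' lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return A data frame with columns `pos`, `cm`.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("pos", "cm"))
  df[order(df$pos), ]
}
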