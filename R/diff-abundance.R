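#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with average
#' ranks, tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors (independent groups), each non-empty.
#' @return Two-sided p-value (`NA` when every value across both groups is
#'   identical, leaving the statistic without variance).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  comb <- c(x, y)
  exact <- length(comb) <= 20L && !anyDuplicated(comb)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  if (is.nan(p)) NA_real_ else p
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped. The null is enumerated exactly over the
#' 2^n sign assignments when at most 25 non-zero differences remain and
#' their absolute values are untied; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param paired_diffs Numeric vector of paired differences.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(paired_diffs) {
  d <- paired_diffs[paired_diffs != 0]
  if (!length(d)) stop("all paired differences are zero")
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  p <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value)
  if (is.nan(p)) NA_real_ else p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` entries are passed through).
#' @return Adjusted p-values in the input order.
#' @export
bh_correct <- function(p) {
  pv <- p[!is.na(p)]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Parameters of the bootstrapped differential-abundance procedure
#'
#' @param subsample_fraction Fraction of each class's samples drawn (without
#'   replacement) in every inner repetition; default 0.5.
#' @param n_median_reps Inner repetitions per bootstrap iteration, i.e. the
#'   length of each class's median vector; default 40.
#' @param n_bootstraps Outer bootstrap iterations; default 1000.
#' @param fdr Benjamini-Hochberg threshold on adjusted p-values; default
#'   0.0001.
#' @param retention_fraction Fraction of bootstrap iterations in which a
#'   taxon must be flagged to be retained; default 0.995.
#' @param seed Integer master seed.
#' @return Validated `boot_diff_params` list.
#' @export
boot_diff_params <- function(subsample_fraction = 0.5, n_median_reps = 40L,
                             n_bootstraps = 1000L, fdr = 1e-4,
                             retention_fraction = 0.995, seed = 1L) {
  if (!(subsample_fraction > 0 && subsample_fraction <= 1))
    stop("subsample_fraction must be in (0, 1]")
  if (n_median_reps < 1L || n_bootstraps < 1L)
    stop("n_median_reps and n_bootstraps must be >= 1")
  if (!(fdr > 0 && fdr < 1)) stop("fdr must be in (0, 1)")
  if (!(retention_fraction > 0 && retention_fraction <= 1))
    stop("retention_fraction must be in (0, 1]")
  structure(list(subsample_fraction = subsample_fraction,
                 n_median_reps = as.integer(n_median_reps),
                 n_bootstraps = as.integer(n_bootstraps),
                 fdr = fdr, retention_fraction = retention_fraction,
                 seed = as.integer(seed)),
            class = "boot_diff_params")
}

#' Bootstrapped differential-abundance analysis
#'
#' For each of `n_bootstraps` outer iterations: draw, `n_median_reps` times,
#' a random `subsample_fraction` of the samples of each class (without
#' replacement; one draw shared by all taxa) and record each taxon's median
#' relative abundance, giving two median vectors per taxon; test each taxon
#' with the Wilcoxon rank-sum normal approximation between the two vectors;
#' adjust across taxa by Benjamini-Hochberg; flag taxa with adjusted
#' p <= `fdr`. Taxa flagged in at least `retention_fraction` of the outer
#' iterations are called significant. The direction of change is taken from
#' the overall per-class median relative abundances.
#'
#' Taxa with zero abundance in every sample of both classes are dropped
#' before testing (their medians are constant and the test statistic has no
#' variance). Each outer iteration draws from its own RNG substream derived
#' from the master seed, so results do not depend on iteration order.
#'
#' @param table An `abundance_table`; counts are converted to percent.
#' @param meta A `sample_meta` data frame; both classes need >= 2 samples.
#' @param params A [boot_diff_params()].
#' @return A `diff_abundance_result` data frame with one row per tested
#'   taxon: `taxon_id`, `retention_fraction_observed`, `significant`,
#'   `direction`, per-class pooled relative contribution, median and range.
#' @export
bootstrapped_diff <- function(table, meta, params = boot_diff_params()) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(params, "boot_diff_params"))
  if (table_unit(table) == "counts") table <- to_relative(table)
  idx_les <- which(colnames(table) %in%
                     meta$sample_id[meta$klass == "lesional"])
  idx_non <- which(colnames(table) %in%
                     meta$sample_id[meta$klass == "non_lesional"])
  if (length(idx_les) < 2L || length(idx_non) < 2L)
    stop("each class needs >= 2 samples")
  k_les <- floor(params$subsample_fraction * length(idx_les))
  k_non <- floor(params$subsample_fraction * length(idx_non))
  if (k_les < 1L || k_non < 1L) stop("subsample size is 0 for a class")

  m <- unclass(table)
  keep <- rowSums(m[, c(idx_les, idx_non), drop = FALSE]) > 0
  dropped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) stop("no taxon with non-zero abundance in either class")

  reps <- params$n_median_reps
  hits <- integer(nrow(m))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  # RNG substreams are keyed to the sample groups themselves (ordered by
  # their first sample id), not to the class labels, so relabelling the
  # classes reuses the same subsample draws and flips results exactly
  first_is_les <- min(colnames(table)[idx_les]) <
    min(colnames(table)[idx_non])
  draw <- function(idx, k, s) {
    set.seed(s)
    matrix(vapply(seq_len(reps), function(r)
      idx[sample.int(length(idx), k)], integer(k)), nrow = k)
  }
  for (b in seq_len(params$n_bootstraps)) {
    s1 <- .substream(params$seed, 2L * b)
    s2 <- .substream(params$seed, 2L * b + 1L)
    if (first_is_les) {
      ia <- draw(idx_les, k_les, s1)
      ib <- draw(idx_non, k_non, s2)
    } else {
      ib <- draw(idx_non, k_non, s1)
      ia <- draw(idx_les, k_les, s2)
    }
    p <- .boot_iteration_pvalues(m, ia, ib)
    padj <- bh_correct(p)
    marked <- !is.na(padj) & padj <= params$fdr
    hits <- hits + marked
  }
  retention <- hits / params$n_bootstraps

  med_les <- apply(m[, idx_les, drop = FALSE], 1L, stats::median)
  med_non <- apply(m[, idx_non, drop = FALSE], 1L, stats::median)
  direction <- ifelse(med_les > med_non, "higher_in_lesional",
                      ifelse(med_les < med_non, "higher_in_non_lesional",
                             "undetermined"))
  contrib_les <- relative_contribution(table, meta, "lesional")[rownames(m)]
  contrib_non <- relative_contribution(table, meta, "non_lesional")[rownames(m)]
  res <- data.frame(
    taxon_id = rownames(m),
    retention_fraction_observed = retention,
    significant = retention >= params$retention_fraction,
    direction = direction,
    contrib_lesional = unname(contrib_les),
    contrib_non_lesional = unname(contrib_non),
    median_lesional = unname(med_les),
    median_non_lesional = unname(med_non),
    min_lesional = apply(m[, idx_les, drop = FALSE], 1L, min),
    max_lesional = apply(m[, idx_les, drop = FALSE], 1L, max),
    min_non_lesional = apply(m[, idx_non, drop = FALSE], 1L, min),
    max_non_lesional = apply(m[, idx_non, drop = FALSE], 1L, max),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "dropped_taxa") <- dropped
  attr(res, "params") <- params
  class(res) <- c("diff_abundance_result", "data.frame")
  res
}

#' Write a differential-abundance result table to TSV
#'
#' Columns mirror the per-class report layout of the analysis: pooled
#' relative contribution, median and range per class, and the direction
#' flag; rows are sorted by taxon id for stable diffs.
#'
#' @param result A `diff_abundance_result`.
#' @param path Output path.
#' @param only_significant Write only retained taxa (default TRUE).
#' @return `path`, invisibly.
#' @export
write_diff_result <- function(result, path, only_significant = TRUE) {
  df <- as.data.frame(result)
  if (only_significant) df <- df[df$significant, , drop = FALSE]
  df <- df[order(df$taxon_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
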