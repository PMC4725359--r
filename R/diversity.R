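#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \ln p_i} over the non-zero parts of a composition,
#' natural logarithm.
#'
#' @param p Non-negative composition vector summing to 1 (renormalization is
#'   not applied; a tolerance of 1e-6 on the sum is enforced). Zeros are
#'   skipped.
#' @return Shannon index (nats).
#' @export
shannon <- function(p) {
  .check_composition(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Simpson evenness index (1 - D)
#'
#' \eqn{1 - \sum p_i^2}: probability that two random assignments belong to
#' different taxa.
#'
#' @inheritParams shannon
#' @return Value in [0, 1).
#' @export
simpson_1_minus_D <- function(p) {
  .check_composition(p)
  1 - sum(p^2)
}

.check_composition <- function(p) {
  if (any(p < 0)) stop("composition has negative entries")
  if (abs(sum(p) - 1) > 1e-6)
    stop("composition must sum to 1 (got ", format(sum(p)), ")")
  invisible(TRUE)
}

#' Bias-corrected Chao-1 richness estimator
#'
#' \eqn{S_{obs} + F_1(F_1 - 1) / (2 (F_2 + 1))} with \eqn{F_1} singletons
#' and \eqn{F_2} doubletons. The bias-corrected form is used so the
#' estimator is defined when no doubletons are observed.
#'
#' @param counts Vector of non-negative integer counts per taxon.
#' @return Estimated richness; equals observed richness when there are no
#'   singletons.
#' @export
chao1 <- function(counts) {
  .check_counts(counts)
  counts <- counts[counts > 0]
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

.check_counts <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be integers")
  invisible(TRUE)
}

#' Fisher's alpha
#'
#' Solves \eqn{S = \alpha \ln(1 + N/\alpha)} for \eqn{\alpha} by bracketed
#' root finding to 1e-9, where S is observed richness and N the total count.
#'
#' @param S Observed richness (>= 1).
#' @param N Total count (>= S).
#' @return Fisher's alpha.
#' @export
fisher_alpha <- function(S, N) {
  if (S < 1 || N < S) stop("need 1 <= S <= N")
  if (S == N)
    stop("S == N (all singletons): Fisher's alpha has no finite solution")
  f <- function(a) a * log1p(N / a) - S
  # f is increasing in alpha; bracket grows until sign change
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Good's coverage
#'
#' \eqn{1 - F_1/N}: estimated fraction of the community captured by the
#' sample (singletons F1, total reads N).
#'
#' @param counts Vector of non-negative integer counts per taxon.
#' @return Coverage in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  .check_counts(counts)
  N <- sum(counts)
  if (N == 0) stop("empty sample")
  1 - sum(counts == 1) / N
}

#' Rarefaction curve
#'
#' Mean observed richness in random subsamples drawn without replacement at
#' each requested depth. `method = "exact"` evaluates the hypergeometric
#' closed form \eqn{\sum_i (1 - C(N - n_i, d)/C(N, d))} instead of
#' resampling.
#'
#' @param counts Count vector for one sample.
#' @param depths Integer subsample depths, each <= sum(counts).
#' @param reps Number of Monte-Carlo subsamples per depth.
#' @param seed RNG seed for the Monte-Carlo path.
#' @param method `"montecarlo"` (default) or `"exact"`.
#' @return Data frame with columns `depth` and `richness`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 10L, seed = 1L,
                              method = c("montecarlo", "exact")) {
  method <- match.arg(method)
  .check_counts(counts)
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds sample total ", N)
  if (any(depths < 1)) stop("depths must be >= 1")
  rich <- if (method == "exact") {
    vapply(depths, function(d) {
      sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
    }, numeric(1))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    pool <- rep.int(seq_along(counts), counts)
    vapply(depths, function(d) {
      if (d == N) return(length(counts))  # exhaustive subsample
      mean(vapply(seq_len(reps), function(r) {
        length(unique(pool[sample.int(N, d)]))
      }, numeric(1)))
    }, numeric(1))
  }
  data.frame(depth = as.integer(depths), richness = rich)
}

#' Per-sample alpha-diversity panel
#'
#' Computes, for every sample of a counts table, the richness estimators
#' (Chao-1, Fisher's alpha), Shannon diversity, Simpson evenness (1 - D)
#' and Good's coverage.
#'
#' @param table A counts `abundance_table`.
#' @param meta Optional `sample_meta`; adds a `class` column.
#' @return Data frame, one row per sample.
#' @export
diversity_report <- function(table, meta = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (table_unit(table) != "counts")
    stop("diversity_report() expects a counts table")
  out <- do.call(rbind, lapply(colnames(table), function(s) {
    x <- unclass(table)[, s]
    p <- x / sum(x)
    data.frame(sample_id = s,
               observed_richness = sum(x > 0),
               chao1 = chao1(x),
               fisher_alpha = fisher_alpha(sum(x > 0), sum(x)),
               shannon = shannon(p),
               simpson_1_minus_D = simpson_1_minus_D(p),
               goods_coverage = goods_coverage(x))
  }))
  if (!is.null(meta))
    out$class <- meta$klass[match(out$sample_id, meta$sample_id)]
  out
}

#' Paired class comparison of diversity indices
#'
#' Wilcoxon signed-rank test on subject-paired index values (lesional minus
#' non-lesional), one row per index.
#'
#' @param report Output of [diversity_report()] (needs a `class` column).
#' @param meta `sample_meta` providing subject pairing.
#' @return Data frame with index name, median difference and p-value.
#' @export
compare_diversity <- function(report, meta) {
  idx <- c("observed_richness", "chao1", "fisher_alpha", "shannon",
           "simpson_1_minus_D")
  subj <- meta$subject_id[match(report$sample_id, meta$sample_id)]
  kl <- meta$klass[match(report$sample_id, meta$sample_id)]
  do.call(rbind, lapply(idx, function(v) {
    les <- report[[v]][kl == "lesional"][order(subj[kl == "lesional"])]
    non <- report[[v]][kl == "non_lesional"][order(subj[kl == "non_lesional"])]
    d <- les - non
    p <- if (all(d == 0)) NA_real_ else wilcoxon_signed_rank(d)
    data.frame(index = v, median_diff = stats::median(d), p_value = p)
  }))
}

#' Successive relative-contribution differences (evenness curve)
#'
#' Retains taxa at or above `min_pct` percent relative contribution, sorts
#' them in descending order, and returns the differences between successive
#' contributions together with the slope of a logarithmic trend line
#' (least-squares fit of difference against the natural log of the rank
#' position). A steep positive slope magnitude indicates one or a few
#' dominating taxa; a flat curve indicates an even community.
#'
#' @param contrib Named numeric vector of percent contributions.
#' @param min_pct Minimum contribution retained (default 1 percent).
#' @return List of class `evenness_curve`: `taxa`, `contributions`,
#'   `differences`, `slope`.
#' @export
successive_contribution_differences <- function(contrib, min_pct = 1) {
  if (min_pct < 0) stop("min_pct must be >= 0")
  keep <- sort(contrib[contrib >= min_pct], decreasing = TRUE)
  if (length(keep) < 2L)
    stop("fewer than 2 taxa at or above ", min_pct, "% contribution")
  d <- -diff(unname(keep))
  pos <- seq_along(d)
  slope <- if (length(d) >= 2L)
    unname(stats::coef(stats::lm(d ~ log(pos)))[2L]) else 0
  if (is.na(slope)) slope <- 0  # single predictor value or all-equal diffs
  structure(list(taxa = names(keep), contributions = unname(keep),
                 differences = d, slope = slope),
            class = "evenness_curve")
}

#' Count taxa at or above contribution thresholds
#'
#' @param contrib Named numeric vector of percent contributions.
#' @param thresholds Positive percent thresholds (default 0.01, 0.1, 1).
#' @return Named integer vector (one count per threshold); counts are
#'   non-increasing in the threshold.
#' @export
taxa_at_thresholds <- function(contrib, thresholds = c(0.01, 0.1, 1)) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  stats::setNames(vapply(thresholds, function(t) sum(contrib >= t),
                         integer(1)),
                  format(thresholds, trim = TRUE, scientific = FALSE))
}
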