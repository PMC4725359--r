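#' Identify core taxa of a sample class
#'
#' A taxon is core to a class when its per-sample relative abundance is at
#' least `min_pct` percent in at least `ceiling(min_prev * n)` of the
#' class's n samples ("at least" semantics on the prevalence fraction, so
#' 80% of 10 samples means 8 samples).
#'
#' @param table A percent `abundance_table` (counts tables are converted).
#' @param meta A `sample_meta` data frame.
#' @param klass `"lesional"` or `"non_lesional"`.
#' @param min_pct Minimum per-sample relative abundance, percent
#'   (default 0.1).
#' @param min_prev Minimum prevalence fraction (default 0.8).
#' @return A `core_set`: list with `klass`, `members` (character vector) and
#'   `parameters`.
#' @export
core_taxa <- function(table, meta, klass, min_pct = 0.1, min_prev = 0.8) {
  stopifnot(inherits(table, "abundance_table"))
  klass <- match.arg(klass, c("lesional", "non_lesional"))
  if (table_unit(table) == "counts") table <- to_relative(table)
  ids <- intersect(colnames(table), meta$sample_id[meta$klass == klass])
  if (!length(ids)) stop("no samples of class '", klass, "'")
  sub <- unclass(table)[, ids, drop = FALSE]
  need <- ceiling(min_prev * length(ids))
  prev <- rowSums(sub >= min_pct)
  structure(list(klass = klass,
                 members = rownames(sub)[prev >= need],
                 parameters = c(min_pct = min_pct, min_prev = min_prev)),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set [%s]: %d taxa (>= %g%% in >= %g%% of samples)\n",
              x$klass, length(x$members), x$parameters[["min_pct"]],
              100 * x$parameters[["min_prev"]]))
  invisible(x)
}

#' Compare two core sets
#'
#' @param a,b `core_set` objects over the same taxon universe.
#' @return List with `common`, `exclusive_a`, `exclusive_b` (character
#'   vectors partitioning the union of members).
#' @export
compare_cores <- function(a, b) {
  stopifnot(inherits(a, "core_set"), inherits(b, "core_set"))
  list(common = intersect(a$members, b$members),
       exclusive_a = setdiff(a$members, b$members),
       exclusive_b = setdiff(b$members, a$members))
}
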