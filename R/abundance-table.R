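#' Construct an abundance table
#'
#' An abundance table is the substrate of every analysis stage in this
#' package: a numeric matrix of taxa (rows) by samples (columns) holding
#' either raw assignment counts or relative abundances in percent.
#'
#' @param values Numeric matrix, taxa in rows and samples in columns, with
#'   row and column names set to taxon and sample identifiers.
#' @param unit Either `"counts"` or `"percent"`. Percent tables must have
#'   column sums of 100; columns within 0.5 of 100 are renormalized, anything
#'   further off is rejected.
#' @return An object of class `abundance_table`: the validated matrix with a
#'   `unit` attribute.
#' @examples
#' m <- matrix(c(10, 90, 40, 60), nrow = 2,
#'             dimnames = list(c("Corynebacterium", "Staphylococcus"),
#'                             c("A1N1", "A1V1")))
#' abundance_table(m, unit = "counts")
#' @export
abundance_table <- function(values, unit = c("counts", "percent")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have taxon row names and sample column names")
  dup_t <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_t))
    stop("duplicate taxon id(s): ", paste(dup_t, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(values))
    stop("abundance values must not contain NA")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (unit == "percent") {
    cs <- colSums(values)
    off <- abs(cs - 100)
    if (any(off > 0.5)) {
      bad <- colnames(values)[which.max(off)]
      stop(sprintf("percent column '%s' sums to %.4f, not 100", bad,
                   cs[which.max(off)]))
    }
    if (any(off > 1e-6))
      values <- sweep(values, 2, cs / 100, "/")
  }
  structure(values, unit = unit, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples [%s]\n",
              nrow(x), ncol(x), table_unit(x)))
  m <- unclass(x)
  attr(m, "unit") <- NULL
  print(utils::head(m[, seq_len(min(6L, ncol(m))), drop = FALSE], 8L), ...)
  invisible(x)
}

#' Unit of an abundance table
#' @param table An `abundance_table`.
#' @return `"counts"` or `"percent"`.
#' @export
table_unit <- function(table) attr(table, "unit")

#' Read an abundance table from TSV
#'
#' Expects tab-separated UTF-8 text with taxon ids in the first column and
#' sample ids in the header; lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @param unit Unit of the stored values, `"counts"` or `"percent"`.
#' @return A validated [abundance_table()].
#' @export
read_abundance_table <- function(path, unit = c("counts", "percent")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance TSV needs a taxon column plus >=1 sample")
  taxa <- as.character(df[[1L]])
  sample_ids <- names(df)[-1L]  # before [.data.frame uniquifies duplicates
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn))
        stop(sprintf("non-numeric cell in column '%s', row '%s'",
                     names(num)[j], taxa[which(is.na(vn))[1]]))
      num[[j]] <- vn
    }
  }
  m <- as.matrix(num)
  rownames(m) <- taxa
  colnames(m) <- sample_ids
  abundance_table(m, unit = unit)
}

#' Write an abundance table to TSV
#' @param table An `abundance_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(taxon_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundance (percent)
#'
#' @param table An `abundance_table` with `unit = "counts"`.
#' @return An `abundance_table` with `unit = "percent"`; every sample column
#'   sums to 100.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table_unit(table) != "counts")
    stop("to_relative() expects a counts table")
  cs <- colSums(table)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(table)[cs == 0], collapse = ", "))
  abundance_table(sweep(unclass(table), 2, cs / 100, "/"), unit = "percent")
}

#' Rank-normalize an abundance table
#'
#' For each taxon row, samples are ranked in ascending order of abundance
#' (ties receive the average of the tied ranks) and ranks are divided by the
#' number of samples, giving normalized ranks in (0, 1]. This is the input
#' representation for tie-aware Spearman co-occurrence analysis: correlating
#' two taxa's normalized rank rows across samples is Spearman's coefficient
#' with average-rank tie handling.
#'
#' @param table An `abundance_table` with at least 2 samples.
#' @return A `rank_matrix`: numeric matrix of the same shape, values in
#'   (0, 1], with an `n_samples` attribute.
#' @export
rank_normalize <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  n <- ncol(table)
  if (n < 2L) stop("rank normalization needs >=2 samples")
  r <- t(apply(unclass(table), 1L, rank, ties.method = "average")) / n
  # t(apply) drops dims for single-row tables
  if (nrow(table) == 1L) {
    r <- matrix(r, nrow = 1L, dimnames = dimnames(table))
  }
  structure(r, n_samples = n, class = c("rank_matrix", "matrix", "array"))
}

#' Class-pooled relative contribution of each taxon
#'
#' The "relative contribution" of a taxon to a sample class is the pooled
#' percentage of all taxonomic assignments in that class attributed to the
#' taxon: taxon total over the class's samples divided by the grand total,
#' times 100. Contributions sum to 100 over taxa.
#'
#' @param table An `abundance_table` (counts, or percent for equal-weight
#'   pooling of samples).
#' @param meta A sample metadata data frame, see [read_sample_meta()].
#' @param klass `"lesional"` or `"non_lesional"`.
#' @return Named numeric vector (percent per taxon).
#' @export
relative_contribution <- function(table, meta, klass) {
  klass <- match.arg(klass, c("lesional", "non_lesional"))
  ids <- meta$sample_id[meta$klass == klass]
  ids <- intersect(colnames(table), ids)
  if (!length(ids)) stop("no samples of class '", klass, "' in table")
  sub <- unclass(table)[, ids, drop = FALSE]
  tot <- sum(sub)
  if (tot == 0) stop("class '", klass, "' has zero total abundance")
  rowSums(sub) / tot * 100
}

#' Parse sample identifiers of the subject-site naming scheme
#'
#' Sample ids follow `<subject><N|V><site>`, e.g. `A1N1` is the non-lesional
#' (N) sample of subject A1 at site 1 and `A1V1` its lesional (V, vitiligo)
#' counterpart.
#'
#' @param sample_ids Character vector of sample ids.
#' @return Sample metadata data frame with columns `sample_id`, `subject_id`,
#'   `site_tag`, `klass`.
#' @export
parse_sample_ids <- function(sample_ids) {
  pat <- "^([A-Za-z]+[0-9]+)([NV])([0-9]+)$"
  ok <- grepl(pat, sample_ids)
  if (!all(ok))
    stop("unparseable sample id(s): ", paste(sample_ids[!ok], collapse = ", "))
  sample_meta(
    sample_id = sample_ids,
    subject_id = sub(pat, "\\1", sample_ids),
    site_tag = sub(pat, "\\2\\3", sample_ids),
    klass = ifelse(sub(pat, "\\2", sample_ids) == "V",
                   "lesional", "non_lesional"))
}

#' Construct sample metadata
#'
#' @param sample_id,subject_id,site_tag Character vectors.
#' @param klass Character vector over `{"lesional", "non_lesional"}`.
#' @return Validated `data.frame` of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, subject_id, site_tag, klass) {
  df <- data.frame(sample_id = as.character(sample_id),
                   subject_id = as.character(subject_id),
                   site_tag = as.character(site_tag),
                   klass = as.character(klass),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$klass), c("lesional", "non_lesional"))
  if (length(bad))
    stop("invalid class value(s): ", paste(bad, collapse = ", "))
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' Columns: `sample_id`, `subject_id`, `site_tag`, `class` (values
#' `lesional` / `non_lesional`, or the one-letter site codes `V` / `N`).
#'
#' @param path Path to TSV.
#' @return A `sample_meta` data frame.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "site_tag", "class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata TSV missing column(s): ", paste(miss, collapse = ", "))
  kl <- df$class
  kl[kl == "V"] <- "lesional"
  kl[kl == "N"] <- "non_lesional"
  sample_meta(df$sample_id, df$subject_id, df$site_tag, kl)
}

#' Write sample metadata to TSV
#' @param meta A `sample_meta` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  out <- data.frame(sample_id = meta$sample_id, subject_id = meta$subject_id,
                    site_tag = meta$site_tag, class = meta$klass)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# closed vocabularies for phenotype annotations attached to network nodes
.phenotype_vocab <- list(
  gram_nature = c("positive", "negative", "variable"),
  sporulation = c("sporulating", "non_sporulating"),
  oxygen_requirement = c("aerobic", "anaerobic", "facultative", "microaerophilic"),
  cell_shape = c("coccus", "bacillus", "coccobacillus", "filamentous",
                 "pleomorphic", "spiral"))

.lineage_ranks <- c("phylum", "class", "order", "family", "genus")

#' Read taxon lineage and phenotype annotations from TSV
#'
#' Keyed by `taxon_id`; optional lineage columns `phylum`, `class`, `order`,
#' `family`, `genus` and optional phenotype columns `gram_nature`,
#' `sporulation`, `oxygen_requirement`, `cell_shape` (closed vocabularies).
#' Empty cells are treated as absent (`NA`).
#'
#' @param path Path to TSV.
#' @return A `taxon_annotations` data frame keyed by `taxon_id`.
#' @export
read_taxon_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df)) stop("annotation TSV needs a taxon_id column")
  taxon_annotations(df)
}

#' Validate a taxon annotation data frame
#' @param df Data frame with a `taxon_id` column plus optional lineage and
#'   phenotype columns.
#' @return The validated data frame, classed `taxon_annotations`.
#' @export
taxon_annotations <- function(df) {
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon_id(s) in annotations")
  known <- c("taxon_id", .lineage_ranks, names(.phenotype_vocab))
  extra <- setdiff(names(df), known)
  if (length(extra))
    stop("unknown annotation column(s): ", paste(extra, collapse = ", "))
  for (ph in intersect(names(.phenotype_vocab), names(df))) {
    v <- df[[ph]]
    v[v == ""] <- NA
    bad <- setdiff(unique(v[!is.na(v)]), .phenotype_vocab[[ph]])
    if (length(bad))
      stop(sprintf("phenotype '%s' has value(s) outside vocabulary: %s",
                   ph, paste(bad, collapse = ", ")))
    df[[ph]] <- v
  }
  for (rk in intersect(.lineage_ranks, names(df))) {
    v <- df[[rk]]
    v[v == ""] <- NA
    df[[rk]] <- v
  }
  class(df) <- c("taxon_annotations", "data.frame")
  df
}
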