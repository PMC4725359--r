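#' Read the packaged differential-OTU reference fixture
#'
#' A 27-row table of differentially abundant OTUs between paired
#' non-lesional ("normal") and lesional ("vitiligo") skin, with per-class
#' pooled relative contributions, medians, ranges and the higher-median
#' class flag. Used as a fixed reference layout for comparing pipeline
#' output shape and summary counts.
#'
#' @param path Path to a fixture TSV; defaults to the packaged copy.
#' @return Data frame with columns `otu_id`, `phylum`, `contrib_normal`,
#'   `contrib_vitiligo`, `median_normal`, `min_normal`, `max_normal`,
#'   `median_vitiligo`, `min_vitiligo`, `max_vitiligo`, `higher_in`.
#' @export
read_differential_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "differential_otus_fixture.tsv",
                        package = "dysbiome", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("otu_id", "phylum", "contrib_normal", "contrib_vitiligo",
            "median_normal", "min_normal", "max_normal", "median_vitiligo",
            "min_vitiligo", "max_vitiligo", "higher_in")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fixture missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$otu_id)) stop("fixture has duplicate otu_id values")
  bad <- setdiff(unique(df$higher_in), c("normal", "vitiligo"))
  if (length(bad))
    stop("fixture higher_in outside {normal, vitiligo}: ",
         paste(bad, collapse = ", "))
  df
}

#' Pipeline configuration
#'
#' Exactly one of `input` (paths to abundance/metadata/annotation TSVs) or
#' `synthetic` (a [synthetic_spec()]) must be given.
#'
#' @param input Optional list with `abundance`, `metadata` and optionally
#'   `annotations` file paths, plus `unit` (default `"counts"`).
#' @param synthetic Optional `synthetic_spec`.
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; per-stage substreams are derived from it.
#' @param diversity_thresholds Contribution thresholds for taxa counts.
#' @param evenness_min_pct Minimum contribution for the evenness curve.
#' @param core_min_pct,core_min_prev Core-taxa parameters.
#' @param diff_params A [boot_diff_params()] (its seed is overridden by a
#'   substream of `seed`).
#' @param network_confidence Confidence level for edge calling.
#' @param network_method `"t_approx"` or `"permutation"`.
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, out_dir,
                            seed = 1L,
                            diversity_thresholds = c(0.01, 0.1, 1),
                            evenness_min_pct = 1,
                            core_min_pct = 0.1, core_min_prev = 0.8,
                            diff_params = boot_diff_params(),
                            network_confidence = 0.99,
                            network_method = c("t_approx", "permutation")) {
  if (is.null(input) == is.null(synthetic))
    stop("provide exactly one of `input` or `synthetic`")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  if (!is.null(input)) {
    if (!all(c("abundance", "metadata") %in% names(input)))
      stop("`input` needs `abundance` and `metadata` paths")
    if (is.null(input$unit)) input$unit <- "counts"
  }
  structure(list(input = input, synthetic = synthetic, out_dir = out_dir,
                 seed = as.integer(seed),
                 diversity_thresholds = diversity_thresholds,
                 evenness_min_pct = evenness_min_pct,
                 core_min_pct = core_min_pct, core_min_prev = core_min_prev,
                 diff_params = diff_params,
                 network_confidence = network_confidence,
                 network_method = match.arg(network_method)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full paired-site analysis pipeline
#'
#' Sequences every stage over one dataset: alpha-diversity report and
#' paired class comparison, evenness curves and taxa-at-threshold counts,
#' per-class core taxa and their comparison, the bootstrapped
#' differential-abundance table, per-class co-occurrence networks with
#' summaries and degree-threshold hub reports, shared core interactions,
#' and a JSON manifest recording all parameters and the seed. All TSV
#' outputs are sorted for byte-stable reruns; the run is deterministic
#' given the configuration.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_bundle` with the in-memory results and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  if (!is.null(config$synthetic)) {
    ds <- .stage("simulate", generate_synthetic(config$synthetic))
    counts <- ds$table
    meta <- ds$meta
    annotations <- taxon_annotations(data.frame(
      taxon_id = names(config$synthetic$phylum_assignment),
      phylum = unname(config$synthetic$phylum_assignment),
      stringsAsFactors = FALSE))
  } else {
    counts <- .stage("read", read_abundance_table(config$input$abundance,
                                                  config$input$unit))
    meta <- .stage("read", read_sample_meta(config$input$metadata))
    annotations <- if (!is.null(config$input$annotations))
      .stage("read", read_taxon_annotations(config$input$annotations))
    else NULL
  }
  pct <- if (table_unit(counts) == "counts") to_relative(counts) else counts

  # diversity (counts needed; skipped for percent input)
  divers <- NULL
  if (table_unit(counts) == "counts") {
    divers <- .stage("diversity", diversity_report(counts, meta))
    utils::write.table(divers[order(divers$sample_id), ],
                       out("diversity.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, out("diversity.tsv"))
    cmp <- .stage("diversity", compare_diversity(divers, meta))
    utils::write.table(cmp, out("diversity_class_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, out("diversity_class_comparison.tsv"))
  }

  # evenness and threshold counts per class
  even_rows <- list()
  thr_rows <- list()
  for (kl in c("non_lesional", "lesional")) {
    contrib <- relative_contribution(counts, meta, kl)
    thr <- taxa_at_thresholds(contrib, config$diversity_thresholds)
    thr_rows[[kl]] <- data.frame(class = kl,
                                 threshold_pct = config$diversity_thresholds,
                                 n_taxa = as.integer(thr))
    ec <- tryCatch(
      successive_contribution_differences(contrib, config$evenness_min_pct),
      error = function(e) NULL)
    if (!is.null(ec))
      even_rows[[kl]] <- data.frame(class = kl,
                                    position = seq_along(ec$differences),
                                    difference = ec$differences,
                                    slope = ec$slope)
  }
  utils::write.table(do.call(rbind, thr_rows), out("taxa_at_thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, out("taxa_at_thresholds.tsv"))
  if (length(even_rows)) {
    utils::write.table(do.call(rbind, even_rows), out("evenness_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, out("evenness_curves.tsv"))
  }

  # core taxa
  core_n <- .stage("core", core_taxa(pct, meta, "non_lesional",
                                     config$core_min_pct,
                                     config$core_min_prev))
  core_l <- .stage("core", core_taxa(pct, meta, "lesional",
                                     config$core_min_pct,
                                     config$core_min_prev))
  cc <- compare_cores(core_n, core_l)
  all_core <- sort(union(core_n$members, core_l$members))
  utils::write.table(
    data.frame(taxon_id = all_core,
               core_non_lesional = all_core %in% core_n$members,
               core_lesional = all_core %in% core_l$members),
    out("core_taxa.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, out("core_taxa.tsv"))

  # differential abundance
  dp <- config$diff_params
  dp$seed <- .substream(config$seed, 101L)
  diff <- .stage("diffabund", bootstrapped_diff(pct, meta, dp))
  write_diff_result(diff, out("differential_taxa.tsv"),
                    only_significant = TRUE)
  write_diff_result(diff, out("differential_taxa_full.tsv"),
                    only_significant = FALSE)
  files <- c(files, out("differential_taxa.tsv"),
             out("differential_taxa_full.tsv"))

  # per-class networks
  nets <- list()
  summaries <- list()
  hubs_rows <- list()
  for (kl in c("non_lesional", "lesional")) {
    ids <- meta$sample_id[meta$klass == kl]
    sub <- abundance_table(unclass(counts)[, ids, drop = FALSE],
                           table_unit(counts))
    ranks <- rank_normalize(sub)
    net <- .stage("network", build_network(
      ranks, annotations, confidence = config$network_confidence,
      klass = kl, method = config$network_method,
      seed = .substream(config$seed, 202L)))
    nets[[kl]] <- net
    write_edge_list(net, out(paste0("network_", kl, "_edges.tsv")))
    files <- c(files, out(paste0("network_", kl, "_edges.tsv")))
    if (nrow(net$edges)) {
      write_graphml(net, out(paste0("network_", kl, ".graphml")))
      files <- c(files, out(paste0("network_", kl, ".graphml")))
    }
    s <- summarize_network(net)
    summaries[[kl]] <- list(n_nodes = s$n_nodes, n_edges = s$n_edges,
                            density = s$density, diameter = s$diameter,
                            max_degree = if (length(s$degree))
                              max(s$degree) else 0L)
    if (nrow(net$edges)) {
      for (hr in hub_analysis(net))
        hubs_rows[[length(hubs_rows) + 1L]] <- data.frame(
          class = kl, threshold_pct = hr$threshold_pct,
          n_hubs = length(hr$hubs),
          hubs = paste(sort(hr$hubs), collapse = ","))
    }
  }
  jsonlite::write_json(summaries, out("network_summaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, out("network_summaries.json"))
  if (length(hubs_rows)) {
    utils::write.table(do.call(rbind, hubs_rows), out("hub_reports.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, out("hub_reports.tsv"))
  }
  ci <- core_interactions(nets$non_lesional, nets$lesional)
  ci <- ci[order(ci$taxon_a, ci$taxon_b), , drop = FALSE]
  utils::write.table(ci, out("core_interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, out("core_interactions.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("dysbiome")),
    seed = config$seed,
    input = if (is.null(config$input)) "synthetic" else config$input,
    synthetic_seed = if (!is.null(config$synthetic))
      config$synthetic$seed else NULL,
    parameters = list(
      diversity_thresholds = config$diversity_thresholds,
      evenness_min_pct = config$evenness_min_pct,
      core_min_pct = config$core_min_pct,
      core_min_prev = config$core_min_prev,
      diff = unclass(config$diff_params),
      network_confidence = config$network_confidence,
      network_method = config$network_method))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, out("manifest.json"))

  structure(list(diversity = divers, core = cc, diff = diff,
                 networks = nets, summaries = summaries,
                 core_interactions = ci, files = files,
                 config = config),
            class = "pipeline_bundle")
}

#' Compare a pipeline run against the packaged differential-OTU fixture
#'
#' Side-by-side summary counts for the run's differential-abundance result
#' and the reference table: number of significant taxa, split by direction,
#' and the number above each pooled-contribution threshold in at least one
#' class.
#'
#' @param bundle A `pipeline_bundle` (or a `diff_abundance_result`).
#' @param fixture A fixture data frame from [read_differential_fixture()].
#' @param thresholds Contribution thresholds (percent) for the count rows.
#' @return Data frame with columns `metric`, `run`, `reference`.
#' @export
summarize_against_fixture <- function(bundle,
                                      fixture = read_differential_fixture(),
                                      thresholds = c(0.1, 1)) {
  diff <- if (inherits(bundle, "pipeline_bundle")) bundle$diff else bundle
  sig <- diff[diff$significant, , drop = FALSE]
  rows <- list(
    data.frame(metric = "n_significant", run = nrow(sig),
               reference = nrow(fixture)),
    data.frame(metric = "n_higher_in_lesional",
               run = sum(sig$direction == "higher_in_lesional"),
               reference = sum(fixture$higher_in == "vitiligo")),
    data.frame(metric = "n_higher_in_non_lesional",
               run = sum(sig$direction == "higher_in_non_lesional"),
               reference = sum(fixture$higher_in == "normal")))
  for (t in thresholds) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = sprintf("n_contrib_gt_%g_pct", t),
      run = sum(pmax(sig$contrib_lesional, sig$contrib_non_lesional) > t),
      reference = sum(pmax(fixture$contrib_vitiligo,
                           fixture$contrib_normal) > t))
  }
  do.call(rbind, rows)
}
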