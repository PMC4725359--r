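#' Tie-aware Spearman correlation of two rank vectors
#'
#' Pearson product-moment form applied to (normalized) rank vectors:
#' \deqn{r_{xy} = \frac{\sum_i (x_i - \bar{x})(y_i - \bar{y})}{(n-1)\,s_x s_y}}
#' with sample standard deviations. Because ties are resolved by average
#' ranks upstream, this is the tie-correct Spearman coefficient.
#'
#' @param x_ranks,y_ranks Equal-length numeric rank vectors, n >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` when either vector has zero
#'   variance (an all-tied taxon), which signals an undefined correlation
#'   rather than aborting matrix construction.
#' @export
spearman_ties <- function(x_ranks, y_ranks) {
  n <- length(x_ranks)
  if (length(y_ranks) != n) stop("rank vectors must have equal length")
  if (n < 3L) stop("need n >= 3 samples")
  dx <- x_ranks - mean(x_ranks)
  dy <- y_ranks - mean(y_ranks)
  sx <- sqrt(sum(dx^2) / (n - 1))
  sy <- sqrt(sum(dy^2) / (n - 1))
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- sum(dx * dy) / ((n - 1) * sx * sy)
  max(-1, min(1, r))
}

#' All-pairs tie-aware Spearman correlation matrix
#'
#' @param ranks A `rank_matrix` from [rank_normalize()].
#' @return List of class `correlation_matrix`: `r` (symmetric matrix, unit
#'   diagonal, `NA` rows/columns for zero-variance taxa), `n` (samples),
#'   `zero_variance` (taxon ids with undefined correlations).
#' @export
correlation_matrix <- function(ranks) {
  n <- ncol(ranks)
  if (n < 3L) stop("need >= 3 samples")
  m <- unclass(ranks)
  ctr <- m - rowMeans(m)
  ss <- rowSums(ctr^2)
  sd_ <- sqrt(ss / (n - 1))
  r <- tcrossprod(ctr) / ((n - 1) * outer(sd_, sd_))
  r[sd_ == 0, ] <- NA_real_
  r[, sd_ == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  d <- diag(r)
  d[sd_ > 0] <- 1
  diag(r) <- d
  structure(list(r = r, n = n, zero_variance = rownames(m)[sd_ == 0]),
            class = "correlation_matrix")
}

#' Critical correlation threshold for edge calling
#'
#' The smallest |r| treated as a significant association at the given
#' confidence level. The default `t_approx` method inverts the two-tailed
#' t statistic \eqn{t = r\sqrt{(n-2)/(1-r^2)}} at df = n - 2, giving
#' \eqn{r_0 = t_c / \sqrt{n - 2 + t_c^2}}. The `permutation` method takes
#' the (1 - alpha/2) quantile of the null Spearman coefficient over random
#' rank permutations (equivalently the (1 - alpha) quantile of |r|).
#'
#' @param n Number of samples (>= 4).
#' @param confidence Confidence level (default 0.99).
#' @param method `"t_approx"` (default) or `"permutation"`.
#' @param perm_reps Permutations for the permutation method.
#' @param seed RNG seed for the permutation method.
#' @return Critical r in (0, 1).
#' @export
critical_r <- function(n, confidence = 0.99,
                       method = c("t_approx", "permutation"),
                       perm_reps = 20000L, seed = 1L) {
  method <- match.arg(method)
  if (n < 4L) stop("need n >= 4")
  if (!(confidence > 0 && confidence < 1))
    stop("confidence must be in (0, 1)")
  alpha <- 1 - confidence
  if (method == "t_approx") {
    tc <- stats::qt(1 - alpha / 2, df = n - 2)
    return(tc / sqrt(n - 2 + tc^2))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  base <- seq_len(n)
  rs <- vapply(seq_len(perm_reps), function(i)
    stats::cor(base, sample(base)), numeric(1))
  unname(stats::quantile(rs, 1 - alpha / 2, names = FALSE))
}

#' Build a per-class co-occurrence network
#'
#' All-pairs tie-aware Spearman correlations of a class's rank-normalized
#' abundances; pairs with r at or above the critical r become positive
#' edges and pairs at or below its negative become negative edges. Values
#' strictly between the two thresholds are insignificant and create no
#' edge. Zero-variance (all-tied) taxa cannot form edges and are reported
#' separately.
#'
#' @param ranks A `rank_matrix` (build it from the class's samples only).
#' @param annotations Optional `taxon_annotations` attached to nodes.
#' @param confidence Confidence level for [critical_r()] (default 0.99).
#' @param klass Optional class label stored on the network.
#' @param method,perm_reps,seed Passed to [critical_r()].
#' @return A `cooccurrence_network`: list with `edges` (data frame
#'   `taxon_a`, `taxon_b`, `r`, `sign`), `nodes` (annotation data frame for
#'   taxa incident to >= 1 edge), `critical_r`, `n_samples`, `klass`,
#'   `zero_variance`.
#' @export
build_network <- function(ranks, annotations = NULL, confidence = 0.99,
                          klass = NA_character_,
                          method = c("t_approx", "permutation"),
                          perm_reps = 20000L, seed = 1L) {
  method <- match.arg(method)
  cm <- correlation_matrix(ranks)
  eligible <- setdiff(rownames(ranks), cm$zero_variance)
  if (length(eligible) < 2L)
    stop("fewer than 2 taxa with rank variance; no pairs to correlate")
  if (ncol(ranks) < 4L) stop("need >= 4 samples to call edges")
  r0 <- critical_r(cm$n, confidence, method, perm_reps, seed)
  r <- cm$r
  ut <- which(upper.tri(r) & !is.na(r) & abs(r) >= r0, arr.ind = TRUE)
  edges <- data.frame(
    taxon_a = rownames(r)[ut[, 1L]],
    taxon_b = colnames(r)[ut[, 2L]],
    r = r[ut],
    sign = ifelse(r[ut] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  node_ids <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  nodes <- data.frame(taxon_id = node_ids, stringsAsFactors = FALSE)
  if (!is.null(annotations))
    nodes <- merge(nodes, annotations, by = "taxon_id", all.x = TRUE,
                   sort = TRUE)
  structure(list(edges = edges, nodes = nodes, critical_r = r0,
                 n_samples = cm$n, klass = klass,
                 zero_variance = cm$zero_variance),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(paste0("cooccurrence_network [%s]: %d nodes, %d edges ",
                     "(critical r = %.3f, n = %d)\n"),
              x$klass, nrow(x$nodes), nrow(x$edges), x$critical_r,
              x$n_samples))
  invisible(x)
}

.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("taxon_a", "taxon_b", "r", "sign")], directed = FALSE,
    vertices = net$nodes)
  g
}

#' Topology and centrality summary of a network
#'
#' Node/edge counts over taxa incident to at least one edge, density,
#' diameter of the largest connected component, per-node degree, and
#' shortest-path betweenness on the unweighted undirected graph (edge signs
#' are metadata, not weights), normalized by (V-1)(V-2)/2.
#'
#' @param net A `cooccurrence_network`.
#' @return List of class `network_summary`: `n_nodes`, `n_edges`,
#'   `density`, `diameter` (`NA` for an edgeless network), `degree`,
#'   `betweenness`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (!nrow(net$edges)) {
    return(structure(list(n_nodes = 0L, n_edges = 0L, density = 0,
                          diameter = NA_integer_, degree = integer(0),
                          betweenness = numeric(0)),
                     class = "network_summary"))
  }
  g <- .as_igraph(net)
  comps <- igraph::components(g)
  big <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  structure(list(
    n_nodes = as.integer(igraph::vcount(g)),
    n_edges = as.integer(igraph::ecount(g)),
    density = igraph::edge_density(g),
    diameter = as.integer(igraph::diameter(big, weights = NA)),
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, weights = NA, normalized = TRUE)),
    class = "network_summary")
}

#' Degree-threshold hub analysis
#'
#' For each threshold N (percent), the hub set contains every node whose
#' degree is at least N% of the maximum degree, together with the phylum
#' and phenotype composition of that set. Hub sets are nested: a higher
#' threshold's set is contained in a lower threshold's.
#'
#' @param net A `cooccurrence_network` with at least one edge.
#' @param thresholds Percent thresholds (default 60, 70, 80, 90).
#' @return List of `hub_report` lists: `threshold_pct`, `hubs`,
#'   `min_degree`, `composition` (list of count tables: `phylum` plus one
#'   per phenotype column available on the nodes).
#' @export
hub_analysis <- function(net, thresholds = c(60, 70, 80, 90)) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (!nrow(net$edges)) stop("network has no edges")
  g <- .as_igraph(net)
  deg <- igraph::degree(g)
  lapply(thresholds, function(th) {
    cut <- th / 100 * max(deg)
    hubs <- names(deg)[deg >= cut]
    rows <- match(hubs, net$nodes$taxon_id)
    comp <- list()
    for (col in intersect(c("phylum", "class", names(.phenotype_vocab)),
                          names(net$nodes))) {
      v <- net$nodes[[col]][rows]
      if (!all(is.na(v))) comp[[col]] <- table(v[!is.na(v)])
    }
    structure(list(threshold_pct = th, hubs = hubs,
                   min_degree = cut, composition = comp),
              class = "hub_report")
  })
}

#' Shared (core) interactions between two networks
#'
#' Undirected edge-set intersection: an interaction is shared when the same
#' unordered taxon pair carries an edge of the same sign in both networks.
#'
#' @param a,b `cooccurrence_network` objects.
#' @return Data frame `taxon_a`, `taxon_b`, `sign`, `r_a`, `r_b`.
#' @export
core_interactions <- function(a, b) {
  stopifnot(inherits(a, "cooccurrence_network"),
            inherits(b, "cooccurrence_network"))
  key <- function(e) {
    lo <- pmin(e$taxon_a, e$taxon_b)
    hi <- pmax(e$taxon_a, e$taxon_b)
    paste(lo, hi, e$sign, sep = "\r")
  }
  if (!nrow(a$edges) || !nrow(b$edges))
    return(data.frame(taxon_a = character(0), taxon_b = character(0),
                      sign = character(0), r_a = numeric(0),
                      r_b = numeric(0), stringsAsFactors = FALSE))
  ka <- key(a$edges)
  kb <- key(b$edges)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka)
  ib <- match(shared, kb)
  data.frame(taxon_a = pmin(a$edges$taxon_a[ia], a$edges$taxon_b[ia]),
             taxon_b = pmax(a$edges$taxon_a[ia], a$edges$taxon_b[ia]),
             sign = a$edges$sign[ia],
             r_a = a$edges$r[ia], r_b = b$edges$r[ib],
             stringsAsFactors = FALSE)
}

#' Write a network's edge list to TSV
#' @param net A `cooccurrence_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges[order(net$edges$taxon_a, net$edges$taxon_b), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML (node annotations and degree included)
#' @param net A `cooccurrence_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  if (!nrow(net$edges)) stop("network has no edges")
  g <- .as_igraph(net)
  igraph::V(g)$degree <- igraph::degree(g)
  # GraphML cannot carry NA attributes; blank them
  for (at in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, at)
    if (is.character(v)) v[is.na(v)] <- ""
    igraph::vertex_attr(g, at) <- v
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
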