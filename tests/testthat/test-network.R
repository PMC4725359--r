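test_that("tie-aware Spearman matches the first-principles oracle", {
  x <- c(1, 2.5, 2.5, 4, 5) / 5
  expect_equal(spearman_ties(x, x), 1)
  expect_equal(spearman_ties(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1)), -1)
  expect_true(is.na(spearman_ties(rep(0.5, 5), c(1, 2, 3, 4, 5))))
  expect_error(spearman_ties(1:4, 1:3), "equal length")
  set.seed(41)
  for (i in 1:50) {
    n <- sample(5:15, 1)
    a <- rank(sample(1:4, n, TRUE), ties.method = "average") / n
    b <- rank(sample(1:4, n, TRUE), ties.method = "average") / n
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    expect_equal(spearman_ties(a, b), oracle_spearman(a, b),
                 tolerance = 1e-12)
    expect_equal(spearman_ties(a, b), spearman_ties(b, a))
    # agrees with R's Spearman through the rank pathway
    expect_equal(spearman_ties(a, b), cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("the correlation matrix is symmetric with unit diagonal and
           flags zero-variance taxa", {
  tab <- rand_paired_table(15, 5, seed = 42)
  m <- unclass(tab)
  m["t003", ] <- 7  # all-tied taxon
  cm <- correlation_matrix(rank_normalize(abundance_table(m, "counts")))
  expect_equal(cm$r, t(cm$r))
  expect_identical(cm$zero_variance, "t003")
  expect_true(all(is.na(cm$r["t003", ])))
  ok <- setdiff(rownames(m), "t003")
  expect_equal(unname(diag(cm$r[ok, ok])), rep(1, length(ok)))
  expect_true(all(abs(cm$r[ok, ok]) <= 1))
})

test_that("critical r decreases with n, rises towards 1 with confidence,
           and agrees with its permutation estimate", {
  r <- vapply(5:50, critical_r, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_gt(critical_r(10, confidence = 1 - 1e-12), 0.99)
  confs <- c(0.9, 0.95, 0.99, 0.999, 0.99999)
  expect_true(all(diff(vapply(confs, function(cf) critical_r(10, cf),
                              numeric(1))) > 0))
  expect_error(critical_r(3), "n >= 4")
  expect_equal(critical_r(20),
               critical_r(20, method = "permutation", perm_reps = 50000,
                          seed = 1),
               tolerance = 0.02)
})

test_that("edge calling keeps only super-critical pairs and excludes
           constant taxa", {
  # two co-monotone taxa plus independent noise taxa
  set.seed(43)
  ids <- sprintf("s%02d", 1:10)
  m <- rbind(a = 1:10, b = (1:10)^2, c = rnorm(10), d = rnorm(10),
             const = rep(5, 10))
  colnames(m) <- ids
  m <- abs(m) + 1
  net <- build_network(rank_normalize(abundance_table(m, "counts")),
                       confidence = 0.99)
  ab <- net$edges[net$edges$taxon_a == "a" & net$edges$taxon_b == "b", ]
  expect_identical(nrow(ab), 1L)
  expect_equal(ab$r, 1)
  expect_identical(ab$sign, "positive")
  expect_identical(net$zero_variance, "const")
  expect_false("const" %in% c(net$edges$taxon_a, net$edges$taxon_b))
  expect_true(all(abs(net$edges$r) >= net$critical_r))
})

test_that("network summaries match known topologies and an exhaustive
           shortest-path oracle", {
  k4 <- expand.grid(a = letters[1:4], b = letters[1:4],
                    stringsAsFactors = FALSE)
  k4 <- k4[k4$a < k4$b, ]
  net <- net_from_edges(data.frame(taxon_a = k4$a, taxon_b = k4$b,
                                   r = 0.9, sign = "positive"))
  s <- summarize_network(net)
  expect_identical(s$n_nodes, 4L)
  expect_identical(s$n_edges, 6L)
  expect_equal(s$density, 1)
  expect_identical(s$diameter, 1L)
  expect_equal(unname(s$degree[letters[1:4]]), rep(3, 4))

  path4 <- net_from_edges(data.frame(taxon_a = c("a", "b", "c"),
                                     taxon_b = c("b", "c", "d"),
                                     r = 0.9, sign = "positive"))
  sp <- summarize_network(path4)
  expect_identical(sp$diameter, 3L)
  expect_gt(min(sp$betweenness[c("b", "c")]),
            max(sp$betweenness[c("a", "d")]))

  set.seed(44)
  for (i in 1:5) {
    nodes <- paste0("n", 1:9)
    pairs <- t(combn(nodes, 2))
    pick <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    if (nrow(pick) < 2) next
    net <- net_from_edges(data.frame(taxon_a = pick[, 1],
                                     taxon_b = pick[, 2],
                                     r = 0.8, sign = "positive"))
    s <- summarize_network(net)
    oracle <- oracle_graph_stats(net$nodes$taxon_id, pick)
    expect_equal(s$degree[names(oracle$degree)], oracle$degree,
                 ignore_attr = TRUE)
    expect_equal(s$betweenness[names(oracle$betweenness)],
                 oracle$betweenness, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("hub sets follow the degree threshold and nest across
           thresholds", {
  star <- data.frame(taxon_a = "hub", taxon_b = paste0("leaf", 1:10),
                     r = 0.9, sign = "positive")
  extra <- data.frame(taxon_a = "leaf1", taxon_b = paste0("leaf", 2:9),
                      r = 0.9, sign = "positive")
  net <- net_from_edges(rbind(star, extra))
  reports <- hub_analysis(net, thresholds = c(60, 70, 80, 90, 100))
  # max degree 11 (hub); leaf1 has degree 9
  expect_setequal(reports[[1]]$hubs, c("hub", "leaf1"))
  expect_setequal(reports[[5]]$hubs, "hub")
  for (i in seq_len(length(reports) - 1))
    expect_true(all(reports[[i + 1]]$hubs %in% reports[[i]]$hubs))
  expect_error(hub_analysis(net_from_edges(
    data.frame(taxon_a = character(0), taxon_b = character(0),
               r = numeric(0), sign = character(0)))), "no edges")
})

test_that("shared interactions require the same pair and the same sign", {
  e1 <- data.frame(taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "d"),
                   r = c(0.9, 0.8, -0.85), sign = c("positive", "positive",
                                                    "negative"))
  same <- core_interactions(net_from_edges(e1), net_from_edges(e1))
  expect_identical(nrow(same), 3L)
  # reversed orientation still matches; flipped sign does not
  e2 <- data.frame(taxon_a = c("b", "c"), taxon_b = c("a", "d"),
                   r = c(0.7, 0.9), sign = c("positive", "positive"))
  got <- core_interactions(net_from_edges(e1), net_from_edges(e2))
  expect_identical(got$taxon_a, "a")
  expect_identical(got$taxon_b, "b")
  disjoint <- core_interactions(net_from_edges(e1), net_from_edges(
    data.frame(taxon_a = "x", taxon_b = "y", r = 0.9, sign = "positive")))
  expect_identical(nrow(disjoint), 0L)
  set.seed(45)
  for (i in 1:10) {
    mk <- function() {
      pairs <- t(combn(paste0("t", 1:8), 2))
      pick <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
      data.frame(taxon_a = pick[, 1], taxon_b = pick[, 2],
                 r = runif(nrow(pick), 0.6, 1) *
                   sample(c(-1, 1), nrow(pick), TRUE),
                 sign = NA, stringsAsFactors = FALSE)
    }
    a <- mk(); a$sign <- ifelse(a$r >= 0, "positive", "negative")
    b <- mk(); b$sign <- ifelse(b$r >= 0, "positive", "negative")
    got <- core_interactions(net_from_edges(a), net_from_edges(b))
    key <- function(e) paste(pmin(e$taxon_a, e$taxon_b),
                             pmax(e$taxon_a, e$taxon_b), e$sign)
    expect_setequal(key(got), intersect(key(a), key(b)))
  }
})

test_that("edge lists and GraphML files round out the network exports", {
  tab <- rand_paired_table(12, 5, seed = 46)
  ann <- taxon_annotations(data.frame(taxon_id = rownames(tab),
                                      phylum = rep(c("Firmicutes",
                                                     "Actinobacteria"), 6)))
  net <- build_network(rank_normalize(tab), ann, confidence = 0.9)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tf)
  back <- utils::read.delim(tf)
  expect_identical(nrow(back), nrow(net$edges))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(as.integer(igraph::ecount(g)), nrow(net$edges))
  expect_true("phylum" %in% igraph::vertex_attr_names(g))
})
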