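# shared fixtures and independent oracles, built in code at test time

# counts table with paired-sample columns S01N1, S01V1, ...
rand_paired_table <- function(n_taxa, n_subjects, seed, lambda = 50) {
  set.seed(seed)
  ids <- as.vector(t(outer(sprintf("S%02d", seq_len(n_subjects)),
                           c("N1", "V1"), paste0)))
  m <- matrix(rpois(n_taxa * 2 * n_subjects, lambda), nrow = n_taxa,
              dimnames = list(sprintf("t%03d", seq_len(n_taxa)), ids))
  abundance_table(m, "counts")
}

paired_meta <- function(table) parse_sample_ids(colnames(table))

# exhaustive rank-sum null: all C(n1+n2, n1) assignments of combined ranks
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x)
  comb <- c(x, y)
  rk <- rank(comb)
  w_obs <- sum(rk[seq_len(n1)])
  sets <- combn(length(comb), n1)
  ws <- apply(sets, 2, function(s) sum(rk[s]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# exhaustive signed-rank null: all 2^n sign assignments
oracle_signed_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# reference BH step-up: sort, p*(m/i), monotonize from the top, cap at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m >= 2) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# first-principles tie-aware Spearman: means, deviations, sample sds
oracle_spearman <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  num <- sum((x - xb) * (y - yb))
  sx <- sqrt(sum((x - xb)^2) / (n - 1))
  sy <- sqrt(sum((y - yb)^2) / (n - 1))
  num / ((n - 1) * sx * sy)
}

# exhaustive shortest-path betweenness and degree for a small undirected
# graph given as a two-column edge matrix of node names
oracle_graph_stats <- function(nodes, edges) {
  adj <- setNames(lapply(nodes, function(v) character(0)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- vapply(adj, length, integer(1))
  bfs_dist <- function(s) {
    d <- setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        q <- c(q, w)
      }
    }
    d
  }
  # enumerate all shortest s->t paths by walking strictly down dist-to-t
  paths_through <- function(s, t, dt) {
    count <- setNames(numeric(length(nodes)), nodes)  # visits per vertex
    total <- 0
    walk <- function(v, interior) {
      if (v == t) {
        total <<- total + 1
        for (u in interior) count[u] <<- count[u] + 1
        return(invisible())
      }
      for (w in adj[[v]]) if (dt[w] == dt[v] - 1)
        walk(w, if (w == t) interior else c(interior, w))
    }
    walk(s, character(0))
    list(count = count, total = total)
  }
  btw <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    s <- nodes[i]; t <- nodes[j]
    dt <- bfs_dist(t)
    if (is.infinite(dt[s])) next
    pt <- paths_through(s, t, dt)
    btw <- btw + pt$count / pt$total
  }
  V <- length(nodes)
  list(degree = deg, betweenness = btw / ((V - 1) * (V - 2) / 2))
}

# tiny cooccurrence_network object from a bare edge list (for topology tests)
net_from_edges <- function(edges_df, nodes = NULL) {
  if (is.null(nodes))
    nodes <- sort(unique(c(edges_df$taxon_a, edges_df$taxon_b)))
  structure(list(edges = edges_df,
                 nodes = data.frame(taxon_id = nodes,
                                    stringsAsFactors = FALSE),
                 critical_r = 0.5, n_samples = 10L, klass = "test",
                 zero_variance = character(0)),
            class = "cooccurrence_network")
}
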