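# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: distances come from igraph's all-pairs BFS,
# expectations from exhaustive enumeration, clustering from dense adjacency
# algebra.

# BA stationary degree distribution for growth with m links per node.
ba_stationary_pdf <- function(k, m = 1) {
  2 * m * (m + 1) / (k * (k + 1) * (k + 2))
}

# Uniform random recursive tree on n nodes (1-based ids, node 1 root).
random_tree_edges <- function(n) {
  parent <- vapply(2:n, function(j) sample.int(j - 1L, 1L), integer(1))
  cbind(parent, 2:n, deparse.level = 0)
}

oracle_graph <- function(edges) {
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

# Brute-force all-pairs shortest-path statistics.
oracle_apsp <- function(edges) {
  d <- igraph::distances(oracle_graph(edges))
  list(diameter = max(d), avg_path = mean(d[upper.tri(d)]))
}

# Local clustering by dense adjacency algebra: triangles through j over
# possible neighbour pairs.
oracle_local_clustering <- function(edges, n) {
  A <- matrix(0L, n, n)
  A[edges] <- 1L; A[edges[, 2:1, drop = FALSE]] <- 1L
  tri <- diag(A %*% A %*% A) / 2
  deg <- rowSums(A)
  ifelse(deg < 2, 0, tri / (deg * (deg - 1) / 2))
}

# Exact expectation of the box-covering cluster count over all uniform
# seed sequences, by memoised recursion over the uncovered-set bitmask.
# Cluster rule mirrors the model definition: a seed's cluster is every
# still-uncovered node within full-network distance r - 1 of it.
oracle_box_cover_expect <- function(edges, n, r) {
  stopifnot(n <= 14)
  d <- igraph::distances(oracle_graph(edges))
  bit <- as.integer(2^(seq_len(n) - 1L))
  ball_mask <- vapply(seq_len(n),
                      function(v) sum(bit[d[v, ] <= r - 1]), numeric(1))
  memo <- new.env(hash = TRUE)
  rec <- function(mask) {
    if (mask == 0) return(0)
    key <- as.character(mask)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    members <- which(bitwAnd(mask, bit) > 0L)
    tot <- 0
    for (s in members)
      tot <- tot + 1 + rec(bitwAnd(mask, bitwNot(as.integer(ball_mask[s]))))
    res <- tot / length(members)
    memo[[key]] <- res
    res
  }
  rec(sum(bit))
}

# Small connected test graphs (n <= 7) built in code.
path_edges <- function(n) cbind(1:(n - 1), 2:n, deparse.level = 0)
star_edges <- function(n) cbind(1L, 2:n, deparse.level = 0)
cycle_edges <- function(n) rbind(path_edges(n), c(n, 1L))
complete_edges <- function(n) t(utils::combn(n, 2))

random_connected_edges <- function(n, extra = 1L) {
  e <- if (n == 1) matrix(integer(), 0, 2) else random_tree_edges(n)
  for (i in seq_len(extra)) {
    cand <- complete_edges(n)
    have <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% have), , drop = FALSE]
    if (nrow(cand) == 0) break
    e <- rbind(e, cand[sample.int(nrow(cand), 1L), ])
  }
  e
}

# Minimal hand-built fpa_network for unit tests of single operations.
make_net <- function(edges, degree, parent, depth, m = 1L, f = 1) {
  structure(list(n = length(degree), m = m, f = f, m0 = NA_integer_,
                 seed = NULL, engine = "r",
                 edges = matrix(as.integer(edges), ncol = 2),
                 degree = as.integer(degree), parent = as.integer(parent),
                 depth = as.integer(depth), diagnostics = NULL),
            class = "fpa_network")
}
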