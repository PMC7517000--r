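# Fractional preferential attachment growth.
#
# Node ids are 1-based in R objects (node i arrived at step i-1); file writers
# translate to the 0-based on-disk convention.

validate_config <- function(n, m, f, m0) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m))
    stop("`m` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || !(f > 0 && f <= 1))
    stop("`f` must be a single real in (0, 1]", call. = FALSE)
  if (!is.numeric(m0) || length(m0) != 1L || m0 != floor(m0) ||
      m0 < 2 || m0 < m + 1)
    stop("`m0` must be an integer >= max(2, m + 1)", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n != floor(n) || n <= m0)
    stop("`n` must be an integer exceeding the seed size `m0`", call. = FALSE)
  invisible(TRUE)
}

new_fpa_network <- function(n, m, f, m0, seed, engine, edges, degree, parent,
                            depth, diagnostics = NULL) {
  structure(
    list(n = as.integer(n), m = as.integer(m), f = f, m0 = as.integer(m0),
         seed = seed, engine = engine,
         edges = edges, degree = as.integer(degree),
         parent = if (is.null(parent)) NULL else as.integer(parent),
         depth = if (is.null(depth)) NULL else as.integer(depth),
         diagnostics = diagnostics),
    class = "fpa_network")
}

#' Generate a fractional preferential attachment (FPA) network
#'
#' Grows a scale-free network by preferential attachment restricted to the
#' upper fraction `f` of existing nodes ranked by degree (ties broken by tree
#' order, then at random), with a parent-comparison redirection rule: a
#' candidate whose degree exceeds its parent's passes the new edge on to the
#' parent. `f = 1` recovers Barabasi-Albert growth; decreasing `f`
#' strengthens the hubs and lowers the degree exponent, giving cumulative
#' degree distributions \eqn{P(k) \sim k^{-\beta}} with \eqn{\beta = f + 1}
#' (density exponent \eqn{\gamma = f + 2}).
#'
#' Growth starts from a star on `m0` nodes whose centre is the root. At each
#' step the new node draws `m` candidates independently from the candidate
#' pool (degree-proportional probabilities applied per link, degrees frozen
#' at the step start), resolves each through the redirection rule, and links
#' once to each distinct resolved endpoint, so for `m > 1` a step can
#' contribute fewer than `m` edges — at small `f` the draws pile onto the
#' hubs and the realised mean degree falls visibly below `2m`. The endpoint
#' of the first established edge becomes the new node's parent. For `m = 1`
#' the result is a tree.
#'
#' @param n Target number of nodes (> `m0`).
#' @param m Number of candidate links brought by each new node (integer >= 1).
#' @param f Candidate fraction in (0, 1].
#' @param seed Optional integer; when given, `set.seed(seed)` is called so the
#'   network is reproducible in isolation.
#' @param m0 Seed-star size, default `m + 1`.
#' @param engine `"cpp"` (fast bucket implementation) or `"r"` (literal
#'   rank/pool/sample reference implementation; also records per-step
#'   diagnostics when `diagnostics = TRUE`).
#' @param diagnostics Logical; with the `"r"` engine, record per-step pool
#'   sizes, drawn candidate ranks and the fraction of pool members whose
#'   parent is also in the pool.
#' @return An object of class `fpa_network`: a list with the edge matrix
#'   (1-based, one row per undirected edge), and per-node `degree`, `parent`
#'   (`NA` for the root) and `depth` (root = 0), plus the generation
#'   parameters.
#' @examples
#' net <- fpa_network(500, m = 1, f = 0.5, seed = 42)
#' net
#' max(net$degree)
#' @seealso [summary.fpa_network()], [degree_curves()], [box_cover_curve()]
#' @export
fpa_network <- function(n, m = 1L, f = 1, seed = NULL, m0 = m + 1L,
                        engine = c("cpp", "r"), diagnostics = FALSE) {
  engine <- match.arg(engine)
  validate_config(n, m, f, m0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (engine == "cpp") {
    raw <- fpa_generate_cpp(as.integer(n), as.integer(m), f, as.integer(m0))
    net <- new_fpa_network(n, m, f, m0, seed, engine, raw$edges, raw$degree,
                           raw$parent, raw$depth)
  } else {
    net <- fpa_seed_state(m, m0, f = f)
    net$diagnostics <- if (diagnostics) list() else NULL
    while (net$n < n) net <- attach_node(net)
    net$seed <- seed
    if (diagnostics)
      net$diagnostics <- do.call(rbind, lapply(net$diagnostics, as.data.frame))
  }
  net
}

#' Seed star for FPA growth
#'
#' The initial network: a star on `m0` nodes whose centre (node 1) is the
#' root, so a new node can always find `m` distinct endpoints.
#'
#' @inheritParams fpa_network
#' @param f Candidate fraction carried along for subsequent [attach_node()]
#'   steps.
#' @return An `fpa_network` with `m0` nodes.
#' @examples
#' fpa_seed_state(3)$degree  # centre degree 3, three leaves
#' @export
fpa_seed_state <- function(m = 1L, m0 = m + 1L, f = 1) {
  if (!is.numeric(m0) || m0 < 2 || m0 < m + 1)
    stop("`m0` must be an integer >= max(2, m + 1)", call. = FALSE)
  edges <- cbind(1L, seq_len(m0 - 1L) + 1L)
  new_fpa_network(m0, m, f, m0, NULL, "r", edges,
                  degree = c(m0 - 1L, rep(1L, m0 - 1L)),
                  parent = c(NA_integer_, rep(1L, m0 - 1L)),
                  depth = c(0L, rep(1L, m0 - 1L)))
}

#' Candidate pool size
#'
#' Number of nodes in the upper fraction `f` of `existing` nodes:
#' `max(1, ceiling(f * existing))`, never 0 and never more than `existing`.
#'
#' @param existing Number of existing nodes (>= 1).
#' @param f Candidate fraction in (0, 1].
#' @examples
#' pool_size(10, 0.3)   # 3
#' pool_size(10, 0.25)  # ceiling(2.5) = 3
#' pool_size(1, 0.1)    # floor of one candidate
#' @export
pool_size <- function(existing, f) {
  if (!is.numeric(f) || any(!(f > 0 & f <= 1)))
    stop("`f` must be in (0, 1]", call. = FALSE)
  if (any(existing < 1)) stop("`existing` must be >= 1", call. = FALSE)
  # guard against f*e landing epsilon above an exact integer in binary
  np <- ceiling(f * existing - 1e-9)
  as.integer(pmax(1, pmin(existing, np)))
}

#' Rank nodes for candidate-pool formation
#'
#' Total order used to form the candidate pool: degree descending, then depth
#' (tree order R) ascending, then uniformly at random among remaining ties.
#' The tie randomness is drawn fresh on every call.
#'
#' @param net An `fpa_network`.
#' @return Integer vector of node ids, best-ranked first.
#' @export
rank_nodes <- function(net) {
  stopifnot(inherits(net, "fpa_network"))
  order(-net$degree, net$depth, sample.int(net$n))
}

#' Sample one attachment candidate from a pool
#'
#' Draws node `i` from `pool` with probability \eqn{k_i / \sum_{s} k_s},
#' degrees taken from the current network state.
#'
#' @param net An `fpa_network`.
#' @param pool Integer vector of candidate node ids (non-empty).
#' @return A single node id.
#' @export
sample_candidate <- function(net, pool) {
  stopifnot(inherits(net, "fpa_network"), length(pool) >= 1)
  w <- net$degree[pool]
  if (sum(w) <= 0) stop("candidate pool has zero total degree", call. = FALSE)
  pool[sample.int(length(pool), 1L, prob = w)]
}

#' Resolve an attachment endpoint through the redirection rule
#'
#' If the candidate is the root, or its degree does not exceed its parent's
#' (`k_i <= k_p(i)`, equality included), the candidate itself is the
#' endpoint; otherwise the edge is redirected to the parent.
#'
#' @param net An `fpa_network`.
#' @param candidate A node id.
#' @return The endpoint node id (which becomes the new node's parent).
#' @export
resolve_endpoint <- function(net, candidate) {
  stopifnot(inherits(net, "fpa_network"),
            candidate >= 1, candidate <= net$n)
  p <- net$parent[candidate]
  if (is.na(p) || net$degree[candidate] <= net$degree[p]) candidate else p
}

#' Attach one node to a growing FPA network (reference implementation)
#'
#' One literal growth step: rank the existing nodes (degrees frozen), form
#' the pool, draw `m` candidates independently with degree-proportional
#' probabilities (the whole pool if it has at most `m` members), resolve each
#' through [resolve_endpoint()], de-duplicate, and link the new node to every
#' distinct endpoint. The first endpoint becomes the parent.
#'
#' This pure-R path is the readable reference for the compiled engine used by
#' [fpa_network()]; it is quadratic and intended for small networks, tests
#' and instrumentation.
#'
#' @param net An `fpa_network` grown with the `"r"` engine.
#' @return The network with one more node.
#' @export
attach_node <- function(net) {
  stopifnot(inherits(net, "fpa_network"))
  ranked <- rank_nodes(net)
  np <- pool_size(net$n, net$f)
  pool <- ranked[seq_len(np)]
  m <- net$m
  if (np <= m) {
    cand <- pool
  } else {
    cand <- vapply(seq_len(m), function(t) sample_candidate(net, pool),
                   integer(1))
  }
  ends <- unique(vapply(cand, function(cc) resolve_endpoint(net, cc),
                        integer(1)))
  if (!is.null(net$diagnostics)) {
    par_pool <- net$parent[pool]
    informative <- !is.na(par_pool)
    net$diagnostics[[length(net$diagnostics) + 1L]] <- list(
      step = net$n + 1L,
      pool_size = np,
      max_candidate_rank = max(match(cand, ranked)),
      parent_in_pool = if (any(informative))
        mean(par_pool[informative] %in% pool) else NA_real_)
  }
  j <- net$n + 1L
  net$edges <- rbind(net$edges, cbind(j, ends), deparse.level = 0)
  net$parent <- c(net$parent, ends[1L])
  net$depth <- c(net$depth, net$depth[ends[1L]] + 1L)
  net$degree[ends] <- net$degree[ends] + 1L
  net$degree <- c(net$degree, length(ends))
  net$n <- j
  net
}

#' Count degree inversions around single nodes
#'
#' Number of nodes with at least two strictly higher-degree neighbours — the
#' configuration the redirection rule is meant to suppress. Reported as an
#' empirical diagnostic rather than enforced to be zero, because under the
#' literal rule a child's degree can transiently exceed its parent's.
#'
#' @param net An `fpa_network`, igraph, or two-column edge matrix.
#' @return Integer count.
#' @export
count_degree_inversions <- function(net) {
  g <- as_net_graph(net)
  deg <- g$degree
  e1 <- g$edges[, 1L]; e2 <- g$edges[, 2L]
  higher <- integer(g$n)
  up1 <- deg[e2] > deg[e1]
  up2 <- deg[e1] > deg[e2]
  if (any(up1)) {
    t1 <- table(e1[up1])
    higher[as.integer(names(t1))] <- higher[as.integer(names(t1))] + as.integer(t1)
  }
  if (any(up2)) {
    t2 <- table(e2[up2])
    higher[as.integer(names(t2))] <- higher[as.integer(names(t2))] + as.integer(t2)
  }
  sum(higher >= 2L)
}
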