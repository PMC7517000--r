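# Topology measurement suite: degree distribution and CCDF exponent beta,
# degree-correlation curve <knn(k)> and exponent alpha, clustering, diameter,
# average shortest path, and the ultra-small-world reference ln N / ln ln N.

# Normalise any supported input (fpa_network, igraph, 2-column edge matrix)
# to a light internal graph with a lazily built igraph.
as_net_graph <- function(x) {
  if (inherits(x, "fpa_graph")) return(x)
  if (inherits(x, "fpa_network")) {
    g <- list(n = x$n, edges = x$edges, degree = x$degree,
              parent = x$parent, depth = x$depth, m = x$m, f = x$f,
              igraph = NULL)
  } else if (inherits(x, "igraph")) {
    el <- igraph::as_edgelist(x, names = FALSE)
    storage.mode(el) <- "integer"
    g <- list(n = igraph::vcount(x), edges = el,
              degree = as.integer(igraph::degree(x)),
              parent = NULL, depth = NULL, m = NA_integer_, f = NA_real_,
              igraph = x)
  } else if (is.matrix(x) && ncol(x) == 2L) {
    storage.mode(x) <- "integer"
    n <- max(x)
    g <- list(n = n, edges = x,
              degree = tabulate(c(x[, 1L], x[, 2L]), nbins = n),
              parent = NULL, depth = NULL, m = NA_integer_, f = NA_real_,
              igraph = NULL)
  } else {
    stop("unsupported network input; give an fpa_network, igraph, ",
         "or 2-column edge matrix", call. = FALSE)
  }
  class(g) <- "fpa_graph"
  g
}

net_igraph <- function(g) {
  if (is.null(g$igraph))
    g$igraph <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  g$igraph
}

is_tree_graph <- function(g) nrow(g$edges) == g$n - 1L

assert_connected <- function(g) {
  ig <- net_igraph(g)
  nc <- igraph::count_components(ig)
  if (nc > 1L)
    stop("network is disconnected (", nc, " components)", call. = FALSE)
  ig
}

#' Convert an FPA network to an igraph object
#'
#' @param x An `fpa_network`.
#' @param ... Unused.
#' @return An undirected igraph graph with `degree`, `depth` and `parent`
#'   vertex attributes (`parent` is `NA` for the root).
#' @export
as.igraph.fpa_network <- function(x, ...) {
  ig <- igraph::graph_from_edgelist(x$edges, directed = FALSE)
  igraph::V(ig)$degree <- x$degree
  if (!is.null(x$depth)) igraph::V(ig)$depth <- x$depth
  if (!is.null(x$parent)) igraph::V(ig)$parent <- x$parent
  ig
}

#' Degree distribution, cumulative distribution and knn curve
#'
#' Tabulates, per observed degree k, the fraction `pdf` of nodes with degree
#' exactly k, the cumulative fraction `cdf` with degree >= k, and the mean
#' nearest-neighbour degree `knn` of k-degree nodes.
#'
#' @param net An `fpa_network`, igraph, or two-column edge matrix.
#' @return A data frame with columns `k`, `pdf`, `cdf`, `knn`, sorted by `k`.
#' @examples
#' net <- fpa_network(2000, f = 0.5, seed = 7)
#' head(degree_curves(net))
#' @export
degree_curves <- function(net) {
  g <- as_net_graph(net)
  k <- sort(unique(g$degree))
  cnt <- as.integer(table(factor(g$degree, levels = k)))
  pdf <- cnt / g$n
  cdf <- rev(cumsum(rev(cnt))) / g$n
  knn_k <- knn_curve(g)$by_degree
  out <- data.frame(k = k, pdf = pdf, cdf = cdf)
  out$knn <- knn_k$knn[match(out$k, knn_k$k)]
  attr(out, "n_nodes") <- g$n
  out
}

#' Mean nearest-neighbour degree curve
#'
#' Per node i, the mean degree of its neighbours; per degree class k, the
#' average over all k-degree nodes, \eqn{\langle k_{nn}(k)\rangle}. A falling
#' curve (negative log-log slope) marks a disassortative network.
#'
#' @inheritParams degree_curves
#' @return A list with `node` (per-node mean neighbour degree, `NA` for
#'   isolated nodes, which are excluded with a warning) and `by_degree`
#'   (data frame `k`, `knn`, `n_nodes`).
#' @export
knn_curve <- function(net) {
  g <- as_net_graph(net)
  deg <- g$degree
  if (any(deg == 0L)) warning("isolated nodes excluded from knn curve")
  e1 <- g$edges[, 1L]; e2 <- g$edges[, 2L]
  s <- numeric(g$n)
  acc <- rowsum(c(deg[e2], deg[e1]), group = c(e1, e2))
  s[as.integer(rownames(acc))] <- acc[, 1L]
  knn_node <- ifelse(deg > 0L, s / deg, NA_real_)
  keep <- deg > 0L
  by_deg <- data.frame(
    k = sort(unique(deg[keep])),
    knn = as.numeric(tapply(knn_node[keep], deg[keep], mean)),
    n_nodes = as.integer(table(deg[keep])))
  rownames(by_deg) <- NULL
  list(node = knn_node, by_degree = by_deg)
}

new_power_fit <- function(quantity, exponent, amplitude, k_range, stderr,
                          r_squared, n_points) {
  structure(list(quantity = quantity, exponent = exponent,
                 amplitude = amplitude, k_range = k_range, stderr = stderr,
                 r_squared = r_squared, n_points = n_points),
            class = "fpa_powerfit")
}

#' @export
print.fpa_powerfit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): exponent %.4f (se %.4f), amplitude %.4g\n",
              x$quantity, x$exponent, x$stderr, x$amplitude))
  cat(sprintf("  window k in [%g, %g], %d points, R^2 = %.4f\n",
              x$k_range[1], x$k_range[2], x$n_points, x$r_squared))
  invisible(x)
}

loglog_fit <- function(xv, yv, quantity, sign = -1) {
  keep <- is.finite(xv) & is.finite(yv) & xv > 0 & yv > 0
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3L)
    stop("need at least 3 points for a log-log fit", call. = FALSE)
  fit <- lm(log10(yv) ~ log10(xv))
  sm <- suppressWarnings(summary(fit))
  new_power_fit(quantity,
                exponent = sign * unname(coef(fit)[2L]),
                amplitude = 10^unname(coef(fit)[1L]),
                k_range = range(xv),
                stderr = unname(sm$coefficients[2L, 2L]),
                r_squared = sm$r.squared,
                n_points = length(xv))
}

#' Fit the cumulative degree distribution exponent beta
#'
#' Ordinary least squares of `log10 cdf(k)` against `log10 k` over the
#' distinct observed degrees; beta is the negated slope. The default window
#' starts at `kmin = m` for a generated network (else the smallest observed
#' degree) and excludes the extreme hub tail: degrees held by fewer than
#' `tail_min_count` nodes at-or-above form a near-flat staircase of single
#' hubs spread over a wide, high-leverage stretch of log k, and visibly
#' depart from the power law. On a noiseless power law the fit is exact
#' regardless of window. The window used is reported in the result.
#'
#' @param x An `fpa_network` (or anything [degree_curves()] accepts), or a
#'   data frame with columns `k` and `cdf` (node count taken from attribute
#'   `n_nodes` when present; without it the hub-staircase cut is skipped).
#' @param kmin Lower end of the fit window; default as described above.
#' @param tail_min_count Minimum number of nodes with degree >= k for k to
#'   enter the fit (default 10).
#' @return An `fpa_powerfit` with `exponent` = beta.
#' @examples
#' cur <- data.frame(k = 1:100, cdf = (1:100)^-2)
#' fit_ccdf_exponent(cur)$exponent  # 2 to machine precision
#' @export
fit_ccdf_exponent <- function(x, kmin = NULL, tail_min_count = 10L) {
  if (is.data.frame(x)) {
    cur <- x
    n_nodes <- attr(x, "n_nodes")
  } else {
    g <- as_net_graph(x)
    cur <- degree_curves(g)
    n_nodes <- g$n
    if (is.null(kmin) && !is.na(g$m)) kmin <- g$m
  }
  kv <- cur$k[cur$cdf > 0]
  cdf <- cur$cdf[cur$cdf > 0]
  if (!is.null(n_nodes)) {
    keep <- cdf >= tail_min_count / n_nodes
    if (sum(keep) >= 3L) { kv <- kv[keep]; cdf <- cdf[keep] }
  }
  if (is.null(kmin)) kmin <- min(kv)
  sel <- kv >= kmin
  loglog_fit(kv[sel], cdf[sel], "beta (CCDF)", sign = -1)
}

#' Fit the degree-correlation exponent alpha
#'
#' Least squares of `log10 <knn(k)>` against `log10 k` over degree classes
#' with at least `min_class` nodes; alpha is the signed slope, negative for
#' disassortative networks. The default uses every observed degree class:
#' sparse high-degree classes are individually noisy but numerous, and
#' excluding them truncates the curve's flat tail and biases alpha away from
#' zero on weakly correlated networks.
#'
#' @param x An `fpa_network` (or anything [knn_curve()] accepts), or a data
#'   frame with columns `k`, `knn` and optionally `n_nodes`.
#' @param min_class Minimum nodes per degree class (default 1, i.e. all
#'   classes).
#' @param kmin Optional lower degree bound for the window.
#' @return An `fpa_powerfit` with `exponent` = alpha (signed).
#' @examples
#' cur <- data.frame(k = 1:50, knn = 100 * (1:50)^-1)
#' fit_alpha(cur)$exponent  # -1
#' @export
fit_alpha <- function(x, min_class = 1L, kmin = NULL) {
  if (is.data.frame(x)) {
    cur <- x
    if (is.null(cur$n_nodes)) cur$n_nodes <- min_class
  } else {
    cur <- knn_curve(as_net_graph(x))$by_degree
  }
  sel <- cur$n_nodes >= min_class
  if (!is.null(kmin)) sel <- sel & cur$k >= kmin
  loglog_fit(cur$k[sel], cur$knn[sel], "alpha (knn)", sign = +1)
}

#' Local clustering coefficients and their average
#'
#' \eqn{C_j = 2x/(k_j(k_j-1))} with x the number of links among j's
#' neighbours; defined as 0 for nodes of degree < 2 and included in the
#' average, so the mean clustering of any tree is exactly 0.
#'
#' @inheritParams degree_curves
#' @return A list with `local` (per-node C_j) and `average`.
#' @export
clustering_coeff <- function(net) {
  g <- as_net_graph(net)
  if (is_tree_graph(g)) {
    local <- numeric(g$n)          # a tree has no triangles
  } else {
    local <- igraph::transitivity(net_igraph(g), type = "local",
                                  isolates = "zero")
    local[is.na(local)] <- 0
  }
  list(local = local, average = mean(local))
}

bfs_dist <- function(ig, from) {
  as.vector(igraph::distances(ig, v = from))
}

#' Network diameter
#'
#' Longest shortest path. Trees: exact double-BFS. General graphs up to
#' `exact_max_n` nodes: exact all-sources BFS. Larger general graphs: the
#' maximum eccentricity over double sweeps from the `n_sweeps` highest-degree
#' roots, reported as a lower-bound estimate (`exact = FALSE`).
#'
#' @inheritParams degree_curves
#' @param exact_max_n Size limit for the exact all-sources computation on
#'   non-tree graphs (default 20000).
#' @param n_sweeps Number of high-degree sweep roots for large general
#'   graphs (default 20).
#' @return A list with `value`, `exact` (logical) and `method`.
#' @export
net_diameter <- function(net, exact_max_n = 20000L, n_sweeps = 20L) {
  g <- as_net_graph(net)
  ig <- assert_connected(g)
  if (is_tree_graph(g)) {
    d1 <- bfs_dist(ig, 1L)
    u <- which.max(d1)
    d2 <- bfs_dist(ig, u)
    return(list(value = max(d2), exact = TRUE, method = "double-bfs"))
  }
  if (g$n <= exact_max_n) {
    return(list(value = igraph::diameter(ig, directed = FALSE),
                exact = TRUE, method = "all-sources-bfs"))
  }
  roots <- order(g$degree, decreasing = TRUE)[seq_len(min(n_sweeps, g$n))]
  best <- 0
  for (r in roots) {
    d1 <- bfs_dist(ig, r)
    u <- which.max(d1)
    ecc <- max(bfs_dist(ig, u))
    if (ecc > best) best <- ecc
  }
  list(value = best, exact = FALSE, method = "double-sweep")
}

# Subtree sizes of a tree given parent pointers with parent id < child id
# (true for m = 1 growth); otherwise derive an order via BFS.
tree_subtree_sizes <- function(g) {
  n <- g$n
  if (length(g$parent) == n && length(g$depth) == n &&
      all(g$parent[-1L] < seq.int(2L, n))) {
    parent <- g$parent
    ord <- seq_len(n)
  } else {
    ig <- net_igraph(g)
    b <- igraph::bfs(ig, root = 1, father = TRUE, order = TRUE)
    parent <- as.integer(b$father)
    ord <- as.integer(b$order)
  }
  sz <- rep(1L, n)
  for (v in rev(ord)) {
    p <- parent[v]
    if (!is.na(p)) sz[p] <- sz[p] + sz[v]
  }
  list(sizes = sz, parent = parent)
}

#' Average shortest path length
#'
#' Trees: exact in linear time via the edge-cut identity
#' \eqn{L = \sum_e s_e (N - s_e) / \binom{N}{2}}, where \eqn{s_e} is the
#' subtree size under edge e. General graphs: mean distance over BFS from
#' `min(N, n_samples)` uniformly sampled sources (seed-controlled through the
#' R RNG); exact when every node is sampled.
#'
#' @inheritParams degree_curves
#' @param n_samples Number of BFS sources for general graphs (default 1000).
#' @return A list with `value`, `exact`, `method`, and `n_sources` where
#'   sampled.
#' @examples
#' p3 <- rbind(c(1, 2), c(2, 3))
#' avg_path_length(p3)$value  # 4/3
#' @export
avg_path_length <- function(net, n_samples = 1000L) {
  g <- as_net_graph(net)
  ig <- assert_connected(g)
  n <- g$n
  if (is_tree_graph(g)) {
    st <- tree_subtree_sizes(g)
    s <- as.numeric(st$sizes[!is.na(st$parent)])
    L <- sum(s * (n - s)) / choose(n, 2)
    return(list(value = L, exact = TRUE, method = "tree-edge-cut"))
  }
  ns <- min(n, n_samples)
  src <- if (ns == n) seq_len(n) else sort(sample.int(n, ns))
  total <- 0
  for (chunk in split(src, ceiling(seq_along(src) / 100))) {
    total <- total + sum(igraph::distances(ig, v = chunk))
  }
  list(value = total / (ns * (n - 1)), exact = ns == n,
       method = if (ns == n) "all-sources-bfs" else "sampled-bfs",
       n_sources = ns)
}

#' Ultra-small-world reference path length
#'
#' The scaling reference \eqn{\ln N / \ln\ln N} to which the measured average
#' path length of an uncorrelated scale-free network is compared.
#'
#' @param n Number of nodes (>= 16, so the double logarithm is well away from
#'   its singularity).
#' @return `log(n) / log(log(n))`.
#' @examples
#' ultra_small_reference(1e5)  # ~4.71
#' @export
ultra_small_reference <- function(n) {
  if (!is.numeric(n) || any(n < 16))
    stop("`n` must be >= 16 for a stable double logarithm", call. = FALSE)
  log(n) / log(log(n))
}

#' Topology summary of a network
#'
#' One row of summary statistics: degree-correlation exponent alpha, average
#' local clustering, mean degree, diameter, average shortest path, maximum
#' degree and CCDF exponent beta, with the fit objects and exact/estimate
#' labels attached.
#'
#' @inheritParams degree_curves
#' @inheritParams fit_ccdf_exponent
#' @inheritParams fit_alpha
#' @param n_samples BFS sample size for the path length of large non-tree
#'   graphs; see [avg_path_length()].
#' @param exact_max_n See [net_diameter()].
#' @return An object of class `fpa_topology`.
#' @export
topology_summary <- function(net, kmin = NULL, tail_min_count = 10L,
                             min_class = 1L, n_samples = 1000L,
                             exact_max_n = 20000L) {
  g <- as_net_graph(net)
  cur <- degree_curves(g)
  beta_fit <- fit_ccdf_exponent(cur, kmin = kmin,
                                tail_min_count = tail_min_count)
  alpha_fit <- fit_alpha(knn_curve(g)$by_degree, min_class = min_class)
  dia <- net_diameter(g, exact_max_n = exact_max_n)
  apl <- avg_path_length(g, n_samples = n_samples)
  structure(list(
    n = g$n, m = g$m, f = g$f,
    alpha = alpha_fit$exponent,
    rho = clustering_coeff(g)$average,
    mean_degree = 2 * nrow(g$edges) / g$n,
    diameter = dia$value, diameter_exact = dia$exact,
    avg_path = apl$value, avg_path_exact = apl$exact,
    kmax = max(g$degree),
    beta = beta_fit$exponent,
    ultra_small_ref = ultra_small_reference(max(g$n, 16)),
    beta_fit = beta_fit, alpha_fit = alpha_fit),
    class = "fpa_topology")
}

#' @export
print.fpa_topology <- function(x, ...) {
  cat(sprintf("FPA topology summary (N = %d, m = %s, f = %s)\n",
              x$n, format(x$m), format(x$f)))
  cat(sprintf("  alpha  %8.3f    rho  %8.4f    <k>   %8.4f\n",
              x$alpha, x$rho, x$mean_degree))
  cat(sprintf("  D      %8d%s   L    %8.3f%s   kmax  %8d\n",
              as.integer(x$diameter), if (x$diameter_exact) " " else "*",
              x$avg_path, if (x$avg_path_exact) " " else "*",
              as.integer(x$kmax)))
  cat(sprintf("  beta   %8.3f    ln N / ln ln N = %.2f\n",
              x$beta, x$ultra_small_ref))
  if (!x$diameter_exact || !x$avg_path_exact)
    cat("  (* sampled or lower-bound estimate)\n")
  invisible(x)
}

#' @export
as.data.frame.fpa_topology <- function(x, ...) {
  data.frame(n = x$n, m = x$m, f = x$f, alpha = x$alpha, rho = x$rho,
             mean_degree = x$mean_degree, diameter = x$diameter,
             avg_path = x$avg_path, kmax = x$kmax, beta = x$beta,
             diameter_exact = x$diameter_exact,
             avg_path_exact = x$avg_path_exact)
}
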