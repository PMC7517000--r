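# Plain-text network interchange: TSV edge lists (0-based ids, '#' comment
# lines carrying generation metadata), node tables, and GraphML via igraph.

#' Write a network as a TSV edge list
#'
#' Two tab-separated columns of 0-based node ids, one undirected edge per
#' line; leading `#` comment lines record the generation parameters.
#'
#' @param net An `fpa_network` (or anything [degree_curves()] accepts).
#' @param path Output file path.
#' @export
write_edgelist <- function(net, path) {
  g <- as_net_graph(net)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# fpanet edge list (0-based node ids)",
               sprintf("# n=%d m=%s f=%s seed=%s", g$n, format(g$m),
                       format(g$f),
                       if (inherits(net, "fpa_network") && !is.null(net$seed))
                         format(net$seed) else "NA")), con)
  write.table(g$edges - 1L, con, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
}

#' Read a TSV edge list
#'
#' @param path File written by [write_edgelist()] or any two-column TSV of
#'   0-based integer node ids (`#` lines ignored).
#' @return An `fpa_network`-classed object carrying edges and degrees;
#'   parent/depth are unavailable for externally supplied networks. `m` and
#'   `f` are recovered from the metadata comments when present.
#' @export
read_edgelist <- function(path) {
  meta <- grep("^#", readLines(path, n = 10L), value = TRUE)
  get_meta <- function(key) {
    hit <- regmatches(meta, regexpr(sprintf("%s=[^ ]+", key), meta))
    if (length(hit)) sub(".*=", "", hit[[1]]) else NA_character_
  }
  edges <- as.matrix(read.table(path, comment.char = "#",
                                colClasses = "integer")) + 1L
  dimnames(edges) <- NULL
  n <- max(edges)
  new_fpa_network(
    n = n,
    m = suppressWarnings(as.integer(get_meta("m"))),
    f = suppressWarnings(as.numeric(get_meta("f"))),
    m0 = NA_integer_,
    seed = suppressWarnings(as.integer(get_meta("seed"))),
    engine = "file",
    edges = edges,
    degree = tabulate(c(edges[, 1L], edges[, 2L]), nbins = n),
    parent = NULL, depth = NULL)
}

#' Write the per-node table
#'
#' TSV with header `node  parent  depth  degree`, 0-based ids, the root's
#' parent written as -1.
#'
#' @param net An `fpa_network` with parent/depth information.
#' @param path Output file path.
#' @export
write_node_table <- function(net, path) {
  stopifnot(inherits(net, "fpa_network"))
  if (is.null(net$parent))
    stop("network carries no parent pointers (externally read?)",
         call. = FALSE)
  par <- ifelse(is.na(net$parent), -1L, net$parent - 1L)
  df <- data.frame(node = seq_len(net$n) - 1L, parent = par,
                   depth = net$depth, degree = net$degree)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Write a network as GraphML
#'
#' Vertex attributes `degree`, `depth` and `parent` (0-based, -1 for the
#' root) are attached when available.
#'
#' @inheritParams write_node_table
#' @export
write_graphml <- function(net, path) {
  ig <- if (inherits(net, "fpa_network")) as.igraph(net)
        else net_igraph(as_net_graph(net))
  if (!is.null(igraph::V(ig)$parent)) {
    p <- igraph::V(ig)$parent
    igraph::V(ig)$parent <- ifelse(is.na(p), -1L, p - 1L)
  }
  igraph::write_graph(ig, path, format = "graphml")
}

#' Read a GraphML network
#'
#' @param path A GraphML file.
#' @return An `fpa_network`-classed object (degrees recomputed from the edge
#'   list; `parent`/`depth` recovered when the file carries them).
#' @export
read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(ig, names = FALSE)
  storage.mode(el) <- "integer"
  n <- igraph::vcount(ig)
  par <- igraph::vertex_attr(ig, "parent")
  if (!is.null(par)) {
    par <- as.integer(par)
    par <- ifelse(par < 0L, NA_integer_, par + 1L)
  }
  dep <- igraph::vertex_attr(ig, "depth")
  new_fpa_network(n = n, m = NA_integer_, f = NA_real_, m0 = NA_integer_,
                  seed = NULL, engine = "file", edges = el,
                  degree = tabulate(c(el[, 1L], el[, 2L]), nbins = n),
                  parent = par,
                  depth = if (is.null(dep)) NULL else as.integer(dep))
}
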