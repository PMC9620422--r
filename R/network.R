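#' Directed gene network
#'
#' Construct a directed gene network from an edge table. The direction
#' convention throughout the package is source = regulator, target =
#' regulated gene: an edge `a -> b` means gene `a` regulates gene `b`.
#' Gene identifiers are opaque, case-sensitive strings; no symbol mapping is
#' attempted.
#'
#' Self-loops are dropped and duplicate edges collapsed at construction (both
#' with a message reporting the counts), so the stored edge set has set
#' semantics. Nodes and edges are kept in sorted order, which makes every
#' downstream computation independent of input row order.
#'
#' @param from,to Character vectors of equal length: regulator and regulated
#'   gene of each edge.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   nodes; the node set is the union of `nodes` and all edge endpoints.
#' @param name Free-text label for the network.
#' @return An object of class `gene_network` with elements `nodes`
#'   (sorted character), `edges` (data.frame with columns `from`, `to`),
#'   and `name`.
#' @examples
#' net <- gene_network(c("a", "b"), c("b", "c"))
#' net$nodes
#' @export
gene_network <- function(from = character(), to = character(),
                         nodes = character(), name = "network") {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop_domain("'from' and 'to' must have equal length")
  }
  if (any(!nzchar(from)) || any(!nzchar(to)) || anyNA(from) || anyNA(to)) {
    stop_domain("gene identifiers must be non-empty strings")
  }
  self <- from == to
  if (any(self)) {
    message("dropped ", sum(self), " self-loop edge(s)")
    from <- from[!self]
    to <- to[!self]
  }
  key <- paste(from, to, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("collapsed ", sum(dup), " duplicate edge(s)")
    from <- from[!dup]
    to <- to[!dup]
  }
  all_nodes <- sort(unique(c(as.character(nodes), from, to)), method = "radix")
  ord <- order(from, to, method = "radix")
  structure(
    list(
      nodes = all_nodes,
      edges = data.frame(from = from[ord], to = to[ord],
                         stringsAsFactors = FALSE),
      name = name
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", x$name, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

#' Read a directed network from an edge-list file
#'
#' Supported formats: `tsv` — two or more tab-separated columns
#' (source, target, extra columns ignored), lines starting with `#` treated
#' as comments; `sif` — `source<TAB>relation<TAB>target[<TAB>target...]`,
#' one row expanding to one edge per listed target. Duplicate rows and
#' self-loops are dropped (and counted) by [gene_network()].
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"sif"`.
#' @param name Label for the network; defaults to the file name.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, format = c("tsv", "sif"), name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_domain("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- which(keep)
  if (length(rows) == 0L) stop_domain("empty network: no edges in ", path)
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  min_fields <- if (format == "tsv") 2L else 3L
  bad <- which(vapply(fields, length, 1L) < min_fields)
  if (length(bad)) {
    stop_domain("malformed ", format, " row at line ", rows[bad[1]],
                ": expected at least ", min_fields, " tab-separated fields")
  }
  if (format == "tsv") {
    from <- vapply(fields, `[[`, "", 1L)
    to <- vapply(fields, `[[`, "", 2L)
  } else {
    from <- unlist(lapply(fields, function(f) rep(f[[1L]], length(f) - 2L)))
    to <- unlist(lapply(fields, function(f) f[-(1:2)]))
  }
  net <- gene_network(from, to, name = name)
  if (n_edges(net) == 0L) stop_domain("empty network: no edges left after ",
                                      "dropping self-loops in ", path)
  net
}

#' Write a network as a two-column TSV edge list
#'
#' @param net A [gene_network()].
#' @param path Output path.
#' @param header Write a `#source  target` comment header line.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, header = TRUE) {
  stopifnot(inherits(net, "gene_network"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("#source\ttarget", con)
  writeLines(paste(net$edges$from, net$edges$to, sep = "\t"), con)
  invisible(path)
}

# Integer adjacency lists, index-aligned with net$nodes.
# mode "out": successors; "in": predecessors; "all": union (for undirected
# h-hop expansion around seed genes).
adjacency <- function(net, mode = c("out", "in", "all")) {
  mode <- match.arg(mode)
  n <- n_nodes(net)
  fi <- match(net$edges$from, net$nodes)
  ti <- match(net$edges$to, net$nodes)
  lev <- seq_len(n)
  out <- switch(mode,
    out = unname(split(ti, factor(fi, levels = lev))),
    `in` = unname(split(fi, factor(ti, levels = lev))),
    all = {
      a <- unname(split(c(ti, fi), factor(c(fi, ti), levels = lev)))
      lapply(a, unique)
    }
  )
  out
}

# Distinct nodes reachable from `start` (1-based index) within <= h hops,
# excluding `start` itself. Bounded breadth-first search over integer
# adjacency lists; cycles cannot inflate the count because visited nodes are
# never re-entered.
bounded_reach <- function(adj, start, h, n) {
  visited <- logical(n)
  visited[start] <- TRUE
  frontier <- start
  for (layer in seq_len(h)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!visited[nxt]]
    if (length(nxt) == 0L) break
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  visited[start] <- FALSE
  which(visited)
}

#' h-layer neighborhood (HLN) profile
#'
#' For every node `v`, the HLN value is the number of *distinct* downstream
#' nodes (excluding `v` itself) reachable from `v` along directed edges in at
#' most `h` hops. The profile also carries the mean and standard deviation of
#' all HLN values, the statistics from which the candidate-driver cutoff
#' mean + SD is formed. The SD uses the population convention (see
#' [pop_sd()]), fixed so thresholds are exactly reproducible.
#'
#' At `h = 1` the HLN equals the out-degree; HLN is non-decreasing in `h` and
#' saturates at the size of the full descendant set.
#'
#' @param net A [gene_network()].
#' @param h Positive integer traversal depth.
#' @return An object of class `hln_profile`: list with `h`, `values` (named
#'   integer vector over all nodes), `mu_bar`, `sigma_mu`.
#' @examples
#' net <- gene_network(c("a", "b", "c"), c("b", "c", "d"))
#' h_layer_neighborhood(net, 2)$values
#' @export
h_layer_neighborhood <- function(net, h) {
  stopifnot(inherits(net, "gene_network"))
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 1 || h != round(h)) {
    stop_domain("'h' must be a positive integer")
  }
  h <- as.integer(h)
  n <- n_nodes(net)
  if (n == 0L) stop_domain("empty network")
  adj <- adjacency(net, "out")
  values <- vapply(seq_len(n), function(v) length(bounded_reach(adj, v, h, n)), 1L)
  names(values) <- net$nodes
  structure(
    list(h = h, values = values,
         mu_bar = mean(values), sigma_mu = pop_sd(values)),
    class = "hln_profile"
  )
}

#' @export
print.hln_profile <- function(x, ...) {
  cat("<hln_profile> h=", x$h, ", ", length(x$values), " nodes, mean HLN ",
      signif(x$mu_bar, 4), ", SD ", signif(x$sigma_mu, 4), "\n", sep = "")
  invisible(x)
}

#' Out-degree profile
#'
#' Number of distinct regulated targets per node, with the mean and
#' population standard deviation used by the out-degree global-driver rule.
#'
#' @param net A [gene_network()].
#' @return List with `values` (named integer vector), `d_bar`, `sigma_d`.
#' @export
out_degrees <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  n <- n_nodes(net)
  if (n == 0L) stop_domain("empty network")
  values <- tabulate(match(net$edges$from, net$nodes), nbins = n)
  names(values) <- net$nodes
  list(values = values, d_bar = mean(values), sigma_d = pop_sd(values))
}

# Induced subgraph on a subset of node names.
induced_subnetwork <- function(net, node_names, name = paste0(net$name, ":sub")) {
  keep_nodes <- intersect(net$nodes, node_names)
  e <- net$edges
  keep <- e$from %in% keep_nodes & e$to %in% keep_nodes
  gene_network(e$from[keep], e$to[keep], nodes = keep_nodes, name = name)
}
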