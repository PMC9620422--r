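#' Candidate driver selection from an HLN profile
#'
#' A node is a candidate driver when its h-layer neighborhood size strictly
#' exceeds the network-wide mean plus one (population) standard deviation of
#' all HLN values. Ties at the cutoff are excluded: the rule is "greater
#' than", so a degenerate profile in which every node has the same HLN yields
#' no candidates (the SD is zero and strict inequality fails).
#'
#' @param profile An [h_layer_neighborhood()] profile.
#' @return Sorted character vector of candidate gene identifiers.
#' @export
select_candidate_drivers <- function(profile) {
  stopifnot(inherits(profile, "hln_profile"))
  if (length(profile$values) == 0L) stop_domain("empty HLN profile")
  cutoff <- profile$mu_bar + profile$sigma_mu
  sort(names(profile$values)[profile$values > cutoff], method = "radix")
}

#' Global/local classification of candidate drivers
#'
#' A candidate is a *global* driver when it has no root node, interpreted as:
#' no other candidate reaches it within `h` directed hops (it lies in no
#' other candidate's h-layer neighborhood). Candidates that are downstream of
#' another candidate are *local* drivers. An alternative reading of "root
#' node" — a graph source — is available as `root_mode = "indegree0"`, under
#' which a candidate is global iff its in-degree in `net` is zero.
#'
#' @param net A [gene_network()].
#' @param candidates Character vector of candidate genes, all in `net$nodes`.
#' @param h Positive integer traversal depth (the same `h` used to compute
#'   the profile).
#' @param root_mode `"candidate"` (default; root = upstream candidate) or
#'   `"indegree0"`.
#' @return List with sorted character vectors `global` and `local`
#'   partitioning `candidates`.
#' @examples
#' net <- gene_network(c("a", "b"), c("b", "c"))
#' classify_drivers(net, c("a", "c"), h = 2)
#' @export
classify_drivers <- function(net, candidates, h,
                             root_mode = c("candidate", "indegree0")) {
  stopifnot(inherits(net, "gene_network"))
  root_mode <- match.arg(root_mode)
  candidates <- sort(unique(as.character(candidates)), method = "radix")
  missing <- setdiff(candidates, net$nodes)
  if (length(missing)) {
    stop_domain("candidate gene(s) not in network: ",
                paste(missing, collapse = ", "))
  }
  if (length(candidates) == 0L) {
    return(list(global = character(), local = character()))
  }
  if (root_mode == "indegree0") {
    indeg <- tabulate(match(net$edges$to, net$nodes), nbins = n_nodes(net))
    names(indeg) <- net$nodes
    is_global <- indeg[candidates] == 0L
  } else {
    adj <- adjacency(net, "out")
    idx <- match(candidates, net$nodes)
    n <- n_nodes(net)
    # one bounded BFS per candidate; a candidate is local iff it lies in some
    # other candidate's h-layer neighborhood (its own is excluded by
    # construction: bounded_reach never returns the start node)
    is_local <- logical(length(idx))
    for (u in seq_along(idx)) {
      reach_u <- bounded_reach(adj, idx[u], h, n)
      is_local[match(intersect(reach_u, idx), idx)] <- TRUE
    }
    is_global <- !is_local
  }
  list(global = candidates[is_global], local = candidates[!is_global])
}

#' Out-degree rule for global driver genes
#'
#' Nodes whose out-degree strictly exceeds the mean plus two (population)
#' standard deviations of all out-degrees. This is the second, more
#' selective global-driver definition; it is computed and reported alongside
#' the root-node classification rather than merged with it.
#'
#' @param net A [gene_network()].
#' @return Sorted character vector of gene identifiers.
#' @export
global_by_out_degree <- function(net) {
  od <- out_degrees(net)
  cutoff <- od$d_bar + 2 * od$sigma_d
  sort(names(od$values)[od$values > cutoff], method = "radix")
}

#' Key driver analysis
#'
#' Given a directed gene network `N` and a seed gene set `G` (typically the
#' differentially expressed genes), identifies the key regulators of `G`:
#'
#' 1. Builds the seed-associated analysis subnetwork: the seed genes present
#'    in `net` plus every node within `h` hops of a seed in either edge
#'    direction, with induced edges. (The paper-level method receives a
#'    vendor-built subnetwork around the gene set; this construction makes
#'    the analysis an explicit, reproducible function of `(net, G, h)`.)
#' 2. Computes the h-layer neighborhood profile on the subnetwork.
#' 3. Selects candidates with HLN > mean + SD
#'    ([select_candidate_drivers()]), partitions them into global ("key
#'    driver genes") and local drivers via the root-node rule
#'    ([classify_drivers()]), and separately applies the out-degree rule
#'    ([global_by_out_degree()]).
#'
#' The result is a pure function of `(net, seed_genes, h)`: input row order
#' never affects it.
#'
#' @param net A [gene_network()].
#' @param seed_genes Character vector of seed genes; genes absent from the
#'   network are dropped with a warning.
#' @param h Positive integer neighborhood depth (default 2).
#' @param root_mode Passed to [classify_drivers()].
#' @return An object of class `driver_call_set`: list with `h`, `seed_genes`
#'   (the effective seeds), `candidates`, `global_drivers`, `local_drivers`,
#'   `outdegree_globals` (all sorted character vectors), `thresholds`
#'   (`mu_bar`, `sigma_mu`, `hln_cutoff`, `d_bar`, `sigma_d`,
#'   `degree_cutoff`), `profile` (the subnetwork [h_layer_neighborhood()]),
#'   `out_degree` (named vector on the subnetwork) and `subnetwork`.
#' @examples
#' net <- gene_network(c("hub", "hub", "hub", "a"), c("a", "b", "c", "d"))
#' run_kda(net, seed_genes = c("a", "b", "c"), h = 2)
#' @export
run_kda <- function(net, seed_genes, h = 2,
                    root_mode = c("candidate", "indegree0")) {
  stopifnot(inherits(net, "gene_network"))
  root_mode <- match.arg(root_mode)
  seed_genes <- unique(as.character(seed_genes))
  eff <- intersect(seed_genes, net$nodes)
  dropped <- setdiff(seed_genes, eff)
  if (length(dropped)) {
    warning(length(dropped), " seed gene(s) absent from the network were dropped",
            call. = FALSE)
  }
  if (length(eff) == 0L) stop_domain("no seed genes in network")

  # subnetwork: seeds +- h hops, either edge direction, induced edges
  adj_all <- adjacency(net, "all")
  n <- n_nodes(net)
  in_sub <- logical(n)
  seed_idx <- match(eff, net$nodes)
  in_sub[seed_idx] <- TRUE
  frontier <- seed_idx
  for (layer in seq_len(h)) {
    nxt <- unique(unlist(adj_all[frontier], use.names = FALSE))
    nxt <- nxt[!in_sub[nxt]]
    if (length(nxt) == 0L) break
    in_sub[nxt] <- TRUE
    frontier <- nxt
  }
  sub <- induced_subnetwork(net, net$nodes[in_sub],
                            name = paste0(net$name, ":kda"))

  profile <- h_layer_neighborhood(sub, h)
  od <- out_degrees(sub)
  candidates <- select_candidate_drivers(profile)
  cls <- classify_drivers(sub, candidates, h, root_mode = root_mode)
  od_globals <- global_by_out_degree(sub)

  structure(
    list(
      h = h,
      seed_genes = sort(eff, method = "radix"),
      candidates = candidates,
      global_drivers = cls$global,
      local_drivers = cls$local,
      outdegree_globals = od_globals,
      thresholds = list(
        mu_bar = profile$mu_bar,
        sigma_mu = profile$sigma_mu,
        hln_cutoff = profile$mu_bar + profile$sigma_mu,
        d_bar = od$d_bar,
        sigma_d = od$sigma_d,
        degree_cutoff = od$d_bar + 2 * od$sigma_d
      ),
      profile = profile,
      out_degree = od$values,
      subnetwork = sub,
      root_mode = root_mode
    ),
    class = "driver_call_set"
  )
}

#' @export
print.driver_call_set <- function(x, ...) {
  cat("<driver_call_set> h=", x$h, ": ", length(x$seed_genes), " seeds, ",
      n_nodes(x$subnetwork), "-node subnetwork\n",
      "  candidates: ", length(x$candidates),
      " (HLN > ", signif(x$thresholds$hln_cutoff, 4), ")\n",
      "  global drivers (root-node rule): ", length(x$global_drivers), "\n",
      "  local drivers: ", length(x$local_drivers), "\n",
      "  out-degree global driver genes (> ",
      signif(x$thresholds$degree_cutoff, 4), "): ",
      length(x$outdegree_globals), "\n", sep = "")
  invisible(x)
}

#' Per-gene KDA result table
#'
#' @param x A `driver_call_set` from [run_kda()].
#' @param ... Unused.
#' @return data.frame with columns `gene`, `hln`, `out_degree`,
#'   `is_candidate`, `driver_class` (`global`/`local`/`none`) and
#'   `passes_outdegree_rule`, sorted by decreasing HLN then gene.
#' @export
as.data.frame.driver_call_set <- function(x, ...) {
  genes <- names(x$profile$values)
  df <- data.frame(
    gene = genes,
    hln = unname(x$profile$values),
    out_degree = unname(x$out_degree[genes]),
    is_candidate = genes %in% x$candidates,
    driver_class = ifelse(genes %in% x$global_drivers, "global",
                          ifelse(genes %in% x$local_drivers, "local", "none")),
    passes_outdegree_rule = genes %in% x$outdegree_globals,
    stringsAsFactors = FALSE
  )
  df[order(-df$hln, df$gene, method = "radix"), , drop = FALSE]
}
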