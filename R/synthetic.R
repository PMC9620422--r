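#' Synthetic ground truth
#'
#' Record of what a generator planted, carried alongside the generated data
#' so every pipeline stage can be scored against known truth. Serializes
#' losslessly to a JSON sidecar ([write_truth()] / [read_truth()]).
#'
#' @param ... Named truth fields (`planted_drivers`, `driver_targets`,
#'   `de_genes`, `enriched_terms`, ...), plus `rng_seed` and
#'   `generator_params`.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(...) {
  structure(list(...), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> fields:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write/read a truth sidecar as JSON
#' @param truth A [synthetic_truth()].
#' @param path JSON path.
#' @return `path` invisibly (write); a [synthetic_truth()] (read).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_truth, x)
}

#' Generate a directed network with planted high-fan-out drivers
#'
#' Plants `n_drivers` regulator hubs, each wired to `fanout` distinct
#' non-driver target genes, inside a sparse random background. The
#' background is Erdos-Renyi by default (every ordered non-self pair gains
#' an edge independently with `background_edge_prob`); a preferential-
#' attachment mode (`model = "preferential"`) is provided because real
#' regulatory networks are heavy-tailed — there, each successively added
#' gene is wired from `pa_edges_per_node` existing regulators chosen with
#' probability proportional to out-degree + 1, and `background_edge_prob`
#' is ignored.
#'
#' Planted drivers receive no incoming edges: a planted key driver is the
#' apex of its regulatory cascade by construction. (If background edges were
#' allowed into a driver, its parents would be genuine — but unlabeled —
#' key drivers of the same cascade, and recovery benchmarks against
#' `planted_drivers` would be scored against semantically wrong truth.)
#'
#' @param n_nodes Total genes, default 1000.
#' @param n_drivers Planted drivers, default 5.
#' @param fanout Targets per driver, default 30.
#' @param background_edge_prob Background edge probability, default 0.002.
#' @param seed Integer RNG seed.
#' @param model `"erdos_renyi"` (default) or `"preferential"`.
#' @param pa_edges_per_node Out-edges wired into each new node in
#'   preferential mode, default 2.
#' @return List with `network` (a [gene_network()]) and `truth` (a
#'   [synthetic_truth()] with `planted_drivers`, `driver_targets` — the
#'   union of all targets, the natural seed set for driver-recovery runs —
#'   `driver_fanout`, `rng_seed`, `generator_params`).
#' @export
generate_planted_network <- function(n_nodes = 1000, n_drivers = 5,
                                     fanout = 30,
                                     background_edge_prob = 0.002,
                                     seed = 1,
                                     model = c("erdos_renyi", "preferential"),
                                     pa_edges_per_node = 2) {
  model <- match.arg(model)
  if (n_drivers * fanout >= n_nodes) {
    stop_domain("infeasible parameters: need n_drivers * fanout < n_nodes")
  }
  if (background_edge_prob < 0 || background_edge_prob > 1) {
    stop_domain("background_edge_prob must lie in [0, 1]")
  }
  genes <- sprintf("g%05d", seq_len(n_nodes))
  with_seed(seed, {
    drivers <- sort(sample(genes, n_drivers))
    non_drivers <- setdiff(genes, drivers)
    from <- rep(drivers, each = fanout)
    to <- unlist(lapply(drivers, function(d) sample(non_drivers, fanout)))
    if (model == "erdos_renyi") {
      n_pairs <- as.double(n_nodes) * (n_nodes - 1)
      m <- stats::rbinom(1, n_pairs, background_edge_prob)
      idx <- sample(n_pairs, m)
      src <- (idx - 1) %/% (n_nodes - 1) + 1
      tgt <- (idx - 1) %% (n_nodes - 1) + 1
      tgt <- ifelse(tgt >= src, tgt + 1, tgt)  # skip the diagonal
      bg_from <- genes[src]
      bg_to <- genes[tgt]
    } else {
      # growing network: node i picks regulators among earlier nodes with
      # probability proportional to current out-degree + 1
      deg <- integer(n_nodes)
      bg_from <- character(0)
      bg_to <- character(0)
      for (i in 2:n_nodes) {
        k <- min(pa_edges_per_node, i - 1)
        regs <- sample.int(i - 1, k, prob = deg[seq_len(i - 1)] + 1)
        deg[regs] <- deg[regs] + 1
        bg_from <- c(bg_from, genes[regs])
        bg_to <- c(bg_to, rep(genes[i], k))
      }
    }
    # drivers are apex regulators: no incoming background edges
    keep <- !(bg_to %in% drivers)
    from <- c(from, bg_from[keep])
    to <- c(to, bg_to[keep])
    net <- suppressMessages(
      gene_network(from, to, nodes = genes, name = "planted")
    )
    truth <- synthetic_truth(
      planted_drivers = drivers,
      driver_targets = sort(unique(to[seq_len(n_drivers * fanout)])),
      driver_fanout = fanout,
      rng_seed = seed,
      generator_params = list(
        n_nodes = n_nodes, n_drivers = n_drivers, fanout = fanout,
        background_edge_prob = background_edge_prob, model = model,
        pa_edges_per_node = pa_edges_per_node
      )
    )
    list(network = net, truth = truth)
  })
}

#' Generate a DE table with planted effects
#'
#' A fraction `frac_de` of genes carries true effects: log2 fold changes
#' drawn from Normal(`lfc_effect_mean`, `lfc_effect_sd`) with random sign,
#' and sharply small p-values (Beta(0.5, 2000), typical p around 1e-4 —
#' what a genuine DE test yields for effects of this size). Null genes get
#' log2fc ~ Normal(0, 0.2) and p ~ Uniform(0, 1). Q-values are
#' Benjamini-Hochberg over all p-values.
#'
#' @param n_genes Number of genes, default 2000. Ignored when `genes` is
#'   supplied.
#' @param frac_de Fraction of genes with true effects, in (0, 1); also 0 is
#'   accepted for pure-null tables. Default 0.1.
#' @param lfc_effect_mean,lfc_effect_sd Effect-size distribution on the
#'   log2 scale, defaults 2 and 0.5.
#' @param seed Integer RNG seed.
#' @param genes Optional character vector of gene identifiers (e.g. the
#'   nodes of a generated network) to use instead of synthetic names.
#' @return List with `table` (a [deg_table()]) and `truth` (`de_genes`,
#'   `rng_seed`, `generator_params`).
#' @export
generate_de_table <- function(n_genes = 2000, frac_de = 0.1,
                              lfc_effect_mean = 2, lfc_effect_sd = 0.5,
                              seed = 1, genes = NULL) {
  if (frac_de < 0 || frac_de >= 1) stop_domain("frac_de must lie in [0, 1)")
  if (is.null(genes)) {
    genes <- sprintf("g%05d", seq_len(n_genes))
  } else {
    genes <- as.character(genes)
    n_genes <- length(genes)
  }
  with_seed(seed, {
    n_de <- round(frac_de * n_genes)
    de_genes <- sort(sample(genes, n_de))
    is_de <- genes %in% de_genes
    lfc <- stats::rnorm(n_genes, 0, 0.2)
    p <- stats::runif(n_genes)
    if (n_de > 0) {
      lfc[is_de] <- stats::rnorm(n_de, lfc_effect_mean, lfc_effect_sd) *
        sample(c(-1, 1), n_de, replace = TRUE)
      p[is_de] <- stats::rbeta(n_de, 0.5, 2000)
    }
    tab <- deg_table(genes, lfc, pvalue = p, qvalue = bh_adjust(p))
    truth <- synthetic_truth(
      de_genes = de_genes,
      rng_seed = seed,
      generator_params = list(
        n_genes = n_genes, frac_de = frac_de,
        lfc_effect_mean = lfc_effect_mean, lfc_effect_sd = lfc_effect_sd
      )
    )
    list(table = tab, truth = truth)
  })
}

#' Generate a gene-set collection with planted enrichment
#'
#' Builds `n_terms` gene sets with sizes uniform on `term_size_range`. The
#' first `n_planted` terms are enriched by construction: a fraction
#' `planted_term_overlap` of their members is drawn from `de_genes`, the
#' rest from the remaining genes. All other terms are uniform random draws
#' from `genes`. With `planted_term_overlap = 0` the planted terms are
#' statistically indistinguishable from the background terms.
#'
#' @param genes Character vector, the gene universe.
#' @param n_terms Total number of terms, default 50.
#' @param term_size_range Integer length-2 vector, default `c(20, 100)`.
#' @param n_planted Number of enriched terms, default 3.
#' @param planted_term_overlap Fraction of each planted term drawn from
#'   `de_genes`, in \[0, 1\]; default 0.8.
#' @param de_genes Character vector of true-effect genes (from
#'   [generate_de_table()] truth).
#' @param seed Integer RNG seed.
#' @return List with `collection` (a [gene_set_collection()]) and `truth`
#'   (`enriched_terms`, `rng_seed`, `generator_params`).
#' @export
generate_gene_sets <- function(genes, n_terms = 50,
                               term_size_range = c(20, 100),
                               n_planted = 3, planted_term_overlap = 0.8,
                               de_genes = character(), seed = 1) {
  genes <- unique(as.character(genes))
  de_genes <- intersect(as.character(de_genes), genes)
  if (max(term_size_range) > length(genes)) {
    stop_domain("term sizes infeasible for ", length(genes), " genes")
  }
  if (planted_term_overlap < 0 || planted_term_overlap > 1) {
    stop_domain("planted_term_overlap must lie in [0, 1]")
  }
  if (n_planted > n_terms) stop_domain("n_planted exceeds n_terms")
  nm <- sprintf("T%03d", seq_len(n_terms))
  with_seed(seed, {
    size_choices <- seq(term_size_range[1], term_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), n_terms,
                                     replace = TRUE)]
    sets <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      if (i <= n_planted && planted_term_overlap > 0) {
        n_in <- round(planted_term_overlap * sizes[i])
        if (n_in > length(de_genes)) {
          stop_domain("infeasible overlap: planted term needs ", n_in,
                      " DE genes but only ", length(de_genes), " available")
        }
        sets[[i]] <- c(sample(de_genes, n_in),
                       sample(setdiff(genes, de_genes), sizes[i] - n_in))
      } else {
        sets[[i]] <- sample(genes, sizes[i])
      }
    }
    names(sets) <- nm
    coll <- gene_set_collection(sets, source = "synthetic")
    truth <- synthetic_truth(
      enriched_terms = if (planted_term_overlap > 0) nm[seq_len(n_planted)]
                       else character(),
      rng_seed = seed,
      generator_params = list(
        n_terms = n_terms, term_size_range = term_size_range,
        n_planted = n_planted, planted_term_overlap = planted_term_overlap
      )
    )
    list(collection = coll, truth = truth)
  })
}
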