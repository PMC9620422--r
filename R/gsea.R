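#' Ranked gene list
#'
#' Genes ordered by a decreasing ranking statistic (e.g. log2 fold change),
#' the input of the running-sum enrichment score. Ties in the statistic are
#' broken by lexicographic gene identifier so that the ordering — and every
#' statistic computed from it — is fully deterministic.
#'
#' @param genes Character vector of unique gene identifiers.
#' @param statistic Numeric ranking statistic, one value per gene.
#' @return Object of class `ranked_list`: list with `genes` and `statistic`,
#'   both in ranked order.
#' @export
ranked_list <- function(genes, statistic) {
  genes <- as.character(genes)
  statistic <- as.numeric(statistic)
  stopifnot(length(genes) == length(statistic))
  if (anyDuplicated(genes)) stop_domain("duplicate genes in ranked list")
  if (anyNA(statistic)) stop_domain("missing ranking statistic")
  ord <- order(-statistic, genes, method = "radix")
  structure(list(genes = genes[ord], statistic = statistic[ord]),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("<ranked_list> ", length(x$genes), " genes, statistic range [",
      signif(min(x$statistic), 4), ", ", signif(max(x$statistic), 4), "]\n",
      sep = "")
  invisible(x)
}

#' Build a ranked list from a DE table
#'
#' @param table A [deg_table()].
#' @param metric `"log2fc"` (default) ranks by signed log2 fold change;
#'   `"signed_logp"` ranks by `-log10(pvalue) * sign(log2fc)`.
#' @return A [ranked_list()].
#' @export
rank_from_deg <- function(table, metric = c("log2fc", "signed_logp")) {
  stopifnot(inherits(table, "deg_table"))
  metric <- match.arg(metric)
  stat <- switch(metric,
    log2fc = table$log2fc,
    signed_logp = {
      if (is.null(table$pvalue)) stop_domain("signed_logp metric needs pvalue")
      -log10(pmax(table$pvalue, .Machine$double.xmin)) * sign(table$log2fc)
    }
  )
  ranked_list(table$gene, stat)
}

#' Running-sum enrichment score
#'
#' Walks the ranked list top to bottom; at a gene in the set the running sum
#' rises by that gene's weight `|statistic|^weight_exponent` normalized by
#' the total in-set weight, at a gene outside the set it falls by
#' `1/(L - Nh)` (`L` list length, `Nh` in-set genes present in the list).
#' The enrichment score (ES) is the running-sum value of maximal absolute
#' deviation from zero, sign retained; when the maximal positive and
#' negative deviations tie exactly, the positive one is taken. With
#' `weight_exponent = 0` every hit carries equal weight (the classic
#' Kolmogorov-Smirnov form). If all in-set statistics are exactly zero at a
#' positive exponent, equal weights are used as a documented fallback.
#'
#' The leading edge contains the in-set genes at or before the extremum (for
#' positive ES) or at or after it (negative ES).
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector; must intersect the ranked genes.
#' @param weight_exponent Non-negative weighting exponent, default 1.
#' @return List with `es` (in \[-1, 1\]), `running_sum` (numeric vector of
#'   length `L`) and `leading_edge` (character vector).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$genes %in% gene_set
  nh <- sum(hit)
  L <- length(ranked$genes)
  if (nh == 0L) stop_domain("gene set does not intersect the ranked list")
  if (nh == L) stop_domain("gene set covers the whole ranked list")
  w <- abs(ranked$statistic)^weight_exponent
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1  # all-zero statistics: equal-weight fallback
  steps <- ifelse(hit, w / sum(w), -1 / (L - nh))
  running <- cumsum(steps)
  # signed extremum of maximal absolute deviation; on an exact tie between
  # the positive and negative deviations the positive one is taken
  max_p <- max(running)
  min_p <- min(running)
  if (max_p >= -min_p) {
    es <- max_p
    i_ext <- which.max(running)
  } else {
    es <- min_p
    i_ext <- which.min(running)
  }
  leading <- if (es > 0) {
    ranked$genes[hit & seq_len(L) <= i_ext]
  } else if (es < 0) {
    ranked$genes[hit & seq_len(L) >= i_ext]
  } else {
    character()
  }
  list(es = es, running_sum = running, leading_edge = leading)
}

#' Gene-label permutation null for the enrichment score
#'
#' Draws `n_perm` uniformly random gene sets of the given size from the
#' ranked list and records their enrichment scores. This is gene-set
#' (label) permutation: the pipeline consumes a ranked list rather than
#' per-sample expression, so phenotype permutation is not applicable.
#' Reproducible under a fixed seed; the caller's RNG state is untouched.
#'
#' @param ranked A [ranked_list()].
#' @param gene_set_size Integer in `(0, L)`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer RNG seed.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return Numeric vector of `n_perm` null ES values.
#' @export
permutation_null <- function(ranked, gene_set_size, n_perm, seed,
                             weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  L <- length(ranked$genes)
  if (!is.numeric(gene_set_size) || gene_set_size < 1 || gene_set_size >= L) {
    stop_domain("gene_set_size must be in [1, list length)")
  }
  if (n_perm < 1) stop_domain("n_perm must be >= 1")
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(L, gene_set_size)
      enrichment_score(ranked, ranked$genes[idx], weight_exponent)$es
    }, numeric(1))
  })
}

#' Normalized enrichment score and permutation significance
#'
#' `nes = es / mean(|null ES of the same sign as es|)`; the permutation
#' p-value is computed within the same-sign null with add-one smoothing,
#' `p = (1 + #\{|null| >= |es|, same sign\}) / (1 + #\{same sign\})`, so it
#' is never zero. `es = 0` gives `nes = 0` and `p = 1`. If no null value
#' shares the sign of `es`, the NES is undefined (`NA`) and `p = 1`.
#'
#' @param es Observed enrichment score.
#' @param null_es Numeric vector of null ES values.
#' @return List with `nes` and `pvalue_perm`.
#' @export
nes_and_significance <- function(es, null_es) {
  if (length(null_es) == 0L) stop_domain("empty null distribution")
  if (es == 0) return(list(nes = 0, pvalue_perm = 1))
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same) == 0L) return(list(nes = NA_real_, pvalue_perm = 1))
  list(
    nes = es / mean(abs(same)),
    pvalue_perm = (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  )
}

#' GSEA over a gene-set collection
#'
#' Per term: running-sum ES, gene-label permutation null of the same set
#' size, NES and permutation p-value; FDR across terms by Benjamini-Hochberg
#' on the permutation p-values (a simpler deterministic alternative to the
#' original NES-histogram FDR). Per-term permutation sub-seeds are derived
#' from `seed` by sorted term name, so permuting the collection order leaves
#' every statistic unchanged.
#'
#' Terms that do not intersect the ranked list (or cover it entirely) are
#' skipped with a message.
#'
#' @param ranked A [ranked_list()].
#' @param collection A [gene_set_collection()].
#' @param n_perm Permutations per term, default 1000.
#' @param seed Integer RNG seed, default 1.
#' @param weight_exponent Passed to [enrichment_score()], default 1.
#' @return data.frame of class `gsea_result`, sorted by decreasing `|nes|`
#'   (ties by term name), with columns `term`, `size`, `es`, `nes`,
#'   `pvalue_perm`, `fdr_perm`, `leading_edge` (comma-joined),
#'   `n_permutations`, `rng_seed`.
#' @export
gsea_collection <- function(ranked, collection, n_perm = 1000, seed = 1,
                            weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"),
            inherits(collection, "gene_set_collection"))
  term_seeds <- derive_seeds(seed, names(collection$sets))
  rows <- lapply(names(collection$sets), function(nm) {
    genes <- intersect(collection$sets[[nm]], ranked$genes)
    if (length(genes) == 0L || length(genes) == length(ranked$genes)) {
      message("skipping term '", nm, "': no usable overlap with ranked list")
      return(NULL)
    }
    sc <- enrichment_score(ranked, genes, weight_exponent)
    null_es <- permutation_null(ranked, length(genes), n_perm,
                                seed = term_seeds[[nm]],
                                weight_exponent = weight_exponent)
    sig <- nes_and_significance(sc$es, null_es)
    data.frame(term = nm, size = length(genes), es = sc$es, nes = sig$nes,
               pvalue_perm = sig$pvalue_perm,
               leading_edge = paste(sc$leading_edge, collapse = ","),
               n_permutations = n_perm, rng_seed = term_seeds[[nm]],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    res <- data.frame(term = character(), size = integer(), es = numeric(),
                      nes = numeric(), pvalue_perm = numeric(),
                      fdr_perm = numeric(), leading_edge = character(),
                      n_permutations = integer(), rng_seed = integer(),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, rows)
    res$fdr_perm <- bh_adjust(res$pvalue_perm)
    res <- res[order(-abs(res$nes), res$term, method = "radix",
                     na.last = TRUE), , drop = FALSE]
    res <- res[, c("term", "size", "es", "nes", "pvalue_perm", "fdr_perm",
                   "leading_edge", "n_permutations", "rng_seed")]
    rownames(res) <- NULL
  }
  class(res) <- c("gsea_result", "data.frame")
  res
}
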