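#' Gene-set collection
#'
#' A named collection of gene sets (GO terms, KEGG pathways, ...). Term
#' names are unique; duplicate genes within a set are collapsed; empty sets
#' are rejected.
#'
#' @param sets Named list: term name -> character vector of member genes.
#' @param descriptions Optional named character vector of term descriptions.
#' @param source Free-text label for the collection (e.g. "GO-BP", "KEGG").
#' @return Object of class `gene_set_collection`: list with `sets` (named
#'   list of sorted unique character vectors), `descriptions`, `source`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source = "custom") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_domain("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) stop_domain("duplicate term names")
  sets <- lapply(sets, function(g) sort(unique(as.character(g)), method = "radix"))
  if (any(lengths(sets) == 0L)) stop_domain("empty gene set in collection")
  desc <- stats::setNames(rep("", length(sets)), names(sets))
  if (!is.null(descriptions)) desc[names(descriptions)] <- descriptions
  structure(list(sets = sets, descriptions = desc, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", x$source, ": ", length(x$sets),
      " sets, sizes ", min(lengths(x$sets)), "-", max(lengths(x$sets)),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' GMT rows are `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a row are collapsed.
#'
#' @param path Path to the GMT file.
#' @param source Label for the collection; defaults to the file name.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop_domain("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop_domain("malformed GMT row at line ", keep[bad[1]],
                ": expected name, description and at least one gene")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, stats::setNames(desc, nm), source = source)
}

#' Write a collection as GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis (hypergeometric / one-sided Fisher)
#'
#' For each term, tests whether the study set overlaps the term more than
#' expected under random sampling from the background universe. With
#' `N = |background|`, `K = |term in background|`, `n = |study|` and
#' `k = |study in term|`, the p-value is the one-sided upper hypergeometric
#' tail `P[X >= k]` — identical to one-sided Fisher's exact test for
#' over-representation. Q-values are Benjamini-Hochberg across all tested
#' terms.
#'
#' Terms are intersected with the background before testing; terms with
#' fewer than `min_size` or more than `max_size` genes after intersection
#' are skipped (a package convention guarding against degenerate tests, not
#' a rule of the underlying method).
#'
#' @param study Character vector, the study gene set (e.g. DEGs). Must be a
#'   subset of `background`; genes outside it are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param background Character vector, the background universe (typically
#'   all genes in the DE table).
#' @param min_size,max_size Term-size bounds after background intersection.
#' @return data.frame of class `enrichment_result`, sorted by p-value (ties
#'   broken by term name), with columns `term`, `k`, `K`, `n`, `N`,
#'   `enrichment_ratio` ((k/n)/(K/N)), `pvalue`, `fdr`.
#' @examples
#' coll <- gene_set_collection(list(T1 = letters[1:5]))
#' ora(letters[1:5], coll, background = letters[1:20])
#' @export
ora <- function(study, collection, background, min_size = 3, max_size = 2000) {
  stopifnot(inherits(collection, "gene_set_collection"))
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (length(study) == 0L) stop_domain("empty study set")
  if (length(background) == 0L) stop_domain("empty background")
  outside <- setdiff(study, background)
  if (length(outside)) {
    warning(length(outside), " study gene(s) not in background were dropped",
            call. = FALSE)
    study <- intersect(study, background)
    if (length(study) == 0L) stop_domain("empty study set after background ",
                                         "intersection")
  }
  N <- length(background)
  n <- length(study)
  rows <- lapply(names(collection$sets), function(nm) {
    term_genes <- intersect(collection$sets[[nm]], background)
    K <- length(term_genes)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(study, term_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N,
               enrichment_ratio = (k / n) / (K / N),
               pvalue = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    res <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(),
                      enrichment_ratio = numeric(), pvalue = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, rows)
    res$fdr <- bh_adjust(res$pvalue)
    res <- res[order(res$pvalue, res$term, method = "radix"), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Filter enrichment results by significance mode
#'
#' Two screening conventions: `"go"` keeps terms with raw p strictly below
#' `p_max` (default 0.05); `"kegg"` keeps terms with FDR at or below
#' `fdr_max` (default 0.5, inclusive). Defaults are overridable.
#'
#' @param results An [ora()] result.
#' @param mode `"go"` or `"kegg"`.
#' @param p_max,fdr_max Threshold overrides.
#' @return The filtered `enrichment_result`.
#' @export
significant_terms <- function(results, mode = c("go", "kegg"),
                              p_max = 0.05, fdr_max = 0.5) {
  stopifnot(inherits(results, "enrichment_result"))
  mode <- match.arg(mode)
  keep <- switch(mode,
    go = results$pvalue < p_max,
    kegg = results$fdr <= fdr_max
  )
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
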