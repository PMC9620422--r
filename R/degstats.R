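#' Differential-expression result table
#'
#' A validated data.frame of per-gene differential-expression statistics, the
#' object the DEG filter acts on. `log2fc` is oriented case-vs-control
#' (positive = up in the case condition). Rows with missing `log2fc` or with
#' a missing significance value in every available column are dropped with a
#' message; p and Q values must lie in \[0, 1\].
#'
#' @param gene Character vector of unique gene identifiers.
#' @param log2fc Numeric log2 fold changes.
#' @param pvalue Optional numeric p-values in \[0, 1\].
#' @param qvalue Optional numeric multiplicity-adjusted Q-values in \[0, 1\];
#'   required (or derivable from `pvalue` via [bh_adjust()]) for filtering.
#' @return data.frame of class `deg_table` with columns `gene`, `log2fc`,
#'   and any of `pvalue`, `qvalue`, plus `direction` (`"up"`/`"down"`/
#'   `"flat"` by the sign of `log2fc`).
#' @export
deg_table <- function(gene, log2fc, pvalue = NULL, qvalue = NULL) {
  gene <- as.character(gene)
  log2fc <- as.numeric(log2fc)
  stopifnot(length(gene) == length(log2fc))
  if (anyDuplicated(gene)) stop_domain("duplicate gene identifiers in DE table")
  check01 <- function(x, what) {
    if (!is.null(x) && any(x < 0 | x > 1, na.rm = TRUE)) {
      stop_domain(what, " values must lie in [0, 1]")
    }
  }
  check01(pvalue, "p")
  check01(qvalue, "Q")
  df <- data.frame(gene = gene, log2fc = log2fc, stringsAsFactors = FALSE)
  if (!is.null(pvalue)) df$pvalue <- as.numeric(pvalue)
  if (!is.null(qvalue)) df$qvalue <- as.numeric(qvalue)
  has_sig <- !is.null(pvalue) || !is.null(qvalue)
  sig_na <- if (has_sig) {
    Reduce(`&`, lapply(df[intersect(c("pvalue", "qvalue"), names(df))], is.na))
  } else FALSE
  bad <- is.na(df$log2fc) | sig_na
  if (any(bad)) {
    message("dropped ", sum(bad), " row(s) with missing log2FC or significance")
    df <- df[!bad, , drop = FALSE]
  }
  df$direction <- ifelse(df$log2fc > 0, "up", ifelse(df$log2fc < 0, "down", "flat"))
  rownames(df) <- NULL
  class(df) <- c("deg_table", "data.frame")
  df
}

#' Read a DE table from TSV
#'
#' Recognized (case-insensitive) column aliases: gene: `gene`, `gene_id`,
#' `id`; log2 fold change: `log2fc`, `log2foldchange`, `lfc`; p-value:
#' `pvalue`, `pval`, `p`; Q-value: `qvalue`, `qval`, `padj`, `fdr`, `q`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A [deg_table()].
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop_domain("DE table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  find <- function(aliases) {
    hit <- which(tolower(names(raw)) %in% aliases)
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  gene <- find(c("gene", "gene_id", "id"))
  lfc <- find(c("log2fc", "log2foldchange", "lfc"))
  if (is.null(gene) || is.null(lfc)) {
    stop_domain("DE table must contain gene and log2FC columns (see docs ",
                "for recognized aliases)")
  }
  deg_table(gene, lfc,
            pvalue = find(c("pvalue", "pval", "p")),
            qvalue = find(c("qvalue", "qval", "padj", "fdr", "q")))
}

#' Write a DE table as TSV
#' @param table A [deg_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, order-aligned with the input.
#' Thin validated wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Filter differentially expressed genes
#'
#' Keeps rows with `|log2fc| >= lfc_min` and `qvalue <= q_max`; both
#' comparisons are inclusive. The fold-change rule is applied to the
#' absolute value by default so that down-regulated genes are retained; a
#' signed mode (`use_abs = FALSE`, keeping only `log2fc >= lfc_min`) is
#' available. When the table has no Q-value column it is derived from the
#' p-value column via [bh_adjust()].
#'
#' @param table A [deg_table()].
#' @param lfc_min Minimum (absolute) log2 fold change; default 1.
#' @param q_max Maximum Q-value; default 0.05.
#' @param use_abs Apply `lfc_min` to `|log2fc|` (default) or to signed
#'   `log2fc`.
#' @return List with `table` (the filtered [deg_table()]) and `counts`
#'   (list `total`, `up`, `down`).
#' @examples
#' tab <- deg_table(c("g1", "g2", "g3"), c(1.5, -2, 0.5),
#'                  qvalue = c(0.01, 0.001, 0.001))
#' filter_degs(tab)$counts
#' @export
filter_degs <- function(table, lfc_min = 1, q_max = 0.05, use_abs = TRUE) {
  stopifnot(inherits(table, "deg_table"))
  if (is.null(table$qvalue)) {
    if (is.null(table$pvalue)) {
      stop_domain("no usable significance column: need qvalue or pvalue")
    }
    table$qvalue <- bh_adjust(table$pvalue)
  }
  lfc <- if (use_abs) abs(table$log2fc) else table$log2fc
  keep <- lfc >= lfc_min & table$qvalue <= q_max
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  list(
    table = out,
    counts = list(
      total = nrow(out),
      up = sum(out$log2fc > 0),
      down = sum(out$log2fc < 0)
    )
  )
}
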