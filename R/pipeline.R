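#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full analysis run:
#' filter -> KDA -> over-representation -> GSEA. Inputs may be given as
#' file paths (`network_path` TSV/SIF, `de_path` TSV, `gmt_path`) or as
#' in-memory objects (`network`, `de`, `collection`); objects win when both
#' are present. Configurations round-trip through YAML via
#' [read_pipeline_config()].
#'
#' @param network_path,de_path,gmt_path Input file paths.
#' @param network,de,collection In-memory [gene_network()], [deg_table()],
#'   [gene_set_collection()].
#' @param out_dir Output directory for stage TSVs and the summary JSON.
#' @param h KDA neighborhood depth, default 2.
#' @param lfc_min,q_max DEG filter thresholds, defaults 1 and 0.05.
#' @param ora_mode `"go"` or `"kegg"`, default `"kegg"`.
#' @param ora_p_max,ora_fdr_max Significance thresholds, defaults 0.05/0.5.
#' @param gsea_n_perm,gsea_exponent GSEA settings, defaults 1000 and 1.
#' @param seed Integer master seed; per-stage sub-seeds are derived from it
#'   deterministically.
#' @return Object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(network_path = NULL, de_path = NULL,
                            gmt_path = NULL, network = NULL, de = NULL,
                            collection = NULL, out_dir = tempfile("kdrun"),
                            h = 2, lfc_min = 1, q_max = 0.05,
                            ora_mode = "kegg", ora_p_max = 0.05,
                            ora_fdr_max = 0.5, gsea_n_perm = 1000,
                            gsea_exponent = 1, seed = 1) {
  stopifnot(h >= 1, lfc_min >= 0, q_max >= 0, q_max <= 1,
            ora_p_max > 0, ora_p_max <= 1, ora_fdr_max >= 0,
            ora_fdr_max <= 1, gsea_n_perm >= 1, gsea_exponent >= 0)
  ora_mode <- match.arg(ora_mode, c("go", "kegg"))
  structure(
    list(network_path = network_path, de_path = de_path, gmt_path = gmt_path,
         network = network, de = de, collection = collection,
         out_dir = out_dir, h = h, lfc_min = lfc_min, q_max = q_max,
         ora_mode = ora_mode, ora_p_max = ora_p_max,
         ora_fdr_max = ora_fdr_max, gsea_n_perm = gsea_n_perm,
         gsea_exponent = gsea_exponent, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  x <- x[!names(x) %in% c("network", "de", "collection")]
  yaml::write_yaml(x, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading, DEG filtering, key driver analysis
#' (seed genes = the filtered DEGs), over-representation analysis (study =
#' DEGs, background = all genes in the DE table), and GSEA on the full
#' ranked DE table. Writes per-stage TSVs, a `thresholds.json` sidecar and
#' a machine-readable `summary.json` into `config$out_dir`. The whole run
#' is a pure function of the inputs and `config$seed`: re-running with the
#' same configuration reproduces every output byte for byte.
#'
#' On failure the partial outputs are moved to a `quarantine/` subdirectory
#' of `out_dir` and the stage-named error is re-thrown.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  staging <- file.path(out_dir, ".staging")
  unlink(staging, recursive = TRUE)
  dir.create(staging)
  ok <- FALSE
  on.exit({
    if (!ok) {
      qdir <- file.path(out_dir, "quarantine")
      unlink(qdir, recursive = TRUE)
      if (dir.exists(staging)) file.rename(staging, qdir)
    }
  })

  net <- stage("load_network", {
    config$network %||% read_edge_list(config$network_path)
  })
  de <- stage("load_de", {
    config$de %||% read_deg_table(config$de_path)
  })
  coll <- stage("load_gene_sets", {
    config$collection %||% read_gmt(config$gmt_path)
  })

  filt <- stage("filter_degs", {
    filter_degs(de, lfc_min = config$lfc_min, q_max = config$q_max)
  })
  stage("filter_degs", write_deg_table(filt$table, file.path(staging, "degs.tsv")))

  kda <- stage("kda", {
    run_kda(net, seed_genes = filt$table$gene, h = config$h)
  })
  stage("kda", utils::write.table(
    as.data.frame(kda), file.path(staging, "drivers.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE))
  stage("kda", jsonlite::write_json(
    kda$thresholds, file.path(staging, "thresholds.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE))

  background <- de$gene
  ora_res <- stage("ora", {
    ora(filt$table$gene, coll, background = background)
  })
  sig <- stage("ora", {
    significant_terms(ora_res, mode = config$ora_mode,
                      p_max = config$ora_p_max, fdr_max = config$ora_fdr_max)
  })
  stage("ora", utils::write.table(
    as.data.frame(ora_res), file.path(staging, "ora.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE))

  gsea_res <- stage("gsea", {
    gsea_collection(rank_from_deg(de), coll, n_perm = config$gsea_n_perm,
                    seed = config$seed, weight_exponent = config$gsea_exponent)
  })
  stage("gsea", utils::write.table(
    as.data.frame(gsea_res), file.path(staging, "gsea.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE))

  summary <- list(
    config = list(h = config$h, lfc_min = config$lfc_min,
                  q_max = config$q_max, ora_mode = config$ora_mode,
                  gsea_n_perm = config$gsea_n_perm,
                  gsea_exponent = config$gsea_exponent, seed = config$seed),
    degs = filt$counts,
    kda = list(
      n_subnetwork_nodes = n_nodes(kda$subnetwork),
      n_candidates = length(kda$candidates),
      n_global_drivers = length(kda$global_drivers),
      n_local_drivers = length(kda$local_drivers),
      n_outdegree_globals = length(kda$outdegree_globals),
      global_drivers = kda$global_drivers,
      outdegree_globals = kda$outdegree_globals,
      thresholds = kda$thresholds
    ),
    ora = list(
      n_tested = nrow(ora_res),
      n_significant = nrow(sig),
      top_terms = utils::head(ora_res$term, 5)
    ),
    gsea = list(
      n_tested = nrow(gsea_res),
      top_terms = utils::head(gsea_res$term, 5),
      top_nes = utils::head(gsea_res$nes, 5)
    )
  )
  stage("summary", jsonlite::write_json(
    summary, file.path(staging, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE))

  for (f in list.files(staging)) {
    file.rename(file.path(staging, f), file.path(out_dir, f))
  }
  unlink(staging, recursive = TRUE)
  ok <- TRUE
  invisible(summary)
}
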