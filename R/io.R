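#' Write a simulated dataset to plain-text files
#'
#' Writes `genotypes.tsv` (binary matrix, columns `iv_001`, ...),
#' `traits.tsv` (columns `trait_01`, ...) and `graph.json` (edges,
#' instruments and pleiotropic effects of the generating graph) into a
#' directory.
#'
#' @param dataset An `mr_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$genotypes, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g <- dataset$graph
  jsonlite::write_json(
    list(trait_ids = g$trait_ids, edges = g$edges,
         instruments = g$instruments, pleiotropy = g$pleiotropy),
    file.path(dir, "graph.json"),
    dataframe = "columns", digits = NA
  )
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `genotypes.tsv`, `traits.tsv`,
#'   `graph.json`.
#' @return An `mr_dataset`.
#' @export
read_dataset <- function(dir) {
  G <- as.matrix(utils::read.table(file.path(dir, "genotypes.tsv"),
                                   header = TRUE, sep = "\t",
                                   check.names = FALSE))
  Y <- as.matrix(utils::read.table(file.path(dir, "traits.tsv"),
                                   header = TRUE, sep = "\t",
                                   check.names = FALSE))
  j <- jsonlite::read_json(file.path(dir, "graph.json"),
                           simplifyVector = TRUE)
  as_df <- function(x, cols) {
    if (length(x) == 0 || (is.list(x) && length(x[[1]]) == 0)) {
      out <- lapply(cols, function(cl) {
        if (cl == "effect" || cl == "freq") numeric(0) else character(0)
      })
      names(out) <- cols
      return(as.data.frame(out, stringsAsFactors = FALSE))
    }
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  graph <- structure(
    list(trait_ids = unlist(j$trait_ids),
         edges = as_df(j$edges, c("parent", "child", "effect")),
         instruments = as_df(j$instruments,
                             c("iv_id", "trait", "effect", "freq")),
         pleiotropy = as_df(j$pleiotropy, c("iv_id", "trait", "effect"))),
    class = "trait_graph"
  )
  structure(list(genotypes = G, traits = Y, graph = graph),
            class = "mr_dataset")
}

#' Write GWAS summary statistics as TSV
#'
#' Long format with columns `instrument`, `trait`, `beta`, `se`, `pval`.
#'
#' @param gwas A `gwas_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  stopifnot(inherits(gwas, "gwas_table"))
  utils::write.table(as.data.frame(gwas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-replicate MR and BN result tables as TSV
#'
#' @param analysis A `replicate_analysis` from [analyse_replicate()].
#' @param mr_path,bn_path Output files (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_replicate_results <- function(analysis, mr_path = NULL, bn_path = NULL) {
  stopifnot(inherits(analysis, "replicate_analysis"))
  if (!is.null(mr_path)) {
    utils::write.table(analysis$mr, mr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bn_path)) {
    utils::write.table(analysis$bn, bn_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(mr_path, bn_path))
}

#' Write experiment outputs: summary table, ROC table and a run manifest
#'
#' The summary and ROC tables are TSV (FDR and power at 4 decimal
#' places); the manifest is JSON recording both configurations and the
#' package version.
#'
#' @param experiment An `mr_bn_experiment` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "mr_bn_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- experiment$summary
  s$mean_fdr <- round(s$mean_fdr, 4)
  s$mean_power <- round(s$mean_power, 4)
  utils::write.table(s, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(experiment$roc)) {
    utils::write.table(experiment$roc, file.path(dir, "roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(sim_config = unclass(experiment$sim_config),
         eval_config = unclass(experiment$eval_config),
         n_failed = experiment$n_failed,
         package_version = as.character(utils::packageVersion("mrbnbench"))),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
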