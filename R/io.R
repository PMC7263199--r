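# TSV/JSON readers and writers for the pipeline's on-disk formats.

#' Write a probes-x-samples matrix as TSV
#'
#' First column holds the row ids (default `probe_id`), remaining columns
#' the samples.
#'
#' @param x matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name of the id column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "probe_id") {
  d <- data.table::data.table(id = rownames(x))
  data.table::setnames(d, "id", id_col)
  d <- cbind(d, data.table::as.data.table(x))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path; the first column supplies rownames.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  m
}

#' Write/read plain data frames as TSV
#'
#' @param df data.frame.
#' @param path TSV path.
#' @export
write_table_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write a list as JSON
#'
#' @param x list of scalars/vectors/data frames.
#' @param path output path.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: a `simulation` block (fields of
#' [sim_config()]) or a `paths` block, plus `target`, `thresholds`,
#' `k_range`, `seed`, `outdir`.
#'
#' @param path YAML file.
#' @return a validated pipeline config list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    if (!is.null(y$simulation$cohorts))
      y$simulation$cohorts <- do.call(rbind, lapply(y$simulation$cohorts,
                                                    as.data.frame))
    sim <- do.call(sim_config, y$simulation)
  }
  pipeline_config(simulation = sim, paths = y$paths, target = y$target,
                  thresholds = y$thresholds, k_range = y$k_range,
                  seed = if (is.null(y$seed)) 1L else y$seed)
}
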