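# Tab-separated interchange: header row, '.' decimal, UTF-8, full double
# precision. All writers go through tsv_write so every artifact is
# formatted identically (and deterministically).

tsv_write <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

tsv_read <- function(path, required = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required) && !all(required %in% names(df))) {
    stopf("%s: missing column(s) %s", path,
          paste(setdiff(required, names(df)), collapse = ", "))
  }
  df
}

#' Read and write single-cell event tables
#'
#' Long TSV with columns `promoter_id`, `condition_id`,
#' `log_fluorescence` (natural log; use `log10_input = TRUE` when reading
#' data recorded in log10 units, which are converted on ingestion).
#'
#' @param events data.frame of events.
#' @param path file path.
#' @param log10_input convert `log_fluorescence` from log10 to natural log.
#' @return `read_event_tsv`: the data.frame; `write_event_tsv`: the path,
#'   invisibly.
#' @export
write_event_tsv <- function(events, path) {
  tsv_write(events[, c("promoter_id", "condition_id", "log_fluorescence")],
            path)
}

#' @rdname write_event_tsv
#' @export
read_event_tsv <- function(path, log10_input = FALSE) {
  df <- tsv_read(path, c("promoter_id", "condition_id", "log_fluorescence"))
  if (log10_input) df$log_fluorescence <- df$log_fluorescence * log(10)
  df
}

#' Read and write regulatory networks as edge lists
#'
#' Two-column TSV (`regulator_id`, `promoter_id`), RegulonDB style. When
#' reading, a promoter universe may be supplied: edges pointing to unknown
#' promoters are dropped with a warning, and promoters without any edge
#' become all-zero rows.
#'
#' @param network binary promoters x regulators matrix.
#' @param path file path.
#' @param promoters optional character vector: the promoter universe.
#' @return `read_network_tsv`: binary promoters x regulators matrix.
#' @export
write_network_tsv <- function(network, path) {
  idx <- which(network != 0, arr.ind = TRUE)
  edges <- data.frame(regulator_id = colnames(network)[idx[, 2L]],
                      promoter_id = rownames(network)[idx[, 1L]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator_id, edges$promoter_id), ]
  tsv_write(edges, path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path, promoters = NULL) {
  edges <- tsv_read(path, c("regulator_id", "promoter_id"))
  if (is.null(promoters)) {
    promoters <- sort(unique(edges$promoter_id))
  } else {
    unknown <- !(edges$promoter_id %in% promoters)
    if (any(unknown)) {
      warnf("read_network_tsv: dropped %d edge(s) with unknown promoter ids",
            sum(unknown))
      edges <- edges[!unknown, , drop = FALSE]
    }
  }
  regulators <- sort(unique(edges$regulator_id))
  S <- matrix(0L, nrow = length(promoters), ncol = length(regulators),
              dimnames = list(promoters, regulators))
  if (nrow(edges) > 0) {
    S[cbind(match(edges$promoter_id, promoters),
            match(edges$regulator_id, regulators))] <- 1L
  }
  S
}

#' Read and write promoters-by-conditions matrices
#'
#' TSV with a `promoter_id` first column and one column per condition.
#' Used for the noise matrix `N_pc` and the mean matrix `m_pc`.
#'
#' @param mat numeric matrix with promoter rownames.
#' @param path file path.
#' @return `read_noise_matrix_tsv`: numeric matrix with promoter rownames.
#' @export
write_noise_matrix_tsv <- function(mat, path) {
  df <- data.frame(promoter_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tsv_write(df, path)
}

#' @rdname write_noise_matrix_tsv
#' @export
read_noise_matrix_tsv <- function(path) {
  df <- tsv_read(path, "promoter_id")
  mat <- as.matrix(df[, setdiff(names(df), "promoter_id"), drop = FALSE])
  rownames(mat) <- df$promoter_id
  mat
}

#' Read and write gene-feature tables
#'
#' TSV with `gene_id` plus feature columns (see [correlation_matrix()]).
#'
#' @param features data.frame.
#' @param path file path.
#' @export
write_feature_tsv <- function(features, path) tsv_write(features, path)

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) tsv_read(path, "gene_id")

#' Read and write per-condition growth rates
#'
#' TSV with columns `condition_id`, `growth_rate` (1/h).
#'
#' @param growth data.frame.
#' @param path file path.
#' @export
write_growth_rate_tsv <- function(growth, path) {
  tsv_write(growth[, c("condition_id", "growth_rate")], path)
}

#' @rdname write_growth_rate_tsv
#' @export
read_growth_rate_tsv <- function(path) {
  tsv_read(path, c("condition_id", "growth_rate"))
}
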