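# Canonical ordering of the 10 gene features used by the correlation /
# PCA analysis.
canonical_features <- c(
  "rna_level", "protein_level", "codon_bias", "dN", "dS", "n_inputs",
  "mean_expression", "expression_plasticity", "mean_noise",
  "noise_plasticity"
)

#' Pairwise-complete correlation matrix of a gene-feature table
#'
#' Pearson correlations between all pairs of feature columns, computed on
#' the genes with complete data for each pair (missing values permitted),
#' with the number of complete pairs recorded per cell. Pearson
#' correlation is invariant to linear rescaling, so features need not be
#' standardized first.
#'
#' @param features data.frame with the feature columns (a `gene_id` column
#'   is ignored); heavily skewed features (e.g. absolute RNA/protein
#'   levels) should be log-transformed at ingestion.
#' @param columns feature columns to use (default: the canonical 10 that
#'   are present).
#' @return object of class `feature_correlation`: list with `R`
#'   (correlation matrix), `n_pairs` (complete observations per cell).
#' @export
correlation_matrix <- function(features, columns = NULL) {
  columns <- columns %||% intersect(canonical_features, names(features))
  if (length(columns) < 2L) stopf("need >= 2 feature columns")
  X <- as.matrix(features[, columns, drop = FALSE])
  sds <- apply(X, 2L, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds < 1e-15)) {
    stopf("zero-variance feature(s): %s",
          paste(columns[!is.finite(sds) | sds < 1e-15], collapse = ", "))
  }
  R <- cor(X, use = "pairwise.complete.obs")
  obs <- !is.na(X)
  n_pairs <- crossprod(obs * 1)
  if (any(n_pairs < 3L)) stopf("some feature pairs have < 3 complete genes")
  structure(list(R = R, n_pairs = n_pairs), class = "feature_correlation")
}

#' Principal component analysis of a feature correlation matrix
#'
#' Eigendecomposition of the correlation matrix. Eigenvalues sum to the
#' number of features (the trace), so each eigenvalue divided by the
#' feature count is that component's fraction of the total variance.
#' Loading signs follow a deterministic convention: the largest-magnitude
#' loading of each component is positive.
#'
#' Pairwise-complete estimation can make the matrix slightly indefinite;
#' eigenvalues below `-1e-8` raise an error unless `repair = TRUE`, which
#' clips negative eigenvalues at zero and rescales to preserve the trace
#' (a nearest-PSD style repair).
#'
#' @param corr a `feature_correlation` (or a bare correlation matrix).
#' @param repair clip-and-rescale an indefinite matrix instead of erroring.
#' @return object of class `feature_pca`: list with `eigenvalues`,
#'   `variance_fraction`, `loadings` (features x components).
#' @export
pca_of_correlation <- function(corr, repair = FALSE) {
  R <- if (inherits(corr, "feature_correlation")) corr$R else corr
  if (!isSymmetric(unname(R), tol = 1e-8)) stopf("correlation matrix must be symmetric")
  k <- ncol(R)
  eig <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    if (!repair) {
      stopf(paste("correlation matrix is indefinite (min eigenvalue %.3g);",
                  "rerun with repair = TRUE for a nearest-PSD repair"),
            min(eig$values))
    }
    vals <- pmax(eig$values, 0)
    eig$values <- vals * (k / sum(vals))
  }
  L <- eig$vectors
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(rownames(R), paste0("PC", seq_len(k)))
  structure(
    list(eigenvalues = eig$values, variance_fraction = eig$values / k,
         loadings = L),
    class = "feature_pca"
  )
}

#' @export
print.feature_pca <- function(x, ...) {
  cat("PCA of feature correlation matrix\n")
  cat("  variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Relative feature contributions to a principal component
#'
#' The relative contribution of feature `i` to a component is its absolute
#' loading normalized by the sum of absolute loadings
#' (`|l_i| / sum_j |l_j|`), so contributions sum to 100%. Optionally
#' reports the cumulative share of a named feature subset.
#'
#' @param pca a `feature_pca`.
#' @param component component index (1 = first).
#' @param subset optional character vector of feature names whose
#'   cumulative share to report.
#' @return list with `contributions` (named, sorted descending) and
#'   `subset_share` (or `NA` when no subset given).
#' @export
component_contributions <- function(pca, component = 1L, subset = NULL) {
  l <- pca$loadings[, component]
  contrib <- abs(l) / sum(abs(l))
  share <- NA_real_
  if (!is.null(subset)) {
    missing <- setdiff(subset, names(contrib))
    if (length(missing) > 0) {
      stopf("unknown features: %s", paste(missing, collapse = ", "))
    }
    share <- sum(contrib[subset])
  }
  list(contributions = sort(contrib, decreasing = TRUE),
       subset_share = share)
}

#' Assemble the 10-feature gene table from pipeline outputs
#'
#' Joins the measured features of this pipeline (mean expression,
#' expression plasticity, mean noise, noise plasticity, number of
#' regulatory inputs, from [compute_plasticities()] plus the mean matrix)
#' with externally provided per-gene features (RNA level, protein level,
#' codon bias, dN, dS).
#'
#' @param plasticities table from [compute_plasticities()].
#' @param mean_matrix promoters x conditions matrix of mean expression.
#' @param external data.frame with `gene_id` and the five external feature
#'   columns; joined on promoter/gene id.
#' @return data.frame with `gene_id` and the 10 canonical feature columns.
#' @export
assemble_feature_table <- function(plasticities, mean_matrix, external) {
  tab <- data.frame(
    gene_id = plasticities$promoter_id,
    n_inputs = plasticities$n_inputs,
    mean_expression = rowMeans(mean_matrix)[plasticities$promoter_id],
    expression_plasticity = plasticities$expression_plasticity,
    mean_noise = plasticities$mean_noise,
    noise_plasticity = plasticities$noise_plasticity,
    stringsAsFactors = FALSE
  )
  ext_cols <- c("rna_level", "protein_level", "codon_bias", "dN", "dS")
  i <- match(tab$gene_id, external$gene_id)
  for (col in ext_cols) tab[[col]] <- external[[col]][i]
  tab[, c("gene_id", canonical_features)]
}
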