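#' Pairwise Pearson correlation matrix of code embeddings
#'
#' Entry (i, j) is the Pearson correlation between the two codes' input
#' vectors across the embedding dimensions. The matrix is exactly
#' symmetrized and the diagonal set to 1.
#'
#' @param model A `cbow_model`.
#' @param codes Codes to include (default: whole vocabulary).
#' @return Symmetric correlation matrix with code dimnames.
#' @export
correlation_matrix <- function(model, codes = NULL) {
  v <- model_vectors(model, codes)
  if (ncol(v) < 2)
    abort("correlation needs embedding dimension >= 2",
          class = "comorbidnet_param_error")
  sds <- apply(v, 1, sd)
  if (any(sds == 0))
    abort(paste0("zero-variance vector(s); correlation undefined for: ",
                 paste(rownames(v)[sds == 0], collapse = ", ")),
          class = "comorbidnet_degenerate_error")
  m <- cor(t(v))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Two-dimensional PCA projection of code embeddings
#'
#' Scores on the top-2 principal components of the mean-centered
#' code-by-dimension matrix, for display. Component orientation is fixed
#' deterministically by making each component's largest-magnitude loading
#' positive.
#'
#' @param model A `cbow_model`.
#' @param codes Codes to project (default: whole vocabulary; at least 3).
#' @return Tibble `code`, `PC1`, `PC2`.
#' @export
pca_2d <- function(model, codes = NULL) {
  v <- model_vectors(model, codes)
  if (nrow(v) < 3)
    abort("PCA projection needs at least 3 codes",
          class = "comorbidnet_param_error")
  p <- prcomp(v, center = TRUE, scale. = FALSE)
  for (j in 1:2) {
    load <- p$rotation[, j]
    if (load[which.max(abs(load))] < 0) p$x[, j] <- -p$x[, j]
  }
  tibble::tibble(code = rownames(v), PC1 = p$x[, 1], PC2 = p$x[, 2])
}

#' Hierarchical clustering of code embeddings
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances between
#' the original (full-dimensional) embedding vectors, with the tree cut at
#' `k` clusters. Deterministic given the input.
#'
#' @param model A `cbow_model`.
#' @param codes Codes to cluster (default: whole vocabulary).
#' @param k Number of clusters.
#' @return Tibble `code`, `cluster` (ids 1..k, each non-empty).
#' @export
hierarchical_clusters <- function(model, codes = NULL, k = 9) {
  v <- model_vectors(model, codes)
  if (k < 1 || k > nrow(v))
    abort("`k` must lie in 1..number of codes",
          class = "comorbidnet_param_error")
  cl <- cutree(hclust(dist(v), method = "ward.D2"), k = k)
  tibble::tibble(code = rownames(v), cluster = unname(cl))
}

#' Extract the thresholded comorbidity edge list
#'
#' All unordered code pairs whose correlation is at least `threshold`
#' (inclusive, matching the ">= 0.5" / ">= 0.8" selection rules), sorted by
#' descending correlation then lexicographic pair; self-pairs excluded, and
#' each pair reported once with `code_a < code_b`.
#'
#' @param corr Symmetric correlation matrix with code dimnames.
#' @param threshold Inclusive correlation threshold in \[-1, 1\].
#' @return Tibble `code_a`, `code_b`, `r`.
#' @export
threshold_edges <- function(corr, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold < -1 || threshold > 1)
    abort("`threshold` must lie in [-1, 1]", class = "comorbidnet_param_error")
  codes <- rownames(corr)
  keep <- which(upper.tri(corr) & corr >= threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    code_a = pmin(codes[keep[, 1]], codes[keep[, 2]]),
    code_b = pmax(codes[keep[, 1]], codes[keep[, 2]]),
    r = corr[keep])
  dplyr::arrange(edges, dplyr::desc(.data$r), .data$code_a, .data$code_b)
}

#' Full association analysis of an embedding model
#'
#' Bundles the correlation matrix, thresholded edge list, hierarchical
#' clustering and 2-D PCA projection into one result object with
#' [tidy()]/[glance()]/[autoplot()] methods.
#'
#' @param model A `cbow_model`.
#' @param codes Codes to analyse (default: whole vocabulary).
#' @param threshold Inclusive correlation threshold for edges (0.5 is the
#'   category-level default; 0.8 the ICD-level one).
#' @param k Number of hierarchical clusters (9 by default).
#' @return An `association_result` with elements `codes`, `corr`, `edges`,
#'   `clusters`, `projection`, `threshold`, `k`.
#' @export
analyze_associations <- function(model, codes = NULL, threshold = 0.5, k = 9) {
  corr <- correlation_matrix(model, codes)
  structure(
    list(codes = rownames(corr),
         corr = corr,
         edges = threshold_edges(corr, threshold),
         clusters = hierarchical_clusters(model, codes, k = k),
         projection = pca_2d(model, codes),
         threshold = threshold, k = k),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> ", length(x$codes), " codes, ",
      nrow(x$edges), " edges at r >= ", x$threshold, ", ",
      x$k, " clusters\n", sep = "")
  invisible(x)
}

#' @describeIn analyze_associations The thresholded edge list joined with
#'   both codes' cluster ids.
#' @param x An `association_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.association_result <- function(x, ...) {
  cl <- stats::setNames(x$clusters$cluster, x$clusters$code)
  dplyr::mutate(x$edges,
                cluster_a = unname(cl[.data$code_a]),
                cluster_b = unname(cl[.data$code_b]))
}

#' @describeIn analyze_associations One-row summary: code, edge and cluster
#'   counts, threshold, mean absolute off-diagonal correlation.
#' @exportS3Method generics::glance
glance.association_result <- function(x, ...) {
  off <- x$corr[upper.tri(x$corr)]
  tibble::tibble(n_codes = length(x$codes), n_edges = nrow(x$edges),
                 threshold = x$threshold, k_clusters = x$k,
                 mean_abs_corr = mean(abs(off)))
}

#' @describeIn analyze_associations PCA map of the codes, coloured by
#'   cluster, with thresholded edges drawn between connected codes.
#' @param object An `association_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.association_result <- function(object, ...) {
  proj <- dplyr::left_join(object$projection, object$clusters, by = "code")
  seg <- object$edges |>
    dplyr::left_join(object$projection, by = c(code_a = "code")) |>
    dplyr::rename(xa = "PC1", ya = "PC2") |>
    dplyr::left_join(object$projection, by = c(code_b = "code"))
  ggplot2::ggplot(proj, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$PC1, yend = .data$PC2),
                          colour = "grey70", inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$cluster)), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$code), vjust = -0.7, size = 2.6) +
    ggplot2::labs(colour = "cluster",
                  title = "Disease map: PCA of code embeddings",
                  subtitle = paste0("edges at r ≥ ", object$threshold)) +
    ggplot2::theme_minimal()
}

#' Export an edge list for network viewers
#'
#' Writers for the thresholded comorbidity network: plain CSV, the simple
#' interaction format (SIF), and GraphML (via igraph) for tools such as
#' Cytoscape.
#'
#' @param edges Edge tibble (`code_a`, `code_b`, `r`, plus any attribute
#'   columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(edges, path) {
  readr::write_csv(edges, path)
  invisible(path)
}

#' @rdname write_edges_csv
#' @export
write_edges_sif <- function(edges, path) {
  writeLines(paste(edges$code_a, "co-occurs", edges$code_b), path)
  invisible(path)
}

#' @rdname write_edges_csv
#' @export
write_edges_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a correlation matrix as delimited text
#'
#' @param corr Correlation matrix with code dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corr_csv <- function(corr, path) {
  df <- tibble::as_tibble(corr, rownames = "code")
  readr::write_csv(df, path)
  invisible(path)
}
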