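#' Standard-scale a matrix column-wise
#'
#' Each column is centred to mean 0 and scaled to unit variance using the
#' population (1/n) standard deviation, matching the usual standard-scaler
#' convention; constant columns map to all zeros.
#'
#' @param m numeric matrix (>= 2 rows).
#' @return matrix of the same shape, with attributes `scaled:center` and
#'   `scaled:scale`.
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stopf("need at least 2 rows to standardize")
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  scale_safe <- ifelse(sdev > 0, sdev, 1)  # constant columns -> all zero
  out <- sweep(sweep(m, 2, mu), 2, scale_safe, "/")
  attr(out, "scaled:center") <- mu
  attr(out, "scaled:scale") <- sdev
  out
}

#' Two-component PCA of the (standardized) feature submatrix
#'
#' Projects genomes onto the top two right singular directions of the
#' centred input. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making coordinates reproducible
#' across platforms up to nothing at all. Explained-variance fractions are
#' computed from the full singular spectrum.
#'
#' @param m numeric matrix with >= 2 rows and >= 2 columns, typically the
#'   output of [standardize()] on an Intersection-Set submatrix.
#' @param labels optional per-row phenotype labels carried into the result.
#' @return object of class `ppa_pca`: list with `coords` (n x 2, columns
#'   PC1/PC2), `explained_variance` (length-2 fractions), `loadings`,
#'   `center`, `scale`, `labels`.
#' @export
pca2 <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stopf("need at least 2 features for a 2-component PCA")
  if (nrow(m) < 2) stopf("need at least 2 genomes")
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  sv <- svd(mc)
  v <- sv$v[, 1:2, drop = FALSE]
  for (j in 1:2) {                      # sign convention
    i_max <- which.max(abs(v[, j]))
    if (v[i_max, j] < 0) v[, j] <- -v[, j]
  }
  coords <- mc %*% v
  colnames(coords) <- c("PC1", "PC2")
  rownames(coords) <- rownames(m)
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(coords = coords,
                 explained_variance = ev[1:2],
                 all_variances = ev,
                 loadings = `colnames<-`(v, c("PC1", "PC2")),
                 center = ctr, labels = labels),
            class = "ppa_pca")
}

#' @export
print.ppa_pca <- function(x, ...) {
  cat(sprintf("ppa_pca: %d genomes; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$coords), 100 * x$explained_variance[1],
              100 * x$explained_variance[2]))
  invisible(x)
}

#' Run the standard-scaled two-component PCA on a feature subset
#'
#' @param pm a [presence_matrix()].
#' @param families feature subset (default: all families), typically the
#'   Intersection Set.
#' @return a [pca2()] result with genome phenotypes attached.
#' @export
pca_ordination <- function(pm, families = NULL) {
  families <- families %||% family_ids(pm)
  sub <- pm$bits[, families, drop = FALSE]
  pca2(standardize(sub), labels = pm$phenotype)
}

#' Scatter plot of a two-component PCA, colored by phenotype
#' @param x a `ppa_pca`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ppa_pca <- function(x, ...) {
  col <- if (is.null(x$labels)) "black"
         else ifelse(x$labels == "multipartite", "red", "blue")
  graphics::plot(x$coords, col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]),
                 ...)
  if (!is.null(x$labels))
    graphics::legend("topright", legend = c("multipartite", "unipartite"),
                     col = c("red", "blue"), pch = 19, bty = "n")
  invisible(x)
}

#' Write PCA coordinates as TSV (genome_id, label, pc1, pc2)
#' @param pca a `ppa_pca`; @param path output file.
#' @export
write_pca_tsv <- function(pca, path) {
  write_tsv(data.frame(genome_id = rownames(pca$coords),
                       label = pca$labels %||% NA,
                       pc1 = pca$coords[, 1], pc2 = pca$coords[, 2]),
            path)
}
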