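#' Per-map, per-chromosome summary matrix
#'
#' Builds the maps-by-chromosomes matrix of per-chromosome totals used for
#' whole-map comparison (PCA, clustering). All maps must share an assembly.
#'
#' @param maps list of [signal_map()]s.
#' @param labels row labels (genotype/time tags); defaults to list names.
#' @return numeric matrix, rows = maps, columns = chromosomes.
#' @export
build_map_matrix <- function(maps, labels = names(maps)) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]$assembly$chroms
  for (m in maps) {
    ch <- m$assembly$chroms
    if (!identical(ch$chrom, ref$chrom) || !identical(ch$length, ref$length))
      stop("maps built on mismatched assemblies")
  }
  if (is.null(labels)) labels <- paste0("map", seq_along(maps))
  mat <- t(vapply(maps, chromosome_totals_vec,
                  numeric(nrow(ref))))
  rownames(mat) <- labels
  colnames(mat) <- ref$chrom
  mat
}

#' Covariance PCA of a map matrix
#'
#' Principal component analysis on column-centered data without unit-variance
#' scaling (covariance PCA), computed by singular value decomposition. The
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive. Variance fractions sum to 1.
#'
#' @param matrix maps-by-chromosomes matrix from [build_map_matrix()]
#'   (at least 3 rows).
#' @return list with `scores` (maps x components), `loadings`
#'   (chromosomes x components), `variance_fractions`, `center`.
#' @export
pca_maps <- function(matrix) {
  if (nrow(matrix) < 3)
    stop("need at least 3 maps for PCA")
  ctr <- colMeans(matrix)
  xc <- sweep(matrix, 2, ctr)
  if (all(abs(xc) < 1e-12))
    stop("constant matrix: no variance to decompose")
  sv <- svd(xc)
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  dimnames(scores) <- list(rownames(matrix),
                           paste0("PC", seq_along(sv$d)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(matrix),
                             paste0("PC", seq_along(sv$d)))
  list(scores = scores, loadings = loadings,
       variance_fractions = sv$d^2 / sum(sv$d^2),
       center = ctr)
}

#' Ward-D2 hierarchical clustering of maps
#'
#' Agglomerative clustering of map rows with Euclidean distances and the
#' Ward D2 criterion. Returns the standard `hclust` merge tree, which is
#' deterministic for a given matrix.
#'
#' @param matrix maps-by-chromosomes matrix (at least 2 rows).
#' @return An object of class `hclust`.
#' @export
cluster_maps <- function(matrix) {
  if (nrow(matrix) < 2)
    stop("need at least 2 maps to cluster")
  stats::hclust(stats::dist(matrix, method = "euclidean"),
                method = "ward.D2")
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` tree from [cluster_maps()].
#' @param path optional file to write; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) ape::write.tree(phy)
  else invisible(ape::write.tree(phy, file = path))
}
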