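# Canonical leaf order: left-to-right traversal putting the smaller subtree
# first at every merge (ties by smallest leaf label).
.canonical_order <- function(hc) {
  n <- length(hc$labels)
  walk <- function(node) {
    if (node < 0) return(-node)
    kids <- hc$merge[node, ]
    left <- walk(kids[1]); right <- walk(kids[2])
    swap <- length(right) < length(left) ||
      (length(right) == length(left) &&
         min(hc$labels[right]) < min(hc$labels[left]))
    if (swap) c(right, left) else c(left, right)
  }
  walk(nrow(hc$merge))
}

#' Hierarchically cluster the species of a sharing matrix
#'
#' Clusters the species columns (average linkage on Euclidean distances by
#' default, the parameters are recorded in the result) and derives the
#' canonical leaf order. A single-species matrix yields a trivial one-leaf
#' result.
#'
#' @param x a [SharingMatrix] or a plain numeric matrix (variants x species).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param metric distance measure passed to [stats::dist()].
#' @return a [SpeciesClustering].
#' @export
clusterSpecies <- function(x, linkage = "average", metric = "euclidean") {
  mat <- if (methods::is(x, "SharingMatrix")) sharingValues(x) else x
  if (is.null(colnames(mat))) stop("species columns must be named")
  if (any(is.na(mat))) stop("sharing matrix contains undefined cells")
  if (ncol(mat) < 2L)
    return(new("SpeciesClustering", hclust = NULL,
               leafOrder = colnames(mat), cophenetic = NULL,
               linkage = linkage, metric = metric))
  d <- stats::dist(t(mat), method = metric)
  hc <- stats::hclust(d, method = linkage)
  ord <- .canonical_order(hc)
  hc$order <- ord
  new("SpeciesClustering", hclust = hc,
      leafOrder = hc$labels[ord],
      cophenetic = stats::cophenetic(hc),
      linkage = linkage, metric = metric)
}

#' Cut the species tree into k flat clusters
#'
#' @param clustering a [SpeciesClustering].
#' @param k number of clusters.
#' @return named integer cluster assignment.
#' @export
cutClusters <- function(clustering, k) {
  if (is.null(clustering@hclust))
    return(stats::setNames(1L, clustering@leafOrder))
  stats::cutree(clustering@hclust, k = k)
}

#' Render the allele-sharing heatmap with its testable TSV twin
#'
#' Writes (i) a heatmap image with cells colour-mapped over [0, 1], species
#' columns in the clustering's canonical leaf order and rows labelled with the
#' variant labels; (ii) an ordered TSV twin of the displayed matrix, which is
#' the artefact assertions run against; and (iii) a JSON metadata file
#' recording linkage, metric and leaf order.
#'
#' @param x a [SharingMatrix].
#' @param clustering a [SpeciesClustering] from [clusterSpecies()]; computed
#'   on the fly when \code{NULL}.
#' @param out_prefix path prefix: writes \code{<prefix>.png},
#'   \code{<prefix>.tsv} and \code{<prefix>.json}.
#' @param cluster_rows also order the variant rows by clustering (off by
#'   default: rows keep their input order).
#' @return named list of the three paths, invisibly.
#' @export
renderHeatmap <- function(x, clustering = NULL, out_prefix,
                          cluster_rows = FALSE) {
  stopifnot(methods::is(x, "SharingMatrix"))
  if (is.null(clustering)) clustering <- clusterSpecies(x)
  mat <- sharingValues(x)
  labels <- variantLabels(x)
  rownames(mat) <- ifelse(is.na(labels) | !nzchar(labels), rownames(mat),
                          labels)
  mat <- mat[, leafOrder(clustering), drop = FALSE]
  if (cluster_rows && nrow(mat) > 1L) {
    rhc <- stats::hclust(stats::dist(mat), method = clustering@linkage)
    mat <- mat[rhc$order, , drop = FALSE]
  }
  paths <- list(image = paste0(out_prefix, ".png"),
                tsv = paste0(out_prefix, ".tsv"),
                metadata = paste0(out_prefix, ".json"))
  grDevices::png(paths$image, width = 200 + 60 * ncol(mat),
                 height = 200 + 18 * nrow(mat), res = 96)
  on.exit(grDevices::dev.off(), add = TRUE)
  pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                     breaks = seq(0, 1, length.out = 101),
                     color = grDevices::hcl.colors(100, "YlOrRd",
                                                   rev = TRUE),
                     main = "Wild-allele sharing by species")
  twin <- data.frame(variant = rownames(mat), mat, check.names = FALSE)
  write_tsv(twin, paths$tsv)
  jsonlite::write_json(
    list(linkage = clustering@linkage, metric = clustering@metric,
         leaf_order = leafOrder(clustering),
         n_variants = nrow(mat), n_species = ncol(mat)),
    paths$metadata, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
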