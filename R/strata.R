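#' @title Stratified network layers and their comparison
#' @description
#' To compare prescription structure across demographic groups, the cohort
#' is split into sex-by-age strata (default: F/M crossed with 0-21, 22-64,
#' 65+, i.e. six groups). Each stratum yields its own DPN; over a shared
#' node universe these form layers of a multiplex network. Two layers are
#' compared through their binary adjacency matrices: entry (i, j) of the
#' cross-layer distance matrix is the Euclidean distance between the
#' neighbourhood profile (adjacency row) of code i in one layer and of code
#' j in the other. Squared distances between binary rows are Hamming
#' distances, so the matrix is integer-rooted by construction. Codes are
#' then grouped by agglomerative clustering of the distance matrix with the
#' ward.D2 linkage.
#' @name strata_compare
NULL

#' Split records into sex-by-age strata
#'
#' @param records record data.frame.
#' @param index_date index date for age computation (window end).
#' @param age_breaks lower bounds of the age strata (default 0/22/65).
#' @param sex_split also split by sex (default `TRUE`).
#' @return named list of record data.frames, one per non-empty stratum,
#'   names like `"F_65+"`; strata are disjoint and cover all records with
#'   non-negative age.
#' @export
stratifyRecords <- function(records, index_date = "2019-06-30",
                            age_breaks = c(0, 22, 65), sex_split = TRUE) {
  age <- ageAtIndex(records$birth_year, index_date)
  keep <- age >= 0
  records <- records[keep, , drop = FALSE]
  age <- age[keep]
  labs <- c(paste0(age_breaks[-length(age_breaks)], "-", age_breaks[-1] - 1L),
            paste0(age_breaks[length(age_breaks)], "+"))
  stratum <- as.character(cut(age, breaks = c(age_breaks, Inf),
                              labels = labs, right = FALSE))
  key <- if (sex_split) paste(records$sex, stratum, sep = "_") else stratum
  split(records, key)
}

#' Binary adjacency layer of a DPN over a node universe
#'
#' @param dpn a [DPN-class] object.
#' @param node_universe ordered character vector of codes containing all of
#'   the DPN's nodes (typically the union over the layers to be compared).
#' @param phi_star optional phi threshold applied before binarisation.
#' @return symmetric 0/1 integer matrix over `node_universe`, zero
#'   diagonal; rows of codes absent from the stratum are all zero. Carries
#'   attribute `label` when `dpn` has one.
#' @export
binaryLayer <- function(dpn, node_universe, phi_star = NULL) {
  if (!all(dpn@nodes$code %in% node_universe)) {
    stop("node universe is missing codes present in the network", call. = FALSE)
  }
  if (!is.null(phi_star)) dpn <- thresholdNetwork(dpn, phi_star)
  k <- length(node_universe)
  A <- matrix(0L, k, k, dimnames = list(node_universe, node_universe))
  if (nrow(dpn@edges)) {
    ii <- match(dpn@edges$i, node_universe)
    jj <- match(dpn@edges$j, node_universe)
    A[cbind(ii, jj)] <- 1L
    A[cbind(jj, ii)] <- 1L
  }
  A
}

#' Cross-layer Euclidean distance matrix
#'
#' `D[i, j]` is the Euclidean distance between row i of `layerA` and row j
#' of `layerB` — the neighbourhood profiles of code i in one stratum and
#' code j in the other. For binary layers `D^2` is the Hamming distance
#' between the rows.
#'
#' @param layerA,layerB binary adjacency matrices from [binaryLayer] over
#'   the identical node universe (same codes, same order).
#' @return numeric distance matrix with the universe as dimnames.
#' @export
layerDistance <- function(layerA, layerB) {
  if (!identical(dim(layerA), dim(layerB)) ||
      !identical(rownames(layerA), rownames(layerB))) {
    stop("layers must share an identical node universe and ordering", call. = FALSE)
  }
  rA <- rowSums(layerA^2)
  rB <- rowSums(layerB^2)
  cross <- layerA %*% t(layerB)
  D2 <- outer(rA, rB, "+") - 2 * cross
  D2[D2 < 0] <- 0 # numerical guard
  D <- sqrt(D2)
  dimnames(D) <- list(rownames(layerA), rownames(layerB))
  D
}

#' Agglomerative clustering with the ward.D2 linkage
#'
#' Clusters the rows/columns of a symmetric distance matrix with the
#' ward.D2 variant of Ward's method (squared distances inside the
#' Lance-Williams update, square-rooted merge heights), as implemented by
#' [stats::hclust].
#'
#' @param D square symmetric non-negative matrix with zero diagonal.
#' @return an [stats::hclust] tree.
#' @export
wardD2 <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) ||
      max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0) || any(D < 0)) {
    stop("ward.D2 needs a square symmetric non-negative matrix with zero ",
         "diagonal", call. = FALSE)
  }
  stats::hclust(stats::as.dist(D), method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges; cluster ids are renumbered by dendrogram
#' (left-to-right leaf) position.
#'
#' @param tree an [stats::hclust] tree.
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return named integer vector mapping labels to cluster ids 1..k.
#' @export
cutClusters <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must be in 1..", n, call. = FALSE)
  raw <- stats::cutree(tree, k = k)
  # renumber clusters by left-to-right dendrogram position
  pos <- integer(k)
  seen <- unique(raw[tree$order])
  pos[seen] <- seq_along(seen)
  out <- pos[raw]
  names(out) <- names(raw)
  out
}

#' Choose k by mean silhouette width
#'
#' Scans k = 2..`k_max` and returns the k with the largest mean silhouette
#' width of the ward.D2 partition under the given distances.
#'
#' @param D symmetric distance matrix.
#' @param k_max largest k to consider (default `min(10, n - 1)`).
#' @return list with `k`, `silhouette` (the mean width at that k) and the
#'   per-k widths.
#' @export
chooseK <- function(D, k_max = NULL) {
  n <- nrow(D)
  if (is.null(k_max)) k_max <- min(10L, n - 1L)
  if (k_max < 2L) stop("need at least 3 items to choose k", call. = FALSE)
  tree <- wardD2(D)
  dd <- stats::as.dist(D)
  widths <- vapply(2:k_max, function(k) {
    sil <- cluster::silhouette(stats::cutree(tree, k = k), dd)
    mean(sil[, "sil_width"])
  }, numeric(1))
  best <- which.max(widths)
  list(k = (2:k_max)[best], silhouette = widths[best],
       widths = stats::setNames(widths, 2:k_max))
}

#' LayerDistance: cross-layer distances with clustering
#'
#' @slot labels the node universe (row/column labels).
#' @slot D the cross-layer Euclidean distance matrix.
#' @slot symmetrised whether `(D + t(D)) / 2` replaced an asymmetric cross
#'   matrix before clustering.
#' @slot tree the ward.D2 merge tree (list-wrapped [stats::hclust]).
#' @slot clusters named integer cluster assignment.
#' @slot k number of clusters extracted.
#' @export
setClass("LayerDistance", representation(
  labels = "character", D = "matrix", symmetrised = "logical",
  tree = "list", clusters = "integer", k = "integer"
))

setMethod("show", "LayerDistance", function(object) {
  cat(sprintf("LayerDistance: %d x %d, %d clusters (ward.D2)%s\n",
              nrow(object@D), ncol(object@D), object@k,
              if (object@symmetrised) ", symmetrised" else ""))
})

#' Compare two stratum DPNs end to end
#'
#' Builds binary layers over the union universe, computes the cross-layer
#' distance matrix, clusters it with ward.D2 (symmetrising an asymmetric
#' cross matrix as `(D + t(D))/2` first) and extracts clusters.
#'
#' @param dpnA,dpnB two [DPN-class] objects at the same ATC level.
#' @param phi_star optional phi threshold applied to both layers.
#' @param k number of clusters; `NULL` chooses k by silhouette ([chooseK]).
#' @return a [LayerDistance-class] object.
#' @export
compareLayers <- function(dpnA, dpnB, phi_star = NULL, k = NULL) {
  if (dpnA@level != dpnB@level) stop("layers must share the ATC level", call. = FALSE)
  universe <- sort(union(dpnA@nodes$code, dpnB@nodes$code))
  A <- binaryLayer(dpnA, universe, phi_star)
  B <- binaryLayer(dpnB, universe, phi_star)
  D <- layerDistance(A, B)
  sym <- max(abs(D - t(D))) <= 1e-8
  Dc <- if (sym) D else (D + t(D)) / 2
  diag(Dc) <- 0
  tree <- wardD2(Dc)
  if (is.null(k)) {
    k <- tryCatch(chooseK(Dc)$k, error = function(e) 1L)
  }
  clusters <- if (k > 1L) cutClusters(tree, k) else
    stats::setNames(rep(1L, length(universe)), universe)
  methods::new("LayerDistance", labels = universe, D = D,
               symmetrised = !sym, tree = unclass(tree),
               clusters = clusters, k = as.integer(k))
}
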