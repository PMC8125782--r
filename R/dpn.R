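#' @title The DPN class: drug prescription networks
#' @description
#' A drug prescription network (DPN) at ATC level L is an undirected weighted
#' graph whose nodes are the ATC codes at level L found in a cohort's records
#' and whose edges join codes co-prescribed to at least one common patient.
#' The node weight Pi is the number of distinct patients prescribed drug i;
#' the edge weight Cij the number of distinct patients prescribed both i and
#' j. Nodes with no co-prescriptions (degree 0) are kept: they are real drugs
#' with Pi >= 1 and enter density and averages.
#' @name dpn_build
NULL

#' DPN: a drug co-prescription network
#'
#' @slot level ATC level (integer 1-5) of the node codes.
#' @slot nPatients size n of the cohort the network was built from.
#' @slot nodes data.frame with columns `code` and `Pi` (distinct patients
#'   prescribed the code), one row per node, including isolates.
#' @slot edges data.frame with columns `i`, `j`, `Cij` (distinct patients
#'   co-prescribed the pair), `i < j` lexicographically, `Cij >= 1`.
#' @export
setClass("DPN", representation(
  level = "integer",
  nPatients = "integer",
  nodes = "data.frame",
  edges = "data.frame"
))

setValidity("DPN", function(object) {
  n <- object@nodes
  e <- object@edges
  msg <- character(0)
  if (!all(c("code", "Pi") %in% names(n))) msg <- c(msg, "nodes needs columns code, Pi")
  if (!all(c("i", "j", "Cij") %in% names(e))) msg <- c(msg, "edges needs columns i, j, Cij")
  if (length(msg)) return(msg)
  if (anyDuplicated(n$code)) msg <- c(msg, "duplicate node codes")
  if (any(n$Pi < 1L)) msg <- c(msg, "node weights Pi must be >= 1")
  if (any(n$Pi > object@nPatients)) msg <- c(msg, "Pi cannot exceed the cohort size")
  if (nrow(e)) {
    if (any(e$i == e$j)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$i > e$j)) msg <- c(msg, "edges must be stored with i < j")
    if (anyDuplicated(paste(e$i, e$j))) msg <- c(msg, "duplicate edges")
    if (any(e$Cij < 1L)) msg <- c(msg, "edge weights Cij must be >= 1")
    idx_i <- match(e$i, n$code); idx_j <- match(e$j, n$code)
    if (anyNA(idx_i) || anyNA(idx_j)) {
      msg <- c(msg, "edge endpoint not among the nodes")
    } else if (any(e$Cij > pmin(n$Pi[idx_i], n$Pi[idx_j]))) {
      msg <- c(msg, "Cij cannot exceed min(Pi, Pj)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DPN object from node and edge tables
#'
#' Low-level constructor; most users build networks from records with
#' [buildIncidence] + [buildDPN].
#'
#' @param level ATC level 1-5.
#' @param nPatients cohort size n.
#' @param nodes data.frame with `code`, `Pi`.
#' @param edges data.frame with `i`, `j`, `Cij` (unordered pairs; reordered
#'   so `i < j` internally).
#' @return a [DPN-class] object.
#' @export
DPN <- function(level, nPatients, nodes, edges) {
  nodes <- data.frame(code = as.character(nodes$code),
                      Pi = as.integer(nodes$Pi), stringsAsFactors = FALSE)
  if (nrow(edges)) {
    i <- as.character(edges$i); j <- as.character(edges$j)
    swap <- i > j
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    edges <- data.frame(i = i, j = j, Cij = as.integer(edges$Cij),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = character(0), j = character(0), Cij = integer(0),
                        stringsAsFactors = FALSE)
  }
  methods::new("DPN", level = as.integer(level),
               nPatients = as.integer(nPatients),
               nodes = nodes, edges = edges)
}

#' @describeIn DPN number of nodes N.
#' @param x,object a `DPN`.
#' @export
setMethod("length", "DPN", function(x) nrow(x@nodes))

#' Accessors for DPN objects
#'
#' `atcLevelOf` returns the network's ATC level, `cohortSize` the number of
#' patients n it was built from, `nNodes`/`nEdges` the counts N and E,
#' `nodeWeights` the named Pi vector and `edgeTable` the edge data.frame
#' with columns `i`, `j`, `Cij`.
#'
#' @param dpn a [DPN-class] object.
#' @return see individual descriptions.
#' @name dpn-accessors
NULL

#' @rdname dpn-accessors
#' @export
atcLevelOf <- function(dpn) dpn@level

#' @rdname dpn-accessors
#' @export
cohortSize <- function(dpn) dpn@nPatients

#' @rdname dpn-accessors
#' @export
nNodes <- function(dpn) nrow(dpn@nodes)

#' @rdname dpn-accessors
#' @export
nEdges <- function(dpn) nrow(dpn@edges)

#' @rdname dpn-accessors
#' @export
nodeWeights <- function(dpn) stats::setNames(dpn@nodes$Pi, dpn@nodes$code)

#' @rdname dpn-accessors
#' @export
edgeTable <- function(dpn) dpn@edges

setMethod("show", "DPN", function(object) {
  cat(sprintf("DPN at ATC level %d: %d nodes, %d edges (cohort n = %d)\n",
              object@level, nrow(object@nodes), nrow(object@edges),
              object@nPatients))
  if (nrow(object@nodes)) {
    top <- utils::head(object@nodes[order(-object@nodes$Pi), ], 3L)
    cat("  most prescribed:",
        paste(sprintf("%s (Pi=%d)", top$code, top$Pi), collapse = ", "), "\n")
  }
})

#' Build a DPN from a patient-by-drug incidence
#'
#' Computes Pi as the column sums of the incidence and Cij as the pairwise
#' column intersections (via the sparse cross-product), keeping every pair
#' with at least one common patient as an edge. Codes prescribed to at least
#' one patient become nodes even when they share no patient with any other
#' code (degree-0 nodes).
#'
#' @param incidence a sparse logical patient-by-code matrix from
#'   [buildIncidence].
#' @return a [DPN-class] object at the incidence's level.
#' @export
buildDPN <- function(incidence) {
  level <- attr(incidence, "level")
  if (is.null(level)) stop("incidence has no ATC level attribute", call. = FALSE)
  if (nrow(incidence) == 0L || ncol(incidence) == 0L) {
    stop("empty incidence: no patients or no codes", call. = FALSE)
  }
  X <- methods::as(incidence, "dMatrix")
  co <- Matrix::crossprod(X) # codes x codes; diagonal = Pi
  Pi <- as.integer(Matrix::diag(co))
  codes <- colnames(incidence)
  nodes <- data.frame(code = codes, Pi = Pi, stringsAsFactors = FALSE)
  co_t <- methods::as(Matrix::triu(co, k = 1L), "TsparseMatrix")
  keep <- co_t@x >= 1
  edges <- data.frame(
    i = codes[co_t@i[keep] + 1L],
    j = codes[co_t@j[keep] + 1L],
    Cij = as.integer(co_t@x[keep]),
    stringsAsFactors = FALSE
  )
  DPN(level = level, nPatients = nrow(incidence), nodes = nodes, edges = edges)
}

#' Convert a DPN to an igraph graph
#'
#' The returned graph is undirected, with vertex attribute `Pi` and edge
#' attribute `Cij`; isolated nodes are preserved.
#'
#' @param dpn a [DPN-class] object.
#' @return an [igraph::igraph] object.
#' @export
asIgraph <- function(dpn) {
  g <- igraph::graph_from_data_frame(
    dpn@edges[, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = dpn@nodes$code, Pi = dpn@nodes$Pi)
  )
  if (nrow(dpn@edges)) {
    igraph::E(g)$Cij <- dpn@edges$Cij
  } else {
    g <- igraph::set_edge_attr(g, "Cij", value = numeric(0))
  }
  g
}

#' Per-node table of weights and centralities
#'
#' One row per node with the patient count Pi and the node metrics (degree
#' ki, betweenness bi, closeness Cli), suitable for popularity-vs-degree
#' scatter plots.
#'
#' @param dpn a [DPN-class] object.
#' @param metrics a node-metrics data.frame from [nodeMetrics]; computed on
#'   `dpn` (with the default weighting) when omitted.
#' @return data.frame with columns `code`, `Pi`, `ki`, `bi`, `Cli`.
#' @export
nodeTable <- function(dpn, metrics = NULL) {
  if (is.null(metrics)) metrics <- nodeMetrics(dpn)
  if (!setequal(metrics$code, dpn@nodes$code)) {
    stop("metrics were computed on a different node set", call. = FALSE)
  }
  m <- metrics[match(dpn@nodes$code, metrics$code), , drop = FALSE]
  data.frame(code = dpn@nodes$code, Pi = dpn@nodes$Pi,
             ki = m$ki, bi = m$bi, Cli = m$Cli,
             stringsAsFactors = FALSE, row.names = NULL)
}
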