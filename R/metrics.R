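#' @title Structural metrics of drug prescription networks
#' @description
#' The metric panel used to characterise DPN structure: density
#' d = 2E/(N(N-1)); per-node degree ki, Freeman betweenness bi (unnormalised,
#' geodesic ties split equally) and closeness Cli = 1/sum of distances to
#' reachable nodes; their means with a coefficient of variation
#' CV% = 100 * population SD / mean; Newman degree assortativity r; and the
#' random-graph giant-component criteria (mean degree above 1: a giant
#' component exists; above ln N: it spans the network).
#'
#' Betweenness and closeness depend on an edge-length convention. Three are
#' provided: `"cij"` (edge length = the raw co-prescription count Cij,
#' treating the weight as a traversal cost — the default), `"inverse-cij"`
#' (length = 1/Cij, strong co-prescription = short) and `"unweighted"`.
#' @name network_metrics
NULL

.resolveWeights <- function(dpn, weighting) {
  switch(weighting,
    "unweighted" = NA,
    "cij" = {
      if (any(dpn@edges$Cij <= 0)) stop("non-positive edge length", call. = FALSE)
      as.numeric(dpn@edges$Cij)
    },
    "inverse-cij" = {
      if (any(dpn@edges$Cij <= 0)) stop("non-positive edge length", call. = FALSE)
      1 / as.numeric(dpn@edges$Cij)
    },
    stop("unknown weighting mode: ", weighting, call. = FALSE)
  )
}

#' Graph density of a DPN
#'
#' @param dpn a [DPN-class] object with at least 2 nodes.
#' @return 2E / (N(N-1)).
#' @export
networkDensity <- function(dpn) {
  N <- nNodes(dpn)
  if (N < 2L) stop("density undefined for fewer than 2 nodes", call. = FALSE)
  2 * nEdges(dpn) / (N * (N - 1))
}

#' Per-node degree, betweenness and closeness
#'
#' @param dpn a [DPN-class] object.
#' @param weighting `"cij"` (default), `"inverse-cij"` or `"unweighted"`;
#'   see [network_metrics].
#' @return data.frame with columns `code`, `ki` (integer degree), `bi`
#'   (Freeman betweenness, unnormalised), `Cli` (closeness; 0 for isolated
#'   nodes; per-component sums for disconnected graphs).
#' @export
nodeMetrics <- function(dpn, weighting = c("cij", "inverse-cij", "unweighted")) {
  weighting <- match.arg(weighting)
  g <- asIgraph(dpn)
  w <- .resolveWeights(dpn, weighting)
  wts <- if (identical(w, NA)) NA else w
  ki <- igraph::degree(g)
  bi <- igraph::betweenness(g, weights = wts, normalized = FALSE)
  Cli <- suppressWarnings(
    igraph::closeness(g, weights = wts, mode = "all", normalized = FALSE)
  )
  Cli[!is.finite(Cli)] <- 0 # isolated nodes
  data.frame(code = igraph::V(g)$name, ki = as.integer(ki),
             bi = as.numeric(bi), Cli = as.numeric(Cli),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Newman degree assortativity
#'
#' Pearson correlation of the degrees at the two ends of every edge, each
#' edge counted in both orientations. Zero degree variance over the edge
#' ends (regular graphs, including complete graphs) gives `NA`, matching the
#' convention of reporting assortativity as not applicable there.
#'
#' @param dpn a [DPN-class] object with at least one edge.
#' @return assortativity in \[-1, 1\], or `NA`.
#' @export
assortativityDegree <- function(dpn) {
  if (nEdges(dpn) == 0L) stop("assortativity undefined without edges", call. = FALSE)
  deg <- stats::setNames(rep(0L, nNodes(dpn)), dpn@nodes$code)
  tab <- table(c(dpn@edges$i, dpn@edges$j))
  deg[names(tab)] <- as.integer(tab)
  x <- c(deg[dpn@edges$i], deg[dpn@edges$j])
  y <- c(deg[dpn@edges$j], deg[dpn@edges$i])
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  r <- igraph::assortativity_degree(asIgraph(dpn), directed = FALSE)
  if (!is.finite(r)) NA_real_ else r
}

#' Giant-component criteria and the true component decomposition
#'
#' Reports the two mean-degree heuristics from random-graph theory — a giant
#' component exists when the mean degree exceeds 1 and spans the network
#' when it exceeds ln N — alongside the actual component sizes, since the
#' criteria are heuristic and can disagree with the decomposition.
#'
#' @param dpn a [DPN-class] object.
#' @return list with `has_giant` (k-bar > 1), `fully_connected_regime`
#'   (k-bar > ln N), and `component_sizes` (decreasing).
#' @export
giantComponentFlags <- function(dpn) {
  N <- nNodes(dpn)
  kbar <- if (N > 0) 2 * nEdges(dpn) / N else 0
  comp <- igraph::components(asIgraph(dpn))
  list(has_giant = kbar > 1,
       fully_connected_regime = N > 0 && kbar > log(N),
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

.cvPct <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  m <- mean(x)
  if (length(x) == 0L || m == 0) return(NA_real_)
  s <- if (sd_type == "population") {
    sqrt(mean((x - m)^2))
  } else {
    stats::sd(x)
  }
  100 * s / m
}

#' One-row structural summary of a DPN
#'
#' Assembles the full metric panel for one network: N, ln N, E, density,
#' mean and CV% of degree/betweenness/closeness, assortativity, and the
#' giant-component flags.
#'
#' @param dpn a [DPN-class] object.
#' @param weighting edge-length convention for betweenness/closeness; see
#'   [nodeMetrics].
#' @param sd_type `"population"` (default) or `"sample"` standard deviation
#'   inside the CV.
#' @return one-row data.frame with columns `level`, `N`, `lnN`, `E`, `d`,
#'   `k_mean`, `k_cv_pct`, `b_mean`, `b_cv_pct`, `cl_mean`, `cl_cv_pct`,
#'   `r`, `has_giant`, `fully_connected_regime`, `weighting`.
#' @export
networkSummary <- function(dpn, weighting = c("cij", "inverse-cij", "unweighted"),
                           sd_type = c("population", "sample")) {
  weighting <- match.arg(weighting)
  sd_type <- match.arg(sd_type)
  N <- nNodes(dpn); E <- nEdges(dpn)
  m <- nodeMetrics(dpn, weighting)
  flags <- giantComponentFlags(dpn)
  r <- if (E >= 1L) assortativityDegree(dpn) else NA_real_
  data.frame(
    level = dpn@level, N = N, lnN = log(N), E = E,
    d = if (N >= 2L) networkDensity(dpn) else NA_real_,
    k_mean = mean(m$ki), k_cv_pct = .cvPct(m$ki, sd_type),
    b_mean = mean(m$bi), b_cv_pct = .cvPct(m$bi, sd_type),
    cl_mean = mean(m$Cli), cl_cv_pct = .cvPct(m$Cli, sd_type),
    r = r,
    has_giant = flags$has_giant,
    fully_connected_regime = flags$fully_connected_regime,
    weighting = weighting,
    stringsAsFactors = FALSE
  )
}
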