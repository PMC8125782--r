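#' @title Phi-correlation edge thresholding and the phi-max statistic
#' @description
#' For an edge between drugs i and j in a cohort of n patients, the phi
#' coefficient is the Pearson correlation of the two binary patient
#' indicator vectors ("was prescribed i" / "was prescribed j"):
#' \deqn{\phi_{ij} = \frac{n C_{ij} - P_i P_j}{\sqrt{P_i (n - P_i) P_j (n - P_j)}}}
#' Thresholding a DPN at increasing values of phi* removes the "weaker"
#' edges first — those with small Cij relative to Pi and Pj. The fractions
#' of connected nodes (degree >= 1) and of edges that survive, as functions
#' of phi*, form a pair of retention curves. Each is fitted with a logistic
#' in x = log10 phi*; phi-max is the phi* value maximising the gap between
#' the fitted node-retention and edge-retention curves, and serves as a
#' principled threshold exposing the network's modular core.
#' @name phi_thresholding
NULL

#' Phi coefficient from 2x2 co-prescription counts
#'
#' Vectorised over all four arguments.
#'
#' @param n cohort size.
#' @param Pi,Pj patients prescribed drug i resp. j; must satisfy
#'   `0 < Pi < n` (otherwise the indicator has zero variance).
#' @param Cij patients prescribed both; must lie within the Frechet bounds
#'   `max(0, Pi + Pj - n) <= Cij <= min(Pi, Pj)`.
#' @return phi in \[-1, 1\], equal to the Pearson correlation of the two
#'   explicit binary indicator vectors.
#' @examples
#' phiCoefficient(100, 50, 50, 25) # independent: 0
#' phiCoefficient(100, 60, 40, 30)
#' @export
phiCoefficient <- function(n, Pi, Pj, Cij) {
  k <- max(length(n), length(Pi), length(Pj), length(Cij))
  n <- as.numeric(rep_len(n, k)); Pi <- as.numeric(rep_len(Pi, k))
  Pj <- as.numeric(rep_len(Pj, k)); Cij <- as.numeric(rep_len(Cij, k))
  if (any(Pi <= 0 | Pi >= n | Pj <= 0 | Pj >= n)) {
    stop("phi undefined: Pi and Pj must lie strictly between 0 and n ",
         "(zero-variance indicator)", call. = FALSE)
  }
  if (any(Cij < pmax(0, Pi + Pj - n) | Cij > pmin(Pi, Pj))) {
    stop("inconsistent counts: Cij outside the Frechet bounds", call. = FALSE)
  }
  (n * Cij - Pi * Pj) / sqrt(Pi * (n - Pi) * Pj * (n - Pj))
}

#' Phi coefficient for every edge of a DPN
#'
#' Edges whose phi is undefined (an endpoint prescribed to every patient in
#' the cohort) are dropped with a warning.
#'
#' @param dpn a [DPN-class] object.
#' @return data.frame with columns `i`, `j`, `Pi`, `Pj`, `Cij`, `phi`.
#' @export
edgePhi <- function(dpn) {
  e <- dpn@edges
  P <- nodeWeights(dpn)
  n <- cohortSize(dpn)
  Pi <- P[e$i]; Pj <- P[e$j]
  defined <- Pi > 0 & Pi < n & Pj > 0 & Pj < n
  if (any(!defined)) {
    warning(sum(!defined), " edge(s) dropped: phi undefined (endpoint ",
            "prescribed to all or no patients)", call. = FALSE)
  }
  e <- e[defined, , drop = FALSE]
  data.frame(i = e$i, j = e$j,
             Pi = as.integer(Pi[defined]), Pj = as.integer(Pj[defined]),
             Cij = e$Cij,
             phi = if (nrow(e)) phiCoefficient(n, Pi[defined], Pj[defined], e$Cij)
                   else numeric(0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Threshold a DPN by phi
#'
#' Keeps the edges with `phi >= phi_star`; all nodes are retained, and
#' "connected nodes" downstream means nodes of surviving degree >= 1.
#'
#' @param dpn a [DPN-class] object.
#' @param phi_star threshold on the phi coefficient.
#' @return a [DPN-class] object with the surviving edges.
#' @export
thresholdNetwork <- function(dpn, phi_star) {
  ep <- suppressWarnings(edgePhi(dpn))
  keep <- ep[ep$phi >= phi_star, c("i", "j", "Cij"), drop = FALSE]
  DPN(level = dpn@level, nPatients = dpn@nPatients,
      nodes = dpn@nodes, edges = keep)
}

#' Default log-spaced phi* grid
#'
#' @param n_points number of grid points (default 50).
#' @param lo,hi grid range (defaults 0.00001 to 1).
#' @return increasing numeric vector.
#' @export
phiGrid <- function(n_points = 50L, lo = 1e-5, hi = 1) {
  10^seq(log10(lo), log10(hi), length.out = n_points)
}

#' Node and edge retention over a phi* grid
#'
#' For each phi* in the grid, the fraction of connected nodes (degree >= 1)
#' and of edges surviving the threshold, relative to the unthresholded
#' connected-node and edge counts.
#'
#' @param dpn a [DPN-class] object with at least one edge.
#' @param grid increasing phi* values; [phiGrid()] by default.
#' @return a [RetentionCurve-class] object (without logistic fits; see
#'   [fitRetention]).
#' @export
retentionCurve <- function(dpn, grid = phiGrid()) {
  if (length(grid) == 0L) stop("empty phi* grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  ep <- suppressWarnings(edgePhi(dpn))
  if (nrow(ep) == 0L) stop("no edges with a defined phi", call. = FALSE)
  n_edges0 <- nrow(ep)
  connected0 <- unique(c(ep$i, ep$j))
  n_nodes0 <- length(connected0)
  node_frac <- edge_frac <- numeric(length(grid))
  for (g in seq_along(grid)) {
    surv <- ep$phi >= grid[g]
    edge_frac[g] <- sum(surv) / n_edges0
    node_frac[g] <- length(unique(c(ep$i[surv], ep$j[surv]))) / n_nodes0
  }
  methods::new("RetentionCurve",
               grid = as.numeric(grid), node_frac = node_frac,
               edge_frac = edge_frac,
               n_nodes0 = n_nodes0, n_edges0 = n_edges0,
               node_fit = list(), edge_fit = list(), phi_max = NA_real_)
}

#' RetentionCurve: node/edge survival under phi thresholding
#'
#' @slot grid increasing phi* values.
#' @slot node_frac,edge_frac fractions (in \[0,1\]) of connected nodes and
#'   edges surviving at each grid value, relative to the unthresholded
#'   counts `n_nodes0` and `n_edges0`.
#' @slot node_fit,edge_fit logistic fits from [fitLogistic] (empty lists
#'   until [fitRetention] is called).
#' @slot phi_max the gap-maximising threshold, `NA` until estimated.
#' @export
setClass("RetentionCurve", representation(
  grid = "numeric", node_frac = "numeric", edge_frac = "numeric",
  n_nodes0 = "integer", n_edges0 = "integer",
  node_fit = "list", edge_fit = "list", phi_max = "numeric"
))

setValidity("RetentionCurve", function(object) {
  msg <- character(0)
  if (length(object@grid) != length(object@node_frac) ||
      length(object@grid) != length(object@edge_frac)) {
    msg <- c(msg, "grid and fraction lengths differ")
  }
  if (is.unsorted(object@grid, strictly = TRUE)) msg <- c(msg, "grid not increasing")
  if (!is.unsorted(rev(object@node_frac)) ||
      any(diff(object@node_frac) > 0) || any(diff(object@edge_frac) > 0)) {
    # non-increasing check done explicitly below
  }
  if (any(diff(object@node_frac) > 1e-12) || any(diff(object@edge_frac) > 1e-12)) {
    msg <- c(msg, "retention fractions must be non-increasing in phi*")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RetentionCurve", function(object) {
  cat(sprintf("RetentionCurve over %d phi* values in [%g, %g]\n",
              length(object@grid), min(object@grid), max(object@grid)))
  cat(sprintf("  baseline: %d connected nodes, %d edges\n",
              object@n_nodes0, object@n_edges0))
  if (!is.na(object@phi_max)) cat(sprintf("  phi_max = %.3f\n", object@phi_max))
})

.logisticCurve <- function(x, A, x0, s) A / (1 + exp((x - x0) / s))

#' Fit a decaying logistic to a retention curve
#'
#' Least-squares fit of `A / (1 + exp((x - x0) / s))` with `x = log10 phi*`.
#' The asymptote A is fixed at 1 by default (retention starts at 1); `x0` is
#' the midpoint on the log10 scale and `s > 0` the decay width in decades.
#'
#' @param xs numeric vector of `log10(phi*)` values (>= 4 distinct).
#' @param fracs retention fractions in \[0, 1\].
#' @param fix_A asymptote value, or `NA` to fit it freely in (0, 1].
#' @return list with `A`, `x0`, `s`, `rss` and `converged`.
#' @export
fitLogistic <- function(xs, fracs, fix_A = 1) {
  if (length(unique(xs)) < 4L) stop("need >= 4 distinct grid points", call. = FALSE)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]", call. = FALSE)
  if (length(unique(round(fracs, 12))) == 1L) {
    stop("degenerate fit: retention fractions are constant", call. = FALSE)
  }
  # start values: midpoint where the curve crosses half its range, with a
  # small spread of widths to escape flat regions of the objective
  A0 <- if (is.na(fix_A)) max(fracs) else fix_A
  x0_start <- xs[which.min(abs(fracs - A0 / 2))]
  span <- diff(range(xs))
  resid_fn <- function(p) {
    A <- if (is.na(fix_A)) p[["A"]] else fix_A
    fracs - .logisticCurve(xs, A, p[["x0"]], p[["s"]])
  }
  best <- NULL
  for (s_start in span * c(0.05, 0.15, 0.4)) {
    par0 <- if (is.na(fix_A)) c(A = A0, x0 = x0_start, s = s_start)
            else c(x0 = x0_start, s = s_start)
    lower <- if (is.na(fix_A)) c(A = 1e-8, x0 = -Inf, s = 1e-8)
             else c(x0 = -Inf, s = 1e-8)
    upper <- if (is.na(fix_A)) c(A = 1, x0 = Inf, s = Inf)
             else c(x0 = Inf, s = Inf)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(list(A = A0, x0 = x0_start, s = span * 0.15, rss = NA_real_,
                converged = FALSE))
  }
  p <- best$par
  list(A = if (is.na(fix_A)) unname(p[["A"]]) else fix_A,
       x0 = unname(p[["x0"]]), s = unname(p[["s"]]),
       rss = best$deviance,
       converged = best$info %in% 1:3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit both retention logistics and estimate phi-max
#'
#' Fits the node- and edge-retention curves with [fitLogistic] and locates
#' phi-max with [phiMax].
#'
#' @param curve a [RetentionCurve-class] object.
#' @param fix_A asymptote handling, see [fitLogistic].
#' @return the curve with `node_fit`, `edge_fit` and `phi_max` filled in.
#' @export
fitRetention <- function(curve, fix_A = 1) {
  xs <- log10(curve@grid)
  curve@node_fit <- fitLogistic(xs, curve@node_frac, fix_A = fix_A)
  curve@edge_fit <- fitLogistic(xs, curve@edge_frac, fix_A = fix_A)
  if (isTRUE(curve@node_fit$converged) && isTRUE(curve@edge_fit$converged)) {
    curve@phi_max <- phiMax(curve@node_fit, curve@edge_fit,
                            interval = range(curve@grid))
  } else {
    warning("logistic fit did not converge; phi_max set to NA", call. = FALSE)
    curve@phi_max <- NA_real_
  }
  curve
}

#' Phi-max: the threshold maximising the node/edge retention gap
#'
#' Evaluates the difference between the fitted node and edge logistic
#' curves on a dense log-spaced grid over `interval` and refines the
#' maximum locally with [stats::optimize]. Returns `NA` (with a message)
#' when the fits are identical or the gap is nowhere positive.
#'
#' @param node_fit,edge_fit logistic fits from [fitLogistic]; both must
#'   have converged.
#' @param interval phi search interval (default `c(1e-5, 1)`).
#' @return phi-max on the phi scale, or `NA`.
#' @export
phiMax <- function(node_fit, edge_fit, interval = c(1e-5, 1)) {
  if (!isTRUE(node_fit$converged) || !isTRUE(edge_fit$converged)) {
    stop("phi-max requires converged logistic fits", call. = FALSE)
  }
  gap <- function(x) { # x on log10 scale
    .logisticCurve(x, node_fit$A, node_fit$x0, node_fit$s) -
      .logisticCurve(x, edge_fit$A, edge_fit$x0, edge_fit$s)
  }
  lo <- log10(interval[1]); hi <- log10(interval[2])
  xs <- seq(lo, hi, length.out = 2000L)
  gs <- gap(xs)
  if (max(gs) <= 1e-12) {
    message("phi-max undefined: node/edge retention gap is nowhere positive")
    return(NA_real_)
  }
  i <- which.max(gs)
  bracket <- c(xs[max(1L, i - 1L)], xs[min(length(xs), i + 1L)])
  opt <- stats::optimize(gap, interval = bracket, maximum = TRUE,
                         tol = 1e-10)
  10^opt$maximum
}

#' @rdname dpn-accessors
#' @param curve a [RetentionCurve-class] object.
#' @export
phiMaxOf <- function(curve) curve@phi_max

#' Retention curve as a data.frame
#'
#' @param x a [RetentionCurve-class] object.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with `phi_star`, `node_frac`, `edge_frac` and, when
#'   fits are present, the fitted values `node_fit`, `edge_fit`.
#' @export
as.data.frame.RetentionCurve <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- data.frame(phi_star = x@grid, node_frac = x@node_frac,
                    edge_frac = x@edge_frac)
  if (length(x@node_fit)) {
    xs <- log10(x@grid)
    out$node_fit <- .logisticCurve(xs, x@node_fit$A, x@node_fit$x0, x@node_fit$s)
    out$edge_fit <- .logisticCurve(xs, x@edge_fit$A, x@edge_fit$x0, x@edge_fit$s)
  }
  out
}
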