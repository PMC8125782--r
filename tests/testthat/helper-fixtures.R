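# Programmatic fixtures: everything is generated in code at test time.

# DPN straight from a list of per-patient drug sets (patient names implied).
dpn_from_sets <- function(sets, level = NULL) {
  codes <- unlist(sets, use.names = FALSE)
  if (is.null(level)) level <- dpnet::atcLevel(codes[1])
  records <- data.frame(
    patient_id = rep(sprintf("P%03d", seq_along(sets)), lengths(sets)),
    sex = "F", birth_year = 1980L, date = as.Date("2019-01-15"),
    atc5 = codes, stringsAsFactors = FALSE
  )
  # sets may already be at a coarse level; bypass projection by building the
  # incidence directly
  pid <- factor(records$patient_id)
  cid <- factor(records$atc5)
  m <- Matrix::sparseMatrix(i = as.integer(pid), j = as.integer(cid), x = TRUE,
                            dims = c(nlevels(pid), nlevels(cid)),
                            dimnames = list(levels(pid), levels(cid)),
                            use.last.ij = TRUE)
  attr(m, "level") <- level
  dpnet::buildDPN(m)
}

# Arbitrary DPN with the given edge list (codes as plain labels), with
# internally consistent Pi/Cij weights, for metric tests where only topology
# and weights matter.
dpn_from_edges <- function(edges, nodes = NULL, cij = NULL, n_patients = 10000L) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$i, edges$j)))
  if (is.null(cij)) cij <- rep(1L, nrow(edges))
  Pi <- stats::setNames(rep(1L, length(nodes)), nodes)
  if (nrow(edges)) {
    incident_max <- tapply(c(cij, cij), c(edges$i, edges$j), max)
    Pi[names(incident_max)] <- pmax(Pi[names(incident_max)],
                                    as.integer(incident_max))
  }
  dpnet::DPN(level = 1L, nPatients = n_patients,
             nodes = data.frame(code = nodes, Pi = as.integer(Pi)),
             edges = data.frame(i = edges$i, j = edges$j, Cij = as.integer(cij)))
}

# Erdos-Renyi-style random DPN with random positive integer edge weights.
random_dpn <- function(n_nodes, p_edge, max_cij = 5L) {
  nodes <- sprintf("X%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  cij <- sample.int(max_cij, nrow(edges), replace = TRUE)
  dpn_from_edges(edges, nodes = nodes, cij = cij)
}

# Edge-length matrix (Inf off-graph) of a DPN under a weighting mode.
length_matrix <- function(dpn, weighting = c("cij", "inverse-cij", "unweighted")) {
  weighting <- match.arg(weighting)
  et <- dpnet::edgeTable(dpn)
  codes <- names(dpnet::nodeWeights(dpn))
  n <- length(codes)
  W <- matrix(Inf, n, n, dimnames = list(codes, codes))
  diag(W) <- 0
  len <- switch(weighting, cij = et$Cij, `inverse-cij` = 1 / et$Cij,
                unweighted = rep(1, nrow(et)))
  if (nrow(et)) {
    W[cbind(match(et$i, codes), match(et$j, codes))] <- len
    W[cbind(match(et$j, codes), match(et$i, codes))] <- len
  }
  W
}

# Tiny records table for ingest tests.
make_records <- function(n = 6L, atc = "J01CR02", sex = "F",
                         birth_year = 1970L, date = "2019-01-15") {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = rep_len(sex, n),
    birth_year = rep_len(as.integer(birth_year), n),
    date = as.Date(rep_len(date, n)),
    atc5 = rep_len(atc, n),
    stringsAsFactors = FALSE
  )
}
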