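#' @title Reading and writing DPNs
#' @description Interchange formats for drug prescription networks: GraphML
#'   (vertex attribute `Pi`, edge attribute `Cij`) and a two-file edge-list
#'   CSV (`<stem>_edges.csv` with columns `i,j,Cij` and `<stem>_nodes.csv`
#'   with `i,Pi`, so isolated nodes survive the round trip). Cohort size and
#'   ATC level travel as graph attributes (GraphML) or a header comment
#'   (CSV).
#' @name dpn_io
NULL

#' Write a DPN to disk
#'
#' @param dpn a [DPN-class] object.
#' @param path output path. For `format = "edgelist"`, `path` is a stem:
#'   `<stem>_edges.csv` and `<stem>_nodes.csv` are written.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
writeGraph <- function(dpn, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- asIgraph(dpn)
    g <- igraph::set_graph_attr(g, "level", dpn@level)
    g <- igraph::set_graph_attr(g, "n_patients", dpn@nPatients)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    hdr <- sprintf("# dpn level=%d n_patients=%d", dpn@level, dpn@nPatients)
    nf <- paste0(path, "_nodes.csv"); ef <- paste0(path, "_edges.csv")
    writeLines(c(hdr, "i,Pi",
                 sprintf("%s,%d", dpn@nodes$code, dpn@nodes$Pi)), nf)
    writeLines(c(hdr, "i,j,Cij",
                 if (nrow(dpn@edges))
                   sprintf("%s,%s,%d", dpn@edges$i, dpn@edges$j, dpn@edges$Cij)
                 else character(0)), ef)
  }
  invisible(path)
}

#' Read a DPN from disk
#'
#' @param path the path (or edge-list stem) given to [writeGraph].
#' @param format `"graphml"` or `"edgelist"`.
#' @return a [DPN-class] object.
#' @export
readGraph <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!"Pi" %in% igraph::vertex_attr_names(g)) {
      stop("schema error: GraphML lacks the vertex attribute 'Pi'", call. = FALSE)
    }
    if (igraph::ecount(g) > 0 && !"Cij" %in% igraph::edge_attr_names(g)) {
      stop("schema error: GraphML lacks the edge attribute 'Cij'", call. = FALSE)
    }
    el <- igraph::as_data_frame(g, what = "edges")
    vs <- igraph::as_data_frame(g, what = "vertices")
    lev <- igraph::graph_attr(g, "level")
    np <- igraph::graph_attr(g, "n_patients")
    DPN(level = lev, nPatients = np,
        nodes = data.frame(code = vs$name, Pi = vs$Pi),
        edges = if (nrow(el)) data.frame(i = el$from, j = el$to, Cij = el$Cij)
                else data.frame(i = character(0), j = character(0), Cij = integer(0)))
  } else {
    nf <- paste0(path, "_nodes.csv"); ef <- paste0(path, "_edges.csv")
    hdr <- readLines(nf, n = 1L)
    m <- regmatches(hdr, regexec("level=(\\d+) n_patients=(\\d+)", hdr))[[1]]
    if (length(m) != 3L) stop("schema error: missing dpn header in ", nf, call. = FALSE)
    nodes <- utils::read.csv(nf, comment.char = "#", colClasses = c("character", "integer"))
    edges <- utils::read.csv(ef, comment.char = "#",
                             colClasses = c("character", "character", "integer"))
    DPN(level = as.integer(m[2]), nPatients = as.integer(m[3]),
        nodes = data.frame(code = nodes$i, Pi = nodes$Pi), edges = edges)
  }
}
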