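#' Construct a directed network
#'
#' The basic container of the package: an ordered node set plus a set of
#' directed, optionally weighted edges. Node identifiers are opaque strings;
#' they are mapped to dense integer indices only at the matrix boundary
#' (see [adjacency_matrix()]). Self-loops are permitted; duplicate edges are
#' collapsed to a single edge with a warning (matching is structural, so
#' multiplicities carry no information).
#'
#' @param from,to character (or coercible) vectors of equal length giving the
#'   source and target node of each edge.
#' @param weight optional numeric vector of edge weights; defaults to 1.
#'   Weights are ignored by the matching module and used by the energy module.
#' @param nodes optional character vector of node identifiers; defaults to the
#'   identifiers appearing in `from`/`to`, in order of first appearance.
#'   Isolated nodes can only be represented by passing them here.
#' @return An object of class `directed_network` with fields `nodes`
#'   (character), `from`, `to` (integer indices into `nodes`) and `weight`.
#' @examples
#' net <- directed_network(c("a", "b"), c("b", "c"))
#' net$N # 3 nodes
#' @export
directed_network <- function(from = character(), to = character(),
                             weight = NULL, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("`from` and `to` must have the same length")
  }
  if (is.null(weight)) {
    weight <- rep(1, length(from))
  } else {
    weight <- as.numeric(weight)
    if (length(weight) != length(from)) {
      stop("`weight` must match the number of edges")
    }
    if (anyNA(weight)) stop("edge weights must be numeric and non-missing")
  }
  if (is.null(nodes)) {
    nodes <- unique(c(from, to))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node identifiers")
    missing <- setdiff(c(from, to), nodes)
    if (length(missing)) {
      stop("edge endpoints not in node set: ", paste(missing, collapse = ", "))
    }
  }
  fi <- match(from, nodes)
  ti <- match(to, nodes)
  key <- paste(fi, ti)
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    warning(sum(!keep), " duplicate edge(s) collapsed")
    fi <- fi[keep]
    ti <- ti[keep]
    weight <- weight[keep]
  }
  structure(
    list(nodes = nodes, from = fi, to = ti, weight = weight,
         N = length(nodes), L = length(fi)),
    class = "directed_network"
  )
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> N = %d nodes, L = %d edges, mean degree = %.3f\n",
              x$N, x$L, mean_degree(x)))
  invisible(x)
}

#' Mean degree of a directed network
#'
#' Defined as L/N (edges per node); equals both the mean in-degree and the
#' mean out-degree.
#' @param net a `directed_network`.
#' @return a scalar; `NaN` for the empty network.
#' @export
mean_degree <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  net$L / net$N
}

#' Edge list of a network as a data frame
#'
#' @param net a `directed_network`.
#' @return data frame with columns `from`, `to` (node labels) and `weight`.
#' @export
edge_list <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  data.frame(from = net$nodes[net$from], to = net$nodes[net$to],
             weight = net$weight, stringsAsFactors = FALSE)
}

#' Read a directed network from a whitespace-delimited edge list
#'
#' Each non-comment line holds `source target [weight]`; lines starting with
#' `#` are ignored. Node identifiers are preserved verbatim. Duplicate edges
#' are collapsed with a warning.
#'
#' @param path path to the file.
#' @param directed must be `TRUE`; undirected networks are not supported.
#' @return a [directed_network()].
#' @export
read_edge_list <- function(path, directed = TRUE) {
  if (!isTRUE(directed)) stop("undirected networks are not supported")
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(directed_network())
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop(sprintf("malformed edge list at line %d: expected 2 or 3 fields, got %d",
                 lineno[bad[1]], nf[bad[1]]))
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  weight <- rep(1, length(parts))
  has_w <- nf == 3L
  if (any(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(parts[has_w], `[[`, "", 3L)))
    if (anyNA(w)) {
      bad <- lineno[has_w][which(is.na(w))[1]]
      stop(sprintf("non-numeric weight at line %d", bad))
    }
    weight[has_w] <- w
  }
  directed_network(from, to, weight)
}

#' Write a network as an edge list
#'
#' Inverse of [read_edge_list()] up to node ordering.
#' @param net a `directed_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  el <- edge_list(net)
  lines <- sprintf("%s\t%s\t%.17g", el$from, el$to, el$weight)
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed network from a GraphML file
#'
#' Minimal read-only import: `<node id=...>` elements define the node set,
#' `<edge source=... target=...>` the edges; an edge `<data>` entry whose key
#' is declared with `attr.name="weight"` is used as the edge weight.
#'
#' @param path path to the GraphML file.
#' @return a [directed_network()].
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  wkey <- NULL
  if (length(keys)) {
    nm <- xml2::xml_attr(keys, "attr.name")
    dom <- xml2::xml_attr(keys, "for")
    hit <- which(nm == "weight" & (is.na(dom) | dom == "edge"))
    if (length(hit)) wkey <- xml2::xml_attr(keys[[hit[1]]], "id")
  }
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//graph/node"), "id")
  edges <- xml2::xml_find_all(doc, ".//graph/edge")
  from <- xml2::xml_attr(edges, "source")
  to <- xml2::xml_attr(edges, "target")
  weight <- rep(1, length(edges))
  if (!is.null(wkey) && length(edges)) {
    w <- vapply(edges, function(e) {
      d <- xml2::xml_find_first(e, sprintf("./data[@key='%s']", wkey))
      if (inherits(d, "xml_missing")) NA_real_ else as.numeric(xml2::xml_text(d))
    }, numeric(1))
    weight[!is.na(w)] <- w[!is.na(w)]
  }
  directed_network(from, to, weight, nodes = nodes)
}

#' Weighted adjacency matrix of a network
#'
#' Returns the matrix `A` that acts on the state in the linear dynamics
#' `dx/dt = A x + B u`. The package convention is that an edge `i -> j` with
#' weight `w` is stored at row `j`, column `i` of `A`: row `j` collects the
#' influences flowing *into* node `j`, as required when rows index state
#' equations.
#'
#' @param net a `directed_network`.
#' @param sparse return a sparse `Matrix` (default) or a dense base matrix.
#' @return an `N x N` matrix with `dimnames` equal to the node labels.
#' @export
adjacency_matrix <- function(net, sparse = TRUE) {
  stopifnot(inherits(net, "directed_network"))
  A <- Matrix::sparseMatrix(i = net$to, j = net$from, x = net$weight,
                            dims = c(net$N, net$N),
                            dimnames = list(net$nodes, net$nodes))
  if (sparse) A else as.matrix(A)
}

#' Rebuild a network from an adjacency matrix
#'
#' Inverse of [adjacency_matrix()] under the same orientation convention
#' (`A[j, i]` nonzero means an edge `i -> j`).
#' @param A a square (possibly sparse) matrix.
#' @param nodes optional node labels; defaults to `dimnames` or `1..N`.
#' @return a [directed_network()].
#' @export
network_from_adjacency <- function(A, nodes = NULL) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                   "TsparseMatrix")
  n <- nrow(A)
  if (n != ncol(A)) stop("adjacency matrix must be square")
  if (is.null(nodes)) nodes <- rownames(A) %||% as.character(seq_len(n))
  directed_network(from = nodes[A@j + 1L], to = nodes[A@i + 1L],
                   weight = A@x, nodes = nodes)
}

#' Write the adjacency matrix in Matrix Market format
#'
#' @param net a `directed_network`; must be non-empty.
#' @param path output path (conventionally `.mtx`).
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  if (net$N == 0) stop("cannot write an empty network")
  Matrix::writeMM(methods::as(adjacency_matrix(net), "CsparseMatrix"), path)
  invisible(path)
}

#' Read a matrix from a Matrix Market file
#'
#' Thin wrapper over [Matrix::readMM()] returning a general sparse matrix;
#' used for adjacency and input matrices.
#' @param path path to a `.mtx` file.
#' @return a sparse `Matrix`.
#' @export
read_matrix_market <- function(path) {
  m <- Matrix::readMM(path)
  # pattern files (written for unit-weight matrices) come back logical
  methods::as(1 * m, "CsparseMatrix")
}

#' Degree bookkeeping, including unmatched (u-) degrees
#'
#' For every node reports its in- and out-degree and, optionally, the
#' u-degrees used by the local-game matching protocol: the u-input degree of a
#' node is the number of its parent neighbours that are still unmatched as
#' parents (have no fixed child), and the u-output degree is the number of its
#' child neighbours still unmatched as children (no fixed parent). Without a
#' match state every neighbour is unmatched, so the u-degrees equal the plain
#' degrees.
#'
#' @param net a `directed_network`.
#' @param lm optionally, an [lm_match()] result whose final match state
#'   defines which neighbours count as unmatched.
#' @return data frame with columns `node`, `in_degree`, `out_degree`,
#'   `u_in`, `u_out`.
#' @export
degree_view <- function(net, lm = NULL) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$N
  din <- tabulate(net$to, n)
  dout <- tabulate(net$from, n)
  if (is.null(lm)) {
    avail_parent <- rep(TRUE, n) # no fixed child yet
    avail_child <- rep(TRUE, n)  # no fixed parent yet
  } else {
    stopifnot(inherits(lm, "lm_result"))
    avail_parent <- is.na(lm$child_of[net$nodes])
    avail_child <- is.na(lm$parent_of[net$nodes])
  }
  u_in <- tabulate(net$to[avail_parent[net$from]], n)
  u_out <- tabulate(net$from[avail_child[net$to]], n)
  data.frame(node = net$nodes, in_degree = din, out_degree = dout,
             u_in = u_in, u_out = u_out, stringsAsFactors = FALSE)
}

# internal: igraph view of the network (used by the MM oracle)
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    edge_list(net)[c("from", "to")],
    directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}
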