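# Reading, writing and validating undirected simple graphs.
#
# Graphs are igraph objects whose vertices carry character names (the node
# ids given in the input, preserved verbatim). Vertices are kept in a
# canonical order: numeric if every id parses as a number, lexicographic
# otherwise, so that all reported matrices and rankings are reproducible.

# order() permutation putting node ids in canonical (numeric-aware) order
.id_order <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) order(num) else order(ids, method = "radix")
}

# reorder vertices of g into canonical id order
.canonical_graph <- function(g) {
  ord <- .id_order(igraph::V(g)$name)
  perm <- integer(length(ord))
  perm[ord] <- seq_along(ord)
  igraph::permute(g, perm)
}

#' Node identifiers in canonical order
#'
#' @param g an undirected graph as returned by the readers or generators.
#' @return Character vector of node ids, numerically sorted when every id is
#'   numeric, lexicographically otherwise.
#' @export
node_ids <- function(g) {
  stopifnot(igraph::is_igraph(g))
  igraph::V(g)$name
}

.check_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("expected an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("graph must be undirected", call. = FALSE)
  if (any(igraph::which_loop(g))) stop("graph must be simple (no self-loops)", call. = FALSE)
  if (any(igraph::which_multiple(g))) stop("graph must be simple (no multi-edges)", call. = FALSE)
  invisible(g)
}

.check_node <- function(g, node) {
  node <- as.character(node)
  if (!(node %in% igraph::V(g)$name)) {
    stop("unknown node id: ", node, call. = FALSE)
  }
  node
}

#' Read an undirected graph from an edge list
#'
#' One edge per line, two whitespace- or comma-separated node ids; lines
#' starting with `#` and blank lines are ignored. Duplicate lines and
#' reversed duplicates collapse to a single undirected edge.
#'
#' @param source path to a file, or a character vector of lines.
#' @param delimiter optional explicit field delimiter; by default any run of
#'   whitespace and/or commas separates the two tokens.
#' @param strict if `TRUE`, a self-loop line is an error; if `FALSE`
#'   (default) self-loops are dropped.
#' @return An undirected simple igraph with named vertices.
#' @examples
#' g <- read_edgelist(c("a b", "b c", "c a"))
#' igraph::gsize(g)
#' @export
read_edgelist <- function(source, delimiter = NULL, strict = FALSE) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  split_re <- if (is.null(delimiter)) "[,[:space:]]+" else delimiter
  ends <- matrix(character(0), ncol = 2)
  if (length(idx)) {
    toks <- strsplit(trimws(lines[idx]), split_re)
    nt <- lengths(toks)
    if (any(nt != 2L)) {
      bad <- idx[which(nt != 2L)[1L]]
      stop("malformed edge list line ", bad, ": ", sQuote(trimws(lines[bad])),
           " (expected two node ids)", call. = FALSE)
    }
    ends <- do.call(rbind, toks)
    loops <- ends[, 1] == ends[, 2]
    if (any(loops)) {
      if (strict) {
        stop("self-loop at line ", idx[which(loops)[1L]], ": ",
             sQuote(trimws(lines[idx[which(loops)[1L]]])), call. = FALSE)
      }
      ends <- ends[!loops, , drop = FALSE]
    }
  }
  if (nrow(ends) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  .canonical_graph(g)
}

#' Read an undirected graph from a dense 0/1 adjacency matrix
#'
#' @param source path to a whitespace- or comma-separated text matrix, or a
#'   numeric matrix. Must be square, symmetric, with zero diagonal and
#'   entries in \{0, 1\}.
#' @param node_names optional node ids; defaults to row names, else
#'   `"1" ... "n"`.
#' @return An undirected simple igraph with named vertices.
#' @export
read_adjacency_matrix <- function(source, node_names = NULL) {
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    txt <- readLines(source, warn = FALSE)
    txt <- txt[!grepl("^\\s*(#|$)", txt)]
    rows <- strsplit(trimws(txt), "[,[:space:]]+")
    a <- suppressWarnings(do.call(rbind, lapply(rows, as.numeric)))
  } else {
    a <- as.matrix(source)
    storage.mode(a) <- "double"
  }
  if (anyNA(a)) stop("adjacency matrix contains non-numeric entries", call. = FALSE)
  if (nrow(a) != ncol(a)) stop("adjacency matrix must be square", call. = FALSE)
  if (!all(a %in% c(0, 1))) stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (!isTRUE(all.equal(a, t(a)))) {
    stop("adjacency matrix must be symmetric (undirected graph)", call. = FALSE)
  }
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero (simple graph)", call. = FALSE)
  if (is.null(node_names)) {
    node_names <- rownames(a)
    if (is.null(node_names)) node_names <- as.character(seq_len(nrow(a)))
  }
  dimnames(a) <- list(node_names, node_names)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  .canonical_graph(g)
}

#' Write a graph as an edge list
#'
#' The output is stable: nodes in canonical order, each edge written once
#' with its smaller endpoint first, so that writing and re-reading
#' round-trips bit-exactly.
#'
#' @param g graph to write.
#' @param path output file path; the lines are also returned invisibly.
#' @param delimiter field separator, default a single space.
#' @export
write_edgelist <- function(g, path, delimiter = " ") {
  .check_graph(g)
  g <- .canonical_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  nm <- igraph::V(g)$name
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  lines <- paste(nm[el[, 1]], nm[el[, 2]], sep = delimiter)
  writeLines(lines, path)
  invisible(lines)
}

#' Write a graph as a dense 0/1 adjacency matrix
#'
#' Rows follow canonical node order; values are space-separated 0/1.
#'
#' @inheritParams write_edgelist
#' @export
write_adjacency_matrix <- function(g, path) {
  .check_graph(g)
  g <- .canonical_graph(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  lines <- apply(a, 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(lines)
}

#' Adjacency matrix in canonical node order
#'
#' @param g graph.
#' @return Dense symmetric 0/1 matrix with node ids as dimnames.
#' @export
adjacency_matrix <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  as.matrix(igraph::as_adjacency_matrix(g))
}
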