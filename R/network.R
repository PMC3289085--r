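# Weighted PPI graph construction: topology weights, combined edge weights,
# vertex weights and the seed queue.

#' Read a PPI edge list
#'
#' Reads a 2+ column whitespace- or tab-separated edge list into an
#' undirected simple graph. Self-loops are dropped and duplicate pairs
#' (in either orientation) collapsed, with counts kept as attributes. An
#' optional third numeric column is retained as `input_weight` but ignored
#' unless explicitly trusted downstream.
#'
#' @param x Edge-list content: file path, single string or character lines.
#'   Lines starting with `#` are comments.
#' @return An object of class `ppi_graph`: list with `vertices` (sorted
#'   character vector), `edges` (data.frame `u`, `v`, optionally
#'   `input_weight`), `n_self_loops`, `n_duplicates`.
#' @export
read_edge_list <- function(x) {
  lines <- as_lines(x)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_data("empty edge list")

  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop_data("edge-list line with fewer than 2 columns: '",
              lines[which(nf < 2L)[1L]], "'")
  }
  u <- vapply(fields, `[[`, "", 1L)
  v <- vapply(fields, `[[`, "", 2L)
  w <- vapply(fields, function(f) {
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else NA_real_
  }, 0)

  self <- u == v
  n_self <- sum(self)
  u <- u[!self]; v <- v[!self]; w <- w[!self]
  if (length(u) == 0L) stop_data("no usable edges after dropping self-loops")

  a <- ifelse(u < v, u, v)
  b <- ifelse(u < v, v, u)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- data.frame(u = a[!dup], v = b[!dup], stringsAsFactors = FALSE)
  if (any(!is.na(w))) edges$input_weight <- w[!dup]
  ord <- radix_order(edges$u, edges$v)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL

  structure(
    list(vertices = sort(unique(c(edges$u, edges$v)), method = "radix"),
         edges = edges, n_self_loops = n_self, n_duplicates = n_dup),
    class = "ppi_graph"
  )
}

# Named list: vertex -> character vector of neighbours.
neighbour_sets <- function(edges, vertices) {
  nb <- split(c(edges$v, edges$u), c(edges$u, edges$v))
  out <- vector("list", length(vertices))
  names(out) <- vertices
  for (v in names(nb)) out[[v]] <- nb[[v]]
  out
}

#' Topology weight of an edge
#'
#' The number of neighbours shared by the two endpoints of an edge
#' (excluding the endpoints themselves).
#'
#' @param u,v Endpoints of an existing edge.
#' @param graph A `ppi_graph` or `oiip_network`.
#' @return Non-negative integer count.
#' @export
topology_weight <- function(u, v, graph) {
  edges <- graph$edges
  a <- min(u, v); b <- max(u, v)
  if (!any(edges$u == a & edges$v == b)) {
    stop_data("no edge between ", u, " and ", v)
  }
  nb <- neighbour_sets(edges, graph$vertices)
  length(setdiff(intersect(nb[[u]], nb[[v]]), c(u, v)))
}

#' Assign semantic + topology weights to a PPI graph
#'
#' Each edge receives `s_sem` (GO semantic similarity of its endpoints;
#' 0 when no annotation index is supplied or an endpoint is unannotated),
#' `topo` (shared-neighbour count) and `total = s_sem + topo`. Vertex
#' weights are the sums of incident edge totals.
#'
#' @param graph A `ppi_graph` from [read_edge_list()].
#' @param index Optional `annotation_index`; `NULL` means all `s_sem = 0`.
#' @param scheme Optional similarity scheme passed to
#'   [semantic_similarity()].
#' @param normalize_topo Logical; divide topology weights by the graph-wide
#'   maximum shared-neighbour count so they lie in `[0, 1]`. Default `FALSE`
#'   (raw counts are summed with `s_sem` unscaled).
#' @param trust_input_weights Logical; if `TRUE` and the edge list carried a
#'   third numeric column, use it directly as `total` (with `s_sem` and
#'   `topo` set to zero). For evaluation-only workflows.
#' @return An object of class `oiip_network`: list with `vertices`, `edges`
#'   (`u`, `v`, `s_sem`, `topo`, `total`), `adj` (vertex -> named numeric of
#'   neighbour total weights), `vertex_weight` and `degree`.
#' @export
assign_edge_weights <- function(graph, index = NULL, scheme = NULL,
                                normalize_topo = FALSE,
                                trust_input_weights = FALSE) {
  edges <- graph$edges
  if (nrow(edges) == 0L) stop_data("graph has no edges")

  if (isTRUE(trust_input_weights)) {
    if (is.null(edges$input_weight) || anyNA(edges$input_weight)) {
      stop_data("--trust-input-weights requires a numeric third column")
    }
    s_sem <- numeric(nrow(edges))
    topo <- numeric(nrow(edges))
    total <- edges$input_weight
  } else {
    nb <- neighbour_sets(edges, graph$vertices)
    topo <- mapply(function(a, b) {
      length(setdiff(intersect(nb[[a]], nb[[b]]), c(a, b)))
    }, edges$u, edges$v, USE.NAMES = FALSE)
    if (isTRUE(normalize_topo) && max(topo) > 0) topo <- topo / max(topo)
    s_sem <- if (is.null(index)) {
      numeric(nrow(edges))
    } else {
      mapply(semantic_similarity, edges$u, edges$v,
             MoreArgs = list(index = index, scheme = scheme),
             USE.NAMES = FALSE)
    }
    total <- s_sem + topo
  }

  wedges <- data.frame(u = edges$u, v = edges$v, s_sem = s_sem,
                       topo = topo, total = total, stringsAsFactors = FALSE)

  adj <- build_adjacency(wedges, graph$vertices)
  vw <- vapply(adj, sum, 0)
  deg <- vapply(adj, length, 1L)

  structure(
    list(vertices = graph$vertices, edges = wedges, adj = adj,
         vertex_weight = vw, degree = deg),
    class = "oiip_network"
  )
}

build_adjacency <- function(wedges, vertices) {
  adj <- vector("list", length(vertices))
  names(adj) <- vertices
  for (v in vertices) adj[[v]] <- numeric(0)
  ends <- c(wedges$u, wedges$v)
  other <- c(wedges$v, wedges$u)
  w <- c(wedges$total, wedges$total)
  idx <- split(seq_along(ends), ends)
  for (v in names(idx)) {
    i <- idx[[v]]
    nbw <- w[i]
    names(nbw) <- other[i]
    adj[[v]] <- nbw[radix_order(names(nbw))]
  }
  adj
}

#' @export
print.oiip_network <- function(x, ...) {
  cat("Weighted PPI network:", length(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  cat("  total edge weight:", format(sum(x$edges$total)), "\n")
  invisible(x)
}

#' Build the seed queue Sq
#'
#' Sorts the vertices of a weighted network non-increasingly by vertex
#' weight; within equal weight, non-increasingly by degree; within equal
#' degree, by ascending identifier (a deterministic final tie-break).
#'
#' @param network An `oiip_network` from [assign_edge_weights()].
#' @return Character vector of vertex ids, class `seed_queue`.
#' @export
build_seed_queue <- function(network) {
  v <- network$vertices
  ord <- radix_order(-network$vertex_weight[v], -network$degree[v], v)
  structure(v[ord], class = "seed_queue")
}

#' Write a weighted edge table
#'
#' Serialises an `oiip_network`'s edges as a TSV with columns
#' `u, v, s_sem, topo, total`.
#'
#' @param network An `oiip_network`.
#' @param path Output file path.
#' @export
write_weighted_edges <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
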