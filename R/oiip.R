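# The OIIP clustering algorithm: seed selection from the weighted vertex
# queue, then greedy cluster extension by interaction probability under a
# diameter bound.

#' OIIP clustering parameters
#'
#' @param t_in Admission threshold on the interaction probability `E_vk`,
#'   in `[0, 1]`. Default 0.4.
#' @param d Positive integer bound on the induced-subgraph diameter of a
#'   growing cluster (`Inf` allowed to disable). Default 2.
#' @param min_size Minimum size of a reported cluster. Default 2.
#' @return Object of class `oiip_params`.
#' @export
oiip_params <- function(t_in = 0.4, d = 2, min_size = 2) {
  if (!is.numeric(t_in) || length(t_in) != 1L || is.na(t_in) ||
      t_in < 0 || t_in > 1) {
    stop_usage("t_in must be a single number in [0, 1]")
  }
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1 ||
      (is.finite(d) && d != floor(d))) {
    stop_usage("d must be a positive integer (or Inf)")
  }
  if (!is.numeric(min_size) || length(min_size) != 1L || is.na(min_size) ||
      min_size < 1 || min_size != floor(min_size)) {
    stop_usage("min_size must be a positive integer")
  }
  structure(list(t_in = t_in, d = d, min_size = as.integer(min_size)),
            class = "oiip_params")
}

# Sum of edge weights inside the subgraph induced by `members`.
internal_weight <- function(members, adj) {
  w <- 0
  for (m in members) {
    nb <- adj[[m]]
    w <- w + sum(nb[names(nb) %in% members])
  }
  w / 2
}

#' Interaction probability of a vertex with respect to a cluster
#'
#' `E_vk = e_vk / w_k`, where `e_vk` is the total weight of edges between
#' vertex `v` and the members of cluster `K`, and `w_k` is the total weight
#' of edges inside `K`. Not bounded above by 1.
#'
#' @param v A vertex not in `members`.
#' @param members Character vector: the members of `K` (at least 2, with
#'   positive internal weight).
#' @param network An `oiip_network`.
#' @return Non-negative numeric.
#' @export
interaction_probability <- function(v, members, network) {
  if (v %in% members) stop_data("vertex ", v, " is already in the cluster")
  if (is.null(network$adj[[v]])) stop_data("unknown vertex: ", v)
  w_k <- internal_weight(members, network$adj)
  if (w_k <= 0) {
    stop_data("E_vk undefined: cluster has internal weight 0 (size ",
              length(members), ")")
  }
  nb <- network$adj[[v]]
  sum(nb[names(nb) %in% members]) / w_k
}

#' Diameter of an induced subgraph
#'
#' Maximum over vertex pairs of the unweighted shortest-path length within
#' the subgraph induced by `members`; `Inf` if the subgraph is disconnected.
#' A single vertex has diameter 0.
#'
#' @param members Non-empty character vector of vertices.
#' @param network An `oiip_network` (or any object with an `adj` field).
#' @return Hop count, possibly `Inf`.
#' @export
induced_diameter <- function(members, network) {
  if (length(members) == 0L) stop_data("empty member set")
  if (length(members) == 1L) return(0)
  dmax <- 0
  for (s in members[-length(members)]) {
    ecc <- bfs_ecc(s, members, network$adj)
    if (is.infinite(ecc)) return(Inf)
    dmax <- max(dmax, ecc)
  }
  dmax
}

# Eccentricity of `s` within the subgraph induced by `members` (BFS over the
# adjacency restricted to members); Inf if some member is unreachable.
bfs_ecc <- function(s, members, adj) {
  dist <- rep(Inf, length(members))
  names(dist) <- members
  dist[s] <- 0
  frontier <- s
  depth <- 0
  while (length(frontier)) {
    depth <- depth + 1
    nxt <- character(0)
    for (u in frontier) {
      nb <- names(adj[[u]])
      nb <- nb[nb %in% members]
      new <- nb[is.infinite(dist[nb])]
      if (length(new)) {
        dist[new] <- depth
        nxt <- c(nxt, new)
      }
    }
    frontier <- nxt
  }
  max(dist)
}

#' Admission test for cluster extension
#'
#' A candidate vertex `v` adjacent to cluster `K` is admitted iff
#' (1) its interaction probability `E_vk` is at least `t_in`, and
#' (2) the subgraph induced by `K + v` has diameter at most `d`.
#'
#' @param v Candidate vertex, not in `members`.
#' @param members Current cluster members (size at least 2).
#' @param network An `oiip_network`.
#' @param params An `oiip_params`.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
extend_judgment <- function(v, members, network, params) {
  e <- interaction_probability(v, members, network)
  if (!isTRUE(e >= params$t_in)) return(FALSE)
  induced_diameter(c(members, v), network) <= params$d
}

#' Grow one cluster from a seed
#'
#' Starting from the seed alone, repeatedly ranks the external neighbours of
#' the cluster by interaction probability (ties: larger edge weight into the
#' cluster, then ascending id) and admits the highest-priority neighbour
#' passing [extend_judgment()]; the cluster state is updated after every
#' admission. Stops when no neighbour passes. Because the internal weight of
#' a bare seed is zero, the first admission is a bootstrap: the neighbour
#' with the heaviest edge to the seed joins unconditionally (diameter 1) and
#' is logged with `e_vk = NA`.
#'
#' @param seed A vertex of the network.
#' @param network An `oiip_network`.
#' @param params An `oiip_params`.
#' @return Object of class `oiip_cluster`: list with `members` (in admission
#'   order, seed first), `seed`, and `admission_log` (data.frame `vertex`,
#'   `e_vk`).
#' @export
extend_cluster <- function(seed, network, params = oiip_params()) {
  adj <- network$adj
  if (is.null(adj[[seed]])) stop_data("unknown seed vertex: ", seed)

  log_vertex <- seed
  log_e <- NA_real_
  members <- seed
  nb <- adj[[seed]]
  if (length(nb) == 0L) {
    return(new_cluster(members, seed, log_vertex, log_e, params))
  }

  # bootstrap admission: heaviest edge to the seed, ties by ascending id
  first <- names(nb)[radix_order(-nb, names(nb))][1L]
  members <- c(members, first)
  w_k <- nb[[first]]
  log_vertex <- c(log_vertex, first)
  log_e <- c(log_e, NA_real_)

  # external frontier: candidate -> summed edge weight into the cluster
  e_ext <- numeric(0)
  for (m in members) {
    mn <- adj[[m]]
    mn <- mn[!(names(mn) %in% members)]
    for (i in seq_along(mn)) {
      n <- names(mn)[i]
      e_ext[n] <- (if (n %in% names(e_ext)) e_ext[[n]] else 0) + mn[[i]]
    }
  }

  repeat {
    if (length(e_ext) == 0L) break
    evk <- e_ext / w_k   # NaN/Inf when w_k == 0: fails the threshold test
    ord <- radix_order(-evk, -e_ext, names(e_ext))
    admitted <- NA_character_
    for (i in ord) {
      if (!isTRUE(evk[[i]] >= params$t_in)) break  # sorted: none later passes
      v <- names(e_ext)[i]
      # K satisfies diam <= d by construction, and adding a vertex never
      # lengthens induced paths between existing members, so diam(K+v) <= d
      # iff v's eccentricity in K+v is <= d.
      if (bfs_ecc(v, c(members, v), adj) <= params$d) {
        admitted <- v
        log_vertex <- c(log_vertex, v)
        log_e <- c(log_e, evk[[i]])
        break
      }
    }
    if (is.na(admitted)) break
    members <- c(members, admitted)
    w_k <- w_k + e_ext[[admitted]]
    vn <- adj[[admitted]]
    e_ext <- e_ext[names(e_ext) != admitted]
    out <- vn[!(names(vn) %in% members)]
    for (i in seq_along(out)) {
      n <- names(out)[i]
      e_ext[n] <- (if (n %in% names(e_ext)) e_ext[[n]] else 0) + out[[i]]
    }
  }

  new_cluster(members, seed, log_vertex, log_e, params)
}

new_cluster <- function(members, seed, log_vertex, log_e, params) {
  structure(
    list(members = members, seed = seed,
         admission_log = data.frame(vertex = log_vertex, e_vk = log_e,
                                    stringsAsFactors = FALSE),
         params = params),
    class = "oiip_cluster"
  )
}

#' @export
print.oiip_cluster <- function(x, ...) {
  cat("Cluster of", length(x$members), "proteins (seed ", x$seed, "):\n  ",
      paste(x$members, collapse = " "), "\n")
  invisible(x)
}

#' Detect protein complexes with OIIP
#'
#' Runs the full clustering: builds the seed queue, grows a cluster from the
#' first queued vertex, removes that cluster's members from the queue (they
#' remain eligible to join later clusters, so clusters may overlap), and
#' repeats until the queue is empty. Exact duplicate member sets are
#' reported once; clusters below `min_size` are dropped from the report but
#' kept in the `dropped` field.
#'
#' @param network An `oiip_network`.
#' @param params An `oiip_params`.
#' @return Object of class `oiip_clusterset`: list with `clusters` (list of
#'   `oiip_cluster`), `params`, `dropped` (below `min_size`) and
#'   `n_duplicates`.
#' @export
oiip_cluster <- function(network, params = oiip_params()) {
  queue <- as.character(build_seed_queue(network))
  clusters <- list()
  dropped <- list()
  seen <- character(0)
  n_dup <- 0L

  while (length(queue)) {
    seed <- queue[1L]
    cl <- extend_cluster(seed, network, params)
    queue <- queue[!(queue %in% cl$members)]
    key <- paste(sort(cl$members, method = "radix"), collapse = "\r")
    if (key %in% seen) {
      n_dup <- n_dup + 1L
    } else {
      seen <- c(seen, key)
      if (length(cl$members) >= params$min_size) {
        clusters[[length(clusters) + 1L]] <- cl
      } else {
        dropped[[length(dropped) + 1L]] <- cl
      }
    }
  }

  structure(list(clusters = clusters, params = params, dropped = dropped,
                 n_duplicates = n_dup),
            class = "oiip_clusterset")
}

#' @export
print.oiip_clusterset <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 1L)
  cat("OIIP result: ", length(x$clusters), " clusters (t_in = ",
      x$params$t_in, ", d = ", x$params$d, ", min_size = ",
      x$params$min_size, ")\n", sep = "")
  if (length(sizes)) {
    cat("  sizes: min ", min(sizes), ", median ", stats::median(sizes),
        ", max ", max(sizes), "\n", sep = "")
  }
  invisible(x)
}

#' Member sets of a cluster set
#'
#' @param x An `oiip_clusterset`.
#' @return List of character vectors (one per reported cluster).
#' @export
cluster_members <- function(x) {
  lapply(x$clusters, `[[`, "members")
}

#' Sweep the admission threshold
#'
#' Reruns [oiip_cluster()] over a grid of `t_in` values on a fixed network,
#' summarising the number of reported clusters and the size of the largest
#' one — the standard way to inspect how the admission threshold shapes the
#' clustering.
#'
#' @param network An `oiip_network`.
#' @param t_in_grid Numeric vector of thresholds. Default `0.1 ... 0.9`.
#' @param d,min_size As in [oiip_params()].
#' @return data.frame with columns `t_in`, `n_clusters`, `max_size`, and the
#'   cluster sets as attribute `clustersets`.
#' @export
oiip_tin_sweep <- function(network, t_in_grid = seq(0.1, 0.9, by = 0.1),
                           d = 2, min_size = 2) {
  sets <- lapply(t_in_grid, function(t) {
    oiip_cluster(network, oiip_params(t_in = t, d = d, min_size = min_size))
  })
  res <- data.frame(
    t_in = t_in_grid,
    n_clusters = vapply(sets, function(s) length(s$clusters), 1L),
    max_size = vapply(sets, function(s) {
      if (length(s$clusters) == 0L) return(0L)
      max(vapply(s$clusters, function(cl) length(cl$members), 1L))
    }, 1L)
  )
  attr(res, "clustersets") <- sets
  res
}
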