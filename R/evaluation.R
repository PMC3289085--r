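# Scoring predicted complexes against a benchmark catalogue: neighbourhood
# affinity matching, clustering-wise Sn/PPV/Acc, and hypergeometric
# functional homogeneity.

#' Read a complex catalogue
#'
#' One complex per line, whitespace-separated protein ids (the CYC2008-style
#' plain-text layout). Empty complexes are dropped and duplicate member sets
#' removed.
#'
#' @param x File path, single string or character lines. `#` lines are
#'   comments.
#' @return List of character vectors (one per complex).
#' @export
read_complexes <- function(x) {
  lines <- as_lines(x)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cx <- lapply(strsplit(lines, "\\s+"), unique)
  cx <- cx[lengths(cx) > 0L]
  if (length(cx) == 0L) stop_data("no complexes in input")
  keys <- vapply(cx, function(m) paste(sort(m, method = "radix"), collapse = "\r"), "")
  cx[!duplicated(keys)]
}

#' Write a complex catalogue
#'
#' @param complexes List of character vectors, or an `oiip_clusterset`.
#' @param path Output file path (one complex per line, tab-separated).
#' @export
write_complexes <- function(complexes, path) {
  if (inherits(complexes, "oiip_clusterset")) {
    complexes <- cluster_members(complexes)
  }
  writeLines(vapply(complexes, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' Neighbourhood affinity between two complexes
#'
#' `NA(p, b) = |Vp ∩ Vb|^2 / (|Vp| · |Vb|)`: 1 iff the member sets are
#' identical, 0 iff disjoint.
#'
#' @param p_members,b_members Non-empty character vectors of protein ids
#'   (predicted and benchmark complex).
#' @return Score in `[0, 1]`.
#' @export
na_score <- function(p_members, b_members) {
  p <- unique(p_members); b <- unique(b_members)
  if (length(p) == 0L || length(b) == 0L) stop_data("empty complex in NA score")
  length(intersect(p, b))^2 / (length(p) * length(b))
}

#' Match predicted complexes to a benchmark
#'
#' A predicted complex `p` and a benchmark complex `b` match when
#' `NA(p, b) >= omega`.
#'
#' @param P,B Lists of character vectors (predicted / benchmark complexes).
#' @param omega Matching threshold in `(0, 1]`; 0.25 by convention
#'   (0.20 is also common).
#' @return List with `n_cp` (predicted complexes matching at least one
#'   benchmark complex), `n_cb` (benchmark complexes matched by at least one
#'   prediction) and `pairs` (data.frame `p`, `b`, `na` of matching index
#'   pairs).
#' @export
match_complexes <- function(P, B, omega = 0.25) {
  if (length(P) == 0L || length(B) == 0L) stop_data("empty complex list")
  if (!is.numeric(omega) || omega <= 0 || omega > 1) {
    stop_usage("omega must be in (0, 1]")
  }
  pi <- integer(0); bi <- integer(0); nav <- numeric(0)
  for (i in seq_along(P)) {
    for (j in seq_along(B)) {
      s <- na_score(P[[i]], B[[j]])
      if (s >= omega) {
        pi <- c(pi, i); bi <- c(bi, j); nav <- c(nav, s)
      }
    }
  }
  list(n_cp = length(unique(pi)), n_cb = length(unique(bi)),
       pairs = data.frame(p = pi, b = bi, na = nav))
}

#' Precision, recall and F-measure of complex prediction
#'
#' `precision = n_cp / |P|`, `recall = n_cb / |B|`, and their harmonic mean
#' `F = 2PR / (P + R)` (0 when both are 0).
#'
#' @param n_cp,n_cb Match counts from [match_complexes()].
#' @param n_predicted,n_benchmark Sizes of the predicted and benchmark sets.
#' @return List with `precision`, `recall`, `f_measure`.
#' @export
precision_recall_f <- function(n_cp, n_cb, n_predicted, n_benchmark) {
  if (n_predicted <= 0 || n_benchmark <= 0) {
    stop_data("need non-empty predicted and benchmark sets")
  }
  p <- n_cp / n_predicted
  r <- n_cb / n_benchmark
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f_measure = f)
}

#' Benchmark-by-prediction overlap matrix
#'
#' `T[i, j]` counts the proteins shared by benchmark complex `i` and
#' predicted complex `j`; `n_i` holds the benchmark complex sizes.
#'
#' @param B,P Lists of character vectors (benchmark, predicted).
#' @return Object of class `overlap_matrix`: list with integer matrix `t`
#'   and integer vector `n_i`.
#' @export
overlap_matrix <- function(B, P) {
  B <- lapply(B, unique); P <- lapply(P, unique)
  t <- matrix(0L, nrow = length(B), ncol = length(P))
  for (i in seq_along(B)) {
    for (j in seq_along(P)) {
      t[i, j] <- length(intersect(B[[i]], P[[j]]))
    }
  }
  structure(list(t = t, n_i = lengths(B)), class = "overlap_matrix")
}

#' Clustering-wise sensitivity, PPV and accuracy
#'
#' `Sn = sum_i max_j T_ij / sum_i N_i`;
#' `PPV = sum_j max_i T_ij / sum_j sum_i T_ij` (0 when the denominator is
#' 0); `Acc = sqrt(Sn * PPV)`.
#'
#' @param t An `overlap_matrix`, or a numeric matrix of overlap counts
#'   (benchmark rows, prediction columns).
#' @param n_i Benchmark complex sizes; required when `t` is a bare matrix.
#' @return List with `sn`, `ppv`, `acc`.
#' @export
sn_ppv_acc <- function(t, n_i = NULL) {
  if (inherits(t, "overlap_matrix")) {
    n_i <- t$n_i
    t <- t$t
  }
  if (is.null(n_i)) stop_usage("n_i required with a bare overlap matrix")
  if (length(n_i) != nrow(t)) stop_data("n_i length must match matrix rows")
  if (sum(n_i) <= 0) stop_data("benchmark sizes sum to zero")
  sn <- sum(apply(t, 1L, max)) / sum(n_i)
  tot <- sum(t)
  ppv <- if (tot == 0) 0 else sum(apply(t, 2L, max)) / tot
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability that a uniformly random cluster of `cluster_size` proteins
#' drawn from a network of `network_size` proteins contains at least `k`
#' members of a functional group of `group_size` proteins:
#' `P(X >= k)` for `X` hypergeometric.
#'
#' @param network_size Total proteins in the network (`|V|`).
#' @param group_size Proteins in the functional group (`|F|`).
#' @param cluster_size Proteins in the cluster (`|C|`).
#' @param k Observed overlap, `0 <= k <= min(group_size, cluster_size)`.
#' @return p-value in `(0, 1]`; `k = 0` gives 1.
#' @export
hypergeometric_pvalue <- function(network_size, group_size, cluster_size, k) {
  if (group_size > network_size || cluster_size > network_size ||
      k > min(group_size, cluster_size) || k < 0 ||
      group_size < 0 || cluster_size < 0) {
    stop_data("inconsistent counts for hypergeometric test")
  }
  stats::phyper(k - 1, group_size, network_size - group_size, cluster_size,
                lower.tail = FALSE)
}

#' Functional homogeneity of a cluster
#'
#' The smallest hypergeometric enrichment p-value of the cluster over all
#' functional groups (groups it shares at least one protein with). Ties go
#' to the lexicographically first group id.
#'
#' @param members Character vector: the cluster's proteins.
#' @param groups Named list: group id -> character vector of proteins.
#' @param network_size Total proteins in the network.
#' @return List with `p` (minimum p-value; 1 if the cluster overlaps no
#'   group) and `group` (winning group id, or `NA`).
#' @export
functional_homogeneity <- function(members, groups, network_size) {
  if (length(groups) == 0L) stop_data("no functional groups supplied")
  members <- unique(members)
  ids <- names(groups)
  if (is.null(ids) || any(!nzchar(ids))) stop_usage("groups must be named")
  ks <- vapply(groups, function(g) length(intersect(members, unique(g))), 1L)
  use <- which(ks >= 1L)
  if (length(use) == 0L) return(list(p = 1, group = NA_character_))
  ps <- vapply(use, function(i) {
    hypergeometric_pvalue(network_size, length(unique(groups[[i]])),
                          length(members), ks[[i]])
  }, 0)
  ord <- radix_order(ps, ids[use])
  list(p = ps[[ord[1L]]], group = ids[use][ord[1L]])
}

#' Fraction of functionally significant clusters
#'
#' The proportion of clusters whose functional homogeneity p-value falls
#' below `alpha` (raw p-values; no multiplicity correction).
#'
#' @param clusters List of character vectors, or an `oiip_clusterset`.
#' @param groups Named list of functional groups.
#' @param network_size Total proteins in the network.
#' @param alpha Significance threshold in `(0, 1)`; default 0.01.
#' @return Proportion in `[0, 1]`.
#' @export
significant_fraction <- function(clusters, groups, network_size, alpha = 0.01) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_usage("alpha must be in (0, 1)")
  }
  if (inherits(clusters, "oiip_clusterset")) {
    clusters <- cluster_members(clusters)
  }
  if (length(clusters) == 0L) return(0)
  ps <- vapply(clusters, function(m) {
    functional_homogeneity(m, groups, network_size)$p
  }, 0)
  mean(ps < alpha)
}

#' Functional groups from direct GO annotations
#'
#' Default functional grouping for enrichment: one group per directly
#' annotated GO term, containing the proteins annotated to it.
#'
#' @param direct Named list protein -> direct term ids (from [parse_gaf()]).
#' @return Named list term id -> character vector of proteins.
#' @export
groups_from_annotations <- function(direct) {
  if (length(direct) == 0L) stop_data("empty annotation map")
  prot <- rep(names(direct), lengths(direct))
  g <- split(prot, unlist(direct, use.names = FALSE))
  g <- lapply(g, function(p) sort(unique(p), method = "radix"))
  g[sort(names(g), method = "radix")]
}

#' Full evaluation of predicted complexes
#'
#' Combines neighbourhood-affinity matching (precision/recall/F) and the
#' overlap-matrix scores (Sn/PPV/Acc) into one report.
#'
#' @param P Predicted complexes: list of character vectors or an
#'   `oiip_clusterset`.
#' @param B Benchmark complexes: list of character vectors.
#' @param omega NA matching threshold; default 0.25.
#' @param min_benchmark_size Optional integer; if set, benchmark complexes
#'   smaller than this are excluded before scoring (e.g. 3 to count only
#'   known complexes of size > 2).
#' @return Object of class `match_report`: list with `n_predicted`,
#'   `n_benchmark`, `n_cp`, `n_cb`, `precision`, `recall`, `f_measure`,
#'   `sn`, `ppv`, `acc`, `omega`.
#' @export
evaluate_predictions <- function(P, B, omega = 0.25,
                                 min_benchmark_size = NULL) {
  if (inherits(P, "oiip_clusterset")) P <- cluster_members(P)
  if (!is.null(min_benchmark_size)) {
    B <- B[lengths(lapply(B, unique)) >= min_benchmark_size]
    if (length(B) == 0L) stop_data("no benchmark complexes pass the size filter")
  }
  m <- match_complexes(P, B, omega)
  prf <- precision_recall_f(m$n_cp, m$n_cb, length(P), length(B))
  spa <- sn_ppv_acc(overlap_matrix(B, P))
  structure(
    c(list(n_predicted = length(P), n_benchmark = length(B),
           n_cp = m$n_cp, n_cb = m$n_cb),
      prf, spa, list(omega = omega)),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat("Complex prediction report (omega = ", x$omega, ")\n", sep = "")
  cat(sprintf("  predicted: %d (matched %d)   benchmark: %d (matched %d)\n",
              x$n_predicted, x$n_cp, x$n_benchmark, x$n_cb))
  cat(sprintf("  precision %.4f  recall %.4f  F %.4f\n",
              x$precision, x$recall, x$f_measure))
  cat(sprintf("  Sn %.4f  PPV %.4f  Acc %.4f\n", x$sn, x$ppv, x$acc))
  invisible(x)
}
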