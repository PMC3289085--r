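# Shared toy inputs built in code: a 5-term GO DAG, its annotation index,
# and small graph builders.

toy_obo <- function() {
  paste(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process",
    "",
    "[Term]", "id: GO:0000002", "name: g1", "namespace: biological_process",
    "is_a: GO:0000001 ! root",
    "",
    "[Term]", "id: GO:0000003", "name: g2", "namespace: biological_process",
    "is_a: GO:0000001 ! root",
    "",
    "[Term]", "id: GO:0000004", "name: g3", "namespace: biological_process",
    "is_a: GO:0000002 ! g1",
    "",
    "[Term]", "id: GO:0000005", "name: g4", "namespace: biological_process",
    "is_a: GO:0000003 ! g2"
  ), collapse = "\n")
}

# P1, P2 direct on g3; P3 direct on g4.
toy_index <- function() {
  dag <- parse_obo(toy_obo())
  propagate_annotations(
    list(P1 = "GO:0000004", P2 = "GO:0000004", P3 = "GO:0000005"), dag)
}

gaf_line <- function(protein, term, qualifier = "", evidence = "IDA",
                     symbol = protein, ncol = 17L) {
  f <- c("TOY", protein, symbol, qualifier, term, "TOY_REF:1", evidence, "",
         "P", "", "", "protein", "taxon:1", "20110101", "TOY", "", "")
  paste(f[seq_len(ncol)], collapse = "\t")
}

# Weighted network from an edge list plus explicit per-edge totals, built
# through the public API (trusted third column).
weighted_net <- function(edge_text) {
  assign_edge_weights(read_edge_list(edge_text), trust_input_weights = TRUE)
}

# Unit-weight network: every edge total exactly 1.
unit_net <- function(pairs) {
  txt <- paste(vapply(pairs, function(p) paste(p[1], p[2], "1"), ""),
               collapse = "\n")
  weighted_net(txt)
}

two_triangles_bridge <- function() {
  # triangle a-b-c, bridge c-d, triangle d-e-f, all edge totals 1
  unit_net(list(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d"),
                c("d", "e"), c("d", "f"), c("e", "f")))
}

# Random Erdos-Renyi network with random positive edge weights, via the
# trusted-weights path. Guarantees at least one edge.
random_weighted_net <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- utils::combn(ids, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[sample.int(length(keep), 1L)] <- TRUE
  w <- round(stats::runif(sum(keep), 0.1, 3), 3)
  weighted_net(paste(pairs[1L, keep], pairs[2L, keep], w, collapse = "\n"))
}
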