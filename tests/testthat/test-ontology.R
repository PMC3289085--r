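test_that("OBO parsing captures terms, parentage and the obsolete rule", {
  minimal <- paste(c("[Term]", "id: GO:0000001", "name: root",
                     "namespace: biological_process", "",
                     "[Term]", "id: GO:0000002", "name: child",
                     "namespace: biological_process",
                     "is_a: GO:0000001 ! root"), collapse = "\n")
  dag <- parse_obo(minimal)
  expect_length(dag$terms, 2L)
  expect_equal(dag$terms[["GO:0000002"]]$parents, "GO:0000001")
  expect_equal(unname(dag$roots["biological_process"]), "GO:0000001")

  with_obsolete <- paste(minimal, "", "[Term]", "id: GO:0000009",
                         "name: gone", "namespace: biological_process",
                         "is_obsolete: true", sep = "\n")
  dag2 <- parse_obo(with_obsolete)
  expect_null(dag2$terms[["GO:0000009"]])
  expect_equal(dag2$n_obsolete, 1L)

  no_ns <- paste(minimal, "", "[Term]", "id: GO:0000010",
                 "name: nameless-space", sep = "\n")
  expect_warning(dag3 <- parse_obo(no_ns), "namespace")
  expect_null(dag3$terms[["GO:0000010"]])
})

test_that("ancestor closure on the 5-term toy DAG is the hand-traced set", {
  dag <- parse_obo(toy_obo())
  expect_setequal(term_ancestors(dag, "GO:0000004"),
                  c("GO:0000004", "GO:0000002", "GO:0000001"))
  expect_setequal(term_ancestors(dag, "GO:0000001"), "GO:0000001")
})

test_that("a cyclic ontology is rejected naming a cycle member", {
  cyc <- paste(c("[Term]", "id: GO:0000001", "name: a",
                 "namespace: biological_process", "is_a: GO:0000002", "",
                 "[Term]", "id: GO:0000002", "name: b",
                 "namespace: biological_process", "is_a: GO:0000001"),
               collapse = "\n")
  expect_error(parse_obo(cyc), "cycle.*GO:000000")
})

test_that("part_of edges count as parentage only when requested", {
  obo <- paste(c("[Term]", "id: GO:0000001", "name: root",
                 "namespace: cellular_component", "",
                 "[Term]", "id: GO:0000002", "name: part",
                 "namespace: cellular_component",
                 "relationship: part_of GO:0000001 ! root"), collapse = "\n")
  expect_warning(no_po <- parse_obo(obo), "parentless")  # both terms are roots
  expect_length(no_po$terms[["GO:0000002"]]$parents, 0L)
  expect_equal(parse_obo(obo, include_part_of = TRUE)$terms[["GO:0000002"]]$parents,
               "GO:0000001")
})

test_that("GAF parsing applies NOT, evidence, dag-membership and column rules", {
  dag <- parse_obo(toy_obo())
  one <- gaf_line("P1", "GO:0000004")
  expect_equal(parse_gaf(one, dag), list(P1 = "GO:0000004"),
               ignore_attr = TRUE)

  expect_error(parse_gaf(gaf_line("P1", "GO:0000004", qualifier = "NOT"), dag),
               "no usable")

  three <- paste(gaf_line("P1", "GO:0000004"), gaf_line("P2", "GO:0000004"),
                 gaf_line("P3", "GO:0000005"), sep = "\n")
  expect_length(parse_gaf(three, dag), 3L)

  mixed <- paste("!gaf-version: 2.1",
                 gaf_line("P1", "GO:0000004"),
                 gaf_line("P2", "GO:9999999"),         # unknown term
                 gaf_line("P3", "GO:0000005", ncol = 5),  # malformed
                 gaf_line("P4", "GO:0000005", evidence = "IEA"),
                 sep = "\n")
  expect_warning(expect_warning(
    res <- parse_gaf(mixed, dag, exclude_evidence = "IEA"),
    "absent"), "malformed")
  expect_named(res, "P1")
  expect_equal(attr(res, "n_skipped_term"), 1L)
  expect_equal(attr(res, "n_skipped_malformed"), 1L)
  expect_equal(attr(res, "n_skipped_evidence"), 1L)

  by_symbol <- parse_gaf(gaf_line("P1", "GO:0000004", symbol = "SYM1"), dag,
                         id_column = "symbol")
  expect_named(by_symbol, "SYM1")
})

test_that("annotation propagation yields the hand-traced transitive sets", {
  idx <- toy_index()
  expect_setequal(idx$term_proteins[["GO:0000004"]], c("P1", "P2"))
  expect_setequal(idx$term_proteins[["GO:0000002"]], c("P1", "P2"))
  expect_setequal(idx$term_proteins[["GO:0000005"]], "P3")
  expect_setequal(idx$term_proteins[["GO:0000001"]], c("P1", "P2", "P3"))
  expect_identical(idx$s_max, 3L)
  expect_setequal(idx$corpus, c("P1", "P2", "P3"))
})

test_that("propagation degenerate inputs behave as specified", {
  dag <- parse_obo(toy_obo())
  single <- propagate_annotations(list(P1 = "GO:0000001"), dag)
  expect_identical(single$s_max, 1L)
  expect_error(propagate_annotations(list(), dag), "corpus")
  expect_error(propagate_annotations(list(P1 = "GO:7777777"), dag), "absent")
})

test_that("common-annotation statistics match hand counts on the toy DAG", {
  idx <- toy_index()
  st <- common_annotation_stats("P1", "P2", idx)
  expect_identical(st$c_size, 3L)   # g3, g1, root
  expect_identical(st$m, 2L)        # |S(g3)|
  st2 <- common_annotation_stats("P1", "P3", idx)
  expect_identical(st2$c_size, 1L)  # root only
  expect_identical(st2$m, 3L)
  st3 <- common_annotation_stats("PX", "P1", idx)  # unannotated
  expect_identical(st3$c_size, 0L)
  expect_identical(st3$m, idx$s_max)
})

test_that("semantic similarity realises the stated boundary behaviour", {
  idx <- toy_index()
  expect_equal(semantic_similarity("P1", "P2", idx), 1 - log(2) / log(3))
  # sharing only the root (m = S_max) is non-informative
  expect_equal(semantic_similarity("P1", "P3", idx), 0)
  # most specific possible case: a term annotating a single protein
  expect_equal(semantic_similarity("P3", "P3", idx), 1)
  # unannotated protein scores 0 against everything
  expect_equal(semantic_similarity("PX", "P1", idx), 0)
})

test_that("similarity is undefined when every term annotates one protein", {
  dag <- parse_obo(toy_obo())
  idx <- propagate_annotations(list(P1 = "GO:0000001"), dag)
  expect_error(semantic_similarity("P1", "P1", idx), "S_max")
})

test_that("a custom similarity scheme is honoured", {
  idx <- toy_index()
  flat <- function(m, c_size, s_max) 0.5
  expect_equal(semantic_similarity("P1", "P2", idx, scheme = flat), 0.5)
})

test_that("similarity is symmetric and specificity-monotone on a random corpus", {
  bundle <- make_planted_network(
    fixture_spec(n_complexes = 4, complex_size_range = c(3, 5), p_in = 0.9,
                 p_out = 0.05, n_background_proteins = 6,
                 annotation_fidelity = 0.8, rng_seed = 11))
  dag <- parse_obo(bundle$obo)
  idx <- propagate_annotations(parse_gaf(bundle$gaf, dag), dag)
  prots <- idx$corpus
  set.seed(1)
  for (r in 1:50) {
    pair <- sample(prots, 2L)
    expect_identical(semantic_similarity(pair[1], pair[2], idx),
                     semantic_similarity(pair[2], pair[1], idx))
  }
  # decreasing m never decreases the default score
  scores <- vapply(seq_len(idx$s_max), oiip:::sem_scheme_default,
                   c_size = 1L, s_max = idx$s_max, 0)
  expect_true(all(diff(scores) <= 0))
  # a protein is always at least as specific alone as jointly with another
  for (r in 1:50) {
    pair <- sample(prots, 2L)
    m_x <- min(idx$term_size[idx$protein_terms[[pair[1]]]])
    m_xy <- common_annotation_stats(pair[1], pair[2], idx)$m
    expect_lte(m_x, m_xy)
  }
})

test_that("annotation sizes never shrink from child to parent", {
  bundle <- make_planted_network(
    fixture_spec(n_complexes = 3, complex_size_range = c(3, 4), p_in = 1,
                 p_out = 0.1, n_background_proteins = 4,
                 annotation_fidelity = 0.7, rng_seed = 5))
  dag <- parse_obo(bundle$obo)
  idx <- propagate_annotations(parse_gaf(bundle$gaf, dag), dag)
  for (id in names(idx$term_size)) {
    for (p in dag$terms[[id]]$parents) {
      expect_true(all(idx$term_proteins[[id]] %in% idx$term_proteins[[p]]))
    }
  }
  expect_identical(idx$s_max, max(idx$term_size))
  root_sizes <- idx$term_size[intersect(unname(dag$roots), names(idx$term_size))]
  expect_identical(max(root_sizes), idx$s_max)
})
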