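# Seeded generators of fully synthetic toy inputs: ontology, annotations,
# planted-complex networks and benchmark catalogues. Everything is text and
# round-trips through the package's own parsers, so the whole pipeline is
# testable with no external downloads.

#' Specification of a planted-complex fixture
#'
#' @param n_complexes Number of planted complexes.
#' @param complex_size_range Length-2 integer vector, minimum and maximum
#'   complex size (sizes are sampled uniformly); both at least 3.
#' @param p_in Within-complex edge probability.
#' @param p_out Background edge probability (between any pair not inside
#'   the same complex); must be strictly below `p_in`.
#' @param n_background_proteins Proteins outside every planted complex.
#' @param annotation_fidelity Probability that a complex member is annotated
#'   to its complex's dedicated GO term.
#' @param rng_seed Mandatory integer seed; the generator has no other source
#'   of randomness.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_complexes = 5, complex_size_range = c(4, 6),
                         p_in = 1, p_out = 0, n_background_proteins = 0,
                         annotation_fidelity = 1, rng_seed) {
  if (missing(rng_seed)) stop_usage("rng_seed is mandatory")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop_usage("need 0 <= p_out < p_in <= 1")
  }
  if (any(complex_size_range < 3) || length(complex_size_range) != 2L ||
      complex_size_range[1L] > complex_size_range[2L]) {
    stop_usage("complex sizes must be >= 3 with min <= max")
  }
  if (n_complexes < 1) stop_usage("need at least one complex")
  if (annotation_fidelity < 0 || annotation_fidelity > 1) {
    stop_usage("annotation_fidelity must be in [0, 1]")
  }
  structure(
    list(n_complexes = as.integer(n_complexes),
         complex_size_range = as.integer(complex_size_range),
         p_in = p_in, p_out = p_out,
         n_background_proteins = as.integer(n_background_proteins),
         annotation_fidelity = annotation_fidelity,
         rng_seed = as.integer(rng_seed)),
    class = "fixture_spec"
  )
}

# Yeast-ORF-like identifiers (Y + chromosome letter + arm + 3 digits + strand),
# purely for parser realism.
make_protein_ids <- function(n) {
  grid <- expand.grid(num = sprintf("%03d", 1:199),
                      arm = c("L", "R"),
                      chr = LETTERS[1:16],
                      strand = c("W", "C"),
                      stringsAsFactors = FALSE)
  ids <- paste0("Y", grid$chr, grid$arm, grid$num, grid$strand)
  if (n > length(ids)) stop_data("too many protein ids requested")
  sample(ids, n)
}

#' Generate a toy GO ontology in OBO format
#'
#' Builds one rooted DAG per requested namespace: terms are placed on levels
#' below the root, each with a parent on a shallower level, and a fraction
#' get a second parent (so the structure is a genuine DAG, not a tree).
#'
#' @param n_terms_per_namespace Terms per namespace including the root.
#' @param depth Number of levels (at least 2: root + one child level).
#' @param rng_seed Integer seed.
#' @param namespaces Character vector of GO namespaces to generate.
#' @return OBO text (single string).
#' @export
make_toy_ontology <- function(n_terms_per_namespace = 8, depth = 3, rng_seed,
                              namespaces = "biological_process") {
  if (missing(rng_seed)) stop_usage("rng_seed is mandatory")
  if (depth < 2) stop_usage("depth must be >= 2")
  if (n_terms_per_namespace < 2) stop_usage("need >= 2 terms per namespace")

  with_seed(rng_seed, {
    stanzas <- c("format-version: 1.2")
    term_no <- 0L
    for (ns in namespaces) {
      n <- n_terms_per_namespace
      ids <- sprintf("GO:%07d", term_no + seq_len(n))
      term_no <- term_no + n
      level <- c(0L, sort(sample(rep(seq_len(depth - 1L), length.out = n - 1L))))
      for (i in seq_len(n)) {
        st <- c("", "[Term]",
                paste0("id: ", ids[i]),
                paste0("name: toy term ", ids[i]),
                paste0("namespace: ", ns))
        if (level[i] > 0L) {
          shallower <- which(level < level[i])
          p1 <- sample(shallower, 1L)
          st <- c(st, paste0("is_a: ", ids[p1], " ! toy"))
          if (length(shallower) > 1L && stats::runif(1) < 0.3) {
            p2 <- sample(setdiff(shallower, p1), 1L)
            st <- c(st, paste0("is_a: ", ids[p2], " ! toy"))
          }
        }
        stanzas <- c(stanzas, st)
      }
    }
    paste(stanzas, collapse = "\n")
  })
}

gaf_row <- function(protein, term, aspect = "P") {
  paste(c("TOY", protein, protein, "", term, "TOY_REF:0000001", "IDA", "",
          aspect, paste0("toy protein ", protein), "", "protein",
          "taxon:559292", "20110101", "TOY", "", ""), collapse = "\t")
}

#' Generate a planted-complex fixture bundle
#'
#' Plants `n_complexes` disjoint protein groups, wires each internally as an
#' Erdős–Rényi graph at `p_in` (regenerated, up to a bounded number of
#' retries, if a group ends up with no internal edge), wires every
#' remaining protein pair at `p_out`, and annotates complex members to a
#' dedicated specific GO term with probability `annotation_fidelity`.
#' Background proteins are annotated to a shared background term. The
#' benchmark file equals the planted truth.
#'
#' @param spec A `fixture_spec`.
#' @return Object of class `fixture_bundle`: list with `obo`, `gaf`,
#'   `edges`, `benchmark` (text blocks), `truth` (list of member vectors)
#'   and `proteins`.
#' @export
make_planted_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$rng_seed, {
    size_choices <- seq(spec$complex_size_range[1L], spec$complex_size_range[2L])
    sizes <- size_choices[sample.int(length(size_choices), spec$n_complexes,
                                     replace = TRUE)]
    n_prot <- sum(sizes) + spec$n_background_proteins
    ids <- make_protein_ids(n_prot)
    truth <- split(ids[seq_len(sum(sizes))], rep(seq_along(sizes), sizes))
    truth <- lapply(truth, function(m) sort(m, method = "radix"))
    background <- ids[-seq_len(sum(sizes))]

    # ontology: one root, one dedicated term per complex, one background term
    root <- "GO:0000001"
    cx_terms <- sprintf("GO:%07d", 1L + seq_along(truth))
    bg_term <- sprintf("GO:%07d", 2L + length(truth))
    obo <- c("format-version: 1.2",
             "", "[Term]", paste0("id: ", root), "name: toy biological process root",
             "namespace: biological_process")
    for (t in c(cx_terms, bg_term)) {
      obo <- c(obo, "", "[Term]", paste0("id: ", t),
               paste0("name: toy process ", t),
               "namespace: biological_process",
               paste0("is_a: ", root, " ! toy biological process root"))
    }

    # edges: dense within complexes, sparse elsewhere
    edge_u <- character(0); edge_v <- character(0)
    for (ci in seq_along(truth)) {
      m <- truth[[ci]]
      pairs <- utils::combn(m, 2L)
      for (try in 1:100) {
        keep <- stats::runif(ncol(pairs)) < spec$p_in
        if (any(keep)) break
      }
      if (!any(keep)) stop_data("planted complex ", ci, " has no internal edge")
      edge_u <- c(edge_u, pairs[1L, keep]); edge_v <- c(edge_v, pairs[2L, keep])
    }
    if (spec$p_out > 0 && n_prot >= 2L) {
      cx_of <- rep(c(seq_along(truth), rep(NA_integer_, length(background))),
                   c(sizes, rep(1L, length(background))))
      names(cx_of) <- c(unlist(truth, use.names = FALSE), background)
      all_pairs <- utils::combn(ids, 2L)
      same <- !is.na(cx_of[all_pairs[1L, ]]) &
        cx_of[all_pairs[1L, ]] == cx_of[all_pairs[2L, ]]
      bg_pairs <- all_pairs[, !same, drop = FALSE]
      keep <- stats::runif(ncol(bg_pairs)) < spec$p_out
      edge_u <- c(edge_u, bg_pairs[1L, keep]); edge_v <- c(edge_v, bg_pairs[2L, keep])
    }
    ord <- radix_order(pmin(edge_u, edge_v), pmax(edge_u, edge_v))
    edges_txt <- paste(edge_u[ord], edge_v[ord], sep = "\t")

    # annotations
    gaf <- "!gaf-version: 2.1"
    for (ci in seq_along(truth)) {
      for (p in truth[[ci]]) {
        if (stats::runif(1) < spec$annotation_fidelity) {
          gaf <- c(gaf, gaf_row(p, cx_terms[ci]))
        } else {
          gaf <- c(gaf, gaf_row(p, root))
        }
      }
    }
    for (p in background) gaf <- c(gaf, gaf_row(p, bg_term))

    structure(
      list(obo = paste(obo, collapse = "\n"),
           gaf = paste(gaf, collapse = "\n"),
           edges = paste(edges_txt, collapse = "\n"),
           benchmark = paste(vapply(truth, paste, "", collapse = "\t"),
                             collapse = "\n"),
           truth = unname(truth),
           proteins = ids,
           spec = spec),
      class = "fixture_bundle"
    )
  })
}

#' Write a fixture bundle to disk
#'
#' Writes `ontology.obo`, `annotations.gaf`, `network.tsv` and
#' `benchmark.txt` into a directory.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Target directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(bundle$obo, file.path(dir, "ontology.obo"))
  writeLines(bundle$gaf, file.path(dir, "annotations.gaf"))
  writeLines(bundle$edges, file.path(dir, "network.tsv"))
  writeLines(bundle$benchmark, file.path(dir, "benchmark.txt"))
  invisible(dir)
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("Synthetic fixture:", length(x$truth), "planted complexes,",
      length(x$proteins), "proteins,",
      length(strsplit(x$edges, "\n", fixed = TRUE)[[1L]]), "edges\n")
  invisible(x)
}
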