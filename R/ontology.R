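# GO ontology structure, annotation propagation and semantic similarity.
#
# The similarity between two proteins is driven by the "annotation size" of
# the most specific GO term they share: the fewer proteins a common term
# annotates, the more specific the term and the more similar the proteins.

#' Parse a GO ontology in OBO format
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 document and returns a directed
#' acyclic graph of non-obsolete GO terms. Parentage is defined by `is_a`
#' edges; `part_of` relationships are included only on request.
#'
#' @param x OBO content: a file path, a single string, or a character vector
#'   of lines.
#' @param include_part_of Logical; if `TRUE`, `relationship: part_of` edges
#'   also count as parentage. Default `FALSE` (`is_a` only).
#' @param namespace Optional character vector restricting the DAG to the
#'   given GO namespaces (e.g. `"biological_process"`). Default: keep all.
#'
#' @return An object of class `go_dag`: a list with `terms` (named list of
#'   term records with fields `id`, `name`, `namespace`, `parents`),
#'   `roots` (named character vector, one root id per namespace) and
#'   `n_obsolete` / `n_rejected` bookkeeping counts.
#'
#' @details Obsolete terms are dropped and never influence any downstream
#'   computation. A term without a namespace is rejected with a warning.
#'   A cycle in the parentage relation is a hard error naming one of the
#'   terms on the cycle.
#'
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process", "",
#'          "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: biological_process", "is_a: GO:0000001 ! root")
#' dag <- parse_obo(obo)
#' dag$terms[["GO:0000002"]]$parents
#' @export
parse_obo <- function(x, include_part_of = FALSE, namespace = NULL) {
  lines <- as_lines(x)
  lines <- sub("\\s+$", "", lines)

  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) {
    stop_data("no [Term] stanzas found in OBO input")
  }
  section_starts <- grep("^\\[", lines)

  terms <- list()
  n_obsolete <- 0L
  n_rejected <- 0L

  for (s in stanza_starts) {
    after <- section_starts[section_starts > s]
    end <- if (length(after)) min(after) - 1L else length(lines)
    body <- lines[seq(s + 1L, length.out = max(0L, end - s))]
    body <- body[nzchar(body) & !startsWith(body, "!")]

    kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    keys <- vapply(kv, function(m) if (length(m) == 3L) m[2L] else NA_character_, "")
    vals <- vapply(kv, function(m) if (length(m) == 3L) m[3L] else NA_character_, "")
    ok <- !is.na(keys)
    keys <- keys[ok]; vals <- vals[ok]

    id <- vals[keys == "id"][1L]
    if (is.na(id) || !nzchar(id)) next
    if (any(keys == "is_obsolete" & vals == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    ns <- vals[keys == "namespace"][1L]
    if (is.na(ns) || !nzchar(ns)) {
      warning("term ", id, " has no namespace; rejected", call. = FALSE)
      n_rejected <- n_rejected + 1L
      next
    }
    parents <- sub("\\s*!.*$", "", vals[keys == "is_a"])
    if (isTRUE(include_part_of)) {
      rel <- vals[keys == "relationship"]
      po <- rel[startsWith(rel, "part_of")]
      po <- sub("\\s*!.*$", "", sub("^part_of\\s+", "", po))
      parents <- c(parents, po)
    }
    terms[[id]] <- list(
      id = id,
      name = vals[keys == "name"][1L],
      namespace = ns,
      parents = unique(parents[nzchar(parents)])
    )
  }

  if (!is.null(namespace)) {
    keep <- vapply(terms, function(t) t$namespace %in% namespace, TRUE)
    terms <- terms[keep]
  }
  if (length(terms) == 0L) stop_data("no usable GO terms after parsing")

  # drop parent references to terms not kept (obsolete / rejected / filtered)
  ids <- names(terms)
  dangling <- 0L
  for (id in ids) {
    p <- terms[[id]]$parents
    kept <- p[p %in% ids]
    dangling <- dangling + length(p) - length(kept)
    terms[[id]]$parents <- kept
  }
  if (dangling > 0L) {
    warning(dangling, " parent reference(s) to absent terms dropped", call. = FALSE)
  }

  dag <- structure(
    list(terms = terms, roots = character(0),
         n_obsolete = n_obsolete, n_rejected = n_rejected),
    class = "go_dag"
  )
  check_acyclic(dag)

  namespaces <- sort(unique(vapply(terms, `[[`, "", "namespace")))
  roots <- character(0)
  for (ns in namespaces) {
    cand <- ids[vapply(terms, function(t) {
      t$namespace == ns && length(t$parents) == 0L
    }, TRUE)]
    cand <- sort(cand, method = "radix")
    if (length(cand) > 1L) {
      warning("namespace ", ns, " has ", length(cand),
              " parentless terms; using ", cand[1L], " as root", call. = FALSE)
    }
    roots[ns] <- cand[1L]
  }
  dag$roots <- roots
  dag
}

# Depth-first cycle check over the is_a (+optional part_of) relation.
check_acyclic <- function(dag) {
  color <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  visit <- function(id) {
    st <- list(list(id = id, i = 0L))
    while (length(st)) {
      top <- st[[length(st)]]
      if (top$i == 0L) assign(top$id, 1L, envir = color)
      parents <- dag$terms[[top$id]]$parents
      if (top$i < length(parents)) {
        st[[length(st)]]$i <- top$i + 1L
        nxt <- parents[top$i + 1L]
        mark <- if (exists(nxt, envir = color)) get(nxt, envir = color) else 0L
        if (mark == 1L) {
          stop_data("cycle detected in ontology involving term ", nxt)
        }
        if (mark == 0L) st[[length(st) + 1L]] <- list(id = nxt, i = 0L)
      } else {
        assign(top$id, 2L, envir = color)
        st[[length(st)]] <- NULL
      }
    }
  }
  for (id in names(dag$terms)) {
    mark <- if (exists(id, envir = color)) get(id, envir = color) else 0L
    if (mark == 0L) visit(id)
  }
  invisible(TRUE)
}

#' @export
print.go_dag <- function(x, ...) {
  ns <- table(vapply(x$terms, `[[`, "", "namespace"))
  cat("GO DAG with", length(x$terms), "terms\n")
  for (n in names(ns)) cat("  ", n, ": ", ns[[n]], " (root ", x$roots[[n]], ")\n", sep = "")
  invisible(x)
}

# Ancestor closure of a term (including the term itself), memoised in `memo`.
term_closure <- function(dag, id, memo) {
  if (!is.null(memo[[id]])) return(memo[[id]])
  res <- id
  for (p in dag$terms[[id]]$parents) {
    res <- union(res, term_closure(dag, p, memo))
  }
  memo[[id]] <- res
  res
}

#' Ancestors of a GO term
#'
#' Returns the ancestor closure of a term — the term itself plus every term
#' reachable by following parentage edges up to the namespace root.
#'
#' @param dag A `go_dag` from [parse_obo()].
#' @param id A GO term accession present in `dag`.
#' @return Character vector of term ids (unordered).
#' @export
term_ancestors <- function(dag, id) {
  if (is.null(dag$terms[[id]])) stop_data("unknown GO term: ", id)
  term_closure(dag, id, new.env(parent = emptyenv()))
}

#' Parse a GAF 2.x annotation file
#'
#' Reads tab-delimited GAF rows into a map from protein identifier to its set
#' of directly annotated GO terms. Rows whose qualifier contains `NOT`, rows
#' annotating a term absent from (or obsolete in) the ontology, rows with an
#' excluded evidence code, and malformed rows (< 15 columns) are skipped;
#' skips are counted in attributes of the result.
#'
#' @param x GAF content: a file path, single string or character lines.
#'   Lines starting with `!` are comments.
#' @param dag A `go_dag` from [parse_obo()].
#' @param exclude_evidence Character vector of evidence codes to drop
#'   (e.g. `"IEA"`). Default: none.
#' @param id_column Which column provides the protein identifier:
#'   `"id"` (DB Object ID, column 2, the default) or `"symbol"` (column 3).
#' @return Named list mapping protein id to a character vector of direct GO
#'   term ids, with attributes `n_skipped_not`, `n_skipped_term`,
#'   `n_skipped_malformed`, `n_skipped_evidence`.
#' @export
parse_gaf <- function(x, dag, exclude_evidence = character(0),
                      id_column = c("id", "symbol")) {
  id_column <- match.arg(id_column)
  lines <- as_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]

  n_not <- 0L; n_term <- 0L; n_mal <- 0L; n_ev <- 0L
  prot <- character(0); term <- character(0)

  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 15L) { n_mal <- n_mal + 1L; next }
    if (grepl("\\bNOT\\b", f[4L])) { n_not <- n_not + 1L; next }
    if (f[7L] %in% exclude_evidence) { n_ev <- n_ev + 1L; next }
    if (is.null(dag$terms[[f[5L]]])) { n_term <- n_term + 1L; next }
    p <- if (id_column == "id") f[2L] else f[3L]
    prot <- c(prot, p); term <- c(term, f[5L])
  }
  if (n_term > 0L) {
    warning(n_term, " annotation row(s) referenced terms absent from the DAG",
            call. = FALSE)
  }
  if (n_mal > 0L) {
    warning(n_mal, " malformed annotation row(s) skipped", call. = FALSE)
  }
  if (length(prot) == 0L) stop_data("no usable annotation rows in GAF input")

  direct <- split(term, prot)
  direct <- lapply(direct, unique)
  direct <- direct[sort(names(direct), method = "radix")]
  attr(direct, "n_skipped_not") <- n_not
  attr(direct, "n_skipped_term") <- n_term
  attr(direct, "n_skipped_malformed") <- n_mal
  attr(direct, "n_skipped_evidence") <- n_ev
  direct
}

#' Propagate annotations up the ontology
#'
#' Applies the transitivity of GO annotation: a protein annotated to a term
#' is implicitly annotated to every ancestor of that term. Builds the index
#' used by all semantic-similarity computations.
#'
#' @param direct Named list: protein id -> character vector of directly
#'   annotated term ids (as from [parse_gaf()]).
#' @param dag A `go_dag`; every direct term must exist in it.
#'
#' @return An object of class `annotation_index` with fields:
#'   * `direct` — the input map;
#'   * `protein_terms` — protein -> transitive term set;
#'   * `term_proteins` — term -> set of transitively annotated proteins;
#'   * `term_size` — named integer, the annotation size of each term;
#'   * `s_max` — the maximum annotation size over all terms;
#'   * `corpus` — all annotated proteins.
#' @export
propagate_annotations <- function(direct, dag) {
  if (length(direct) == 0L) stop_data("empty annotation map: no corpus")
  missing <- setdiff(unique(unlist(direct, use.names = FALSE)), names(dag$terms))
  if (length(missing)) {
    stop_data("direct annotation to term(s) absent from DAG: ",
              paste(utils::head(missing, 3L), collapse = ", "))
  }
  memo <- new.env(parent = emptyenv())
  protein_terms <- lapply(direct, function(ts) {
    sort(unique(unlist(lapply(ts, term_closure, dag = dag, memo = memo),
                       use.names = FALSE)), method = "radix")
  })
  prot_rep <- rep(names(protein_terms), lengths(protein_terms))
  term_proteins <- split(prot_rep, unlist(protein_terms, use.names = FALSE))
  term_proteins <- lapply(term_proteins, function(p) sort(unique(p), method = "radix"))
  term_size <- vapply(term_proteins, length, 1L)

  structure(
    list(direct = direct,
         protein_terms = protein_terms,
         term_proteins = term_proteins,
         term_size = term_size,
         s_max = max(term_size),
         corpus = sort(names(direct), method = "radix")),
    class = "annotation_index"
  )
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("Annotation index:", length(x$corpus), "proteins,",
      length(x$term_size), "terms after propagation; S_max =", x$s_max, "\n")
  invisible(x)
}

#' Common-annotation statistics for a protein pair
#'
#' For proteins `x` and `y`, `C(x, y)` is the set of GO terms whose
#' (transitive) annotation includes both. This returns how many such terms
#' exist and the annotation size of the most specific one.
#'
#' @param x,y Protein identifiers (need not be annotated).
#' @param index An `annotation_index` from [propagate_annotations()].
#' @return List with `c_size` (number of common terms) and `m` (minimum
#'   annotation size over the common terms; reported as `s_max`, the
#'   maximally non-informative value, when there is no common term).
#' @export
common_annotation_stats <- function(x, y, index) {
  tx <- index$protein_terms[[x]]
  ty <- index$protein_terms[[y]]
  common <- if (is.null(tx) || is.null(ty)) character(0) else intersect(tx, ty)
  if (length(common) == 0L) {
    list(c_size = 0L, m = index$s_max)
  } else {
    list(c_size = length(common), m = min(index$term_size[common]))
  }
}

#' Semantic similarity between two proteins
#'
#' Scores how functionally similar two proteins are from their shared GO
#' annotation. The default scheme uses the annotation size `m` of the most
#' specific common term: `S_sem = 1 - ln(m) / ln(S_max)`, clamped to
#' `[0, 1]`. The score is 1 when the most specific shared term annotates a
#' single protein, 0 when the proteins share only maximally general terms
#' (e.g. only a root), and decreases as `m` grows.
#'
#' @param x,y Protein identifiers.
#' @param index An `annotation_index`.
#' @param scheme Optional replacement scoring function with signature
#'   `function(m, c_size, s_max)` returning a score; it must be
#'   non-increasing in `m` and map `m = 1` to 1 and `m = s_max` to 0.
#' @return Numeric score in `[0, 1]`; 0 when the pair shares no informative
#'   term (including unannotated proteins).
#' @export
semantic_similarity <- function(x, y, index, scheme = NULL) {
  if (index$s_max < 2L) {
    stop_data("semantic similarity undefined: S_max = ", index$s_max, " (< 2)")
  }
  st <- common_annotation_stats(x, y, index)
  if (st$c_size == 0L) return(0)
  f <- scheme %||% sem_scheme_default
  min(1, max(0, f(st$m, st$c_size, index$s_max)))
}

sem_scheme_default <- function(m, c_size, s_max) 1 - log(m) / log(s_max)
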