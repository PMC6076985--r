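#' Parse an OBO 1.2 ontology into a DAG
#'
#' Reads `[Term]` stanzas from an OBO 1.2 flat file. `is_a:` lines and
#' `relationship: part_of` lines become child-to-parent edges; other
#' relationship types are ignored (with a message), following the usual
#' true-path-rule conventions. Obsolete terms are retained and flagged but
#' take part in no edges. `alt_id`s are recorded so annotations citing them
#' can be rewritten to the primary id.
#'
#' @param path file path, connection, or a character vector of lines (any
#'   vector longer than one element, or containing a newline, is treated as
#'   file content rather than a path).
#' @return An object of class `ontology_dag`: a list with
#'   \describe{
#'     \item{terms}{data frame `id`, `name`, `namespace`, `obsolete`}
#'     \item{edges}{data frame `child`, `parent`, `relation`}
#'     \item{roots}{ids of non-obsolete terms with no parents}
#'     \item{alt_ids}{named character vector mapping alt id to primary id}
#'     \item{graph}{an igraph directed graph with edges child to parent}
#'   }
#' @export
parse_obo <- function(path) {
  lines <- if (is.character(path) &&
               (length(path) > 1L || grepl("\n", path, fixed = TRUE))) {
    unlist(strsplit(path, "\n", fixed = TRUE))
  } else readLines(path, warn = FALSE)

  lines <- sub("\\s*!.*$", "", lines)          # trailing comments
  starts <- which(trimws(lines) == "[Term]")
  if (!length(starts))
    abort2("no [Term] stanzas found", "pheno2go_parse_error")
  # any stanza header ends the previous term stanza
  headers <- which(grepl("^\\[.*\\]\\s*$", lines))
  bounds <- c(headers, length(lines) + 1L)

  ids <- character(); nms <- character(); nss <- character()
  obs <- logical(); alt_from <- character(); alt_to <- character()
  ech <- character(); epa <- character(); erel <- character()
  ignored_rel <- character()

  for (s in starts) {
    end <- min(bounds[bounds > s]) - 1L
    block <- lines[seq(s + 1L, max(s + 1L, end))]
    block <- block[nzchar(trimws(block))]
    getv <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    id <- getv("id")
    if (length(id) != 1L)
      abort2("stanza without exactly one id: line", "pheno2go_parse_error")
    name <- getv("name"); ns <- getv("namespace")
    obsolete <- identical(tolower(getv("is_obsolete")), "true")
    ids <- c(ids, id)
    nms <- c(nms, if (length(name)) name[1L] else "")
    nss <- c(nss, if (length(ns)) ns[1L] else "")
    obs <- c(obs, obsolete)
    for (a in getv("alt_id")) { alt_from <- c(alt_from, a); alt_to <- c(alt_to, id) }
    if (!obsolete) {
      for (p in getv("is_a")) {
        ech <- c(ech, id); epa <- c(epa, p); erel <- c(erel, "is_a")
      }
      for (r in getv("relationship")) {
        parts <- strsplit(trimws(r), "\\s+")[[1L]]
        if (length(parts) >= 2L && parts[1L] == "part_of") {
          ech <- c(ech, id); epa <- c(epa, parts[2L]); erel <- c(erel, "part_of")
        } else if (length(parts) >= 1L) {
          ignored_rel <- c(ignored_rel, parts[1L])
        }
      }
    }
  }
  if (length(ignored_rel))
    message("ignoring relation types: ",
            paste(unique(ignored_rel), collapse = ", "))
  if (anyDuplicated(ids))
    abort2(sprintf("duplicate term id '%s'", ids[duplicated(ids)][1L]),
           "pheno2go_structural_error")
  dangling <- setdiff(epa, ids)
  if (length(dangling))
    abort2(sprintf("edge references undeclared parent term '%s'",
                   dangling[1L]), "pheno2go_structural_error")
  to_obsolete <- obs[match(epa, ids)]
  if (any(to_obsolete)) {   # drop edges into obsolete parents
    ech <- ech[!to_obsolete]; epa <- epa[!to_obsolete]
    erel <- erel[!to_obsolete]
  }
  terms <- data.frame(id = ids, name = nms, namespace = nss, obsolete = obs,
                      stringsAsFactors = FALSE)
  edges <- unique(data.frame(child = ech, parent = epa, relation = erel,
                             stringsAsFactors = FALSE))
  new_ontology_dag(terms, edges,
                   stats::setNames(alt_to, alt_from))
}

# shared constructor: validates acyclicity, derives roots, builds the graph
new_ontology_dag <- function(terms, edges, alt_ids = character()) {
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent"), drop = FALSE],
    directed = TRUE, vertices = terms$id)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    e1 <- igraph::ends(g, cyc[1L])
    abort2(sprintf("ontology contains a cycle through edge %s -> %s",
                   e1[1L], e1[2L]), "pheno2go_structural_error")
  }
  has_parent <- terms$id %in% edges$child
  roots <- terms$id[!terms$obsolete & !has_parent]
  structure(list(terms = terms, edges = edges, roots = roots,
                 alt_ids = alt_ids, graph = g),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms (%d obsolete), %d edges, roots: %s\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Serialize a DAG back to OBO 1.2 text
#'
#' Inverse of [parse_obo()] up to stanza ordering: parse, write and re-parse
#' yield an identical DAG.
#'
#' @param dag an `ontology_dag`.
#' @param path file path or connection.
#' @return Invisibly, the number of term stanzas written.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  alt_by_id <- if (length(dag$alt_ids))
    split(names(dag$alt_ids), unname(dag$alt_ids)) else list()
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    out <- c(out, "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (nzchar(t$namespace)) out <- c(out, paste0("namespace: ", t$namespace))
    for (a in alt_by_id[[t$id]]) out <- c(out, paste0("alt_id: ", a))
    e <- dag$edges[dag$edges$child == t$id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[j] == "is_a") paste0("is_a: ", e$parent[j])
               else paste0("relationship: part_of ", e$parent[j]))
    }
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(nrow(dag$terms))
}

#' Resolve term ids, rewriting alt ids to primary ids
#' @param dag an `ontology_dag`.
#' @param ids character vector of term ids.
#' @return Character vector with alt ids replaced by their primary id;
#'   unknown ids pass through unchanged.
#' @export
resolve_term_ids <- function(dag, ids) {
  hit <- ids %in% names(dag$alt_ids)
  ids[hit] <- unname(dag$alt_ids[ids[hit]])
  ids
}

#' Ancestors of a term
#'
#' All terms reachable from `term` by following child-to-parent edges,
#' excluding the term itself.
#'
#' @param dag an `ontology_dag`.
#' @param term a single term id (alt ids are resolved).
#' @return Character vector of ancestor ids (empty for a root).
#' @export
term_ancestors <- function(dag, term) {
  term <- resolve_term_ids(dag, term)
  if (!term %in% dag$terms$id)
    abort2(sprintf("unknown term id '%s'", term), "pheno2go_lookup_error")
  anc <- igraph::subcomponent(dag$graph, term, mode = "out")
  setdiff(names(anc), term)
}

# ancestor list for many terms at once (named list keyed by term id)
ancestors_map <- function(dag, terms) {
  terms <- unique(terms)
  res <- igraph::ego(dag$graph, order = nrow(dag$terms), nodes = terms,
                     mode = "out", mindist = 1)
  stats::setNames(lapply(res, names), terms)
}

#' Propagate annotations by the true path rule
#'
#' An entity annotated with a term is implicitly annotated with every
#' ancestor of that term; propagation makes those pairs explicit. The output
#' is deduplicated and closed under ancestors, so propagation is idempotent.
#'
#' @param annot an `annotation_set`; terms citing alt ids are rewritten to
#'   primary ids first.
#' @param dag an `ontology_dag`.
#' @param on_missing what to do with annotations to terms absent from the
#'   DAG: `"drop"` (default, with a warning) or `"error"`.
#' @return A propagated `annotation_set`.
#' @export
propagate_annotations <- function(annot, dag,
                                  on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  pairs <- annot$pairs
  pairs$term <- resolve_term_ids(dag, pairs$term)
  known <- pairs$term %in% dag$terms$id
  if (!all(known)) {
    missing <- unique(pairs$term[!known])
    if (on_missing == "error")
      abort2(sprintf("annotated term '%s' absent from the ontology",
                     missing[1L]), "pheno2go_lookup_error")
    warning(sprintf("dropping %d annotation(s) to %d term(s) absent from the ontology",
                    sum(!known), length(missing)))
    pairs <- pairs[known, , drop = FALSE]
  }
  if (!nrow(pairs)) return(annotation_set(namespace = annot$namespace))
  anc <- ancestors_map(dag, pairs$term)
  n_anc <- lengths(anc)[pairs$term]
  extra_entity <- rep(pairs$entity, n_anc)
  extra_term <- unlist(anc[pairs$term], use.names = FALSE)
  annotation_set(c(pairs$entity, extra_entity),
                 c(pairs$term, extra_term), annot$namespace)
}

#' Per-term information content from a propagated corpus
#'
#' Information accretion: for a term \eqn{v} with parents \eqn{P(v)},
#' \eqn{ia(v) = -\log_2 \Pr(v \mid P(v))}, with the conditional probability
#' estimated as the number of entities annotated with \eqn{v} divided by the
#' number annotated with every parent of \eqn{v} (for a root, all annotated
#' entities). Terms with no propagated annotation, or a zero denominator,
#' are absent from the result.
#'
#' @param propagated an `annotation_set` closed under ancestors (verified:
#'   non-propagated input is an error).
#' @param dag an `ontology_dag`.
#' @param base logarithm base; 2 (bits) by default.
#' @return Object of class `term_ic`: list with `ic` (named numeric vector,
#'   all values >= 0) and `source_count` (number of annotated entities).
#' @export
information_content <- function(propagated, dag, base = 2) {
  pairs <- propagated$pairs
  pairs$term <- resolve_term_ids(dag, pairs$term)
  # closure check: every (entity, ancestor) pair must already be present
  anc <- ancestors_map(dag, unique(pairs$term))
  key <- paste(pairs$entity, pairs$term)
  n_anc <- lengths(anc)[pairs$term]
  need <- paste(rep(pairs$entity, n_anc), unlist(anc[pairs$term], use.names = FALSE))
  if (!all(need %in% key))
    abort2("annotation set is not closed under ancestors; propagate it first",
           "pheno2go_precondition_error")

  ents_by_term <- split(pairs$entity, pairs$term)
  all_entities <- unique(pairs$entity)
  parents_by_term <- split(dag$edges$parent, dag$edges$child)
  ic <- vapply(names(ents_by_term), function(t) {
    pv <- parents_by_term[[t]]
    denom_set <- if (is.null(pv)) all_entities else {
      sets <- ents_by_term[pv]
      if (any(vapply(sets, is.null, TRUE))) return(NA_real_)
      Reduce(intersect, sets)
    }
    if (!length(denom_set)) return(NA_real_)
    -log(length(ents_by_term[[t]]) / length(denom_set), base = base)
  }, numeric(1))
  ic <- ic[!is.na(ic)]
  ic[ic < 0 & ic > -1e-12] <- 0     # guard tiny negative rounding
  structure(list(ic = ic, source_count = length(all_entities)),
            class = "term_ic")
}

#' @export
print.term_ic <- function(x, ...) {
  cat(sprintf("<term_ic> %d terms, %d source entities, ic range [%.3g, %.3g]\n",
              length(x$ic), x$source_count,
              if (length(x$ic)) min(x$ic) else NA,
              if (length(x$ic)) max(x$ic) else NA))
  invisible(x)
}
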