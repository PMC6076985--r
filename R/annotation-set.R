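#' Annotation sets
#'
#' An annotation set is a deduplicated table of (entity, term) associations:
#' entities are gene symbols or protein accessions, terms are ontology ids
#' (`HP:nnnnnnn` or `GO:nnnnnnn`). It is the container both training corpora
#' (gene-phenotype and gene-function annotations) are held in.
#'
#' @param entity character vector of entity identifiers.
#' @param term character vector of term identifiers, same length as `entity`.
#' @param namespace `"HPO"` or `"GO"`.
#' @return An object of class `annotation_set`: a list with elements
#'   `pairs` (a two-column data frame, unique and sorted) and `namespace`.
#' @examples
#' annotation_set(c("BRCA1", "BRCA1", "TP53"),
#'                c("HP:0000001", "HP:0000002", "HP:0000001"), "HPO")
#' @export
annotation_set <- function(entity = character(), term = character(),
                           namespace = c("HPO", "GO")) {
  namespace <- match.arg(namespace)
  stopifnot(length(entity) == length(term))
  pairs <- unique(data.frame(entity = as.character(entity),
                             term = as.character(term),
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$entity, pairs$term), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, namespace = namespace),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set [%s]> %d pairs, %d entities, %d terms\n",
              x$namespace, nrow(x$pairs),
              length(unique(x$pairs$entity)), length(unique(x$pairs$term))))
  invisible(x)
}

#' Number of annotation pairs
#' @param x an `annotation_set`.
#' @return Integer count of unique (entity, term) pairs.
#' @export
n_pairs <- function(x) nrow(x$pairs)

#' Per-term entity counts
#'
#' The number of distinct entities annotated with each term: the
#' \eqn{N_{HPO}} / \eqn{N_{GO}} quantities of the co-occurrence similarity.
#'
#' @param x an `annotation_set`.
#' @return Named integer vector, one element per term.
#' @export
term_counts <- function(x) {
  tab <- table(x$pairs$term)
  stats::setNames(as.integer(tab), names(tab))
}

#' Entities annotated with a term
#' @param x an `annotation_set`.
#' @param term a single term id.
#' @return Character vector of entity ids.
#' @export
term_entities <- function(x, term) {
  x$pairs$entity[x$pairs$term == term]
}

#' The 13 curated GO evidence codes used for training
#'
#' Experimental, curated and author-statement codes; excludes the electronic
#' IEA code, which is only added when an enlarged training corpus is wanted.
#' @return Character vector of evidence codes.
#' @export
curated_evidence_codes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "IBA",
    "IC", "IKR", "ISS", "NAS", "ND", "TAS")
}

#' Read a gene-to-phenotype annotation file
#'
#' Parses the tab-separated `genes_to_phenotype` dialect: four columns
#' (entrez gene id, gene symbol, HPO term name, HPO term id). Lines starting
#' with `#` are skipped. The entity identifier is the gene symbol, matched
#' exactly and case-sensitively; the term-name column is ignored.
#'
#' @param path file path or connection to the TSV.
#' @return An `annotation_set` with namespace `"HPO"`.
#' @export
read_hpo_gene_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep)) {
    warning("no annotation rows found; returning an empty set")
    return(annotation_set(namespace = "HPO"))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    lineno <- which(keep)[bad[1L]]
    abort2(sprintf("line %d: expected 4 tab-separated columns, found %d",
                   lineno, length(fields[[bad[1L]]])), "pheno2go_parse_error")
  }
  m <- do.call(rbind, fields)
  annotation_set(m[, 2L], m[, 4L], "HPO")
}

#' Read a GO annotation export
#'
#' Reads tab-separated GO annotation rows carrying at least a gene symbol, a
#' GO term id, an evidence code and an ontology aspect. Column positions are
#' configurable; the default layout is a QuickGO-style export with those four
#' columns first, and `dialect = "gaf"` selects the GAF 2.1 positions
#' (symbol in column 3, GO id in column 5, evidence in column 7, aspect in
#' column 9). Rows whose evidence code is not in `evidence` are dropped, and
#' surviving (gene, GO term) pairs are deduplicated across evidence codes and
#' aspects.
#'
#' @param path file path or connection.
#' @param evidence character vector of evidence codes to keep, or `NULL` to
#'   keep everything. Defaults to [curated_evidence_codes()].
#' @param include_iea add `IEA` to the allowed codes (the enlarged-corpus
#'   variant).
#' @param dialect `"quickgo"` (default) or `"gaf"`.
#' @param columns optional named integer vector overriding the column
#'   positions, with names `symbol`, `go`, `evidence`, `aspect`.
#' @return An `annotation_set` with namespace `"GO"`.
#' @export
read_go_annotations <- function(path, evidence = curated_evidence_codes(),
                                include_iea = FALSE,
                                dialect = c("quickgo", "gaf"),
                                columns = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(columns))
    columns <- switch(dialect,
      quickgo = c(symbol = 1L, go = 2L, evidence = 3L, aspect = 4L),
      gaf     = c(symbol = 3L, go = 5L, evidence = 7L, aspect = 9L))
  if (!is.null(evidence) && include_iea) evidence <- union(evidence, "IEA")
  if (!is.null(evidence) && !length(evidence))
    abort2("evidence filter requested with an empty code set",
           "pheno2go_config_error")
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "!") & !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep)) {
    warning("no annotation rows found; returning an empty set")
    return(annotation_set(namespace = "GO"))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  need <- max(columns)
  bad <- which(lengths(fields) < need)
  if (length(bad)) {
    lineno <- which(keep)[bad[1L]]
    abort2(sprintf("line %d: expected at least %d tab-separated columns",
                   lineno, need), "pheno2go_parse_error")
  }
  sym <- vapply(fields, `[[`, "", columns[["symbol"]])
  go <- vapply(fields, `[[`, "", columns[["go"]])
  ev <- vapply(fields, `[[`, "", columns[["evidence"]])
  ok_id <- grepl("^GO:\\d{7}$", go)
  if (!all(ok_id)) {
    lineno <- which(keep)[which(!ok_id)[1L]]
    abort2(sprintf("line %d: malformed GO identifier '%s'",
                   lineno, go[!ok_id][1L]), "pheno2go_parse_error")
  }
  if (!is.null(evidence)) {
    sel <- ev %in% evidence
    sym <- sym[sel]; go <- go[sel]
  }
  annotation_set(sym, go, "GO")
}

#' Read a two-column annotation TSV
#'
#' The generic (entity, term) dialect written by [write_annotation_set()].
#'
#' @param path file path or connection.
#' @param namespace `"HPO"` or `"GO"`.
#' @return An `annotation_set`.
#' @export
read_annotation_set <- function(path, namespace = c("HPO", "GO")) {
  namespace <- match.arg(namespace)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep)) return(annotation_set(namespace = namespace))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    abort2(sprintf("line %d: expected 2 tab-separated columns",
                   which(keep)[bad[1L]]), "pheno2go_parse_error")
  m <- do.call(rbind, fields)
  annotation_set(m[, 1L], m[, 2L], namespace)
}

#' Write an annotation set as a two-column TSV
#'
#' Rows are sorted lexicographically by (entity, term) so identical sets
#' serialize byte-identically; reading the file back recovers an equal set.
#'
#' @param annot an `annotation_set`.
#' @param path file path or connection.
#' @return Invisibly, the number of data rows written.
#' @export
write_annotation_set <- function(annot, path) {
  p <- annot$pairs[order(annot$pairs$entity, annot$pairs$term), , drop = FALSE]
  utils::write.table(p, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(p))
}

#' Keep only annotations whose evidence passes a filter
#'
#' Helper for pre-parsed tables; reading functions normally filter inline.
#' Filtering with the universal code set is the identity.
#'
#' @param pairs data frame with columns `entity`, `term`, `evidence`.
#' @param allowed character vector of evidence codes.
#' @param namespace namespace for the result.
#' @return An `annotation_set` of the surviving pairs.
#' @export
filter_evidence <- function(pairs, allowed, namespace = "GO") {
  if (!length(allowed))
    abort2("evidence filter requested with an empty code set",
           "pheno2go_config_error")
  sel <- pairs$evidence %in% allowed
  annotation_set(pairs$entity[sel], pairs$term[sel], namespace)
}
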