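#' Predict phenotype terms for proteins from their GO annotations
#'
#' Every mapping record (hpo_id, go_id, S) transfers the phenotype term
#' `hpo_id` with probabilistic score `S` to each protein annotated with
#' `go_id`. When several GO annotations of one protein reach the same
#' phenotype term, the maximum similarity wins and the contributing GO term
#' is recorded. Ontology roots are never emitted when the phenotype DAG is
#' supplied.
#'
#' @param mappings a filtered `mapping_table` (a table without
#'   `applied_thresholds` is accepted with a warning).
#' @param go_annot `annotation_set` of protein/gene GO annotations (the
#'   query corpus).
#' @param score_floor predictions scoring below this are dropped
#'   (default 0.01, the prediction-format minimum).
#' @param dag optional phenotype `ontology_dag`: its roots are removed from
#'   the output, and `propagate = TRUE` additionally emits every ancestor of
#'   a predicted term at the maximum score of its descendants.
#' @param propagate emit ancestor terms (default `FALSE`; evaluation
#'   propagates internally, so prediction files normally stay unpropagated).
#' @return A `prediction_set`: data frame with columns `protein_id`,
#'   `hpo_id`, `score`, `via_go`, unique per (protein, term), sorted.
#' @export
predict_hpo <- function(mappings, go_annot, score_floor = 0.01, dag = NULL,
                        propagate = FALSE) {
  if (is.null(attr(mappings, "applied_thresholds")))
    warning("mapping table carries no applied thresholds; using it as-is")
  empty <- data.frame(protein_id = character(), hpo_id = character(),
                      score = numeric(), via_go = character(),
                      stringsAsFactors = FALSE)
  map_df <- as.data.frame(mappings)[, c("hpo_id", "go_id", "S")]
  joined <- merge(go_annot$pairs, map_df, by.x = "term", by.y = "go_id")
  if (!nrow(joined))
    return(new_prediction_set(empty, mappings))
  df <- data.frame(protein_id = joined$entity, hpo_id = joined$hpo_id,
                   score = joined$S, via_go = joined$term,
                   stringsAsFactors = FALSE)
  if (propagate && !is.null(dag)) {
    anc <- ancestors_map(dag, unique(df$hpo_id))
    n_anc <- lengths(anc)[df$hpo_id]
    df <- rbind(df, data.frame(
      protein_id = rep(df$protein_id, n_anc),
      hpo_id = unlist(anc[df$hpo_id], use.names = FALSE),
      score = rep(df$score, n_anc),
      via_go = rep(df$via_go, n_anc), stringsAsFactors = FALSE))
  }
  # max score per (protein, term); ties broken by lexicographically
  # smallest contributing GO id for determinism
  df <- df[order(df$protein_id, df$hpo_id, -df$score, df$via_go), ,
           drop = FALSE]
  df <- df[!duplicated(df[, c("protein_id", "hpo_id")]), , drop = FALSE]
  df <- df[df$score >= score_floor, , drop = FALSE]
  if (!is.null(dag)) df <- df[!df$hpo_id %in% dag$roots, , drop = FALSE]
  new_prediction_set(df, mappings)
}

new_prediction_set <- function(df, mappings = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("prediction_set", "data.frame"),
            mapping_provenance = if (!is.null(mappings))
              attr(mappings, "provenance"),
            mapping_thresholds = if (!is.null(mappings))
              attr(mappings, "applied_thresholds"))
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d predictions for %d proteins, %d terms\n",
              nrow(x), length(unique(x$protein_id)),
              length(unique(x$hpo_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Write predictions in the community challenge exchange format
#'
#' `AUTHOR`, `MODEL` and `KEYWORDS` header lines, then one
#' `target term score` row per prediction with the score rounded to two
#' decimals (a score rounding to 0.00 is clamped to 0.01 with a warning),
#' then `END`. Rows are sorted by (target, term) so output is deterministic.
#'
#' @param preds a `prediction_set`.
#' @param model_tag model identifier for the `MODEL` line.
#' @param path file path or connection.
#' @param author author string for the `AUTHOR` line.
#' @param keywords keywords string.
#' @return Invisibly, the number of data rows written.
#' @export
write_cafa_predictions <- function(preds, model_tag, path,
                                   author = "pheno2go",
                                   keywords = "ontology mapping.") {
  stopifnot(all(preds$score > 0), all(preds$score <= 1))
  df <- as.data.frame(preds)[order(preds$protein_id, preds$hpo_id), ,
                             drop = FALSE]
  sc <- round(df$score, 2)
  if (any(sc < 0.01)) {
    warning(sprintf("%d score(s) rounded below 0.01; clamped", sum(sc < 0.01)))
    sc[sc < 0.01] <- 0.01
  }
  lines <- c(paste("AUTHOR", author), paste("MODEL", model_tag),
             paste("KEYWORDS", keywords),
             if (nrow(df)) sprintf("%s %s %.2f", df$protein_id, df$hpo_id, sc),
             "END")
  writeLines(lines, path)
  invisible(nrow(df))
}

#' Read a challenge-format prediction file
#' @param path file path or connection.
#' @return A `prediction_set` (with `via_go` set to `NA`).
#' @export
read_cafa_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!grepl("^(AUTHOR|MODEL|KEYWORDS|END)\\b", lines) &
                      nzchar(lines)]
  if (!length(data_lines))
    return(new_prediction_set(data.frame(protein_id = character(),
                                         hpo_id = character(),
                                         score = numeric(),
                                         via_go = character())))
  m <- do.call(rbind, strsplit(data_lines, "\\s+"))
  new_prediction_set(data.frame(protein_id = m[, 1L], hpo_id = m[, 2L],
                                score = as.numeric(m[, 3L]),
                                via_go = NA_character_,
                                stringsAsFactors = FALSE))
}

#' Write predictions as a plain TSV
#'
#' Columns `protein_id, hpo_id, score, via_go` with full score precision;
#' deterministic row order.
#'
#' @param preds a `prediction_set`.
#' @param path file path or connection.
#' @return Invisibly, the number of rows written.
#' @export
write_prediction_tsv <- function(preds, path) {
  df <- as.data.frame(preds)[order(preds$protein_id, preds$hpo_id), ,
                             drop = FALSE]
  hdr <- paste(c("protein_id", "hpo_id", "score", "via_go"), collapse = "\t")
  body <- if (nrow(df)) sprintf("%s\t%s\t%.6f\t%s", df$protein_id, df$hpo_id,
                                df$score, df$via_go) else character()
  writeLines(c(hdr, body), path)
  invisible(nrow(df))
}

#' Read a prediction TSV written by [write_prediction_tsv()]
#' @param path file path or connection.
#' @return A `prediction_set`.
#' @export
read_prediction_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "character"))
  new_prediction_set(df)
}
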