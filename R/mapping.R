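#' Co-occurrence similarity between two annotation gene sets
#'
#' The Dice-style score \eqn{S = 2n / (N_{hpo} + N_{go})}, where `n` is the
#' number of genes annotated with both terms and `N_hpo`, `N_go` are the
#' total numbers of genes annotated with each term over its whole corpus.
#' `S` is 1 exactly when the two gene sets are identical.
#'
#' @param n co-annotation count (>= 0).
#' @param N_hpo genes annotated with the phenotype term (>= max(n, 1)).
#' @param N_go genes annotated with the GO term (>= max(n, 1)).
#' @return Numeric similarity in \[0, 1\]; vectorized.
#' @examples
#' cooccurrence_similarity(3, 3, 4)  # 6/7
#' @export
cooccurrence_similarity <- function(n, N_hpo, N_go) {
  if (any(N_hpo + N_go == 0))
    abort2("N_hpo + N_go must be positive", "pheno2go_domain_error")
  if (any(n < 0) || any(N_hpo < pmax(n, 1)) || any(N_go < pmax(n, 1)))
    abort2("need n >= 0, N_hpo >= max(n, 1), N_go >= max(n, 1)",
           "pheno2go_domain_error")
  2 * n / (N_hpo + N_go)
}

new_mapping_table <- function(df, provenance = "original", thresholds = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("mapping_table", "data.frame"),
            provenance = provenance, applied_thresholds = thresholds)
}

#' @export
print.mapping_table <- function(x, ...) {
  thr <- attr(x, "applied_thresholds")
  cat(sprintf("<mapping_table [%s]> %d records%s\n", attr(x, "provenance"),
              nrow(x),
              if (is.null(thr)) "" else
                sprintf(", filtered at S >= %g, n >= %g",
                        thr[["s_min"]], thr[["n_min"]])))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Build the raw phenotype-to-GO mapping table
#'
#' One record per (HPO term, GO term) pair whose annotation gene sets share
#' at least one gene. `n` is the size of the intersection; `N_hpo` and
#' `N_go` are whole-corpus counts (not restricted to the shared gene
#' universe); `S` is their co-occurrence similarity. Records are sorted by
#' (hpo_id, go_id) for reproducible files.
#'
#' @param hpo_annot `annotation_set` of gene-phenotype annotations.
#' @param go_annot `annotation_set` of gene-GO annotations, same entity
#'   namespace (gene symbols).
#' @param provenance label stored on the table (`"original"` or `"null"`).
#' @return A `mapping_table`: data frame with columns `hpo_id`, `go_id`,
#'   `n`, `N_hpo`, `N_go`, `S`.
#' @export
build_raw_mapping <- function(hpo_annot, go_annot, provenance = "original") {
  N_hpo <- term_counts(hpo_annot)
  N_go <- term_counts(go_annot)
  joined <- merge(hpo_annot$pairs, go_annot$pairs, by = "entity")
  empty <- data.frame(hpo_id = character(), go_id = character(),
                      n = integer(), N_hpo = integer(), N_go = integer(),
                      S = numeric(), stringsAsFactors = FALSE)
  if (!nrow(joined)) {
    warning("the two corpora share no co-annotated genes; empty mapping table")
    return(new_mapping_table(empty, provenance))
  }
  key <- paste(joined$term.x, joined$term.y, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  df <- data.frame(hpo_id = parts[, 1L], go_id = parts[, 2L],
                   n = as.integer(tab), stringsAsFactors = FALSE)
  df$N_hpo <- as.integer(N_hpo[df$hpo_id])
  df$N_go <- as.integer(N_go[df$go_id])
  df$S <- cooccurrence_similarity(df$n, df$N_hpo, df$N_go)
  df <- df[order(df$hpo_id, df$go_id), , drop = FALSE]
  new_mapping_table(df, provenance)
}

#' Filter a mapping table at similarity and count thresholds
#'
#' Keeps exactly the records with `n >= n_min` and `S >= s_min`; both
#' conditions must hold. Filtering at (0, 1) is the identity on a raw table.
#'
#' @param table a `mapping_table`.
#' @param s_min minimum co-occurrence similarity (>= 0).
#' @param n_min minimum co-annotation count (>= 0).
#' @return The filtered `mapping_table` with `applied_thresholds` recorded.
#' @export
filter_mapping <- function(table, s_min, n_min) {
  stopifnot(s_min >= 0, n_min >= 0)
  keep <- table$n >= n_min & table$S >= s_min
  new_mapping_table(as.data.frame(table)[keep, , drop = FALSE],
                    attr(table, "provenance"),
                    thresholds = c(s_min = s_min, n_min = n_min))
}

#' Summarize a mapping table over similarity thresholds
#'
#' For each threshold, the cumulative number of records with `S` at or above
#' it (strictly above for threshold 0) and the numbers of distinct HPO and
#' GO terms among them. Counts are monotone non-increasing in the threshold.
#'
#' @param table a `mapping_table`.
#' @param s_thresholds numeric vector of thresholds.
#' @return Data frame with columns `s_threshold`, `n_mappings`,
#'   `n_hpo_terms`, `n_go_terms`.
#' @export
summarize_mapping <- function(table, s_thresholds = c(0, 0.1, 0.2, 0.3,
                                                      0.4, 0.5, 0.6)) {
  rows <- lapply(s_thresholds, function(s) {
    keep <- if (s == 0) table$S > 0 else table$S >= s
    data.frame(s_threshold = s, n_mappings = sum(keep),
               n_hpo_terms = length(unique(table$hpo_id[keep])),
               n_go_terms = length(unique(table$go_id[keep])))
  })
  do.call(rbind, rows)
}

#' Write a mapping table as TSV
#'
#' Columns `hpo_id, go_id, n, N_hpo, N_go, S` (S with six decimals), after
#' `#key=value` comment lines carrying provenance and any applied
#' thresholds.
#'
#' @param table a `mapping_table`.
#' @param path file path or connection.
#' @return Invisibly, the number of data rows written.
#' @export
write_mapping_table <- function(table, path) {
  thr <- attr(table, "applied_thresholds")
  hdr <- c(sprintf("#provenance=%s", attr(table, "provenance")),
           if (!is.null(thr))
             sprintf("#thresholds=s_min:%g,n_min:%g",
                     thr[["s_min"]], thr[["n_min"]]),
           paste(c("hpo_id", "go_id", "n", "N_hpo", "N_go", "S"),
                 collapse = "\t"))
  body <- if (nrow(table)) sprintf("%s\t%s\t%d\t%d\t%d\t%.6f",
                                   table$hpo_id, table$go_id, table$n,
                                   table$N_hpo, table$N_go, table$S)
          else character()
  writeLines(c(hdr, body), path)
  invisible(nrow(table))
}

#' Read a mapping table TSV written by [write_mapping_table()]
#' @param path file path or connection.
#' @return A `mapping_table`.
#' @export
read_mapping_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  prov <- sub("^#provenance=", "", grep("^#provenance=", meta, value = TRUE))
  thr <- NULL
  tl <- grep("^#thresholds=", meta, value = TRUE)
  if (length(tl)) {
    v <- regmatches(tl, gregexpr("[0-9.]+", tl))[[1L]]
    thr <- c(s_min = as.numeric(v[1L]), n_min = as.numeric(v[2L]))
  }
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1L], "\t")[[1L]]
  body <- body[-1L]
  if (!length(body)) {
    df <- data.frame(hpo_id = character(), go_id = character(), n = integer(),
                     N_hpo = integer(), N_go = integer(), S = numeric())
  } else {
    m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    colnames(m) <- header
    df <- data.frame(hpo_id = m[, "hpo_id"], go_id = m[, "go_id"],
                     n = as.integer(m[, "n"]), N_hpo = as.integer(m[, "N_hpo"]),
                     N_go = as.integer(m[, "N_go"]), S = as.numeric(m[, "S"]),
                     stringsAsFactors = FALSE)
  }
  new_mapping_table(df, if (length(prov)) prov else "original", thr)
}
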