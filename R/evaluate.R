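#' Assemble a benchmark set
#'
#' Propagates the truth annotations by the true path rule, removes ontology
#' roots, and records the benchmark protein list and evaluation mode.
#'
#' @param truth an `annotation_set` of reference (protein, phenotype term)
#'   annotations.
#' @param dag the phenotype `ontology_dag`.
#' @param proteins benchmark protein ids; defaults to the truth entities.
#'   Every truth entity must be present.
#' @param mode `"full"` (recall averaged over all benchmark proteins) or
#'   `"partial"` (recall over predicted proteins only).
#' @return Object of class `benchmark_set`: list with `truth` (propagated,
#'   roots removed), `proteins`, `mode`.
#' @export
benchmark_set <- function(truth, dag, proteins = NULL,
                          mode = c("full", "partial")) {
  mode <- match.arg(mode)
  prop <- propagate_annotations(truth, dag)
  keep <- !prop$pairs$term %in% dag$roots
  prop <- annotation_set(prop$pairs$entity[keep], prop$pairs$term[keep],
                         truth$namespace)
  if (is.null(proteins)) proteins <- unique(prop$pairs$entity)
  if (!all(prop$pairs$entity %in% proteins))
    abort2("every truth entity must appear in the benchmark protein list",
           "pheno2go_precondition_error")
  structure(list(truth = prop, proteins = sort(unique(proteins)),
                 mode = mode), class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("<benchmark_set [%s mode]> %d proteins, %d truth pairs\n",
              x$mode, length(x$proteins), n_pairs(x$truth)))
  invisible(x)
}

# Propagated per-protein prediction scores: each predicted term transfers its
# score to all ancestors; an ancestor keeps the maximum over its descendants;
# roots removed. Returns a named list of named numeric vectors.
propagated_scores <- function(preds, dag) {
  if (!nrow(preds)) return(list())
  anc <- ancestors_map(dag, unique(preds$hpo_id))
  n_anc <- lengths(anc)[preds$hpo_id]
  prot <- c(preds$protein_id, rep(preds$protein_id, n_anc))
  term <- c(preds$hpo_id, unlist(anc[preds$hpo_id], use.names = FALSE))
  score <- c(preds$score, rep(preds$score, n_anc))
  keep <- !term %in% dag$roots
  prot <- prot[keep]; term <- term[keep]; score <- score[keep]
  if (!length(prot)) return(list())
  key <- split(seq_along(prot), prot)
  lapply(key, function(idx) {
    mx <- tapply(score[idx], term[idx], max)
    stats::setNames(as.numeric(mx), names(mx))
  })
}

truth_by_protein <- function(bench) {
  split(bench$truth$pairs$term, bench$truth$pairs$entity)
}

ic_of <- function(ic, terms) {
  v <- ic$ic[terms]
  v[is.na(v)] <- 0
  sum(v)
}

# Metrics at one score threshold, given precomputed per-protein structures.
metrics_at_tau <- function(tau, proteins, truth_list, score_list, ic, mode) {
  tp <- fp <- fn <- 0L
  pr_sum <- rc_sum <- 0
  wpr_sum <- wrc_sum <- 0
  ru_sum <- mi_sum <- 0
  n_pred <- 0L
  n_ru <- 0L
  for (p in proteins) {
    Tset <- truth_list[[p]] %||% character()
    sv <- score_list[[p]]
    Pset <- if (is.null(sv)) character() else names(sv)[sv >= tau]
    tpp <- intersect(Pset, Tset)
    fpp <- setdiff(Pset, Tset)
    fnp <- setdiff(Tset, Pset)
    tp <- tp + length(tpp); fp <- fp + length(fpp); fn <- fn + length(fnp)
    predicted <- length(Pset) > 0L
    if (predicted) {
      n_pred <- n_pred + 1L
      pr_sum <- pr_sum + length(tpp) / length(Pset)
      wt <- ic_of(ic, tpp); wf <- ic_of(ic, fpp)
      wpr_sum <- wpr_sum + if (wt + wf > 0) wt / (wt + wf) else 0
    }
    in_rc <- mode == "full" || predicted
    if (in_rc) {
      n_ru <- n_ru + 1L
      if (length(Tset)) {
        rc_sum <- rc_sum + length(tpp) / length(Tset)
        wt <- ic_of(ic, tpp); wn <- ic_of(ic, fnp)
        wrc_sum <- wrc_sum + if (wt + wn > 0) wt / (wt + wn) else 1
      } else rc_sum <- rc_sum + 1        # vacuous truth: nothing to recover
      ru_sum <- ru_sum + ic_of(ic, fnp)
      mi_sum <- mi_sum + ic_of(ic, fpp)
    }
  }
  precision <- if (n_pred > 0) pr_sum / n_pred else 0
  w_precision <- if (n_pred > 0) wpr_sum / n_pred else 0
  recall <- if (n_ru > 0) rc_sum / n_ru else 0
  w_recall <- if (n_ru > 0) wrc_sum / n_ru else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  wf <- if (w_precision + w_recall > 0)
    2 * w_precision * w_recall / (w_precision + w_recall) else 0
  data.frame(tau = tau, tp = tp, fp = fp, fn = fn,
             n_predicted = n_pred, precision = precision, recall = recall,
             f_score = f, w_precision = w_precision, w_recall = w_recall,
             w_f_score = wf,
             ru = if (n_ru > 0) ru_sum / n_ru else 0,
             mi = if (n_ru > 0) mi_sum / n_ru else 0)
}

#' Protein-centric metrics at one score threshold
#'
#' Per protein, the predicted set at threshold `tau` is the true-path-rule
#' propagation of its predictions with score at least `tau` (roots removed);
#' the truth is the propagated benchmark annotation. Precision is averaged
#' over proteins with at least one prediction at `tau`; recall over all
#' benchmark proteins in full mode (predicted proteins in partial mode).
#' Remaining uncertainty `ru` and misinformation `mi` are per-protein means
#' of summed information content over false negatives and false positives.
#'
#' @param preds a `prediction_set`.
#' @param bench a `benchmark_set`.
#' @param dag the phenotype `ontology_dag`.
#' @param ic a `term_ic` (missing terms weigh 0).
#' @param tau score threshold in (0, 1].
#' @return One-row data frame: `tau, tp, fp, fn, n_predicted, precision,
#'   recall, f_score, w_precision, w_recall, w_f_score, ru, mi`.
#' @export
threshold_metrics <- function(preds, bench, dag, ic, tau) {
  if (tau <= 0 || tau > 1)
    abort2("tau must lie in (0, 1]", "pheno2go_domain_error")
  metrics_at_tau(tau, bench$proteins, truth_by_protein(bench),
                 propagated_scores(preds, dag), ic, bench$mode)
}

#' Evaluate predictions against a benchmark
#'
#' Sweeps the score-threshold grid and reports the protein-centric maximum
#' F-score (Fmax), its information-content-weighted variant, the minimum
#' semantic distance \eqn{S_{min} = \min_\tau \sqrt{Ru_\tau^2 + Mi_\tau^2}}
#' (the all-predictions-discarded point is always part of the scan),
#' coverage, and term-centric AUROCs.
#'
#' @inheritParams threshold_metrics
#' @param tau_grid score thresholds (default `seq(0.01, 1, 0.01)`).
#' @param on_missing_ic truth terms without defined information content:
#'   `"zero"` (weigh 0, default) or `"error"`.
#' @return Object of class `evaluation_summary`: list with `fmax`,
#'   `weighted_fmax`, `smin`, `coverage`, `curve` (one row per threshold),
#'   `term_auroc`, `macro_auroc`, `skipped_terms`, `mode`.
#' @export
evaluate_predictions <- function(preds, bench, dag, ic,
                                 tau_grid = seq(0.01, 1, by = 0.01),
                                 on_missing_ic = c("zero", "error")) {
  on_missing_ic <- match.arg(on_missing_ic)
  stopifnot(length(tau_grid) > 0)
  truth_terms <- unique(bench$truth$pairs$term)
  undef <- setdiff(truth_terms, names(ic$ic))
  if (length(undef) && on_missing_ic == "error")
    abort2(sprintf("truth term '%s' has no defined information content",
                   undef[1L]), "pheno2go_precondition_error")
  if (length(undef))
    warning(sprintf("%d truth term(s) lack information content; weighted at 0",
                    length(undef)))
  truth_list <- truth_by_protein(bench)
  score_list <- propagated_scores(preds, dag)
  curve <- do.call(rbind, lapply(sort(tau_grid), metrics_at_tau,
                                 proteins = bench$proteins,
                                 truth_list = truth_list,
                                 score_list = score_list, ic = ic,
                                 mode = bench$mode))
  fmax <- max(curve$f_score)
  wfmax <- max(curve$w_f_score)
  # the empty-prediction point: everything discarded
  ru_empty <- mean(vapply(bench$proteins, function(p)
    ic_of(ic, truth_list[[p]] %||% character()), numeric(1)))
  smin <- min(c(sqrt(curve$ru^2 + curve$mi^2), ru_empty))
  auc <- term_centric_auroc(preds, bench, dag = dag)
  structure(list(fmax = fmax, weighted_fmax = wfmax, smin = smin,
                 coverage = coverage(preds, bench), curve = curve,
                 term_auroc = auc$term_auroc, macro_auroc = auc$macro_auroc,
                 skipped_terms = auc$skipped_terms, mode = bench$mode),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_summary [%s mode]>\n",
                     "  Fmax = %.4f  weighted Fmax = %.4f  Smin = %.4f\n",
                     "  coverage = %.4f  macro AUROC = %s  (%d terms scored,",
                     " %d skipped)\n"),
              x$mode, x$fmax, x$weighted_fmax, x$smin, x$coverage,
              if (is.na(x$macro_auroc)) "NA" else sprintf("%.4f", x$macro_auroc),
              length(x$term_auroc), length(x$skipped_terms)))
  invisible(x)
}

#' Term-centric AUROC
#'
#' For every phenotype term with at least one positive and one negative
#' protein in the universe, the area under the ROC curve of the predicted
#' scores (a protein without a prediction for the term scores 0), computed
#' with the rank-average (Mann-Whitney) tie convention. Terms with no
#' positive or no negative are skipped and reported.
#'
#' @param preds a `prediction_set`.
#' @param bench a `benchmark_set` (its propagated truth defines positives).
#' @param protein_universe proteins over which to rank; defaults to the
#'   benchmark proteins and must contain them.
#' @param dag optional phenotype `ontology_dag`; when supplied, prediction
#'   scores are true-path-rule propagated before ranking.
#' @return List with `term_auroc` (named numeric), `macro_auroc` (unweighted
#'   mean; `NA` when no term is scorable) and `skipped_terms`.
#' @export
term_centric_auroc <- function(preds, bench, protein_universe = NULL,
                               dag = NULL) {
  universe <- protein_universe %||% bench$proteins
  if (!all(bench$proteins %in% universe))
    abort2("protein universe must contain all benchmark proteins",
           "pheno2go_precondition_error")
  score_list <- if (!is.null(dag)) propagated_scores(preds, dag)
    else if (nrow(preds)) lapply(split(seq_len(nrow(preds)), preds$protein_id),
      function(idx) stats::setNames(preds$score[idx], preds$hpo_id[idx]))
    else list()
  terms <- sort(unique(bench$truth$pairs$term))
  pos_by_term <- split(bench$truth$pairs$entity, bench$truth$pairs$term)
  auroc <- numeric(); skipped <- character()
  for (t in terms) {
    pos <- unique(pos_by_term[[t]])
    neg <- setdiff(universe, pos)
    if (!length(pos) || !length(neg)) { skipped <- c(skipped, t); next }
    sc <- vapply(universe, function(p) {
      v <- score_list[[p]]
      if (!is.null(v) && t %in% names(v)) unname(v[[t]]) else 0
    }, numeric(1))
    r <- rank(sc, ties.method = "average")
    np <- length(pos); nn <- length(neg)
    auroc[[t]] <- (sum(r[universe %in% pos]) - np * (np + 1) / 2) / (np * nn)
  }
  list(term_auroc = auroc,
       macro_auroc = if (length(auroc)) mean(auroc) else NA_real_,
       skipped_terms = skipped)
}

#' Benchmark coverage
#'
#' Fraction of benchmark proteins receiving at least one prediction at any
#' score.
#'
#' @param preds a `prediction_set`.
#' @param bench a `benchmark_set`.
#' @return A fraction in \[0, 1\].
#' @export
coverage <- function(preds, bench) {
  if (!length(bench$proteins))
    abort2("benchmark protein list is empty", "pheno2go_domain_error")
  length(intersect(unique(preds$protein_id), bench$proteins)) /
    length(bench$proteins)
}

#' Write an evaluation report
#'
#' A per-threshold TSV (`<path_prefix>_curve.tsv`) and a JSON summary
#' (`<path_prefix>_summary.json`) with Fmax, weighted Fmax, Smin, coverage
#' and macro AUROC.
#'
#' @param summary an `evaluation_summary`.
#' @param path_prefix output path prefix.
#' @return Invisibly, the JSON path.
#' @export
write_evaluation_report <- function(summary, path_prefix) {
  curve_path <- paste0(path_prefix, "_curve.tsv")
  utils::write.table(format(summary$curve, digits = 6, trim = TRUE),
                     curve_path, sep = "\t", quote = FALSE, row.names = FALSE)
  json_path <- paste0(path_prefix, "_summary.json")
  jsonlite::write_json(list(
    fmax = summary$fmax, weighted_fmax = summary$weighted_fmax,
    smin = summary$smin, coverage = summary$coverage,
    macro_auroc = summary$macro_auroc, mode = summary$mode,
    n_terms_scored = length(summary$term_auroc),
    skipped_terms = summary$skipped_terms),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}
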