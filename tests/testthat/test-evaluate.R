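# the shared 2-protein hand-worked fixture lives in helper-fixtures.R

test_that("threshold_metrics reproduces the 2-protein hand enumeration", {
  cs <- two_protein_case()
  m <- threshold_metrics(cs$preds, cs$bench, cs$dag, cs$ic, tau = 0.9)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.75)          # (1/2 + 1) / 2
  expect_equal(m$tp + m$fn, 3L)         # conservation: total truth size
  expect_condition(threshold_metrics(cs$preds, cs$bench, cs$dag, cs$ic, 0),
                   class = "pheno2go_domain_error")
  expect_condition(threshold_metrics(cs$preds, cs$bench, cs$dag, cs$ic, 1.2),
                   class = "pheno2go_domain_error")
})

test_that("the F-score curve peaks at 6/7 on the 2-protein example", {
  cs <- two_protein_case()
  ev <- evaluate_predictions(cs$preds, cs$bench, cs$dag, cs$ic,
                             tau_grid = c(0.4, 0.9))
  expect_equal(ev$curve$f_score[ev$curve$tau == 0.9], 6 / 7)
  expect_equal(ev$curve$f_score[ev$curve$tau == 0.4], 0.6)
  expect_equal(ev$fmax, 6 / 7)
  # ic is identically 1, so the weighted curve coincides with the plain one
  expect_equal(ev$weighted_fmax, ev$fmax)
})

test_that("perfect predictions score Fmax 1 and Smin 0", {
  dag <- flat_dag(c("HP:0000010", "HP:0000011"))
  truth <- annotation_set(c("P1", "P2"), c("HP:0000010", "HP:0000011"), "HPO")
  bench <- benchmark_set(truth, dag)
  preds <- manual_preds(c("P1", "P2"), c("HP:0000010", "HP:0000011"),
                        c(1, 1))
  ic <- information_content(propagate_annotations(truth, dag), dag)
  ev <- evaluate_predictions(preds, bench, dag, ic)
  expect_equal(ev$fmax, 1)
  expect_equal(ev$smin, 0)
  expect_equal(ev$coverage, 1)
})

test_that("the Smin scan includes the empty-prediction point (Smin = 3)", {
  dag <- flat_dag(c("HP:0000010", "HP:0000011", "HP:0000012"))
  truth <- annotation_set(c("P1", "P1"), c("HP:0000010", "HP:0000011"), "HPO")
  bench <- benchmark_set(truth, dag)
  preds <- manual_preds(c("P1", "P1"), c("HP:0000010", "HP:0000012"),
                        c(0.9, 0.9))
  ic <- manual_ic("HP:0000010" = 1, "HP:0000011" = 2, "HP:0000012" = 3)
  # at tau <= 0.9: Ru = 2, Mi = 3 -> sqrt(13); discarding all: Ru = 3, Mi = 0
  m <- threshold_metrics(preds, bench, dag, ic, 0.9)
  expect_equal(sqrt(m$ru^2 + m$mi^2), sqrt(13))
  ev <- evaluate_predictions(preds, bench, dag, ic, tau_grid = c(0.5, 0.9))
  expect_equal(ev$smin, 3)
})

test_that("predictions are propagated before comparison, roots excluded", {
  # deep truth at the leaf; prediction only at the leaf must still recall the
  # intermediate terms after propagation
  dag <- parse_obo(diamond_obo())
  truth <- annotation_set("P1", "GO:0000004", "HPO")
  bench <- benchmark_set(truth, dag)
  expect_setequal(bench$truth$pairs$term,
                  c("GO:0000004", "GO:0000002", "GO:0000003"))  # root removed
  preds <- manual_preds("P1", "GO:0000004", 0.8)
  ic <- manual_ic("GO:0000002" = 1, "GO:0000003" = 1, "GO:0000004" = 1)
  m <- threshold_metrics(preds, bench, dag, ic, 0.5)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
})

test_that("full and partial modes differ only in the recall denominator", {
  dag <- flat_dag(c("HP:0000010", "HP:0000011"))
  truth <- annotation_set(c("P1", "P2"), c("HP:0000010", "HP:0000011"), "HPO")
  preds <- manual_preds("P1", "HP:0000010", 0.9)   # P2 never predicted
  ic <- manual_ic("HP:0000010" = 1, "HP:0000011" = 1)
  full <- threshold_metrics(preds, benchmark_set(truth, dag, mode = "full"),
                            dag, ic, 0.5)
  part <- threshold_metrics(preds, benchmark_set(truth, dag, mode = "partial"),
                            dag, ic, 0.5)
  expect_equal(full$precision, part$precision)
  expect_equal(full$recall, 0.5)
  expect_equal(part$recall, 1)
})

test_that("term-centric AUROC follows the Mann-Whitney tie convention", {
  dag <- flat_dag("HP:0000010")
  truth <- annotation_set(c("P1", "P2"), rep("HP:0000010", 2), "HPO")
  bench <- benchmark_set(truth, dag, proteins = c("P1", "P2", "P3"))
  # positives score 0.9 and 0.4, the negative 0.6 -> AUROC (1 + 0) / 2
  preds <- manual_preds(c("P1", "P2", "P3"), rep("HP:0000010", 3),
                        c(0.9, 0.4, 0.6))
  a <- term_centric_auroc(preds, bench)
  expect_equal(unname(a$term_auroc["HP:0000010"]), 0.5)
  # all scores identical -> 0.5 by the tie convention
  tie <- manual_preds(c("P1", "P2", "P3"), rep("HP:0000010", 3), rep(0.5, 3))
  expect_equal(unname(term_centric_auroc(tie, bench)$term_auroc), 0.5)
  # a term positive for every benchmark protein is skipped
  nobody <- benchmark_set(truth, dag)
  s <- term_centric_auroc(preds, nobody)
  expect_true("HP:0000010" %in% s$skipped_terms)
  expect_true(is.na(s$macro_auroc))
})

test_that("coverage is the predicted fraction of benchmark proteins", {
  dag <- flat_dag("HP:0000010")
  truth <- annotation_set(c("P1", "P2"), rep("HP:0000010", 2), "HPO")
  bench <- benchmark_set(truth, dag)
  preds <- manual_preds("P1", "HP:0000010", 0.9)
  expect_equal(coverage(preds, bench), 0.5)
  none <- manual_preds(character(), character(), numeric())
  expect_equal(coverage(none, bench), 0)
  empty_bench <- list(proteins = character())
  expect_condition(coverage(preds, empty_bench),
                   class = "pheno2go_domain_error")
})

test_that("evaluation reports serialize the curve and the summary", {
  cs <- two_protein_case()
  ev <- evaluate_predictions(cs$preds, cs$bench, cs$dag, cs$ic)
  prefix <- file.path(withr::local_tempdir(), "eval")
  write_evaluation_report(ev, prefix)
  expect_true(file.exists(paste0(prefix, "_curve.tsv")))
  js <- jsonlite::read_json(paste0(prefix, "_summary.json"))
  expect_equal(js$fmax, 6 / 7, tolerance = 1e-12)
  expect_named(js, c("fmax", "weighted_fmax", "smin", "coverage",
                     "macro_auroc", "mode", "n_terms_scored",
                     "skipped_terms"), ignore.order = TRUE)
})
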