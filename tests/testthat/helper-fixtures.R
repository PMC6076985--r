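# Shared fixtures: small ontologies built from OBO text so every test also
# exercises the parser.

toy_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: root", "",
    "[Term]", "id: HP:0000010", "name: a", "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000011", "name: b", "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000012", "name: c", "is_a: HP:0000010",
    "alt_id: HP:0000099", "",
    "[Term]", "id: HP:0000013", "name: d",
    "is_a: HP:0000010", "relationship: part_of HP:0000011", "")
}

# diamond: t4 -> {t2, t3} -> t1 (root)
diamond_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: r", "",
    "[Term]", "id: GO:0000002", "name: l", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: m", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: b",
    "is_a: GO:0000002", "is_a: GO:0000003", "")
}

# a flat phenotype ontology: one root, every other term a direct child
flat_dag <- function(terms, root = "HP:0000001") {
  stanza <- function(id, parent = NULL)
    c("[Term]", paste0("id: ", id), paste0("name: ", id),
      if (!is.null(parent)) paste0("is_a: ", parent), "")
  parse_obo(c("format-version: 1.2", "", stanza(root),
              unlist(lapply(terms, stanza, parent = root))))
}

# a term_ic with hand-picked weights
manual_ic <- function(...) {
  v <- c(...)
  structure(list(ic = v, source_count = NA_integer_), class = "term_ic")
}

# prediction_set from vectors, bypassing predict_hpo
manual_preds <- function(protein, term, score) {
  df <- data.frame(protein_id = protein, hpo_id = term, score = score,
                   via_go = rep(NA_character_, length(protein)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("prediction_set", "data.frame"))
}

# seeded sample() without disturbing the ambient RNG state
with_seed_sample <- function(seed, x, n) withr::with_seed(seed, sample(x, n))

# the spec's 2-protein hand-worked evaluation fixture:
# truth P1:{a,b}, P2:{a}; preds P1:{a@0.9, c@0.4}, P2:{a@0.9, b@0.4};
# flat DAG, ic identically 1
two_protein_case <- function() {
  dag <- flat_dag(c("HP:0000010", "HP:0000011", "HP:0000012"))
  truth <- annotation_set(c("P1", "P1", "P2"),
                          c("HP:0000010", "HP:0000011", "HP:0000010"), "HPO")
  preds <- manual_preds(c("P1", "P1", "P2", "P2"),
                        c("HP:0000010", "HP:0000012", "HP:0000010",
                          "HP:0000011"),
                        c(0.9, 0.4, 0.9, 0.4))
  list(dag = dag, bench = benchmark_set(truth, dag, mode = "full"),
       preds = preds,
       ic = manual_ic("HP:0000010" = 1, "HP:0000011" = 1, "HP:0000012" = 1))
}
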