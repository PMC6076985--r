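test_that("parse_obo builds terms, edges, roots and alt ids", {
  dag <- parse_obo(toy_obo())
  expect_s3_class(dag, "ontology_dag")
  expect_equal(nrow(dag$terms), 5L)
  expect_equal(dag$roots, "HP:0000001")
  expect_equal(sum(dag$edges$relation == "part_of"), 1L)
  expect_equal(resolve_term_ids(dag, c("HP:0000099", "HP:0000010")),
               c("HP:0000012", "HP:0000010"))
})

test_that("obsolete terms are retained but carry no edges", {
  lines <- c(toy_obo(),
             "[Term]", "id: HP:0000014", "name: gone",
             "is_a: HP:0000010", "is_obsolete: true", "")
  dag <- parse_obo(lines)
  expect_true(dag$terms$obsolete[dag$terms$id == "HP:0000014"])
  expect_false("HP:0000014" %in% dag$edges$child)
  expect_false("HP:0000014" %in% dag$roots)
})

test_that("structural problems raise classed errors", {
  dup <- c("format-version: 1.2", "",
           "[Term]", "id: HP:0000001", "name: r", "",
           "[Term]", "id: HP:0000001", "name: again", "")
  expect_condition(parse_obo(dup), class = "pheno2go_structural_error")
  dangling <- c("format-version: 1.2", "",
                "[Term]", "id: HP:0000001", "name: r",
                "is_a: HP:9999999", "")
  expect_condition(parse_obo(dangling), class = "pheno2go_structural_error")
  cyc <- c("format-version: 1.2", "",
           "[Term]", "id: HP:0000001", "name: a", "is_a: HP:0000002", "",
           "[Term]", "id: HP:0000002", "name: b", "is_a: HP:0000001", "")
  err <- tryCatch(parse_obo(cyc), condition = function(e) e)
  expect_s3_class(err, "pheno2go_structural_error")
  expect_match(conditionMessage(err), "cycle")
})

test_that("write_obo and parse_obo are mutually inverse", {
  dag <- parse_obo(toy_obo())
  f <- withr::local_tempfile()
  write_obo(dag, f)
  dag2 <- parse_obo(f)
  expect_equal(dag2$terms, dag$terms)
  expect_equal(dag2$edges[order(dag2$edges$child, dag2$edges$parent), ],
               dag$edges[order(dag$edges$child, dag$edges$parent), ],
               ignore_attr = TRUE)
  expect_equal(dag2$alt_ids, dag$alt_ids)
})

test_that("term_ancestors follows all paths in a diamond", {
  dag <- parse_obo(diamond_obo())
  expect_setequal(term_ancestors(dag, "GO:0000004"),
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_length(term_ancestors(dag, "GO:0000001"), 0L)
  expect_condition(term_ancestors(dag, "GO:1111111"),
                   class = "pheno2go_lookup_error")
})

test_that("propagation is closed under ancestors and idempotent", {
  dag <- parse_obo(toy_obo())
  a <- annotation_set(c("g1", "g2"), c("HP:0000013", "HP:0000012"), "HPO")
  p <- propagate_annotations(a, dag)
  # d is_a a, part_of b: g1 gains a, b, root
  expect_setequal(p$pairs$term[p$pairs$entity == "g1"],
                  c("HP:0000013", "HP:0000010", "HP:0000011", "HP:0000001"))
  expect_equal(propagate_annotations(p, dag)$pairs, p$pairs)
})

test_that("annotations to unknown terms are dropped or rejected", {
  dag <- parse_obo(toy_obo())
  a <- annotation_set(c("g1", "g1"), c("HP:0000010", "HP:7777777"), "HPO")
  expect_warning(p <- propagate_annotations(a, dag), "absent")
  expect_false("HP:7777777" %in% p$pairs$term)
  expect_condition(propagate_annotations(a, dag, on_missing = "error"),
                   class = "pheno2go_lookup_error")
})

test_that("information accretion matches the conditional-probability formula", {
  dag <- flat_dag(c("HP:0000010", "HP:0000011"))
  # 4 entities annotated; 1 of the 4 reaches HP:0000010, 2 reach HP:0000011
  a <- annotation_set(c("g1", "g2", "g3", "g4", "g1", "g2", "g3"),
                      c(rep("HP:0000001", 4), "HP:0000010",
                        rep("HP:0000011", 2)), "HPO")
  ic <- information_content(a, dag)
  expect_equal(unname(ic$ic["HP:0000001"]), 0)      # root: -log2(4/4)
  expect_equal(unname(ic$ic["HP:0000010"]), 2)      # -log2(1/4)
  expect_equal(unname(ic$ic["HP:0000011"]), 1)      # -log2(2/4)
  expect_equal(ic$source_count, 4L)
})

test_that("information_content rejects non-propagated input", {
  dag <- flat_dag("HP:0000010")
  a <- annotation_set("g1", "HP:0000010", "HPO")   # missing the root pair
  expect_condition(information_content(a, dag),
                   class = "pheno2go_precondition_error")
})
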