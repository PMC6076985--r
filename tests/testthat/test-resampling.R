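test_that("entity relabeling is a bijection preserving per-term counts", {
  cfg <- synthetic_config(n_genes = 100, n_hpo_terms = 20, n_go_terms = 30,
                          n_planted_pairs = 5, seed = 11)
  d <- generate_planted_dataset(cfg)
  r <- randomize_annotations(d$hpo, seed = 4)
  expect_equal(term_counts(r), term_counts(d$hpo))
  expect_setequal(unique(r$pairs$entity), unique(d$hpo$pairs$entity))
  expect_equal(randomize_annotations(d$hpo, seed = 4)$pairs, r$pairs)
  expect_false(identical(randomize_annotations(d$hpo, seed = 5)$pairs,
                         r$pairs))
})

test_that("build_null_mapping yields independent null tables", {
  cfg <- synthetic_config(n_genes = 100, n_hpo_terms = 20, n_go_terms = 30,
                          n_planted_pairs = 5, seed = 11)
  d <- generate_planted_dataset(cfg)
  nulls <- build_null_mapping(d$hpo, d$go, n_permutations = 3, seed = 1)
  expect_length(nulls, 3L)
  expect_true(all(vapply(nulls, function(x) attr(x, "provenance"),
                         "") == "null"))
  expect_false(identical(as.data.frame(nulls[[1]]),
                         as.data.frame(nulls[[2]])))
})

test_that("similarity histograms use half-open bins covering (0, 1]", {
  hpo <- annotation_set(c("g1", "g2", "g1"),
                        c("HP:0000010", "HP:0000010", "HP:0000011"), "HPO")
  go <- annotation_set(c("g1", "g2"), c("GO:0000100", "GO:0000101"), "GO")
  raw <- build_raw_mapping(hpo, go)   # S values: 2/3, 2/3, 1/2... per pair
  h <- s_histogram(raw, bin_width = 0.02)
  expect_equal(sum(h$counts), nrow(raw))
  expect_length(h$counts, 50L)
  expect_equal(h$bin_edges[c(1, 51)], c(0, 1))
  # a value equal to a bin edge falls in the lower bin: S = 0.5 -> bin 25
  tab <- raw[raw$S == 0.5, , drop = FALSE]
  if (nrow(tab)) {
    h2 <- s_histogram(tab)
    expect_equal(which(h2$counts > 0), 25L)
  }
})

test_that("ks_two_sample matches the known exact result and tie behavior", {
  r <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 0.1)
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  short <- ks_two_sample(c(1, 2), c(1, 2, 3))
  expect_equal(short$status, "insufficient")
  expect_true(is.na(short$p_value))
})

test_that("select_thresholds scans the full grid and records statuses", {
  cfg <- synthetic_config(n_genes = 300, n_hpo_terms = 40, n_go_terms = 60,
                          n_planted_pairs = 15, seed = 2)
  d <- generate_planted_dataset(cfg)
  raw <- build_raw_mapping(d$hpo, d$go)
  nulls <- build_null_mapping(d$hpo, d$go, seed = 1)
  grid <- select_thresholds(raw, nulls)
  expect_equal(dim(grid$p_values), c(5L, 7L))            # 35 cells
  expect_true(all(grid$status %in% c("ok", "insufficient")))
  expect_true(all(is.na(grid$p_values[grid$status == "insufficient"])))
  sel <- grid$selection
  expect_false(is.null(sel))
  # the selection is the first significant cell in the (S asc, n asc) scan
  first <- NULL
  for (si in seq_along(grid$s_grid)) for (ni in seq_along(grid$n_grid)) {
    if (is.null(first) && grid$status[ni, si] == "ok" &&
        grid$p_values[ni, si] < grid$alpha)
      first <- c(s_min = grid$s_grid[si], n_min = grid$n_grid[ni])
  }
  expect_equal(sel, first)
})

test_that("grid and histogram files serialize with their metadata", {
  cfg <- synthetic_config(n_genes = 200, n_hpo_terms = 30, n_go_terms = 40,
                          n_planted_pairs = 10, seed = 5)
  d <- generate_planted_dataset(cfg)
  raw <- build_raw_mapping(d$hpo, d$go)
  grid <- select_thresholds(raw, build_null_mapping(d$hpo, d$go, seed = 1))
  f <- withr::local_tempfile()
  write_threshold_grid(grid, f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "#alpha=0.01")))
  expect_true(any(grepl("^#selection=", lines)))
  expect_length(lines, 3 + 1 + 5)         # comments, header, 5 count rows
  write_histogram(s_histogram(raw), f)
  expect_length(readLines(f), 51L)
})
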