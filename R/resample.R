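#' Randomize an annotation table by relabeling its entities
#'
#' Applies one uniform random bijection over the entity set: every entity id
#' is replaced by another (or the same) id, so each term keeps exactly its
#' original number of annotated entities while all cross-table coupling
#' through shared genes is destroyed. Deterministic given the seed.
#'
#' @param annot an `annotation_set` (needs >= 1 entity; with a single entity
#'   the only bijection is the identity).
#' @param seed integer seed.
#' @return A relabeled `annotation_set`.
#' @export
randomize_annotations <- function(annot, seed) {
  ents <- sort(unique(annot$pairs$entity))
  if (length(ents) < 2L) return(annot)
  relab <- with_local_seed(seed, stats::setNames(sample(ents), ents))
  annotation_set(unname(relab[annot$pairs$entity]), annot$pairs$term,
                 annot$namespace)
}

#' Build randomized null mapping tables
#'
#' Generates `n_permutations` independent relabelings of the phenotype
#' annotation table (optionally also the GO table) and maps each against the
#' GO corpus. A single permutation mirrors the one-shot randomization used
#' on genome-scale corpora; pooling several stabilizes the null similarity
#' distribution on small corpora, and the size-capped test samples used by
#' [select_thresholds()] make the comparison insensitive to the pooling
#' factor.
#'
#' @param hpo_annot,go_annot the two training `annotation_set`s.
#' @param n_permutations number of relabelings (default 10).
#' @param seed integer seed; permutation k uses `seed + k`.
#' @param shuffle_go also relabel the GO table (independent bijection).
#' @return A list of `mapping_table`s with provenance `"null"`.
#' @export
build_null_mapping <- function(hpo_annot, go_annot, n_permutations = 10,
                               seed = 1, shuffle_go = FALSE) {
  stopifnot(n_permutations >= 1)
  lapply(seq_len(n_permutations), function(k) {
    h <- randomize_annotations(hpo_annot, seed + k)
    g <- if (shuffle_go) randomize_annotations(go_annot, seed + k + 5e5)
         else go_annot
    build_raw_mapping(h, g, provenance = "null")
  })
}

#' Histogram of co-occurrence similarities
#'
#' Bins the `S` values of the records passing the (s_min, n_min) filter into
#' half-open bins `(lo, hi]` covering `(0, 1]`; a value equal to a bin edge
#' falls in the lower bin.
#'
#' @param table a `mapping_table`.
#' @param s_min,n_min filter thresholds (records must satisfy both; a
#'   similarity threshold of 0 means `S > 0`).
#' @param bin_width bin width in (0, 1\]; default 0.02 (50 bins).
#' @return Object of class `s_histogram`: list with `bin_edges` (length
#'   nbins + 1) and `counts`.
#' @export
s_histogram <- function(table, s_min = 0, n_min = 1, bin_width = 0.02) {
  stopifnot(bin_width > 0, bin_width <= 1)
  nb <- ceiling(1 / bin_width - 1e-9)
  edges <- c(seq(0, by = bin_width, length.out = nb), 1)
  s <- filtered_s(table, s_min, n_min)
  idx <- bin_index(s, bin_width, nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = edges, counts = counts,
                 thresholds = c(s_min = s_min, n_min = n_min)),
            class = "s_histogram")
}

filtered_s <- function(table, s_min, n_min) {
  table$S[table$n >= n_min & table$S >= s_min & table$S > 0]
}

bin_index <- function(s, bin_width, nb) {
  pmin(nb, pmax(1L, ceiling(s / bin_width - 1e-9)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided two-sample KS statistic and p-value, exact for small samples
#' (including in the presence of ties) and asymptotic otherwise, via
#' [stats::ks.test()]. Samples shorter than `min_n` give status
#' `"insufficient"` with undefined statistic and p (the analogue of a NaN
#' cell in a threshold grid).
#'
#' @param a,b numeric sample vectors.
#' @param min_n minimum sample length for an `"ok"` result (default 3).
#' @return Object of class `ks_result`: list with `statistic`, `p_value`,
#'   `status` (`"ok"` or `"insufficient"`).
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6))  # D = 1, exact p = 0.1
#' @export
ks_two_sample <- function(a, b, min_n = 3) {
  if (length(a) < min_n || length(b) < min_n)
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          status = "insufficient"), class = "ks_result"))
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value), status = "ok"),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<ks_result> D = %.4f, p = %.4g\n", x$statistic, x$p_value))
  else cat("<ks_result> insufficient samples\n")
  invisible(x)
}

# Fixed-resolution summary of a binned S distribution: bin each similarity
# value to its bin midpoint, then take at most `sketch_size` equally spaced
# order statistics. The summary length is min(sketch_size, n records), so the
# KS comparison gains power with data mass but cannot be overwhelmed by it --
# the reason histograms are compared instead of the raw similarity values.
sketch_s <- function(s, bin_width, sketch_size) {
  if (!length(s)) return(numeric())
  nb <- ceiling(1 / bin_width - 1e-9)
  mids <- (seq_len(nb) - 0.5) * bin_width
  v <- sort(mids[bin_index(s, bin_width, nb)])
  m <- min(sketch_size, length(v))
  stats::quantile(v, probs = (seq_len(m) - 0.5) / m, type = 1, names = FALSE)
}

#' Select mapping-reliability thresholds from a permutation null
#'
#' For every combination of a similarity threshold and a co-annotation-count
#' threshold, both the original and the randomized mapping tables are
#' filtered, their similarity distributions are histogrammed and summarized
#' at fixed resolution, and the two summaries are compared with a two-sample
#' KS test. A cell is significant when its p-value is below `alpha`; cells
#' where either filtered table holds fewer than `min_records` mappings are
#' marked insufficient. The selection is the first significant cell scanning
#' similarity thresholds in ascending order and, within each, count
#' thresholds in ascending order — the lowest thresholds at which the
#' original mappings demonstrably diverge from chance.
#'
#' @param original the original `mapping_table`.
#' @param null a null `mapping_table` or a list of them (pooled).
#' @param s_grid similarity thresholds (default the 7-value grid
#'   `0, 0.1, ..., 0.6`, where 0 means `S > 0`).
#' @param n_grid count thresholds (default `1:5`).
#' @param alpha significance level (default 0.01).
#' @param bin_width histogram bin width (default 0.02).
#' @param sketch_size maximum KS sample length per side (default 20).
#' @param min_records minimum filtered mappings per side for a testable cell
#'   (default 3).
#' @return Object of class `threshold_grid`: list with `s_grid`, `n_grid`,
#'   `p_values` and `statistic` matrices (rows = count thresholds, columns =
#'   similarity thresholds), `status` matrix, `alpha`, and `selection`
#'   (named vector `c(s_min, n_min)` or `NULL`).
#' @export
select_thresholds <- function(original, null,
                              s_grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                              n_grid = 1:5, alpha = 0.01, bin_width = 0.02,
                              sketch_size = 20, min_records = 3) {
  stopifnot(length(s_grid) > 0, length(n_grid) > 0, alpha > 0, alpha < 1)
  nulls <- if (inherits(null, "mapping_table")) list(null) else null
  dn <- list(sprintf("n>=%g", n_grid), sprintf("S>=%g", s_grid))
  P <- matrix(NA_real_, length(n_grid), length(s_grid), dimnames = dn)
  D <- P
  status <- matrix("insufficient", length(n_grid), length(s_grid),
                   dimnames = dn)
  selection <- NULL
  for (si in seq_along(s_grid)) {
    for (ni in seq_along(n_grid)) {
      a <- filtered_s(original, s_grid[si], n_grid[ni])
      b <- unlist(lapply(nulls, filtered_s, s_grid[si], n_grid[ni]))
      if (length(a) < min_records || length(b) < min_records) next
      kt <- ks_two_sample(sketch_s(a, bin_width, sketch_size),
                          sketch_s(b, bin_width, sketch_size),
                          min_n = min_records)
      P[ni, si] <- kt$p_value
      D[ni, si] <- kt$statistic
      status[ni, si] <- kt$status
      if (is.null(selection) && kt$status == "ok" && kt$p_value < alpha)
        selection <- c(s_min = s_grid[si], n_min = n_grid[ni])
    }
  }
  structure(list(s_grid = s_grid, n_grid = n_grid, p_values = P,
                 statistic = D, status = status, alpha = alpha,
                 bin_width = bin_width, sketch_size = sketch_size,
                 min_records = min_records, selection = selection),
            class = "threshold_grid")
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat(sprintf("<threshold_grid> %d x %d cells, alpha = %g\n",
              length(x$n_grid), length(x$s_grid), x$alpha))
  print(round(x$p_values, 4))
  if (is.null(x$selection)) cat("no significant cell; selection absent\n")
  else cat(sprintf("selected thresholds: S >= %g, n >= %g\n",
                   x$selection[["s_min"]], x$selection[["n_min"]]))
  invisible(x)
}

#' Serialize a threshold grid as a TSV matrix
#'
#' Rows are count thresholds, columns similarity thresholds, cells the KS
#' p-values (`NA` for insufficient cells), after `#key=value` comments
#' recording alpha and the selection.
#'
#' @param grid a `threshold_grid`.
#' @param path file path or connection.
#' @return Invisibly, `path`.
#' @export
write_threshold_grid <- function(grid, path) {
  hdr <- c(sprintf("#alpha=%g", grid$alpha),
           sprintf("#bin_width=%g", grid$bin_width),
           if (!is.null(grid$selection))
             sprintf("#selection=s_min:%g,n_min:%g",
                     grid$selection[["s_min"]], grid$selection[["n_min"]])
           else "#selection=none",
           paste(c("n_threshold", sprintf("S>=%g", grid$s_grid)),
                 collapse = "\t"))
  body <- vapply(seq_along(grid$n_grid), function(i)
    paste(c(sprintf("n>=%g", grid$n_grid[i]),
            ifelse(is.na(grid$p_values[i, ]), "NA",
                   sprintf("%.6g", grid$p_values[i, ]))), collapse = "\t"),
    character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Serialize a similarity histogram as TSV
#' @param hist an `s_histogram`.
#' @param path file path or connection.
#' @return Invisibly, `path`.
#' @export
write_histogram <- function(hist, path) {
  nb <- length(hist$counts)
  writeLines(c("bin_lo\tbin_hi\tcount",
               sprintf("%.6g\t%.6g\t%d", hist$bin_edges[seq_len(nb)],
                       hist$bin_edges[-1L], hist$counts)), path)
  invisible(path)
}
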