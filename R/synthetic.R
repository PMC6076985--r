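#' Configuration for the planted-signal annotation generator
#'
#' Defaults describe the standard study corpus: 1,000 genes, 150 phenotype
#' and 200 GO terms, 50 planted term pairs each co-annotated to 3-6 genes,
#' and independent background annotations at a per-(gene, term) rate of
#' 0.002 — a sparse corpus in which true co-annotation signal sits on a thin
#' random background, the regime the mapping method assumes.
#'
#' @param n_genes,n_hpo_terms,n_go_terms corpus dimensions (all >= 1).
#' @param n_planted_pairs number of planted (HPO, GO) associations.
#' @param planted_coannotation_range `c(min, max)` genes per planted pair
#'   (min >= 1).
#' @param background_rate per-(gene, term) Bernoulli annotation probability
#'   in \[0, 1).
#' @param degree_exponent optional power-law exponent for heterogeneous gene
#'   degrees (`NULL`, the default, gives homogeneous background; a value
#'   such as 1.5 concentrates background on hub genes).
#' @param seed integer seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000, n_hpo_terms = 150,
                             n_go_terms = 200, n_planted_pairs = 50,
                             planted_coannotation_range = c(3, 6),
                             background_rate = 0.002,
                             degree_exponent = NULL, seed = 7) {
  ok <- n_genes >= 1 && n_hpo_terms >= 1 && n_go_terms >= 1 &&
    n_planted_pairs >= 0 && planted_coannotation_range[1] >= 1 &&
    planted_coannotation_range[2] >= planted_coannotation_range[1] &&
    background_rate >= 0 && background_rate < 1
  if (!ok) abort2("invalid synthetic configuration", "pheno2go_config_error")
  if (n_planted_pairs > min(n_hpo_terms, n_go_terms) ||
      planted_coannotation_range[2] > n_genes)
    abort2("planted load exceeds gene or term capacity",
           "pheno2go_config_error")
  structure(list(n_genes = n_genes, n_hpo_terms = n_hpo_terms,
                 n_go_terms = n_go_terms, n_planted_pairs = n_planted_pairs,
                 planted_coannotation_range = planted_coannotation_range,
                 background_rate = background_rate,
                 degree_exponent = degree_exponent, seed = seed),
            class = "synthetic_config")
}

#' Generate annotation corpora with planted co-annotation structure
#'
#' For each planted (HPO term, GO term) pair, a random gene subset of the
#' configured size is annotated with both terms; background annotations are
#' then added by independent Bernoulli draws over every (gene, term)
#' combination. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return List with `hpo` and `go` (`annotation_set`s) and `truth`, a data
#'   frame of planted pairs with their seeded gene sets (class
#'   `planted_truth`; column `genes` is a list column).
#' @export
generate_planted_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    hpo_terms <- sprintf("HP:%07d", seq_len(config$n_hpo_terms) + 1L)
    go_terms <- sprintf("GO:%07d", seq_len(config$n_go_terms) + 1L)
    k <- config$n_planted_pairs
    ph <- sample(hpo_terms, k); pg <- sample(go_terms, k)
    rng <- config$planted_coannotation_range
    sizes <- sample(seq(rng[1], rng[2]), k, replace = TRUE)
    seeded <- lapply(sizes, function(m) sort(sample(genes, m)))
    h_ent <- rep(ph, sizes); h_gene <- unlist(seeded)
    g_ent <- rep(pg, sizes)
    # background: Bernoulli per (gene, term); optional hub-gene weighting
    wt <- if (is.null(config$degree_exponent)) NULL else {
      w <- seq_len(config$n_genes)^(-config$degree_exponent)
      w / mean(w)
    }
    draw_bg <- function(terms) {
      nt <- length(terms)
      p <- if (is.null(wt)) config$background_rate
           else pmin(0.999, rep(wt, nt) * config$background_rate)
      hit <- which(stats::runif(config$n_genes * nt) < p)
      list(gene = genes[(hit - 1L) %% config$n_genes + 1L],
           term = terms[(hit - 1L) %/% config$n_genes + 1L])
    }
    bh <- draw_bg(hpo_terms); bg <- draw_bg(go_terms)
    list(hpo = annotation_set(c(h_gene, bh$gene), c(h_ent, bh$term), "HPO"),
         go = annotation_set(c(unlist(seeded), bg$gene), c(g_ent, bg$term),
                             "GO"),
         truth = structure(data.frame(hpo_id = ph, go_id = pg,
                                      n_seeded = sizes,
                                      stringsAsFactors = FALSE,
                                      genes = I(seeded)),
                           class = c("planted_truth", "data.frame")))
  })
}

#' Generate a random rooted ontology DAG
#'
#' A random tree over `n_terms` terms (term 1 is the single root, every
#' later term choosing an earlier parent, with `branching` controlling how
#' strongly recent terms are preferred) plus optional extra `is_a` edges to
#' other earlier terms; acyclic by construction.
#'
#' @param n_terms number of terms (>= 1).
#' @param branching mean branching factor steering parent choice.
#' @param seed integer seed.
#' @param prefix id prefix, `"HP"` or `"GO"`.
#' @param extra_edge_prob probability a non-root term gets one extra parent.
#' @return An `ontology_dag`.
#' @export
generate_toy_dag <- function(n_terms, branching = 2, seed = 1,
                             prefix = "HP", extra_edge_prob = 0.1) {
  stopifnot(n_terms >= 1)
  with_local_seed(seed, {
    ids <- sprintf("%s:%07d", prefix, seq_len(n_terms))
    terms <- data.frame(id = ids, name = sprintf("term %d", seq_len(n_terms)),
                        namespace = "", obsolete = FALSE,
                        stringsAsFactors = FALSE)
    ech <- character(); epa <- character()
    for (i in seq_len(n_terms)[-1]) {
      cand <- seq_len(i - 1L)
      # geometric-ish preference for recent terms keeps width ~ branching
      w <- branching^(cand - max(cand))
      p <- cand[sample.int(length(cand), 1L, prob = w)]
      ech <- c(ech, ids[i]); epa <- c(epa, ids[p])
      if (i > 2L && stats::runif(1) < extra_edge_prob) {
        q <- setdiff(cand, p)
        q <- q[sample.int(length(q), 1L)]
        ech <- c(ech, ids[i]); epa <- c(epa, ids[q])
      }
    }
    edges <- data.frame(child = ech, parent = epa,
                        relation = rep("is_a", length(ech)),
                        stringsAsFactors = FALSE)
    new_ontology_dag(terms, edges)
  })
}

#' Generate a benchmark with controllable score separability
#'
#' Samples truth from a planted corpus and draws one prediction score for
#' every (benchmark protein, phenotype term) combination, so every term is
#' scored for positives and negatives alike (a balanced fixture). A positive
#' pair scores `s + (1 - s) * U`, a negative `(1 - s) * U` with `U` uniform
#' on (0, 1). At separability 1 positives all score 1 and negatives fall
#' below the score floor (perfect separation); at 0 the two groups are
#' exchangeable, so term-centric AUROC centers on 0.5. Deterministic given
#' the seed.
#'
#' @param config a [synthetic_config()] (its phenotype corpus supplies the
#'   truth; proteins are its annotated genes).
#' @param separability value in \[0, 1\].
#' @param seed integer seed (defaults to the config seed).
#' @param score_floor predictions below this are dropped (default 0.01).
#' @return List with `predictions` (a `prediction_set`), `benchmark`
#'   (a `benchmark_set`, full mode) and `dag` (flat phenotype DAG used for
#'   propagation).
#' @export
generate_benchmark_case <- function(config, separability,
                                    seed = config$seed, score_floor = 0.01) {
  stopifnot(separability >= 0, separability <= 1)
  data <- generate_planted_dataset(config)
  truth <- data$hpo
  used_terms <- sort(unique(truth$pairs$term))
  root <- "HP:0000001"
  dag <- new_ontology_dag(
    data.frame(id = c(root, used_terms),
               name = c("root", used_terms), namespace = "",
               obsolete = FALSE, stringsAsFactors = FALSE),
    data.frame(child = used_terms, parent = rep(root, length(used_terms)),
               relation = rep("is_a", length(used_terms)),
               stringsAsFactors = FALSE))
  bench <- benchmark_set(truth, dag, mode = "full")
  with_local_seed(seed + 31L, {
    grid <- expand.grid(entity = bench$proteins, term = used_terms,
                        stringsAsFactors = FALSE)
    truth_key <- paste(bench$truth$pairs$entity, bench$truth$pairs$term)
    is_pos <- paste(grid$entity, grid$term) %in% truth_key
    u <- stats::runif(nrow(grid))
    score <- ifelse(is_pos, separability + (1 - separability) * u,
                    (1 - separability) * u)
    df <- data.frame(protein_id = grid$entity, hpo_id = grid$term,
                     score = pmin(score, 1), via_go = NA_character_,
                     stringsAsFactors = FALSE)
    df <- df[df$score >= score_floor, , drop = FALSE]
    df <- df[order(df$protein_id, df$hpo_id), , drop = FALSE]
    rownames(df) <- NULL
    list(predictions = new_prediction_set(df), benchmark = bench, dag = dag)
  })
}
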