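#' Configuration for a synthetic world
#'
#' A world bundles everything the pipeline consumes: a typed
#' planted-partition knowledge graph, a co-occurrence table, a templated
#' abstract corpus, and ground truth (true pairs, planted-missing held-out
#' pairs, co-mention-only decoys). Defaults describe a desk-scale study:
#' 200 proteins in 4 blocks with within/between edge probabilities
#' 0.3/0.01, 20 held-out pairs, 20 decoys. Co-occurrence p-values for
#' truly interacting pairs are drawn from `Beta(p_alpha, p_beta)` (default
#' Beta(1, 19), mean 0.05 — skewed low); null pairs draw from the uniform
#' Beta(1, 1).
#'
#' @param n_proteins number of protein nodes (default 200).
#' @param n_other_entities non-protein nodes (diseases, drugs, phenotypes)
#'   attached to random proteins (default 40).
#' @param n_short_names proteins given 4-character names, exercising the
#'   short-name filter (default 5).
#' @param n_blocks planted blocks (default 4).
#' @param p_within,p_between edge probabilities (0.3, 0.01).
#' @param p_alpha,p_beta Beta parameters for true-pair co-occurrence
#'   p-values (1, 19).
#' @param n_heldout within-block edges removed from the emitted graph and
#'   planted as discovery targets (default 20).
#' @param n_decoys co-mention-only pairs (default 20).
#' @param seed integer seed (default 0).
#' @return a list of class `kg_world_config`.
#' @export
world_config <- function(n_proteins = 200, n_other_entities = 40,
                         n_short_names = 5, n_blocks = 4,
                         p_within = 0.3, p_between = 0.01,
                         p_alpha = 1, p_beta = 19,
                         n_heldout = 20, n_decoys = 20, seed = 0) {
  stopifnot(n_proteins >= 2 * n_blocks, p_within >= 0, p_within <= 1,
            p_between >= 0, p_between <= 1, p_alpha > 0, p_beta > 0,
            n_heldout >= 0, n_decoys >= 0, n_short_names < n_proteins)
  structure(as.list(environment()), class = "kg_world_config")
}

protein_name <- function(i) sprintf("PRTN%03dA", i)

#' Generate a seeded synthetic world
#'
#' Builds the planted-partition graph over typed nodes, removes
#' `n_heldout` within-block edges as discovery targets, assigns
#' co-occurrence p-values (low for true and held-out pairs, uniform for
#' decoys and a matched pool of null pairs), and writes one templated
#' abstract per true/held-out pair (the two names linked by a verb from
#' [interaction_verbs()] in one sentence) and per decoy (the two names in
#' separate sentences, no linking verb). Fully reproducible from the seed.
#'
#' @param cfg a [world_config()].
#' @return a list of class `kg_world`: `graph` (`kg_graph`), `cooc`
#'   (co-occurrence tibble), `corpus` (tibble `doc_id`, `text`, `u`, `v`),
#'   `truth` (list of tibbles `true_pairs`, `held_out`, `decoys`),
#'   `object_p` (per-node query-term co-occurrence p), `config`.
#' @export
make_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "kg_world_config"))
  with_seed(cfg$seed, {
    ids <- sprintf("P%03d", seq_len(cfg$n_proteins))
    names_ <- protein_name(seq_len(cfg$n_proteins))
    if (cfg$n_short_names > 0) {
      short_idx <- seq_len(cfg$n_short_names)
      names_[short_idx] <- sprintf("SN%02d", short_idx)
    }
    block <- rep(seq_len(cfg$n_blocks), length.out = cfg$n_proteins)
    nodes <- tibble::tibble(id = ids, name = names_, type = "protein")

    other_types <- c("disease", "drug", "phenotype")
    if (cfg$n_other_entities > 0) {
      oid <- sprintf("O%03d", seq_len(cfg$n_other_entities))
      otype <- rep(other_types, length.out = cfg$n_other_entities)
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        id = oid, name = sprintf("%s_%03d", toupper(otype),
                                 seq_len(cfg$n_other_entities)),
        type = otype
      ))
    }

    cmb <- utils::combn(seq_len(cfg$n_proteins), 2)
    same <- block[cmb[1, ]] == block[cmb[2, ]]
    prob <- ifelse(same, cfg$p_within, cfg$p_between)
    present <- stats::rbinom(ncol(cmb), 1, prob) == 1
    pp_edges <- tibble::tibble(
      u = ids[cmb[1, present]], v = ids[cmb[2, present]],
      type = "interaction", within = same[present]
    )

    long_named <- ids[nchar(names_) >= 5]
    eligible <- which(pp_edges$within &
                      pp_edges$u %in% long_named & pp_edges$v %in% long_named)
    if (cfg$n_heldout > length(eligible)) {
      stop("infeasible config: ", cfg$n_heldout, " held-out pairs requested ",
           "but only ", length(eligible), " eligible within-block edges exist",
           call. = FALSE)
    }
    hold_idx <- sample(eligible, cfg$n_heldout)
    held_out <- pp_edges[hold_idx, c("u", "v")]
    kept_edges <- pp_edges[-hold_idx, c("u", "v", "type")]
    true_pairs <- kept_edges[, c("u", "v")]

    edges <- kept_edges
    if (cfg$n_other_entities > 0) {
      n_other <- cfg$n_other_entities
      oid <- sprintf("O%03d", seq_len(n_other))
      assoc <- purrr::map_dfr(seq_len(n_other), function(k) {
        tibble::tibble(u = oid[k], v = sample(ids, 3), type = "association")
      })
      edges <- dplyr::bind_rows(edges, assoc)
    }
    graph <- kg_graph(nodes, edges)

    all_edge_key <- pair_key(pp_edges$u, pp_edges$v)
    forbidden <- tibble::tibble(
      u = pmin(pp_edges$u, pp_edges$v), v = pmax(pp_edges$u, pp_edges$v)
    )
    decoy_pool <- sample_nonedges(long_named, cfg$n_decoys + nrow(true_pairs),
                                  exclude = forbidden)
    decoys <- decoy_pool[seq_len(cfg$n_decoys), ]
    null_pool <- decoy_pool[-seq_len(cfg$n_decoys), ]

    cooc <- dplyr::bind_rows(
      dplyr::mutate(true_pairs,
                    p_value = stats::rbeta(nrow(true_pairs),
                                           cfg$p_alpha, cfg$p_beta)),
      dplyr::mutate(held_out,
                    p_value = stats::rbeta(nrow(held_out),
                                           cfg$p_alpha, cfg$p_beta)),
      dplyr::mutate(decoys, p_value = stats::runif(nrow(decoys))),
      dplyr::mutate(null_pool, p_value = stats::runif(nrow(null_pool)))
    ) |> cooc_table()

    name_of <- function(id) nodes$name[match(id, nodes$id)]
    verbs <- interaction_verbs()
    tissues <- c("neurons", "hepatocytes", "fibroblasts", "myocytes",
                 "lymphocytes")
    docs_pos <- dplyr::bind_rows(true_pairs, held_out)
    pos_corpus <- tibble::tibble(
      u = docs_pos$u, v = docs_pos$v,
      text = paste0(
        "We report that ", name_of(docs_pos$u), " ",
        sample(verbs, nrow(docs_pos), replace = TRUE), " ",
        name_of(docs_pos$v), " in ",
        sample(tissues, nrow(docs_pos), replace = TRUE),
        ". This finding suggests a functional role in cellular signalling."
      )
    )
    decoy_corpus <- tibble::tibble(
      u = decoys$u, v = decoys$v,
      text = paste0(
        "Expression of ", name_of(decoys$u), " was profiled in ",
        sample(tissues, nrow(decoys), replace = TRUE),
        ". In a separate assay, ", name_of(decoys$v),
        " levels were also recorded across the cohort."
      )
    )
    corpus <- dplyr::bind_rows(pos_corpus, decoy_corpus)
    corpus <- tibble::tibble(
      doc_id = sprintf("D%05d", seq_len(nrow(corpus))),
      text = corpus$text, u = corpus$u, v = corpus$v
    )

    object_p <- tibble::tibble(
      object = ids, p_value = stats::rbeta(length(ids), 1, 9)
    )

    structure(list(
      graph = graph, cooc = cooc, corpus = corpus,
      truth = list(true_pairs = true_pairs, held_out = held_out,
                   decoys = decoys, null_pool = null_pool),
      object_p = object_p, block = stats::setNames(block, ids), config = cfg
    ), class = "kg_world")
  })
}

#' @export
print.kg_world <- function(x, ...) {
  cat("<kg_world> seed ", x$config$seed, ": ", sep = "")
  print(x$graph)
  invisible(x)
}

#' Summary statistics of a synthetic world
#'
#' @param world a `kg_world`.
#' @return a one-row tibble: node/edge counts, type count, counts of true/
#'   held-out/decoy pairs, corpus size, and the mean co-occurrence p-value
#'   by pair class.
#' @export
world_report <- function(world) {
  stopifnot(inherits(world, "kg_world"))
  cooc_p <- function(pairs) {
    if (nrow(pairs) == 0) return(NA_real_)
    j <- dplyr::inner_join(pairs, world$cooc, by = c("u", "v"))
    mean(j$p_value)
  }
  tibble::tibble(
    n_nodes = nrow(world$graph$nodes),
    n_types = dplyr::n_distinct(world$graph$nodes$type),
    n_edges = nrow(kg_pairs(world$graph)),
    n_true_pairs = nrow(world$truth$true_pairs),
    n_held_out = nrow(world$truth$held_out),
    n_decoys = nrow(world$truth$decoys),
    n_documents = nrow(world$corpus),
    mean_p_true = cooc_p(world$truth$true_pairs),
    mean_p_null = cooc_p(world$truth$null_pool)
  )
}

#' Labelled training pairs for the classifier from a world
#'
#' Positives are the emitted graph edges (true pairs); negatives are the
#' world's null pool (non-edges with uniform co-occurrence p). Held-out
#' pairs and decoys are excluded — they are discovery targets, not
#' training data.
#'
#' @param world a `kg_world`.
#' @return a tibble `u`, `v`, `label` (1/0).
#' @export
world_training_pairs <- function(world) {
  stopifnot(inherits(world, "kg_world"))
  dplyr::bind_rows(
    dplyr::mutate(world$truth$true_pairs, label = 1),
    dplyr::mutate(world$truth$null_pool, label = 0)
  )
}

#' Read a corpus written as JSON lines
#'
#' Inverse of the `corpus.jsonl` emitted by [write_world()]: one JSON
#' object per line with fields `doc_id`, `text`, `u`, `v`.
#'
#' @param path JSONL file path.
#' @return a corpus tibble.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path)
  purrr::map_dfr(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  })
}

#' @rdname read_corpus_jsonl
#' @param corpus a corpus tibble (`doc_id`, `text`, `u`, `v`).
#' @return (`write_corpus_jsonl`) the path, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(as.list(corpus[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Randomly rewire a graph's edges (structure-destroying control)
#'
#' Replaces the protein-protein edge set with uniformly random non-self
#' pairs of the same count over the same nodes. Used as a chance-level
#' control: a link predictor trained on a rewired graph should score
#' held-out links at chance.
#'
#' @param kg a `kg_graph`.
#' @param seed integer seed.
#' @return a `kg_graph` with the same nodes and a random edge set of equal
#'   size.
#' @export
rewire_edges <- function(kg, seed = 0) {
  stopifnot(inherits(kg, "kg_graph"))
  n_e <- nrow(kg_pairs(kg))
  with_seed(seed, {
    newp <- sample_nonedges(kg$nodes$id, n_e,
                            exclude = tibble::tibble(u = character(0),
                                                     v = character(0)))
    kg_graph(kg$nodes, dplyr::mutate(newp, type = "rewired"))
  })
}

#' Write all world artefacts to a directory
#'
#' Emits `nodes.csv`, `edges.csv`, `cooc.csv`, `corpus.jsonl`, and
#' `truth.json` in the formats consumed by the rest of the pipeline.
#'
#' @param world a `kg_world`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_graph(world$graph, file.path(dir, "nodes.csv"),
              file.path(dir, "edges.csv"))
  utils::write.csv(world$cooc, file.path(dir, "cooc.csv"),
                   row.names = FALSE, quote = FALSE)
  write_corpus_jsonl(world$corpus, file.path(dir, "corpus.jsonl"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
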