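#' Fixture-backed document store
#'
#' The document store is a contract, not a database: given a canonical
#' pair it returns the abstracts mentioning that pair, and given an object
#' it returns the co-occurrence p-value of that object with the query
#' term the store was built around. This implementation is backed by
#' in-memory tibbles (e.g. a synthetic-world corpus); a live literature
#' index can implement the same two accessors.
#'
#' @param corpus tibble with columns `doc_id`, `text`, `u`, `v`.
#' @param object_p optional tibble with columns `object`, `p_value`.
#' @return a list of class `kg_doc_store`.
#' @export
doc_store <- function(corpus, object_p = NULL) {
  corpus <- tibble::as_tibble(corpus)
  stopifnot(all(c("doc_id", "text", "u", "v") %in% names(corpus)))
  swap <- corpus$u > corpus$v
  tmp <- corpus$u[swap]; corpus$u[swap] <- corpus$v[swap]; corpus$v[swap] <- tmp
  structure(list(corpus = corpus, object_p = object_p),
            class = "kg_doc_store")
}

#' @rdname doc_store
#' @param store a `kg_doc_store`.
#' @param u,v pair of node ids (order-free).
#' @return (`store_query`) tibble of `doc_id`, `text` for documents
#'   mentioning the pair.
#' @export
store_query <- function(store, u, v) {
  stopifnot(inherits(store, "kg_doc_store"))
  a <- min(u, v); b <- max(u, v)
  store$corpus[store$corpus$u == a & store$corpus$v == b,
               c("doc_id", "text")]
}

#' @rdname doc_store
#' @param object an object id.
#' @return (`store_object_p`) the co-occurrence p-value with the store's
#'   query term, or `NA` if unknown.
#' @export
store_object_p <- function(store, object) {
  stopifnot(inherits(store, "kg_doc_store"))
  if (is.null(store$object_p)) return(NA_real_)
  p <- store$object_p$p_value[match(object, store$object_p$object)]
  if (length(p) == 0) NA_real_ else p
}

#' Keep objects significantly co-occurring with the query term
#'
#' Objects whose co-occurrence p-value with the query term is *strictly
#' greater* than `alpha` are filtered out; `p == alpha` exactly is kept.
#' Objects with no recorded p-value are dropped with a warning.
#'
#' @param objects character vector of object ids.
#' @param store a [doc_store()] with object-level p-values.
#' @param alpha significance threshold (default 0.05).
#' @return the surviving object ids.
#' @export
filter_by_cooccurrence <- function(objects, store, alpha = 0.05) {
  p <- vapply(objects, function(o) store_object_p(store, o), numeric(1))
  if (any(is.na(p))) {
    warning(sum(is.na(p)), " object(s) had no co-occurrence p-value and ",
            "were dropped", call. = FALSE)
  }
  objects[!is.na(p) & p <= alpha]
}

#' Enumerate unconnected node pairs
#'
#' All unordered pairs within `nodes` (default: every graph node) that are
#' not joined by an edge; canonical order, no self-pairs.
#'
#' @param kg a `kg_graph`.
#' @param nodes subset of node ids (default all).
#' @return a tibble `u`, `v`.
#' @export
enumerate_nonedges <- function(kg, nodes = NULL) {
  stopifnot(inherits(kg, "kg_graph"))
  nodes <- nodes %||% kg$nodes$id
  bad <- setdiff(nodes, kg$nodes$id)
  if (length(bad) > 0) {
    stop("unknown node(s): ", paste(utils::head(bad, 3), collapse = ", "),
         call. = FALSE)
  }
  if (length(nodes) < 2) return(tibble::tibble(u = character(0),
                                               v = character(0)))
  nodes <- sort(nodes)
  cmb <- utils::combn(nodes, 2)
  all_pairs <- tibble::tibble(u = cmb[1, ], v = cmb[2, ])
  dplyr::anti_join(all_pairs, kg_pairs(kg), by = c("u", "v"))
}

nature_keywords <- function() {
  list(
    regulatory = c("regulates", "activates", "inhibits", "represses",
                   "modulates", "induces expression"),
    `physical binding` = c("binds", "forms a complex with", "phosphorylates",
                           "physically associates"),
    `co-localization` = c("colocalizes", "co-localizes", "colocalization")
  )
}

# Assign an interaction-nature tag from the validator explanation by a
# small keyword map; "untyped" when no keyword class matches.
classify_nature <- function(explanation) {
  kw <- nature_keywords()
  for (nature in names(kw)) {
    if (any(stringr::str_detect(tolower(explanation),
                                stringr::fixed(kw[[nature]])))) {
      return(nature)
    }
  }
  "untyped"
}

#' Run the discovery pipeline on a graph
#'
#' Orchestrates the full workflow: enumerate unconnected pairs among
#' `nodes`, build fused pair features (pairs without a co-occurrence
#' entry are skipped), classify with the trained MLP, retrieve mentioning
#' abstracts for predicted positives, validate each abstract with the
#' backend, and confirm a pair when *any* document yields a YES verdict.
#' Confirmed pairs become new edges carrying the classifier probability,
#' supporting documents, verdicts with explanations, and an
#' interaction-nature tag derived from the explanation (regulatory /
#' physical binding / co-localization / untyped). Predicted positives
#' with no mentioning document are reported as unverified, never added.
#'
#' @param kg a `kg_graph` (the base network).
#' @param cooc a [cooc_table()].
#' @param store a [doc_store()].
#' @param embeddings node embedding matrix (from [train_gnn()]).
#' @param mlp_model a trained `kg_mlp_model`.
#' @param backend a `kg_backend`.
#' @param nodes candidate node subset (default: all protein-typed nodes,
#'   falling back to all nodes when no type column distinguishes them).
#' @return an object of class `kg_expanded_network`: list with `base`,
#'   `new_edges` (tibble: `u`, `v`, `probability`, `n_docs`, `n_yes`,
#'   `nature`, `doc_ids`, `explanation`), `unverified`, `verdicts`, and
#'   `audit` (stage-count funnel: candidates, with_cooccurrence,
#'   classified_positive, with_documents, confirmed).
#' @export
run_discovery <- function(kg, cooc, store, embeddings, mlp_model, backend,
                          nodes = NULL) {
  stopifnot(inherits(kg, "kg_graph"), inherits(mlp_model, "kg_mlp_model"),
            inherits(backend, "kg_backend"), inherits(store, "kg_doc_store"))
  if (is.null(nodes)) {
    nodes <- if ("protein" %in% kg$nodes$type) {
      kg$nodes$id[kg$nodes$type == "protein"]
    } else kg$nodes$id
  }
  candidates <- enumerate_nonedges(kg, nodes)
  feat <- pair_feature_matrix(candidates, embeddings, cooc)
  audit <- tibble::tibble(stage = "candidates", n = nrow(candidates))
  audit <- dplyr::add_row(audit, stage = "with_cooccurrence",
                          n = nrow(feat$pairs))

  if (nrow(feat$pairs) == 0) {
    empty <- tibble::tibble(u = character(0), v = character(0),
                            probability = numeric(0), n_docs = integer(0),
                            n_yes = integer(0), nature = character(0),
                            doc_ids = list(), explanation = character(0))
    audit <- dplyr::add_row(audit, stage = "classified_positive", n = 0L)
    audit <- dplyr::add_row(audit, stage = "with_documents", n = 0L)
    audit <- dplyr::add_row(audit, stage = "confirmed", n = 0L)
    return(structure(list(base = kg, new_edges = empty,
                          unverified = empty[, c("u", "v", "probability")],
                          verdicts = tibble::tibble(), audit = audit),
                     class = "kg_expanded_network"))
  }

  preds <- mlp_predict(mlp_model, feat$features, feat$pairs[, c("u", "v")])
  positives <- dplyr::filter(preds, .data$label)
  audit <- dplyr::add_row(audit, stage = "classified_positive",
                          n = nrow(positives))

  per_pair <- purrr::map(seq_len(nrow(positives)), function(i) {
    u <- positives$u[i]; v <- positives$v[i]
    docs <- store_query(store, u, v)
    if (nrow(docs) == 0) {
      return(list(status = "unverified", u = u, v = v,
                  probability = positives$probability[i]))
    }
    name_u <- kg$nodes$name[match(u, kg$nodes$id)]
    name_v <- kg$nodes$name[match(v, kg$nodes$id)]
    examples <- tibble::tibble(
      doc_id = docs$doc_id,
      prompt = purrr::map_chr(docs$text, build_instruction,
                              name_a = name_u, name_b = name_v)
    )
    verdicts <- validate_examples(examples, backend)
    verdicts$u <- u; verdicts$v <- v
    yes <- dplyr::filter(verdicts, .data$decision == "YES")
    list(status = if (nrow(yes) > 0) "confirmed" else "rejected",
         u = u, v = v, probability = positives$probability[i],
         verdicts = verdicts,
         n_docs = nrow(docs), n_yes = nrow(yes),
         doc_ids = yes$doc_id,
         explanation = if (nrow(yes) > 0) yes$explanation[1] else NA_character_)
  })

  status <- purrr::map_chr(per_pair, "status")
  audit <- dplyr::add_row(audit, stage = "with_documents",
                          n = sum(status != "unverified"))
  confirmed <- per_pair[status == "confirmed"]
  audit <- dplyr::add_row(audit, stage = "confirmed", n = length(confirmed))

  new_edges <- purrr::map_dfr(confirmed, function(x) {
    tibble::tibble(
      u = x$u, v = x$v, probability = x$probability,
      n_docs = x$n_docs, n_yes = x$n_yes,
      nature = classify_nature(x$explanation),
      doc_ids = list(x$doc_ids), explanation = x$explanation
    )
  })
  unverified <- purrr::map_dfr(per_pair[status == "unverified"], function(x) {
    tibble::tibble(u = x$u, v = x$v, probability = x$probability)
  })
  verdicts <- purrr::map_dfr(per_pair[status != "unverified"], "verdicts")

  structure(list(base = kg, new_edges = new_edges, unverified = unverified,
                 verdicts = verdicts, audit = audit),
            class = "kg_expanded_network")
}

#' @export
print.kg_expanded_network <- function(x, ...) {
  cat("<kg_expanded_network> ", nrow(x$new_edges), " new edges over a ",
      nrow(kg_pairs(x$base)), "-edge base graph\n", sep = "")
  print(x$audit)
  invisible(x)
}

#' @rdname run_discovery
#' @param x,object a `kg_expanded_network`.
#' @param ... unused.
#' @export
tidy.kg_expanded_network <- function(x, ...) x$new_edges

#' @rdname run_discovery
#' @export
glance.kg_expanded_network <- function(x, ...) {
  tidyr::pivot_wider(x$audit, names_from = "stage", values_from = "n")
}

#' @rdname run_discovery
#' @export
autoplot.kg_expanded_network <- function(object, ...) {
  df <- dplyr::mutate(object$audit,
                      stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.2) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, .15))) +
    ggplot2::labs(x = "pairs", y = NULL, title = "Discovery funnel")
}

#' Serialise an expanded network to JSON (plus an edge-list CSV)
#'
#' @param net a `kg_expanded_network`.
#' @param json_path output JSON path.
#' @param csv_path optional edge-list CSV path.
#' @return `json_path`, invisibly.
#' @export
write_expanded_network <- function(net, json_path, csv_path = NULL) {
  stopifnot(inherits(net, "kg_expanded_network"))
  payload <- list(
    base_edges = kg_pairs(net$base),
    new_edges = dplyr::mutate(net$new_edges,
                              doc_ids = purrr::map_chr(.data$doc_ids,
                                                       paste, collapse = ";")),
    audit = net$audit
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) {
    utils::write.csv(payload$new_edges[, c("u", "v", "probability", "nature")],
                     csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
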