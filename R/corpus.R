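#' Gold-standard relation documents
#'
#' A gold document is an annotated abstract: its text, the entity mentions
#' found in it (with character spans), and typed relations between those
#' entities. Corpora in this form (one JSON record per document) are the
#' evaluation substrate for the context validator.
#'
#' @param doc_id document identifier.
#' @param text abstract text.
#' @param entities data frame with columns `mention`, `entity_id`, `start`,
#'   `end` (1-based character spans into `text`).
#' @param relations data frame with columns `a`, `b` (entity ids) and
#'   `type` (e.g. `"PPI"`); may have zero rows.
#' @return a list of class `kg_gold_document`.
#' @export
gold_document <- function(doc_id, text, entities, relations = NULL) {
  entities <- tibble::as_tibble(entities)
  stopifnot(all(c("mention", "entity_id", "start", "end") %in% names(entities)))
  if (is.null(relations) || nrow(tibble::as_tibble(relations)) == 0) {
    relations <- tibble::tibble(a = character(0), b = character(0),
                                type = character(0))
  } else {
    relations <- tibble::as_tibble(relations)
    stopifnot(all(c("a", "b", "type") %in% names(relations)))
  }
  if (nrow(entities) > 0 &&
      (any(entities$start < 1) || any(entities$end > nchar(text)))) {
    stop("entity span outside text bounds in document ", doc_id,
         call. = FALSE)
  }
  dangling <- setdiff(c(relations$a, relations$b), entities$entity_id)
  if (length(dangling) > 0) {
    stop("relation references unknown entity '", dangling[1],
         "' in document ", doc_id, call. = FALSE)
  }
  structure(list(doc_id = as.character(doc_id), text = text,
                 entities = entities, relations = relations),
            class = "kg_gold_document")
}

#' Read / write a gold corpus as JSON
#'
#' The on-disk schema is a JSON object with a `documents` array; each
#' document carries `doc_id`, `text`, `entities[]`, `relations[]`.
#'
#' @param path JSON file path.
#' @return a list of `kg_gold_document`s.
#' @export
read_gold_corpus <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map(raw$documents, function(d) {
    gold_document(
      doc_id = d$doc_id, text = d$text,
      entities = purrr::map_dfr(d$entities, tibble::as_tibble),
      relations = if (length(d$relations) > 0) {
        purrr::map_dfr(d$relations, tibble::as_tibble)
      } else NULL
    )
  })
}

#' @rdname read_gold_corpus
#' @param docs list of `kg_gold_document`s.
#' @return (`write_gold_corpus`) the path, invisibly.
#' @export
write_gold_corpus <- function(docs, path) {
  out <- list(documents = purrr::map(docs, function(d) {
    list(doc_id = d$doc_id, text = d$text,
         entities = purrr::transpose(as.list(d$entities)),
         relations = purrr::transpose(as.list(d$relations)))
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = FALSE,
                       digits = NA)
  invisible(path)
}

#' The default few-shot instruction blocks
#'
#' Two worked examples using drug-drug interactions (deliberately outside
#' the protein domain, to teach the output format without biasing the
#' model toward particular protein pairs). Each block shows a context, the
#' question, and a correctly formatted answer beginning with YES or NO,
#' followed by a confidence level and an explanation.
#'
#' @return character vector of two example blocks.
#' @export
default_few_shot <- function() {
  c(
    paste0(
      "Example 1.\n",
      "Context: Co-administration of warfarin with fluconazole markedly ",
      "increased warfarin plasma levels, and fluconazole inhibits the ",
      "CYP2C9-mediated metabolism of warfarin.\n",
      "Question: Using only the provided context, do warfarin and ",
      "fluconazole interact? Begin your answer with YES or NO, state a ",
      "confidence level (high, medium, or low), and explain your ",
      "conclusion.\n",
      "Answer: YES. Confidence: high. The context states that fluconazole ",
      "inhibits the metabolism of warfarin, a direct pharmacokinetic ",
      "interaction."
    ),
    paste0(
      "Example 2.\n",
      "Context: Patients in the cohort received either metformin or ",
      "lisinopril. Metformin use was recorded in the diabetes subgroup. ",
      "Lisinopril use was recorded in the hypertension subgroup.\n",
      "Question: Using only the provided context, do metformin and ",
      "lisinopril interact? Begin your answer with YES or NO, state a ",
      "confidence level (high, medium, or low), and explain your ",
      "conclusion.\n",
      "Answer: NO. Confidence: high. The two drugs are only mentioned in ",
      "separate patient subgroups; the context reports no interaction ",
      "between them."
    )
  )
}

#' Build an instruction prompt for a candidate pair
#'
#' Assembles, in order: the few-shot example blocks, the document context,
#' a question asking whether the named pair interacts using only the
#' provided context, a request for a confidence level (high, medium, low),
#' and a request for an explanation. The required answer format — a
#' leading YES or NO indicator — is stated in the question.
#'
#' @param context document text (non-empty).
#' @param name_a,name_b the two entity names (non-empty).
#' @param few_shot character vector of example blocks
#'   (default [default_few_shot()]).
#' @return the prompt string.
#' @export
build_instruction <- function(context, name_a, name_b,
                              few_shot = default_few_shot()) {
  if (is.null(context) || !nzchar(trimws(context))) {
    stop("`context` must be a non-empty document text", call. = FALSE)
  }
  stopifnot(nzchar(name_a), nzchar(name_b))
  paste0(
    paste(few_shot, collapse = "\n\n"),
    "\n\nContext: ", context,
    "\nQuestion: Using only the provided context, do ", name_a, " and ",
    name_b, " interact? Begin your answer with YES or NO, state a ",
    "confidence level (high, medium, or low), and explain your conclusion.",
    "\nAnswer:"
  )
}

#' Parse a gold corpus into labelled instruction examples
#'
#' Documents whose `relations` list is empty (entity markup only, no
#' interaction information) are dropped. Positive examples are exactly the
#' relation pairs typed `"PPI"`. When `include_negatives = TRUE`,
#' co-mentioned entity pairs *without* a PPI relation in the same document
#' are added as negatives.
#'
#' @param docs list of `kg_gold_document`s.
#' @param include_negatives also emit candidate negative pairs?
#' @param few_shot example blocks for [build_instruction()].
#' @return a tibble with columns `doc_id`, `name_a`, `name_b`, `label`
#'   (`"positive"`/`"negative"`), `prompt`.
#' @export
parse_gold <- function(docs, include_negatives = FALSE,
                       few_shot = default_few_shot()) {
  rows <- purrr::map(docs, function(d) {
    stopifnot(inherits(d, "kg_gold_document"))
    if (nrow(d$relations) == 0) return(NULL)
    name_of <- function(id) d$entities$mention[match(id, d$entities$entity_id)]
    ppi <- d$relations[d$relations$type == "PPI", , drop = FALSE]
    pos <- NULL
    if (nrow(ppi) > 0) {
      pos <- tibble::tibble(
        doc_id = d$doc_id,
        name_a = name_of(ppi$a), name_b = name_of(ppi$b),
        label = "positive"
      )
    }
    neg <- NULL
    if (include_negatives && nrow(d$entities) >= 2) {
      ids <- unique(d$entities$entity_id)
      cmb <- utils::combn(sort(ids), 2)
      rel_key <- pair_key(ppi$a, ppi$b)
      keep <- !(pair_key(cmb[1, ], cmb[2, ]) %in% rel_key)
      if (any(keep)) {
        neg <- tibble::tibble(
          doc_id = d$doc_id,
          name_a = name_of(cmb[1, keep]), name_b = name_of(cmb[2, keep]),
          label = "negative"
        )
      }
    }
    out <- dplyr::bind_rows(pos, neg)
    if (is.null(out) || nrow(out) == 0) return(NULL)
    out$prompt <- purrr::map2_chr(out$name_a, out$name_b, function(a, b) {
      build_instruction(d$text, a, b, few_shot)
    })
    out
  })
  dplyr::bind_rows(rows)
}

#' Negative instruction examples from non-interacting pairs
#'
#' For each experimentally non-interacting pair, one mentioning abstract
#' is drawn (seeded, uniformly) from the document store and turned into a
#' negative-labelled instruction example. Pairs with no mentioning
#' document are skipped with a warning.
#'
#' @param pairs tibble of pairs (`u`, `v` — used both as ids and display
#'   names unless `names` columns `name_u`, `name_v` are present).
#' @param store a [doc_store()].
#' @param seed integer seed for the per-pair document choice.
#' @param few_shot example blocks.
#' @return a tibble like [parse_gold()]'s output, all labels `"negative"`.
#' @export
pair_negatives <- function(pairs, store, seed = 1,
                           few_shot = default_few_shot()) {
  pairs <- tibble::as_tibble(pairs)
  with_seed(seed, {
    rows <- purrr::pmap(pairs, function(u, v, ...) {
      extra <- list(...)
      docs <- store_query(store, u, v)
      if (nrow(docs) == 0) {
        warning("pair (", u, ", ", v, ") has no mentioning document; skipped",
                call. = FALSE)
        return(NULL)
      }
      pick <- docs[sample.int(nrow(docs), 1), ]
      name_a <- extra$name_u %||% u
      name_b <- extra$name_v %||% v
      tibble::tibble(
        doc_id = pick$doc_id, name_a = name_a, name_b = name_b,
        label = "negative",
        prompt = build_instruction(pick$text, name_a, name_b, few_shot)
      )
    })
    dplyr::bind_rows(rows)
  })
}
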