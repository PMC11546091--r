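test_that("documents without relation information are dropped", {
  markup_only <- gold_document(
    doc_id = "d0", text = "KINA1 and KINB2 were assayed.",
    entities = data.frame(mention = c("KINA1", "KINB2"),
                          entity_id = c("e1", "e2"),
                          start = c(1, 11), end = c(5, 15))
  )
  out <- parse_gold(list(markup_only, gold_doc_simple()))
  expect_equal(unique(out$doc_id), "d1")
})

test_that("positive examples are exactly the PPI-typed relations", {
  one_ppi <- gold_doc_simple()
  non_ppi <- gold_doc_simple(doc_id = "d2", rel_type = "regulation")
  out <- parse_gold(list(one_ppi, non_ppi))
  expect_equal(sum(out$label == "positive"), 1)
  expect_equal(out$doc_id[out$label == "positive"], "d1")
})

test_that("co-mentioned non-PPI pairs appear only as requested negatives", {
  doc <- gold_document(
    doc_id = "d3",
    text = "KINA1 binds KINB2. KINC3 was also detected.",
    entities = data.frame(
      mention = c("KINA1", "KINB2", "KINC3"),
      entity_id = c("e1", "e2", "e3"),
      start = c(1, 13, 20), end = c(5, 17, 24)
    ),
    relations = data.frame(a = "e1", b = "e2", type = "PPI")
  )
  pos_only <- parse_gold(list(doc))
  expect_equal(nrow(pos_only), 1)
  both <- parse_gold(list(doc), include_negatives = TRUE)
  expect_equal(sum(both$label == "negative"), 2)  # (e1,e3), (e2,e3)
})

test_that("dangling relation endpoints are integrity errors naming the document", {
  expect_error(
    gold_document(
      doc_id = "dX", text = "KINA1 binds KINB2.",
      entities = data.frame(mention = "KINA1", entity_id = "e1",
                            start = 1, end = 5),
      relations = data.frame(a = "e1", b = "eZ", type = "PPI")
    ),
    "dX"
  )
  expect_error(
    gold_document(
      doc_id = "dY", text = "short",
      entities = data.frame(mention = "LONGMENTION", entity_id = "e1",
                            start = 1, end = 50)
    ),
    "span outside"
  )
})

test_that("instruction prompts contain every component in order", {
  ctx <- "KINA1 binds KINB2 in fibroblasts."
  prompt <- build_instruction(ctx, "KINA1", "KINB2")
  # two few-shot blocks by default
  expect_equal(length(gregexpr("Example [0-9]", prompt)[[1]]), 2)
  # context appears verbatim
  expect_true(grepl(ctx, prompt, fixed = TRUE))
  # question restricted to provided context, leading-indicator format
  expect_true(grepl("Using only the provided context", prompt, fixed = TRUE))
  expect_true(grepl("Begin your answer with YES or NO", prompt, fixed = TRUE))
  expect_true(grepl("confidence level (high, medium, or low)", prompt,
                    fixed = TRUE))
  # ordering: few-shot < context < question
  pos_ex <- max(gregexpr("Example", prompt, fixed = TRUE)[[1]])
  pos_ctx <- max(gregexpr("Context: ", prompt, fixed = TRUE)[[1]])
  pos_q <- max(gregexpr("Question: ", prompt, fixed = TRUE)[[1]])
  expect_true(pos_ex < pos_ctx && pos_ctx < pos_q)
  expect_error(build_instruction("  ", "A", "B"), "non-empty")
})

test_that("every parsed example round-trips names and context by substring", {
  w <- small_world(4)
  st <- doc_store(w$corpus)
  name_of <- function(id) w$graph$nodes$name[match(id, w$graph$nodes$id)]
  pairs <- head(w$truth$true_pairs, 5)
  for (i in seq_len(nrow(pairs))) {
    docs <- store_query(st, pairs$u[i], pairs$v[i])
    prompt <- build_instruction(docs$text[1],
                                name_of(pairs$u[i]), name_of(pairs$v[i]))
    expect_true(grepl(docs$text[1], prompt, fixed = TRUE))
    expect_true(grepl(name_of(pairs$u[i]), prompt, fixed = TRUE))
    expect_true(grepl(name_of(pairs$v[i]), prompt, fixed = TRUE))
  }
})

test_that("pair_negatives draws one seeded document per pair and skips undocumented pairs", {
  corpus <- tibble::tibble(
    doc_id = c("k1", "k2", "k3"),
    text = c("AAAA1 and BBBB2 appear here.",
             "AAAA1 and BBBB2 appear again.",
             "AAAA1 and BBBB2 a third time."),
    u = "a", v = "b"
  )
  st <- doc_store(corpus)
  pairs <- tibble::tibble(u = c("a", "x"), v = c("b", "y"),
                          name_u = c("AAAA1", "XXXX1"),
                          name_v = c("BBBB2", "YYYY2"))
  expect_warning(out <- pair_negatives(pairs, st, seed = 7), "no mentioning")
  expect_equal(nrow(out), 1)
  expect_equal(out$label, "negative")
  out2 <- suppressWarnings(pair_negatives(pairs, st, seed = 7))
  expect_identical(out, out2)  # seeded choice is deterministic

  # n documented pairs -> n examples
  pairs_ok <- pairs[1, ]
  expect_equal(nrow(pair_negatives(pairs_ok, st, seed = 1)), 1)
})

test_that("gold corpora round-trip through the JSON schema", {
  docs <- list(gold_doc_simple(),
               gold_doc_simple(doc_id = "d9", rel_type = "regulation"))
  path <- withr::local_tempfile(fileext = ".json")
  write_gold_corpus(docs, path)
  back <- read_gold_corpus(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$doc_id, docs[[1]]$doc_id)
  expect_equal(back[[1]]$text, docs[[1]]$text)
  expect_equal(back[[1]]$relations$type, "PPI")
  expect_equal(back[[2]]$entities$mention, docs[[2]]$entities$mention)
})
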