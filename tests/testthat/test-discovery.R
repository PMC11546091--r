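test_that("co-occurrence filtering keeps p <= alpha and drops unknowns", {
  st <- doc_store(
    tibble::tibble(doc_id = character(0), text = character(0),
                   u = character(0), v = character(0)),
    object_p = tibble::tibble(object = c("a", "b", "c"),
                              p_value = c(0.04, 0.06, 0.05))
  )
  expect_equal(filter_by_cooccurrence(c("a", "b"), st), "a")
  # boundary: exactly alpha is kept (the filter removes strictly greater)
  expect_equal(filter_by_cooccurrence(c("b", "c"), st), "c")
  expect_warning(out <- filter_by_cooccurrence(c("a", "zz"), st), "dropped")
  expect_equal(out, "a")

  # survivors equal a brute-force scan
  withr::with_seed(20, {
    objs <- sprintf("o%02d", 1:40)
    ps <- runif(40)
  })
  st2 <- doc_store(st$corpus, tibble::tibble(object = objs, p_value = ps))
  expect_equal(filter_by_cooccurrence(objs, st2), objs[ps <= 0.05])
})

test_that("non-edge enumeration covers the complement of the edge set", {
  # complete triangle -> nothing to enumerate
  tri <- kg_graph(
    nodes = data.frame(id = c("a", "b", "c"),
                       name = c("AAAA1", "BBBB1", "CCCC1"), type = "protein"),
    edges = data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"))
  )
  expect_equal(nrow(enumerate_nonedges(tri)), 0)

  # five isolated nodes -> all C(5,2) pairs
  iso <- kg_graph(nodes = data.frame(id = letters[1:5],
                                     name = paste0(LETTERS[1:5], "XXXX"),
                                     type = "protein"))
  ne <- enumerate_nonedges(iso)
  expect_equal(nrow(ne), 10)
  expect_true(all(ne$u < ne$v))

  # random graph: count equals C(n,2) - |E|
  kg <- er_graph(25, 60, seed = 9)
  expect_equal(nrow(enumerate_nonedges(kg)), choose(25, 2) - 60)

  # subset restriction
  sub <- letters[1:3]
  expect_equal(nrow(enumerate_nonedges(iso, sub)), 3)
  expect_error(enumerate_nonedges(iso, c("a", "zz")), "unknown")
})

test_that("discovery recovers planted pairs, rejects decoys, and audits stages", {
  w <- small_world(1)
  kg <- filter_short_names(project_unipartite(w$graph, "protein"))
  fit <- train_gnn(kg, gnn_config(seed = 1))
  tp <- world_training_pairs(w)
  pf <- pair_feature_matrix(tp[, c("u", "v")], fit$embeddings, w$cooc)
  labs <- dplyr::inner_join(pf$pairs[, c("u", "v")], tp,
                            by = c("u", "v"))$label
  mlp <- train_mlp(pf$features, labs,
                   mlp_config(max_epochs = 80, patience = 30, seed = 2))
  st <- doc_store(w$corpus, tibble::tibble(object = w$object_p$object,
                                           p_value = w$object_p$p_value))
  net <- run_discovery(kg, w$cooc, st, fit$embeddings, mlp, mock_backend())

  # audit funnel is monotonically non-increasing
  expect_true(all(diff(net$audit$n) <= 0))
  expect_equal(net$audit$stage,
               c("candidates", "with_cooccurrence", "classified_positive",
                 "with_documents", "confirmed"))

  # no decoy co-mention pair is admitted (mock backend rejects them)
  admitted_decoys <- dplyr::inner_join(net$new_edges, w$truth$decoys,
                                       by = c("u", "v"))
  expect_equal(nrow(admitted_decoys), 0)

  # every new edge has at least one YES verdict and is not a base edge
  if (nrow(net$new_edges) > 0) {
    expect_true(all(net$new_edges$n_yes >= 1))
    overlap <- dplyr::inner_join(net$new_edges[, c("u", "v")], kg_pairs(kg),
                                 by = c("u", "v"))
    expect_equal(nrow(overlap), 0)
  }

  # predicted positives without documents are reported unverified, not added
  if (nrow(net$unverified) > 0) {
    in_new <- dplyr::inner_join(net$unverified[, c("u", "v")],
                                net$new_edges[, c("u", "v")],
                                by = c("u", "v"))
    expect_equal(nrow(in_new), 0)
  }

  # deterministic rerun reproduces the expanded network exactly
  net2 <- run_discovery(kg, w$cooc, st, fit$embeddings, mlp, mock_backend())
  expect_identical(net$new_edges, net2$new_edges)
  expect_identical(net$audit, net2$audit)
})

test_that("an empty candidate set leaves the network unchanged", {
  tri <- kg_graph(
    nodes = data.frame(id = c("a", "b", "c"),
                       name = c("AAAA1", "BBBB1", "CCCC1"), type = "protein"),
    edges = data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"))
  )
  emb <- matrix(rnorm(3 * 64), 3, 64, dimnames = list(c("a", "b", "c"), NULL))
  cooc <- cooc_table(data.frame(u = "a", v = "b", p_value = 0.1))
  st <- doc_store(tibble::tibble(doc_id = character(0), text = character(0),
                                 u = character(0), v = character(0)))
  dims <- c(129, 8, 1)
  mlp <- new_mlp_model(list(W = list(matrix(0, 129, 8), matrix(0, 8, 1)),
                            b = list(rep(0, 8), 0)))
  net <- run_discovery(tri, cooc, st, emb, mlp, mock_backend())
  expect_equal(nrow(net$new_edges), 0)
  expect_identical(net$base, tri)
  expect_equal(net$audit$n[1], 0)
})

test_that("interaction nature tags follow the explanation keyword map", {
  expect_equal(kgppi:::classify_nature("A regulates B strongly"), "regulatory")
  expect_equal(kgppi:::classify_nature("X binds Y directly"),
               "physical binding")
  expect_equal(kgppi:::classify_nature("the pair colocalizes in the nucleus"),
               "co-localization")
  expect_equal(kgppi:::classify_nature("they interact somehow"), "untyped")
})

test_that("expanded networks serialise to JSON plus an edge-list CSV", {
  tri <- kg_graph(
    nodes = data.frame(id = c("a", "b", "c"),
                       name = c("AAAA1", "BBBB1", "CCCC1"), type = "protein"),
    edges = data.frame(u = "a", v = "b")
  )
  net <- structure(list(
    base = tri,
    new_edges = tibble::tibble(u = "a", v = "c", probability = 0.9,
                               n_docs = 1L, n_yes = 1L, nature = "regulatory",
                               doc_ids = list("d1"), explanation = "x"),
    unverified = tibble::tibble(), verdicts = tibble::tibble(),
    audit = tibble::tibble(stage = "confirmed", n = 1L)
  ), class = "kg_expanded_network")
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_expanded_network(net, jp, cp)
  payload <- jsonlite::read_json(jp)
  expect_equal(payload$new_edges[[1]]$u, "a")
  csv <- utils::read.csv(cp)
  expect_equal(csv$nature, "regulatory")
})
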