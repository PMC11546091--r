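test_that("load_graph builds a canonical graph from minimal tables", {
  kg <- load_graph(
    data.frame(id = c("a", "b"), name = c("ALPHA", "BETAX"), type = "protein"),
    data.frame(u = "a", v = "b", type = "binding")
  )
  expect_s3_class(kg, "kg_graph")
  expect_equal(nrow(kg$nodes), 2)
  expect_equal(nrow(kg$edges), 1)
})

test_that("symmetric duplicate edges collapse to one canonical edge", {
  kg <- load_graph(
    data.frame(id = c("a", "b"), name = c("ALPHA", "BETAX"), type = "protein"),
    data.frame(u = c("a", "b"), v = c("b", "a"), type = "assoc")
  )
  expect_equal(nrow(kg$edges), 1)
  expect_true(all(kg$edges$u < kg$edges$v))
})

test_that("per-type census matches an independent row scan", {
  types <- rep(paste0("t", 1:11), times = 1:11)
  withr::with_seed(5, types <- sample(types))
  nodes <- data.frame(id = sprintf("n%02d", seq_along(types)),
                      name = sprintf("NAME%02d", seq_along(types)),
                      type = types)
  kg <- load_graph(nodes, data.frame(u = character(0), v = character(0)))
  census <- kg_census(kg)
  independent <- table(types)
  expect_equal(nrow(census), 11)
  for (tt in names(independent)) {
    expect_equal(census$n[census$type == tt], unname(independent[[tt]]))
  }
})

test_that("integrity violations are rejected with informative errors", {
  nodes <- data.frame(id = c("a", "b"), name = c("ALPHA", "BETAX"),
                      type = "protein")
  expect_error(load_graph(nodes, data.frame(u = "a", v = "zz")),
               "unknown node")
  expect_error(load_graph(nodes, data.frame(u = "a", v = "a")), "self-loop")
  expect_error(load_graph(nodes, data.frame(u = c("a", ""), v = c("b", "b"))),
               "row 2")
  expect_error(
    load_graph(data.frame(id = c("a", "a"), name = c("X1234", "Y1234"),
                          type = "protein"),
               data.frame(u = character(0), v = character(0))),
    "duplicate node id"
  )
})

test_that("unipartite projection keeps exactly the kept type's induced subgraph", {
  kg <- triangle_world_graph()
  prot <- project_unipartite(kg, "protein")
  expect_setequal(prot$nodes$id, c("p1", "p2", "p3"))
  expect_equal(nrow(kg_pairs(prot)), 3)

  # no protein-protein edge at all -> edgeless projection
  kg2 <- kg_graph(
    nodes = data.frame(id = c("p1", "p2", "d1"),
                       name = c("KINA1", "KINB2", "FLUXX"),
                       type = c("protein", "protein", "disease")),
    edges = data.frame(u = c("d1", "d1"), v = c("p1", "p2"))
  )
  expect_equal(nrow(project_unipartite(kg2, "protein")$edges), 0)

  expect_warning(empty <- project_unipartite(kg, "metabolite"), "no node")
  expect_equal(nrow(empty$nodes), 0)
})

test_that("projection equals a brute-force endpoint-type filter on random graphs", {
  for (seed in 1:3) {
    w <- small_world(seed)
    kg <- w$graph
    proj <- project_unipartite(kg, "protein")
    is_prot <- function(id) kg$nodes$type[match(id, kg$nodes$id)] == "protein"
    brute <- kg$edges[is_prot(kg$edges$u) & is_prot(kg$edges$v), ]
    expect_equal(proj$edges, brute, ignore_attr = TRUE)
  }
})

test_that("short-name filtering removes four-character names and keeps five", {
  kg <- kg_graph(
    nodes = data.frame(id = c("a", "b", "c"),
                       name = c("ABCD", "ABCDE", "AB"),
                       type = "protein"),
    edges = data.frame(u = c("a", "b"), v = c("b", "c"))
  )
  filtered <- filter_short_names(kg)
  expect_setequal(filtered$nodes$name, "ABCDE")
  expect_equal(nrow(filtered$edges), 0)  # incident edges removed

  # survivors match an independent length scan on a generated world
  w <- small_world(2)
  f <- filter_short_names(w$graph)
  expect_setequal(f$nodes$id,
                  w$graph$nodes$id[nchar(w$graph$nodes$name) >= 5])
})

test_that("co-occurrence feature is 1 - p on [0, 1] and rejects bad input", {
  expect_equal(cooccurrence_feature(1), 0)
  expect_equal(cooccurrence_feature(0), 1)
  expect_equal(cooccurrence_feature(0.05), 0.95)
  expect_error(cooccurrence_feature(-0.1), "\\[0, 1\\]")
  expect_error(cooccurrence_feature(1.1), "\\[0, 1\\]")
})

test_that("cooc_table canonicalizes pairs and validates p-values", {
  tab <- cooc_table(data.frame(u = c("b", "a"), v = c("a", "c"),
                               p_value = c(0.2, 0.3)))
  expect_true(all(tab$u < tab$v))
  expect_error(cooc_table(data.frame(u = "a", v = "b", p_value = 1.5)),
               "\\[0, 1\\]")
})

test_that("projection is idempotent and commutes with name filtering", {
  for (seed in 1:3) {
    w <- small_world(seed)
    kg <- w$graph
    p1 <- project_unipartite(kg, "protein")
    p2 <- project_unipartite(p1, "protein")
    expect_identical(p1, p2)

    a <- filter_short_names(project_unipartite(kg, "protein"))
    b <- project_unipartite(filter_short_names(kg), "protein")
    expect_identical(a, b)
  }
})

test_that("graph CSV write/load round-trips bit-identically", {
  w <- small_world(1)
  kg <- w$graph
  d <- withr::local_tempdir()
  n1 <- file.path(d, "n1.csv"); e1 <- file.path(d, "e1.csv")
  write_graph(kg, n1, e1)
  kg2 <- load_graph(n1, e1)
  expect_identical(kg2$nodes, kg$nodes)
  expect_identical(kg2$edges, kg$edges)
  n2 <- file.path(d, "n2.csv"); e2 <- file.path(d, "e2.csv")
  write_graph(kg2, n2, e2)
  expect_identical(readBin(n1, "raw", file.size(n1)),
                   readBin(n2, "raw", file.size(n2)))
  expect_identical(readBin(e1, "raw", file.size(e1)),
                   readBin(e2, "raw", file.size(e2)))
})
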