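test_that("a 100-edge graph splits into 10 validation, 5 test, 85 train edges", {
  kg <- er_graph(30, 100, seed = 3)
  split <- split_links(kg, gnn_config(seed = 1))
  expect_equal(nrow(split$val_pos), 10)
  expect_equal(nrow(split$test_pos), 5)
  expect_equal(nrow(split$train_pos), 85)
  expect_equal(nrow(split$val_neg), 10)
  expect_equal(nrow(split$test_neg), 5)
  expect_equal(nrow(split$train_neg), 85)
})

test_that("link-split partitions are disjoint and negatives avoid true edges", {
  kg <- er_graph(30, 100, seed = 3)
  split <- split_links(kg, gnn_config(seed = 1))
  key <- function(df) paste(df$u, df$v)
  pos_keys <- c(key(split$train_pos), key(split$val_pos), key(split$test_pos))
  expect_equal(anyDuplicated(pos_keys), 0)
  neg_keys <- c(key(split$train_neg), key(split$val_neg), key(split$test_neg))
  expect_equal(anyDuplicated(neg_keys), 0)
  expect_length(intersect(neg_keys, key(kg_pairs(kg))), 0)
})

test_that("link splits are reproducible for a fixed seed and reject tiny graphs", {
  kg <- er_graph(30, 100, seed = 3)
  s1 <- split_links(kg, gnn_config(seed = 9))
  s2 <- split_links(kg, gnn_config(seed = 9))
  expect_identical(s1, s2)
  expect_error(split_links(er_graph(10, 15, seed = 1)), "at least 20")
})

test_that("encoder reproduces hand-computed mean-aggregation arithmetic", {
  # path a - b - c with scalar features 1, 2, 3; layer 1 keeps
  # [self, neighbour-mean], layer 2 computes [self1 + agg1, self2 - agg2].
  X <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  edges <- data.frame(u = c("a", "b"), v = c("b", "c"))
  params <- list(
    W1_self = matrix(c(1, 0), 1, 2), W1_neigh = matrix(c(0, 1), 1, 2),
    b1 = c(0, 0),
    W2_self = diag(2), W2_neigh = matrix(c(1, 0, 0, -1), 2, 2),
    b2 = c(0, 0)
  )
  # by hand: H1 = [[1,2],[2,2],[3,2]]; neighbour means of H1 are all [2,2];
  # Z = H1 + [2,-2] = [[3,0],[4,0],[5,0]]
  Z <- sage_encode(X, edges, params)
  expect_equal(unname(Z), matrix(c(3, 4, 5, 0, 0, 0), 3, 2))
})

test_that("isolated node with zero features and zero bias embeds to zero", {
  X <- matrix(0, 1, 2, dimnames = list("solo", NULL))
  params <- list(
    W1_self = matrix(rnorm(6), 2, 3), W1_neigh = matrix(rnorm(6), 2, 3),
    b1 = rep(0, 3),
    W2_self = matrix(rnorm(6), 3, 2), W2_neigh = matrix(rnorm(6), 3, 2),
    b2 = rep(0, 2)
  )
  Z <- sage_encode(X, data.frame(u = character(0), v = character(0)), params)
  expect_equal(unname(Z), matrix(0, 1, 2))
  expect_error(
    sage_encode(X, data.frame(u = character(0), v = character(0)),
                within(params, W1_self <- matrix(0, 5, 3))),
    "dimensions"
  )
})

test_that("trained embeddings have the configured output length", {
  w <- small_world(1)
  kg <- filter_short_names(project_unipartite(w$graph, "protein"))
  fit <- train_gnn(kg, gnn_config(seed = 1, max_epochs = 30, patience = 30))
  expect_equal(ncol(fit$embeddings), 64)
  expect_setequal(rownames(fit$embeddings), kg$nodes$id)
})

test_that("link score is the dot product, symmetric, and shape-checked", {
  expect_equal(link_score(c(1, 0), c(0, 1)), 0)
  e1 <- c(1, rep(0, 9))
  expect_equal(link_score(e1, e1), 1)
  expect_equal(link_score(c(1, 2, 3), c(4, 5, 6)), 32)
  withr::with_seed(1, {
    for (i in 1:20) {
      a <- rnorm(8); b <- rnorm(8)
      expect_equal(link_score(a, b), link_score(b, a))
    }
  })
  expect_error(link_score(1:3, 1:4), "lengths differ")
})

test_that("link F1 is 1 for perfect ranking, 0 for inverted, ~0.5 for random", {
  emb <- matrix(c(1, 1, -1, -1), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  pos <- data.frame(u = "a", v = "a")  # score 2 > 0
  neg <- data.frame(u = "a", v = "b")  # score -2 < 0
  expect_equal(evaluate_link_f1(emb, pos, neg), 1)
  expect_equal(evaluate_link_f1(emb, neg, pos), 0)
  expect_error(evaluate_link_f1(emb, pos[0, ], neg), "at least one")

  # Monte-Carlo: symmetric random embeddings on balanced sets
  withr::with_seed(11, {
    n <- 3000
    emb <- matrix(rnorm(2 * n * 4), 2 * n, 4,
                  dimnames = list(sprintf("r%05d", seq_len(2 * n)), NULL))
    ids <- rownames(emb)
    pairs <- data.frame(u = ids[seq_len(n)], v = ids[n + seq_len(n)])
    half <- seq_len(n / 2)
    f1 <- evaluate_link_f1(emb, pairs[half, ], pairs[-half, ])
    expect_lt(abs(f1 - 0.5), 0.05)
  })
})

test_that("training separates planted blocks and is seed-reproducible", {
  w <- small_world(3)
  kg <- filter_short_names(project_unipartite(w$graph, "protein"))
  fit1 <- train_gnn(kg, gnn_config(seed = 5))
  fit2 <- train_gnn(kg, gnn_config(seed = 5))
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$embeddings, fit2$embeddings)

  # stopping rule: never more than `patience` epochs past the best one
  cfg <- gnn_config(seed = 5)
  expect_lte(nrow(fit1$history) - fit1$best_epoch, cfg$patience)

  # within-block pairs outscore between-block pairs after training
  blocks <- w$block[rownames(fit1$embeddings)]
  Z <- fit1$embeddings
  ids <- rownames(Z)
  withr::with_seed(2, {
    pick <- t(utils::combn(sample(ids, 24), 2))
  })
  s <- vapply(seq_len(nrow(pick)),
              function(i) link_score(Z[pick[i, 1], ], Z[pick[i, 2], ]),
              numeric(1))
  same <- blocks[pick[, 1]] == blocks[pick[, 2]]
  expect_gt(mean(s[same]), mean(s[!same]))
})

test_that("embedding tables persist to CSV and back", {
  w <- small_world(1)
  kg <- filter_short_names(project_unipartite(w$graph, "protein"))
  fit <- train_gnn(kg, gnn_config(seed = 2, max_epochs = 10, patience = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_embeddings(fit$embeddings, path)
  back <- read_embeddings(path)
  expect_equal(dim(back), dim(fit$embeddings))
  expect_equal(back, fit$embeddings, tolerance = 1e-8, ignore_attr = TRUE)
})
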