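#' Configuration for the neighbourhood-aggregation link predictor
#'
#' Defaults mirror the two-layer mean-aggregation architecture used for
#' the associative-network embeddings: 128-dimensional hidden layer,
#' 64-dimensional final embeddings, AdamW at learning rate 0.01, early
#' stopping on validation loss with a patience of 20 epochs, and a link
#' split holding out 10% of edges for validation and 5% for testing with
#' 1:1 negative sampling.
#'
#' @param hidden_dim hidden representation width (default 128).
#' @param out_dim embedding length (default 64).
#' @param learning_rate AdamW learning rate (default 0.01).
#' @param weight_decay decoupled weight-decay coefficient (default 0.01).
#' @param patience epochs without validation-loss improvement before
#'   stopping (default 20).
#' @param val_fraction,test_fraction fraction of edges held out (0.1, 0.05).
#' @param max_epochs hard cap on training epochs (default 400).
#' @param identity_features append a trainable per-node one-hot channel to
#'   the structural features (default `FALSE`: the spectral positional
#'   features below identify nodes already and generalise better).
#' @param spectral_dim number of adjacency-spectral positional features
#'   computed from the training edges and appended to the node features
#'   (default 16; 0 disables; see [spectral_features()]).
#' @param resample_negatives draw fresh training negatives every epoch
#'   instead of reusing the frozen 1:1 sample from the link split (default
#'   `FALSE`: frozen negatives keep the score distribution of generic
#'   unseen pairs centred, so the probability-0.5 threshold stays
#'   calibrated).
#' @param restore_best return the parameters of the best-validation epoch
#'   (default `TRUE`). Set `FALSE` to keep the final-epoch model, e.g. for
#'   fit-to-convergence control experiments where the validation loss
#'   carries no signal and its minimum is just the initialisation.
#' @param seed integer seed controlling the split, initialisation, and
#'   negative sampling.
#' @return a list of class `kg_gnn_config`.
#' @export
gnn_config <- function(hidden_dim = 128, out_dim = 64, learning_rate = 0.01,
                       weight_decay = 0.01, patience = 20,
                       val_fraction = 0.1, test_fraction = 0.05,
                       max_epochs = 400, identity_features = FALSE,
                       spectral_dim = 16, restore_best = TRUE,
                       resample_negatives = FALSE, seed = 1) {
  stopifnot(hidden_dim > 0, out_dim > 0, learning_rate > 0, patience >= 1,
            val_fraction > 0, test_fraction > 0,
            val_fraction + test_fraction < 1)
  structure(list(hidden_dim = hidden_dim, out_dim = out_dim,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 patience = patience, val_fraction = val_fraction,
                 test_fraction = test_fraction, max_epochs = max_epochs,
                 identity_features = identity_features,
                 spectral_dim = as.integer(spectral_dim),
                 restore_best = isTRUE(restore_best),
                 resample_negatives = isTRUE(resample_negatives),
                 seed = as.integer(seed)),
            class = "kg_gnn_config")
}

#' Split graph edges into train/validation/test link sets with negatives
#'
#' Partitions the distinct node-pair edges: `round(val_fraction * |E|)`
#' validation, `round(test_fraction * |E|)` test, remainder training. Each
#' partition gets an equal number of negative pairs sampled uniformly from
#' the non-edges of the *full* graph; negatives are disjoint across
#' partitions. Reproducible for a fixed seed.
#'
#' @param kg a `kg_graph` with at least 20 edges.
#' @param cfg a [gnn_config()].
#' @return a list of class `kg_link_split` with tibbles `train_pos`,
#'   `val_pos`, `test_pos`, `train_neg`, `val_neg`, `test_neg`.
#' @export
split_links <- function(kg, cfg = gnn_config()) {
  stopifnot(inherits(kg, "kg_graph"))
  pairs <- kg_pairs(kg)
  n_e <- nrow(pairs)
  if (n_e < 20) {
    stop("graph has only ", n_e, " edges; at least 20 are required for a ",
         "link split", call. = FALSE)
  }
  n_val <- round(cfg$val_fraction * n_e)
  n_test <- round(cfg$test_fraction * n_e)
  n_train <- n_e - n_val - n_test
  if (n_val == 0 || n_test == 0 || n_train <= 0) {
    stop("link split would leave an empty partition; adjust fractions",
         call. = FALSE)
  }
  with_seed(cfg$seed, {
    perm <- sample.int(n_e)
    val_pos <- pairs[perm[seq_len(n_val)], ]
    test_pos <- pairs[perm[n_val + seq_len(n_test)], ]
    train_pos <- pairs[perm[(n_val + n_test + 1):n_e], ]
    negs <- sample_nonedges(kg$nodes$id, n_e, exclude = pairs)
    split <- list(
      train_pos = train_pos, val_pos = val_pos, test_pos = test_pos,
      train_neg = negs[perm[(n_val + n_test + 1):n_e], ],
      val_neg = negs[perm[seq_len(n_val)], ],
      test_neg = negs[perm[n_val + seq_len(n_test)], ]
    )
    structure(split, class = "kg_link_split")
  })
}

#' Two-layer mean-aggregation encoder
#'
#' Computes node embeddings by two rounds of neighbourhood aggregation:
#' layer 1 maps input features to the hidden width through separate self
#' and mean-of-neighbours weight matrices, followed by a rectified-linear
#' activation; layer 2 maps the hidden representation to the final
#' embedding the same way. Deterministic given `params`.
#'
#' @param features numeric matrix, one row per node (rownames = node ids).
#' @param edges tibble/data frame of undirected edges (`u`, `v` node ids)
#'   defining the aggregation neighbourhoods.
#' @param params named list of weights: `W1_self`, `W1_neigh` (d x hidden),
#'   `b1` (hidden), `W2_self`, `W2_neigh` (hidden x out), `b2` (out).
#' @return embedding matrix, one row per node (rownames preserved).
#' @export
sage_encode <- function(features, edges, params) {
  ids <- rownames(features)
  if (is.null(ids)) stop("`features` must have node ids as rownames",
                         call. = FALSE)
  check_dims <- function(W, r, c, nm) {
    if (!all(dim(W) == c(r, c))) {
      stop("parameter ", nm, " has dimensions ", paste(dim(W), collapse = "x"),
           ", expected ", r, "x", c, call. = FALSE)
    }
  }
  d <- ncol(features)
  h <- ncol(params$W1_self)
  o <- ncol(params$W2_self)
  check_dims(params$W1_self, d, h, "W1_self")
  check_dims(params$W1_neigh, d, h, "W1_neigh")
  check_dims(params$W2_self, h, o, "W2_self")
  check_dims(params$W2_neigh, h, o, "W2_neigh")
  A <- mean_aggregator(ids, tibble::as_tibble(edges))
  fwd <- sage_forward(features, A, params)
  Z <- fwd$Z
  rownames(Z) <- ids
  Z
}

sage_forward <- function(X, A, params) {
  AX <- as.matrix(A %*% X)
  H1pre <- X %*% params$W1_self + AX %*% params$W1_neigh +
    matrix(params$b1, nrow(X), length(params$b1), byrow = TRUE)
  H1 <- relu(H1pre)
  AH1 <- as.matrix(A %*% H1)
  Z <- H1 %*% params$W2_self + AH1 %*% params$W2_neigh +
    matrix(params$b2, nrow(X), length(params$b2), byrow = TRUE)
  list(Z = Z, H1 = H1, H1pre = H1pre, AX = AX, AH1 = AH1)
}

# Weights: seeded uniform fan-in. Biases: zeros, so that at initialisation
# the embedding cloud is centred and dot-product scores are sign-symmetric
# (a shared bias offset would make every pair score the same sign).
sage_init <- function(d, hidden, out) {
  list(
    W1_self = init_weight(d, hidden), W1_neigh = init_weight(d, hidden),
    b1 = numeric(hidden),
    W2_self = init_weight(hidden, out), W2_neigh = init_weight(hidden, out),
    b2 = numeric(out)
  )
}

# Gradient of mean BCE-with-logits loss over scored pairs w.r.t. all encoder
# parameters. `ui`, `vi` are node indices of the scored pairs, `y` their
# 0/1 labels.
sage_backward <- function(X, A, fwd, params, ui, vi, y) {
  m <- length(y)
  Z <- fwd$Z
  s <- rowSums(Z[ui, , drop = FALSE] * Z[vi, , drop = FALSE])
  g <- (sigmoid(s) - y) / m
  n <- nrow(Z)
  Su <- Matrix::sparseMatrix(i = seq_len(m), j = ui, x = 1, dims = c(m, n))
  Sv <- Matrix::sparseMatrix(i = seq_len(m), j = vi, x = 1, dims = c(m, n))
  dZ <- as.matrix(Matrix::t(Su) %*% (g * Z[vi, , drop = FALSE]) +
                  Matrix::t(Sv) %*% (g * Z[ui, , drop = FALSE]))
  grads <- list(
    W2_self = crossprod(fwd$H1, dZ),
    W2_neigh = crossprod(fwd$AH1, dZ),
    b2 = colSums(dZ)
  )
  dH1 <- dZ %*% t(params$W2_self) +
    as.matrix(Matrix::t(A) %*% dZ) %*% t(params$W2_neigh)
  dH1pre <- dH1 * (fwd$H1pre > 0)
  grads$W1_self <- crossprod(X, dH1pre)
  grads$W1_neigh <- crossprod(fwd$AX, dH1pre)
  grads$b1 <- colSums(dH1pre)
  list(grads = grads, logits = s)
}

#' Dot-product link score between two embeddings
#'
#' The score for a candidate edge is the inner product of the two node
#' embeddings, `s(u, v) = sum_i z_u[i] * z_v[i]`; it is symmetric in its
#' arguments and is interpreted as a logit.
#'
#' @param z_u,z_v numeric vectors of equal length.
#' @return a single number.
#' @examples
#' link_score(c(1, 2, 3), c(4, 5, 6)) # 32
#' @export
link_score <- function(z_u, z_v) {
  if (length(z_u) != length(z_v)) {
    stop("embedding lengths differ (", length(z_u), " vs ", length(z_v), ")",
         call. = FALSE)
  }
  sum(z_u * z_v)
}

pair_logits <- function(embeddings, pairs) {
  ui <- match(pairs$u, rownames(embeddings))
  vi <- match(pairs$v, rownames(embeddings))
  if (anyNA(ui) || anyNA(vi)) {
    stop("pair references a node with no embedding", call. = FALSE)
  }
  rowSums(embeddings[ui, , drop = FALSE] * embeddings[vi, , drop = FALSE])
}

#' Held-out link F1 from an embedding table
#'
#' Scores each positive and negative pair with the dot product, thresholds
#' the logit at 0 (probability 0.5 through the logistic), and returns the
#' F1 score of the resulting labels.
#'
#' @param embeddings embedding matrix with node-id rownames.
#' @param positives,negatives tibbles of pairs (`u`, `v`).
#' @return the F1 score.
#' @export
evaluate_link_f1 <- function(embeddings, positives, negatives) {
  if (nrow(positives) == 0 || nrow(negatives) == 0) {
    stop("need at least one positive and one negative pair", call. = FALSE)
  }
  logits <- c(pair_logits(embeddings, positives),
              pair_logits(embeddings, negatives))
  truth <- c(rep(1, nrow(positives)), rep(0, nrow(negatives)))
  f1_score(as.numeric(logits > 0), truth)
}

#' Train the link predictor on a knowledge graph
#'
#' Full pipeline: builds node features, splits links, and optimises the
#' two-layer mean-aggregation encoder with a dot-product decoder under
#' binary cross-entropy on logits (AdamW). Message passing uses the
#' training edges only, so held-out links are never seen by the
#' aggregator. Training negatives are resampled each epoch (1:1 with the
#' positives); validation/test negatives are frozen in the split. Stops
#' when the validation loss has not improved for `patience` epochs and
#' restores the best-validation parameters.
#'
#' @param kg a `kg_graph`.
#' @param cfg a [gnn_config()].
#' @return an object of class `kg_gnn_fit`: list with `embeddings` (matrix,
#'   best-validation epoch), `params`, `history` (tibble: epoch,
#'   train_loss, val_loss, val_f1), `best_epoch`, `test_f1`, `split`,
#'   `config`.
#' @export
train_gnn <- function(kg, cfg = gnn_config()) {
  stopifnot(inherits(kg, "kg_graph"))
  split <- split_links(kg, cfg)
  X <- node_feature_matrix(kg, identity = cfg$identity_features)
  ids <- rownames(X)
  if (cfg$spectral_dim > 0) {
    X <- cbind(X, spectral_features(ids, split$train_pos, cfg$spectral_dim))
  }
  A <- mean_aggregator(ids, split$train_pos)
  all_pairs <- kg_pairs(kg)

  idx <- function(pairs) cbind(match(pairs$u, ids), match(pairs$v, ids))
  tr_pos <- idx(split$train_pos)
  va <- idx(dplyr::bind_rows(split$val_pos, split$val_neg))
  y_va <- c(rep(1, nrow(split$val_pos)), rep(0, nrow(split$val_neg)))

  with_seed(cfg$seed + 1L, {
    params <- sage_init(ncol(X), cfg$hidden_dim, cfg$out_dim)
    opt <- adamw_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    history <- vector("list", cfg$max_epochs)
    stale <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      if (cfg$resample_negatives) {
        negs <- sample_nonedges(ids, nrow(split$train_pos),
                                exclude = all_pairs)
        tr <- rbind(tr_pos, idx(negs))
        y_tr <- c(rep(1, nrow(tr_pos)), rep(0, nrow(negs)))
      } else {
        tr <- rbind(tr_pos, idx(split$train_neg))
        y_tr <- c(rep(1, nrow(tr_pos)), rep(0, nrow(split$train_neg)))
      }
      fwd <- sage_forward(X, A, params)
      bwd <- sage_backward(X, A, fwd, params, tr[, 1], tr[, 2], y_tr)
      train_loss <- bce_with_logits(bwd$logits, y_tr)
      if (!is.finite(train_loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      }
      step <- adamw_step(params, bwd$grads, opt, cfg$learning_rate,
                         cfg$weight_decay)
      params <- step$params
      opt <- step$state

      fwd2 <- sage_forward(X, A, params)
      s_va <- rowSums(fwd2$Z[va[, 1], , drop = FALSE] *
                      fwd2$Z[va[, 2], , drop = FALSE])
      val_loss <- bce_with_logits(s_va, y_va)
      val_f1 <- f1_score(as.numeric(s_va > 0), y_va)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss,
        val_loss = val_loss, val_f1 = val_f1
      )
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
    history <- dplyr::bind_rows(history)
    chosen <- if (cfg$restore_best) best$params else params
    Z <- sage_forward(X, A, chosen)$Z
    rownames(Z) <- ids
    # Test-time protocol: once the model is selected, message passing may
    # also use the validation edges (they are no longer held out), giving
    # the aggregator the richest graph that still excludes test links.
    A_test <- mean_aggregator(ids, dplyr::bind_rows(split$train_pos,
                                                    split$val_pos))
    Z_test <- sage_forward(X, A_test, chosen)$Z
    rownames(Z_test) <- ids
    test_f1 <- evaluate_link_f1(Z_test, split$test_pos, split$test_neg)
    structure(list(embeddings = Z_test, embeddings_train_mp = Z,
                   params = chosen, history = history,
                   best_epoch = best$epoch, test_f1 = test_f1,
                   split = split, config = cfg),
              class = "kg_gnn_fit")
  })
}

#' @export
print.kg_gnn_fit <- function(x, ...) {
  cat("<kg_gnn_fit> ", nrow(x$embeddings), " nodes x ", ncol(x$embeddings),
      "-d embeddings; best epoch ", x$best_epoch,
      " (val loss ", signif(min(x$history$val_loss), 4),
      "), test F1 ", signif(x$test_f1, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname train_gnn
#' @param x,object a `kg_gnn_fit`.
#' @param ... unused.
#' @export
tidy.kg_gnn_fit <- function(x, ...) x$history

#' @rdname train_gnn
#' @export
glance.kg_gnn_fit <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$embeddings), out_dim = ncol(x$embeddings),
    epochs_run = nrow(x$history), best_epoch = x$best_epoch,
    best_val_loss = min(x$history$val_loss),
    val_f1 = x$history$val_f1[x$best_epoch], test_f1 = x$test_f1
  )
}

#' @rdname train_gnn
#' @export
autoplot.kg_gnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(title = "Link-predictor training",
                  subtitle = paste0("dashed line: best validation epoch (",
                                    object$best_epoch, ")"))
}

#' Persist / restore an embedding table as CSV
#'
#' @param embeddings matrix with node-id rownames.
#' @param path output CSV path (`node_id` column + one column per dimension).
#' @return the path, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(node_id = rownames(embeddings), embeddings,
                   row.names = NULL, check.names = FALSE)
  colnames(df) <- c("node_id", paste0("z", seq_len(ncol(embeddings))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  Z <- as.matrix(df[, -1, drop = FALSE])
  rownames(Z) <- df$node_id
  colnames(Z) <- NULL
  Z
}
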