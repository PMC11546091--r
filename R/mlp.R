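#' Fuse two node embeddings and a co-occurrence value into a pair feature
#'
#' The classifier input for a candidate pair is the concatenation
#' `z_u (64) || z_v (64) || 1 - p (1)`: 129 numbers, with the literature
#' co-occurrence p-value entering through `1 - p` so that significant
#' co-mentions score near 1.
#'
#' @param z_u,z_v node embedding vectors (equal length, default 64).
#' @param p co-occurrence p-value in \[0, 1\].
#' @param out_dim expected embedding length (default 64).
#' @return a numeric vector of length `2 * out_dim + 1`.
#' @examples
#' f <- build_pair_feature(rnorm(64), rnorm(64), p = 0.05)
#' length(f) # 129
#' f[129]    # 0.95
#' @export
build_pair_feature <- function(z_u, z_v, p, out_dim = 64) {
  if (length(z_u) != out_dim || length(z_v) != out_dim) {
    stop("embeddings must have length ", out_dim, " (got ", length(z_u),
         " and ", length(z_v), ")", call. = FALSE)
  }
  c(z_u, z_v, cooccurrence_feature(p))
}

#' Pair-feature matrix for a table of candidate pairs
#'
#' Looks up both embeddings and the co-occurrence entry for each pair.
#' Pairs with no co-occurrence entry, or whose node was filtered out of
#' the embedded graph (no embedding row), are *skipped*, not imputed:
#' absence of data is a distinct state.
#'
#' @param pairs tibble with columns `u`, `v` (canonical order).
#' @param embeddings embedding matrix with node-id rownames.
#' @param cooc a [cooc_table()] tibble (`u`, `v`, `p_value`).
#' @return a list with `features` (matrix, one row per kept pair), `pairs`
#'   (the kept pairs, with `p_value`), and `skipped` (pairs lacking a
#'   co-occurrence entry or an embedding).
#' @export
pair_feature_matrix <- function(pairs, embeddings, cooc) {
  pairs <- tibble::as_tibble(pairs)
  joined <- dplyr::left_join(pairs, cooc, by = c("u", "v"))
  embedded <- joined$u %in% rownames(embeddings) &
    joined$v %in% rownames(embeddings)
  skipped <- dplyr::filter(joined, is.na(.data$p_value) | !embedded)
  kept <- dplyr::filter(joined, !is.na(.data$p_value) & embedded)
  if (nrow(kept) == 0) {
    return(list(features = matrix(numeric(0), 0, 2 * ncol(embeddings) + 1),
                pairs = kept, skipped = skipped[c("u", "v")]))
  }
  ui <- match(kept$u, rownames(embeddings))
  vi <- match(kept$v, rownames(embeddings))
  features <- cbind(embeddings[ui, , drop = FALSE],
                    embeddings[vi, , drop = FALSE],
                    cooccurrence_feature(kept$p_value))
  dimnames(features) <- NULL
  list(features = features, pairs = kept, skipped = skipped[c("u", "v")])
}

#' Drop the co-occurrence slot from a pair-feature matrix
#'
#' Ablation counterpart of [build_pair_feature()]: removes the final
#' (co-occurrence) column, leaving the two embedding blocks untouched, for
#' retraining the classifier without literature information.
#'
#' @param features matrix (or vector) of 129-long pair features.
#' @return the same features with the last column removed (length 128).
#' @export
ablate_cooccurrence <- function(features) {
  if (is.null(dim(features))) return(features[-length(features)])
  features[, -ncol(features), drop = FALSE]
}

#' Configuration for the pair-classifier MLP
#'
#' Three hidden layers of 256, 128, and 64 rectified-linear units, a single
#' logistic output unit, binary cross-entropy loss, AdamW at learning rate
#' 0.001, mini-batches of 64, and early stopping on the validation
#' Matthews correlation coefficient with a patience of 50 epochs.
#' Probabilities strictly above `threshold` are labelled positive.
#'
#' @param hidden integer vector of hidden-layer sizes.
#' @param learning_rate AdamW learning rate (default 0.001).
#' @param weight_decay decoupled weight decay (default 0.01).
#' @param batch_size mini-batch size (default 64).
#' @param patience epochs without validation-MCC improvement (default 50).
#' @param threshold decision threshold on the predicted probability;
#'   exactly `threshold` is classified negative (default 0.5).
#' @param val_fraction,test_fraction stratified split fractions (0.1, 0.1).
#' @param max_epochs hard cap (default 300).
#' @param seed integer seed.
#' @return a list of class `kg_mlp_config`.
#' @export
mlp_config <- function(hidden = c(256, 128, 64), learning_rate = 0.001,
                       weight_decay = 0.01, batch_size = 64, patience = 50,
                       threshold = 0.5, val_fraction = 0.1,
                       test_fraction = 0.1, max_epochs = 300, seed = 1) {
  stopifnot(all(hidden > 0), learning_rate > 0, batch_size >= 1,
            patience >= 1, threshold > 0, threshold < 1,
            val_fraction > 0, test_fraction >= 0,
            val_fraction + test_fraction < 1)
  structure(list(hidden = as.integer(hidden), learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), threshold = threshold,
                 val_fraction = val_fraction, test_fraction = test_fraction,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "kg_mlp_config")
}

mlp_init <- function(in_dim, hidden) {
  dims <- c(in_dim, hidden, 1L)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    W[[l]] <- init_weight(dims[l], dims[l + 1])
    b[[l]] <- init_bias(dims[l], dims[l + 1])
  }
  list(W = W, b = b)
}

#' Construct an MLP model from explicit weights
#'
#' Mainly for tests and hand-set architectures; [train_mlp()] is the normal
#' entry point.
#'
#' @param params list with `W` (list of weight matrices) and `b` (list of
#'   bias vectors), input through output layer.
#' @param threshold decision threshold (default 0.5).
#' @return an object of class `kg_mlp_model`.
#' @export
new_mlp_model <- function(params, threshold = 0.5) {
  stopifnot(is.list(params$W), is.list(params$b),
            length(params$W) == length(params$b))
  structure(list(params = params, threshold = threshold,
                 in_dim = nrow(params$W[[1]])),
            class = "kg_mlp_model")
}

mlp_forward <- function(params, X) {
  L <- length(params$W)
  H <- vector("list", L + 1)   # H[[1]] = input; H[[l+1]] = activation of layer l
  pre <- vector("list", L)
  H[[1]] <- X
  for (l in seq_len(L)) {
    pre[[l]] <- H[[l]] %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(X), length(params$b[[l]]), byrow = TRUE)
    H[[l + 1]] <- if (l < L) relu(pre[[l]]) else pre[[l]]
  }
  list(logits = drop(pre[[L]]), H = H, pre = pre)
}

mlp_backward <- function(params, fwd, y) {
  L <- length(params$W)
  m <- length(y)
  delta <- matrix((sigmoid(fwd$logits) - y) / m, m, 1)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params$W[[l]])) * (fwd$pre[[l - 1]] > 0)
    }
  }
  list(W = gW, b = gb)
}

# flatten/unflatten param lists so the generic AdamW can drive them
mlp_flatten <- function(p) {
  out <- c(stats::setNames(p$W, paste0("W", seq_along(p$W))),
           stats::setNames(p$b, paste0("b", seq_along(p$b))))
  out
}
mlp_unflatten <- function(flat, L) {
  list(W = unname(flat[paste0("W", seq_len(L))]),
       b = unname(flat[paste0("b", seq_len(L))]))
}

stratified_split <- function(y, val_fraction, test_fraction) {
  idx_val <- integer(0); idx_test <- integer(0)
  for (cls in unique(y)) {
    pool <- which(y == cls)
    pool <- pool[sample.int(length(pool))]
    n_val <- round(val_fraction * length(pool))
    n_test <- round(test_fraction * length(pool))
    idx_val <- c(idx_val, pool[seq_len(n_val)])
    if (n_test > 0) idx_test <- c(idx_test, pool[n_val + seq_len(n_test)])
  }
  list(val = sort(idx_val), test = sort(idx_test),
       train = setdiff(seq_along(y), c(idx_val, idx_test)))
}

#' Train the fused-feature pair classifier
#'
#' Optimises the MLP with binary cross-entropy on logits and AdamW over
#' shuffled mini-batches. The data are split 80/10/10 (train/validation/
#' test), stratified by class. After each epoch the validation Matthews
#' correlation coefficient is computed; training stops when it has not
#' improved for `patience` epochs, and the best-validation weights are
#' restored.
#'
#' @param features numeric matrix of pair features (rows = pairs).
#' @param labels 0/1 vector, one per row.
#' @param cfg an [mlp_config()].
#' @return an object of class `kg_mlp_model` with additional fields
#'   `history` (tibble: epoch, train_loss, val_mcc), `best_epoch`,
#'   `val_mcc`, `test_mcc`, `config`, and the split indices.
#' @export
train_mlp <- function(features, labels, cfg = mlp_config()) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(0, 1)))
  with_seed(cfg$seed, {
    split <- stratified_split(labels, cfg$val_fraction, cfg$test_fraction)
    y_tr <- labels[split$train]; y_va <- labels[split$val]
    if (length(unique(y_tr)) < 2 || length(unique(y_va)) < 2) {
      stop("train and validation splits must both contain both classes ",
           "(MCC is degenerate otherwise)", call. = FALSE)
    }
    X_tr <- features[split$train, , drop = FALSE]
    X_va <- features[split$val, , drop = FALSE]

    params <- mlp_init(ncol(features), cfg$hidden)
    opt <- adamw_init(mlp_flatten(params))
    L <- length(params$W)
    best <- list(mcc = -Inf, params = params, epoch = 0L)
    history <- vector("list", cfg$max_epochs)
    stale <- 0L
    n_tr <- nrow(X_tr)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      losses <- numeric(0)
      for (start in seq(1, n_tr, by = cfg$batch_size)) {
        take <- ord[start:min(start + cfg$batch_size - 1, n_tr)]
        fwd <- mlp_forward(params, X_tr[take, , drop = FALSE])
        loss <- bce_with_logits(fwd$logits, y_tr[take])
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        }
        losses <- c(losses, loss)
        g <- mlp_backward(params, fwd, y_tr[take])
        step <- adamw_step(mlp_flatten(params),
                           mlp_flatten(g), opt,
                           cfg$learning_rate, cfg$weight_decay)
        params <- mlp_unflatten(step$params, L)
        opt <- step$state
      }
      p_va <- sigmoid(mlp_forward(params, X_va)$logits)
      val_mcc <- mcc(confusion(as.numeric(p_va > cfg$threshold), y_va))
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(losses), val_mcc = val_mcc
      )
      if (val_mcc > best$mcc) {
        best <- list(mcc = val_mcc, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
    model <- new_mlp_model(best$params, cfg$threshold)
    model$history <- dplyr::bind_rows(history)
    model$best_epoch <- best$epoch
    model$val_mcc <- best$mcc
    model$config <- cfg
    model$split <- split
    if (length(split$test) > 0) {
      y_te <- labels[split$test]
      p_te <- sigmoid(mlp_forward(best$params,
                                  features[split$test, , drop = FALSE])$logits)
      model$test_mcc <- mcc(confusion(as.numeric(p_te > cfg$threshold), y_te))
    } else {
      model$test_mcc <- NA_real_
    }
    model
  })
}

#' Score pair features with a trained classifier
#'
#' Forward pass through the MLP with a logistic output; probabilities
#' strictly above the model threshold are labelled positive (a probability
#' of exactly 0.5 is negative).
#'
#' @param model a `kg_mlp_model`.
#' @param features matrix (or single vector) of pair features.
#' @param pairs optional tibble (`u`, `v`) aligned with the feature rows.
#' @return a tibble with columns `probability` and `label` (logical),
#'   preceded by `u`, `v` when `pairs` is supplied.
#' @export
mlp_predict <- function(model, features, pairs = NULL) {
  if (!inherits(model, "kg_mlp_model")) {
    stop("`model` must be a trained or explicitly initialised kg_mlp_model",
         call. = FALSE)
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$in_dim) {
    stop("feature width ", ncol(features), " does not match the model input ",
         "layer (", model$in_dim, ")", call. = FALSE)
  }
  prob <- sigmoid(mlp_forward(model$params, features)$logits)
  out <- tibble::tibble(probability = prob,
                        label = prob > model$threshold)
  if (!is.null(pairs)) out <- dplyr::bind_cols(tibble::as_tibble(pairs), out)
  out
}

#' @export
print.kg_mlp_model <- function(x, ...) {
  dims <- c(x$in_dim, vapply(x$params$W, ncol, integer(1)))
  cat("<kg_mlp_model> ", paste(dims, collapse = " -> "), sep = "")
  if (!is.null(x$val_mcc)) {
    cat("; best epoch ", x$best_epoch, ", val MCC ", signif(x$val_mcc, 4),
        ", test MCC ", signif(x$test_mcc, 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname train_mlp
#' @param x,object a `kg_mlp_model`.
#' @param ... unused.
#' @export
tidy.kg_mlp_model <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has no training history (explicitly initialised?)",
         call. = FALSE)
  }
  x$history
}

#' @rdname train_mlp
#' @export
glance.kg_mlp_model <- function(x, ...) {
  tibble::tibble(
    in_dim = x$in_dim, epochs_run = nrow(x$history %||% tibble::tibble()),
    best_epoch = x$best_epoch %||% NA_integer_,
    val_mcc = x$val_mcc %||% NA_real_, test_mcc = x$test_mcc %||% NA_real_
  )
}

#' @rdname train_mlp
#' @export
autoplot.kg_mlp_model <- function(object, ...) {
  if (is.null(object$history)) {
    stop("model has no training history", call. = FALSE)
  }
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$val_mcc)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(y = "validation MCC", title = "Pair-classifier training")
}
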