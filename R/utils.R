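# Internal numerical helpers shared by the two learners.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable mean binary cross-entropy on logits:
# softplus(x) - y*x, with softplus(x) = log1p(exp(-|x|)) + max(x, 0).
bce_with_logits <- function(logits, y) {
  mean(log1p(exp(-abs(logits))) + pmax(logits, 0) - y * logits)
}

relu <- function(x) pmax(x, 0)

# Seeded uniform fan-in initialisation, U(-1/sqrt(fan_in), 1/sqrt(fan_in)),
# the PyTorch default for linear layers.
init_weight <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  matrix(runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
}

init_bias <- function(fan_in, n) {
  bound <- 1 / sqrt(fan_in)
  runif(n, -bound, bound)
}

# Decoupled-weight-decay Adam (AdamW). `params` and `grads` are named lists
# of numeric arrays; `state` carries first/second moment estimates and the
# step counter. Weight decay is applied to matrices only, not bias vectors.
adamw_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    wd <- if (is.matrix(params[[nm]])) weight_decay else 0
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + wd * params[[nm]])
  }
  list(params = params, state = state)
}

# Uniformly sample `n` unordered node pairs that are not in `exclude`
# (a tibble u,v in canonical order) and not self-pairs. Rejection sampling;
# deterministic given the RNG state.
sample_nonedges <- function(node_ids, n, exclude) {
  if (n == 0) {
    return(tibble::tibble(u = character(0), v = character(0)))
  }
  n_nodes <- length(node_ids)
  max_pairs <- n_nodes * (n_nodes - 1) / 2
  if (n > max_pairs - nrow(exclude)) {
    stop("not enough non-edges to sample ", n, " pairs", call. = FALSE)
  }
  excl_key <- paste(exclude$u, exclude$v, sep = "\r")
  got_u <- character(0); got_v <- character(0)
  seen <- character(0)
  while (length(got_u) < n) {
    k <- max(2 * (n - length(got_u)), 16)
    i <- node_ids[sample.int(n_nodes, k, replace = TRUE)]
    j <- node_ids[sample.int(n_nodes, k, replace = TRUE)]
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    swap <- i > j
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    key <- paste(i, j, sep = "\r")
    ok <- !(key %in% excl_key) & !(key %in% seen) & !duplicated(key)
    i <- i[ok]; j <- j[ok]; key <- key[ok]
    take <- seq_len(min(length(i), n - length(got_u)))
    got_u <- c(got_u, i[take]); got_v <- c(got_v, j[take])
    seen <- c(seen, key[take])
  }
  tibble::tibble(u = got_u, v = got_v)
}

pair_key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\r")
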