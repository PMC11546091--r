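# Shared fixture builders. Everything is generated in code, seeded.

# Minimal typed graph: a protein triangle plus one disease node linked to
# all three proteins.
triangle_world_graph <- function() {
  kg_graph(
    nodes = data.frame(
      id = c("p1", "p2", "p3", "d1"),
      name = c("KINA1", "KINB2", "KINC3", "INSOMNIA"),
      type = c("protein", "protein", "protein", "disease")
    ),
    edges = data.frame(
      u = c("p1", "p2", "p1", "d1", "d1", "d1"),
      v = c("p2", "p3", "p3", "p1", "p2", "p3"),
      type = "assoc"
    )
  )
}

# Erdos-Renyi style graph with exactly n_edges distinct edges.
er_graph <- function(n_nodes, n_edges, seed = 1, type = "protein") {
  ids <- sprintf("n%03d", seq_len(n_nodes))
  stopifnot(n_edges <= n_nodes * (n_nodes - 1) / 2)
  withr::with_seed(seed, {
    cmb <- utils::combn(ids, 2)
    pick <- sample.int(ncol(cmb), n_edges)
    kg_graph(
      nodes = data.frame(id = ids, name = toupper(ids), type = type),
      edges = data.frame(u = cmb[1, pick], v = cmb[2, pick], type = "e")
    )
  })
}

# Small world for fast unit tests (not the default study conditions).
small_world <- function(seed = 0) {
  make_world(world_config(n_proteins = 60, n_other_entities = 10,
                          n_short_names = 2, n_blocks = 2,
                          p_within = 0.4, p_between = 0.02,
                          n_heldout = 5, n_decoys = 5, seed = seed))
}

# Labelled pair-feature set where the embedding blocks carry a class shift
# of `embed_shift` per dimension and the co-occurrence slot is informative
# (low p for class 1, high-ish for class 0).
ablation_dataset <- function(n_per_class = 600, embed_shift = 0.05,
                             seed = 10) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    y <- rep(c(1, 0), each = n_per_class)
    Z <- matrix(rnorm(n * 128), n, 128) + embed_shift * y
    p <- ifelse(y == 1, rbeta(n, 1, 19), rbeta(n, 8, 2))
    list(features = cbind(Z, 1 - p), labels = y)
  })
}

# Independent brute-force metrics oracle: plain loops and the textbook
# count definitions, no package code.
oracle_metrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  rat <- function(a, b) if (b == 0) 0 else a / b
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    precision = rat(tp, tp + fp),
    accuracy = rat(tp + tn, tp + tn + fp + fn),
    f1 = rat(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den)
  )
}

oracle_confusion <- function(pred, truth) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# One-document gold corpus builders.
gold_doc_simple <- function(doc_id = "d1",
                            text = "KINA1 binds KINB2 in neurons.",
                            rel_type = "PPI") {
  gold_document(
    doc_id = doc_id, text = text,
    entities = data.frame(
      mention = c("KINA1", "KINB2"), entity_id = c("e1", "e2"),
      start = c(1, 13), end = c(5, 17)
    ),
    relations = data.frame(a = "e1", b = "e2", type = rel_type)
  )
}
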