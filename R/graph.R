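#' Knowledge graphs of typed nodes and undirected typed edges
#'
#' A `kg_graph` holds two tibbles: `nodes` (columns `id`, `name`, `type`,
#' plus any number of `feat_*` numeric columns) and `edges` (columns `u`,
#' `v`, `type`). Edges are undirected and stored canonically with `u < v`
#' by string comparison; self-loops are rejected and duplicate
#' `(u, v, type)` rows are merged. Parallel edges of *different* interaction
#' types are kept as distinct rows — the pair-level edge set is their
#' distinct `(u, v)` projection (see [kg_pairs()]).
#'
#' @param nodes a data frame with columns `id`, `name`, `type` (ids unique).
#' @param edges a data frame with columns `u`, `v` and optionally `type`
#'   (defaulting to `"associative"`).
#' @return a `kg_graph` object.
#' @examples
#' kg <- kg_graph(
#'   nodes = data.frame(id = c("a", "b"), name = c("ALPHA", "BETA"),
#'                      type = "protein"),
#'   edges = data.frame(u = "b", v = "a")
#' )
#' kg
#' @export
kg_graph <- function(nodes, edges = NULL) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("id", "name", "type")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    stop("node table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  nodes$name <- as.character(nodes$name)
  nodes$type <- as.character(nodes$type)
  bad <- which(is.na(nodes$id) | nodes$id == "")
  if (length(bad) > 0) {
    stop("malformed node row ", bad[1], ": empty or missing id", call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    dup <- nodes$id[duplicated(nodes$id)][1]
    stop("duplicate node id: ", dup, call. = FALSE)
  }

  if (is.null(edges) || nrow(tibble::as_tibble(edges)) == 0) {
    edges <- tibble::tibble(u = character(0), v = character(0),
                            type = character(0))
  } else {
    edges <- tibble::as_tibble(edges)
    if (!all(c("u", "v") %in% names(edges))) {
      stop("edge table must have columns `u` and `v`", call. = FALSE)
    }
    if (!"type" %in% names(edges)) edges$type <- "associative"
    edges$u <- as.character(edges$u)
    edges$v <- as.character(edges$v)
    edges$type <- as.character(edges$type)
    bad <- which(is.na(edges$u) | is.na(edges$v) | edges$u == "" | edges$v == "")
    if (length(bad) > 0) {
      stop("malformed edge row ", bad[1], ": empty or missing endpoint",
           call. = FALSE)
    }
    loop <- which(edges$u == edges$v)
    if (length(loop) > 0) {
      stop("self-loop at edge row ", loop[1], " (node ", edges$u[loop[1]], ")",
           call. = FALSE)
    }
    unknown <- setdiff(c(edges$u, edges$v), nodes$id)
    if (length(unknown) > 0) {
      stop("edge references unknown node(s): ",
           paste(utils::head(unknown, 3), collapse = ", "),
           call. = FALSE)
    }
    edges <- canonicalize_edges(edges)
  }
  structure(list(nodes = nodes, edges = edges), class = "kg_graph")
}

canonicalize_edges <- function(edges) {
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]
  edges$u[swap] <- edges$v[swap]
  edges$v[swap] <- tmp
  edges |>
    dplyr::distinct(.data$u, .data$v, .data$type) |>
    dplyr::arrange(.data$u, .data$v, .data$type)
}

#' @export
print.kg_graph <- function(x, ...) {
  cat("<kg_graph> ", nrow(x$nodes), " nodes (",
      dplyr::n_distinct(x$nodes$type), " types), ",
      nrow(kg_pairs(x)), " edges\n", sep = "")
  invisible(x)
}

#' Distinct node-pair edge list of a graph
#'
#' Collapses parallel typed edges to one row per unordered pair.
#'
#' @param kg a `kg_graph`.
#' @return a tibble with columns `u`, `v`, canonically ordered.
#' @export
kg_pairs <- function(kg) {
  stopifnot(inherits(kg, "kg_graph"))
  dplyr::distinct(kg$edges, .data$u, .data$v)
}

#' Load a knowledge graph from node and edge tables
#'
#' Accepts in-memory data frames or paths to CSV files. The node CSV must
#' have columns `id,name,type` (plus optional `feat_*` columns); the edge
#' CSV must have `u,v` and optionally `type`. Symmetric duplicate edges are
#' merged into the canonical `u < v` form.
#'
#' @param node_table data frame or CSV path.
#' @param edge_table data frame or CSV path.
#' @return a `kg_graph`.
#' @examples
#' nodes <- data.frame(id = c("p1", "p2"), name = c("KINASE1", "TARGET2"),
#'                     type = "protein")
#' edges <- data.frame(u = "p2", v = "p1", type = "binding")
#' load_graph(nodes, edges)
#' @export
load_graph <- function(node_table, edge_table) {
  if (is.character(node_table)) {
    node_table <- utils::read.csv(node_table, stringsAsFactors = FALSE,
                                  colClasses = NA)
  }
  if (is.character(edge_table)) {
    edge_table <- utils::read.csv(edge_table, stringsAsFactors = FALSE)
  }
  kg_graph(node_table, edge_table)
}

#' Write a knowledge graph to a pair of CSV files
#'
#' Inverse of [load_graph()]: writes the canonical node and edge tables so
#' that a load/write/load cycle is bit-identical.
#'
#' @param kg a `kg_graph`.
#' @param node_path,edge_path output CSV paths.
#' @return `kg`, invisibly.
#' @export
write_graph <- function(kg, node_path, edge_path) {
  stopifnot(inherits(kg, "kg_graph"))
  utils::write.csv(kg$nodes, node_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(kg$edges, edge_path, row.names = FALSE, quote = FALSE)
  invisible(kg)
}

#' Project a heterogeneous graph onto one entity type
#'
#' Keeps exactly the nodes of `kept_type` and the edges whose *both*
#' endpoints are of that type (induced subgraph). Edges that run through
#' nodes of other types are dropped, not contracted.
#'
#' @param kg a `kg_graph`.
#' @param kept_type an entity-type label, e.g. `"protein"`.
#' @return the projected `kg_graph`. If no node has `kept_type` the result
#'   is an empty graph and a warning is raised.
#' @export
project_unipartite <- function(kg, kept_type) {
  stopifnot(inherits(kg, "kg_graph"), is.character(kept_type),
            length(kept_type) == 1)
  keep <- kg$nodes$id[kg$nodes$type == kept_type]
  if (length(keep) == 0) {
    warning("no node has type '", kept_type, "'; returning an empty graph",
            call. = FALSE)
  }
  induce_subgraph(kg, keep)
}

induce_subgraph <- function(kg, node_ids) {
  nodes <- kg$nodes[kg$nodes$id %in% node_ids, , drop = FALSE]
  edges <- kg$edges[kg$edges$u %in% node_ids & kg$edges$v %in% node_ids, ,
                    drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "kg_graph")
}

#' Drop nodes with short names
#'
#' Short entity names (four characters or fewer, by default) are the main
#' source of dictionary-mapping ambiguity in literature-derived networks,
#' so they are filtered out before embedding. Incident edges are removed
#' with the node.
#'
#' @param kg a `kg_graph`.
#' @param min_chars minimum name length to keep (default 5: names of four
#'   characters or less are removed).
#' @return the filtered `kg_graph`.
#' @export
filter_short_names <- function(kg, min_chars = 5) {
  stopifnot(inherits(kg, "kg_graph"), min_chars >= 1)
  keep <- kg$nodes$id[nchar(kg$nodes$name) >= min_chars]
  induce_subgraph(kg, keep)
}

#' Co-occurrence feature from a p-value
#'
#' Literature co-occurrence significance enters the pair classifier as
#' `1 - p`, so that strongly co-mentioned pairs score near 1.
#'
#' @param p co-occurrence p-value(s) in \[0, 1\].
#' @return `1 - p`.
#' @examples
#' cooccurrence_feature(0.05) # 0.95
#' @export
cooccurrence_feature <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  1 - p
}

#' Validate and canonicalize a co-occurrence table
#'
#' @param df data frame or CSV path with columns `u`, `v`, `p_value`.
#' @return a tibble with canonical pair keys (`u < v`) and `p_value` in
#'   \[0, 1\]. A pair absent from the table is a distinct state (no
#'   co-occurrence data), never imputed as `p = 1`.
#' @export
cooc_table <- function(df) {
  if (is.character(df)) df <- utils::read.csv(df, stringsAsFactors = FALSE)
  df <- tibble::as_tibble(df)
  if (!all(c("u", "v", "p_value") %in% names(df))) {
    stop("co-occurrence table needs columns u, v, p_value", call. = FALSE)
  }
  if (any(is.na(df$p_value)) || any(df$p_value < 0) || any(df$p_value > 1)) {
    stop("co-occurrence p-values must lie in [0, 1]", call. = FALSE)
  }
  df$u <- as.character(df$u); df$v <- as.character(df$v)
  swap <- df$u > df$v
  tmp <- df$u[swap]; df$u[swap] <- df$v[swap]; df$v[swap] <- tmp
  dplyr::distinct(df, .data$u, .data$v, .keep_all = TRUE) |>
    dplyr::arrange(.data$u, .data$v)
}

#' Per-type node census
#'
#' @param kg a `kg_graph`.
#' @return a tibble with columns `type`, `n`.
#' @export
kg_census <- function(kg) {
  stopifnot(inherits(kg, "kg_graph"))
  dplyr::count(kg$nodes, .data$type, name = "n")
}
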