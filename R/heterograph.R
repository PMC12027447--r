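#' Node types of the biomolecular heterograph
#'
#' The eight molecular/entity classes, with their fixed integer labels 0-7.
#' @export
hetero_node_types <- function() {
  c(miRNA = 0L, disease = 1L, drug = 2L, mRNA = 3L, protein = 4L,
    lncRNA = 5L, microbe = 6L, circRNA = 7L)
}

#' Default relation manifest
#'
#' The sixteen typed association classes wiring the heterograph, each naming
#' its endpoint node types. Users may supply their own manifest to
#' [build_heterograph()] to regroup sources.
#' @return data.frame with columns `relation`, `src_type`, `dst_type`.
#' @export
relation_manifest <- function() {
  m <- rbind(
    c("miRNA-disease",   "miRNA",   "disease"),
    c("circRNA-disease", "circRNA", "disease"),
    c("circRNA-miRNA",   "circRNA", "miRNA"),
    c("mRNA-disease",    "mRNA",    "disease"),
    c("lncRNA-disease",  "lncRNA",  "disease"),
    c("microbe-disease", "microbe", "disease"),
    c("drug-disease",    "drug",    "disease"),
    c("drug-protein",    "drug",    "protein"),
    c("miRNA-drug",      "miRNA",   "drug"),
    c("drug-microbe",    "drug",    "microbe"),
    c("mRNA-drug",       "mRNA",    "drug"),
    c("lncRNA-miRNA",    "lncRNA",  "miRNA"),
    c("lncRNA-mRNA",     "lncRNA",  "mRNA"),
    c("miRNA-mRNA",      "miRNA",   "mRNA"),
    c("lncRNA-protein",  "lncRNA",  "protein"),
    c("miRNA-protein",   "miRNA",   "protein"))
  data.frame(relation = m[, 1L], src_type = m[, 2L], dst_type = m[, 3L],
             stringsAsFactors = FALSE)
}

#' Build the typed heterogeneous biomolecular graph
#'
#' Nodes are collected from the edge tables (plus optional explicit id
#' lists), ordered lexicographically within type for reproducible indexing.
#' Edges are deduplicated and mirrored (stored in both directions), since
#' every source association is a symmetric co-occurrence relation. Isolated
#' nodes are retained.
#'
#' @param tables named list of data.frames with columns `src_id`, `dst_id`;
#'   names must appear in the manifest's `relation` column.
#' @param manifest relation -> endpoint-type table, default
#'   [relation_manifest()].
#' @param extra_nodes optional named list (by node type) of ids to include
#'   even if they touch no edge.
#' @return object of class `heterograph`: per-type id lists, global index
#'   offsets, per-relation integer edge matrices (global indices, mirrored),
#'   relation ids, and the type labels.
#' @export
build_heterograph <- function(tables, manifest = relation_manifest(),
                              extra_nodes = NULL) {
  types <- hetero_node_types()
  if (!all(names(tables) %in% manifest$relation))
    stop("unknown relation(s): ",
         paste(setdiff(names(tables), manifest$relation), collapse = ", "))
  if (!all(manifest$src_type %in% names(types)) ||
      !all(manifest$dst_type %in% names(types)))
    stop("manifest references unknown node type")
  # collect ids per type
  ids <- stats::setNames(vector("list", length(types)), names(types))
  add_ids <- function(type, x) {
    ids[[type]] <<- union(ids[[type]], as.character(x))
  }
  for (rel in names(tables)) {
    row <- manifest[manifest$relation == rel, ]
    tb <- tables[[rel]]
    if (!all(c("src_id", "dst_id") %in% names(tb)))
      stop("edge table '", rel, "' needs src_id/dst_id columns")
    if (any(tb$src_id == tb$dst_id))
      stop("self-loop in relation '", rel, "'")
    add_ids(row$src_type, tb$src_id)
    add_ids(row$dst_type, tb$dst_id)
  }
  if (!is.null(extra_nodes))
    for (tp in names(extra_nodes)) add_ids(tp, extra_nodes[[tp]])
  ids <- lapply(ids, function(x) sort(x %||% character(0)))
  counts <- vapply(ids, length, integer(1))
  offsets <- c(0L, cumsum(counts))[seq_along(counts)]
  names(offsets) <- names(types)
  glob <- function(type, id) offsets[[type]] + match(id, ids[[type]])
  edges <- list()
  for (rel in names(tables)) {
    row <- manifest[manifest$relation == rel, ]
    tb <- unique(data.frame(src_id = as.character(tables[[rel]]$src_id),
                            dst_id = as.character(tables[[rel]]$dst_id),
                            stringsAsFactors = FALSE))
    if (!nrow(tb)) next
    s <- glob(row$src_type, tb$src_id)
    d <- glob(row$dst_type, tb$dst_id)
    e <- cbind(src = c(s, d), dst = c(d, s))  # mirror
    edges[[rel]] <- unique(e)
    attr(edges[[rel]], "table") <- tb
  }
  structure(list(node_types = types,
                 nodes = ids,
                 n_nodes = sum(counts),
                 offsets = offsets,
                 edges = edges,
                 relation_ids = stats::setNames(
                   seq_len(nrow(manifest)) - 1L, manifest$relation),
                 manifest = manifest),
            class = "heterograph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Global node index for ids of one type
#' @param graph a `heterograph`; `type` node type; `id` character ids.
#' @export
node_index <- function(graph, type, id) {
  idx <- graph$offsets[[type]] + match(as.character(id), graph$nodes[[type]])
  if (anyNA(idx)) stop("unknown ", type, " id(s): ",
                       paste(id[is.na(idx)], collapse = ", "))
  idx
}

#' Row-normalised adjacency operator
#'
#' Sparse matrix \eqn{\hat A} whose product with a node-feature matrix gives
#' each node the mean of its neighbours (across all relations pooled, the
#' default) or the mean of per-relation means. Rows of isolated nodes are
#' zero, so their neighbour context is the zero vector.
#'
#' @param graph a `heterograph`.
#' @param aggregator `"mean"` or `"relation_mean"`.
#' @return a `dgCMatrix` of dimension n_nodes x n_nodes.
#' @export
hetero_adjacency <- function(graph, aggregator = c("mean", "relation_mean")) {
  aggregator <- match.arg(aggregator)
  n <- graph$n_nodes
  if (!length(graph$edges))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  if (aggregator == "mean") {
    e <- do.call(rbind, graph$edges)
    e <- unique(e)
    a <- Matrix::sparseMatrix(i = e[, "src"], j = e[, "dst"], x = 1,
                              dims = c(n, n))
    deg <- Matrix::rowSums(a)
    inv <- ifelse(deg > 0, 1 / deg, 0)
    Matrix::Diagonal(x = inv) %*% a
  } else {
    acc <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n))
    nrel <- numeric(n)
    for (rel in names(graph$edges)) {
      e <- graph$edges[[rel]]
      a <- Matrix::sparseMatrix(i = e[, "src"], j = e[, "dst"], x = 1,
                                dims = c(n, n))
      deg <- Matrix::rowSums(a)
      inv <- ifelse(deg > 0, 1 / deg, 0)
      acc <- acc + Matrix::Diagonal(x = inv) %*% a
      nrel <- nrel + (deg > 0)
    }
    inv <- ifelse(nrel > 0, 1 / nrel, 0)
    Matrix::Diagonal(x = inv) %*% acc
  }
}

#' Initial node features for the heterograph
#'
#' miRNA and disease rows are the fused (projected) similarity features;
#' the six other types are drawn i.i.d. N(0, 0.1^2) under the given seed.
#'
#' @param graph a `heterograph`.
#' @param fused_mirna,fused_disease matrices with rownames covering the
#'   graph's miRNA / disease ids; width `embed_dim`.
#' @param embed_dim feature width; `seed` RNG seed for the random types.
#' @return n_nodes x embed_dim matrix.
#' @export
init_node_features <- function(graph, fused_mirna, fused_disease,
                               embed_dim, seed = 1L) {
  if (ncol(fused_mirna) != embed_dim || ncol(fused_disease) != embed_dim)
    stop("fused feature width does not match embed_dim")
  if (!all(graph$nodes$miRNA %in% rownames(fused_mirna)))
    stop("fused_mirna missing graph miRNA id(s)")
  if (!all(graph$nodes$disease %in% rownames(fused_disease)))
    stop("fused_disease missing graph disease id(s)")
  set.seed(as.integer(seed))
  h <- matrix(stats::rnorm(graph$n_nodes * embed_dim, sd = 0.1),
              graph$n_nodes, embed_dim)
  if (length(graph$nodes$miRNA))
    h[node_index(graph, "miRNA", graph$nodes$miRNA), ] <-
      fused_mirna[graph$nodes$miRNA, , drop = FALSE]
  if (length(graph$nodes$disease))
    h[node_index(graph, "disease", graph$nodes$disease), ] <-
      fused_disease[graph$nodes$disease, , drop = FALSE]
  h
}

#' Write / read a heterograph as TSV edge lists
#'
#' One file per relation (`<relation>.tsv`, columns src_id/dst_id/relation,
#' un-mirrored) plus `nodes.tsv` (node_id, node_type) so isolated nodes
#' round-trip.
#'
#' @param graph a `heterograph`; `dir` output directory.
#' @export
write_heterograph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_nodes <- do.call(rbind, lapply(names(graph$nodes), function(tp) {
    if (!length(graph$nodes[[tp]])) return(NULL)
    data.frame(node_id = graph$nodes[[tp]], node_type = tp)
  }))
  utils::write.table(all_nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (rel in names(graph$edges)) {
    tb <- attr(graph$edges[[rel]], "table")
    df <- data.frame(src_id = tb$src_id, dst_id = tb$dst_id, relation = rel)
    utils::write.table(df, file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", rel), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_heterograph
#' @param manifest manifest used to rebuild; default [relation_manifest()].
#' @export
read_heterograph <- function(dir, manifest = relation_manifest()) {
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"),
                             colClasses = "character")
  extra <- split(nodes$node_id, nodes$node_type)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  files <- files[basename(files) != "nodes.tsv"]
  tables <- list()
  for (f in files) {
    df <- utils::read.delim(f, colClasses = "character")
    rel <- unique(df$relation)
    if (length(rel) != 1L) stop("mixed relations in ", f)
    tables[[rel]] <- df[, c("src_id", "dst_id")]
  }
  tables <- tables[intersect(manifest$relation, names(tables))]
  build_heterograph(tables, manifest = manifest, extra_nodes = extra)
}
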