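#' Synthetic study specification
#'
#' Parameters of the planted-partition fixture generator: entity counts per
#' node type, the number of latent groups shared by miRNAs, diseases and the
#' auxiliary molecules, within/between-group edge probabilities (the planted
#' signal requires `intra > inter`), DAG shape, sequence lengths and
#' mutation rate.
#'
#' @param n_mirna,n_disease entity counts for the two focal types.
#' @param n_other count for each of the six auxiliary types.
#' @param n_groups latent groups; `intra`,`inter` edge probabilities.
#' @param dag_depth levels per disease DAG including the disease itself
#'   (1 = bare root); `dag_branching` parent terms fanning out at the level
#'   above the diseases.
#' @param seq_len_range inclusive sequence length range, within \[15, 30\].
#' @param mutation_rate per-position substitution rate off the group
#'   template.
#' @param p_down probability an association is a down-regulation (k = 1).
#' @param seed master seed of the generator.
#' @export
synthetic_spec <- function(n_mirna = 60L, n_disease = 50L, n_other = 20L,
                           n_groups = 4L, intra = 0.4, inter = 0.02,
                           dag_depth = 3L, dag_branching = 2L,
                           seq_len_range = c(20L, 23L), mutation_rate = 0.1,
                           p_down = 0.2, seed = 7L) {
  stopifnot(intra >= 0, intra <= 1, inter >= 0, inter <= 1)
  if (intra <= inter) stop("planted signal requires intra > inter")
  if (seq_len_range[1] < 15L || seq_len_range[2] > 30L)
    stop("seq_len_range must lie within [15, 30]")
  if (dag_depth < 1L) stop("dag_depth must be >= 1")
  structure(list(n_mirna = as.integer(n_mirna),
                 n_disease = as.integer(n_disease),
                 n_other = as.integer(n_other),
                 n_groups = as.integer(n_groups),
                 intra = intra, inter = inter,
                 dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 seq_len_range = as.integer(seq_len_range),
                 mutation_rate = mutation_rate,
                 p_down = p_down,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.group_of <- function(n, g) rep_len(seq_len(g), n)

.synth_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Generate the disease DAG forest
#'
#' Diseases in one latent group share a chain of ancestor terms (depth - 1
#' levels), with the last level fanned out over `dag_branching` parent
#' terms; groups are disjoint, so between-group semantic similarity is
#' exactly zero while within-group diseases overlap heavily.
#'
#' @param spec a [synthetic_spec()]; `lambda` decay factor for the DAGs.
#' @return named list of [disease_dag()].
#' @export
make_dag_forest <- function(spec, lambda = 0.5) {
  set.seed(derive_seed(spec$seed, "dags"))
  dids <- .synth_ids("D", spec$n_disease)
  grp <- .group_of(spec$n_disease, spec$n_groups)
  dags <- stats::setNames(vector("list", spec$n_disease), dids)
  for (i in seq_len(spec$n_disease)) {
    d <- dids[i]; g <- grp[i]
    if (spec$dag_depth == 1L) {
      dags[[d]] <- disease_dag(d, d, lambda = lambda)
      next
    }
    chain <- sprintf("G%d_anc%d", g, seq_len(spec$dag_depth - 1L))
    nodes <- c(d, chain)
    edges <- NULL
    if (length(chain) > 1L)
      edges <- cbind(chain[-length(chain)], chain[-1L])
    if (spec$dag_branching > 1L && spec$dag_depth > 1L) {
      # fan the last ancestor level out into branching parents
      parent <- sprintf("G%d_par%d", g,
                        ((i - 1L) %% spec$dag_branching) + 1L)
      nodes <- c(nodes, parent)
      edges <- rbind(edges, c(chain[length(chain)], parent),
                     c(parent, d))
    } else {
      edges <- rbind(edges, c(chain[length(chain)], d))
    }
    dags[[d]] <- disease_dag(d, nodes, edges, lambda = lambda)
  }
  dags
}

#' Generate miRNA sequences
#'
#' One random template per latent group (length uniform in
#' `seq_len_range`); each miRNA copies its group's template with i.i.d.
#' point substitutions at `mutation_rate`.
#'
#' @param spec a [synthetic_spec()].
#' @return named character vector over the RNA alphabet.
#' @export
make_sequences <- function(spec) {
  set.seed(derive_seed(spec$seed, "seqs"))
  alph <- c("A", "C", "G", "U")
  mids <- .synth_ids("M", spec$n_mirna)
  grp <- .group_of(spec$n_mirna, spec$n_groups)
  templates <- lapply(seq_len(spec$n_groups), function(g) {
    len <- sample(seq(spec$seq_len_range[1], spec$seq_len_range[2]), 1L)
    sample(alph, len, replace = TRUE)
  })
  seqs <- vapply(seq_len(spec$n_mirna), function(i) {
    tpl <- templates[[grp[i]]]
    mut <- stats::runif(length(tpl)) < spec$mutation_rate
    tpl[mut] <- vapply(which(mut), function(j)
      sample(setdiff(alph, tpl[j]), 1L), character(1))
    paste(tpl, collapse = "")
  }, character(1))
  stats::setNames(seqs, mids)
}

#' Generate the heterograph tables and planted ground truth
#'
#' Every entity carries a latent group; for each relation in the manifest,
#' an edge between a group-g and a group-g' entity is drawn Bernoulli with
#' probability `intra` if g = g' and `inter` otherwise. The miRNA-disease
#' association table additionally carries a regulation sign. Group labels
#' are returned as the planted truth.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `assoc` (signed association table), `aux_tables` (typed
#'   edge tables for the other relations), `groups` (named list of integer
#'   group labels per node type), `mirna_ids`, `disease_ids`.
#' @export
make_heterograph <- function(spec) {
  set.seed(derive_seed(spec$seed, "graph"))
  types <- names(hetero_node_types())
  counts <- stats::setNames(c(spec$n_mirna, spec$n_disease,
                              rep(spec$n_other, 6L)), types)
  prefixes <- c(miRNA = "M", disease = "D", drug = "R", mRNA = "T",
                protein = "P", lncRNA = "L", microbe = "B", circRNA = "C")
  ids <- lapply(types, function(tp) .synth_ids(prefixes[[tp]], counts[[tp]]))
  names(ids) <- types
  groups <- lapply(types, function(tp) {
    g <- .group_of(counts[[tp]], spec$n_groups)
    stats::setNames(g, ids[[tp]])
  })
  names(groups) <- types
  draw_edges <- function(src_type, dst_type) {
    gs <- groups[[src_type]]; gd <- groups[[dst_type]]
    p <- outer(gs, gd, function(a, b) ifelse(a == b, spec$intra, spec$inter))
    hit <- which(matrix(stats::runif(length(p)) < p, nrow(p)), arr.ind = TRUE)
    data.frame(src_id = names(gs)[hit[, 1L]],
               dst_id = names(gd)[hit[, 2L]],
               stringsAsFactors = FALSE)
  }
  manifest <- relation_manifest()
  tables <- list()
  for (r in seq_len(nrow(manifest)))
    tables[[manifest$relation[r]]] <-
      draw_edges(manifest$src_type[r], manifest$dst_type[r])
  md <- tables[["miRNA-disease"]]
  assoc <- data.frame(mirna = md$src_id, disease = md$dst_id,
                      k = as.integer(stats::runif(nrow(md)) < spec$p_down),
                      stringsAsFactors = FALSE)
  list(assoc = assoc,
       aux_tables = tables[setdiff(names(tables), "miRNA-disease")],
       groups = groups,
       mirna_ids = ids$miRNA, disease_ids = ids$disease)
}

#' Generate a complete in-memory study dataset
#'
#' Bundles DAG forest, sequences, association and auxiliary tables into the
#' input list consumed by [fit_gonnmda()] and [run_cv()].
#'
#' @param spec a [synthetic_spec()]; `lambda` DAG decay factor.
#' @export
make_dataset <- function(spec = synthetic_spec(), lambda = 0.5) {
  hg <- make_heterograph(spec)
  list(assoc = hg$assoc,
       dags = make_dag_forest(spec, lambda = lambda),
       seqs = make_sequences(spec),
       aux_tables = hg$aux_tables,
       groups = hg$groups,
       mirna_ids = hg$mirna_ids,
       disease_ids = hg$disease_ids,
       spec = spec)
}

#' In-sample AUC of a logistic oracle on the planted groups
#'
#' Fits a logistic regression of the pair labels on the interaction of the
#' two planted group factors -- the generator's own latent variables -- and
#' reports its AUC on the dataset. Certifies how much signal the fixture
#' carries before the graph model is judged against it.
#'
#' @param dataset labelled pair data.frame (`mirna`, `disease`, `label`).
#' @param groups the `groups` element of [make_dataset()].
#' @export
planted_oracle_auc <- function(dataset, groups) {
  df <- data.frame(
    y = dataset$label,
    gm = factor(groups$miRNA[dataset$mirna]),
    gd = factor(groups$disease[dataset$disease]))
  fit <- suppressWarnings(stats::glm(y ~ gm * gd, family = stats::binomial(),
                                     data = df))
  threshold_free_metrics(df$y, stats::fitted(fit))$auc
}

#' Write a synthetic dataset to disk
#'
#' Emits the exact dialects the readers consume: `mirna.fasta`,
#' `disease_dags.tsv` (child, parent, root_disease; empty parent declares a
#' bare node), `associations.tsv` (mirna, disease, k), one TSV per
#' auxiliary relation, and `groups.tsv` with the planted labels.
#'
#' @param spec a [synthetic_spec()]; `dir` output directory.
#' @return the dataset list, invisibly.
#' @export
simulate_dataset <- function(spec = synthetic_spec(), dir) {
  data <- make_dataset(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste0(">", names(data$seqs), "\n", unname(data$seqs)),
             file.path(dir, "mirna.fasta"))
  dag_rows <- do.call(rbind, lapply(data$dags, function(dag) {
    if (nrow(dag$edges)) {
      data.frame(child = dag$edges[, "child"], parent = dag$edges[, "parent"],
                 root_disease = dag$disease_id)
    } else {
      data.frame(child = dag$disease_id, parent = "",
                 root_disease = dag$disease_id)
    }
  }))
  utils::write.table(dag_rows, file.path(dir, "disease_dags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data$assoc, file.path(dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (rel in names(data$aux_tables)) {
    df <- data$aux_tables[[rel]]
    df$relation <- rep(rel, nrow(df))
    utils::write.table(df,
                       file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", rel), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  grp <- do.call(rbind, lapply(names(data$groups), function(tp)
    data.frame(node_id = names(data$groups[[tp]]), node_type = tp,
               group = unname(data$groups[[tp]]))))
  utils::write.table(grp, file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(data)
}

#' Read a dataset directory written by [simulate_dataset()]
#'
#' @param dir dataset directory; `lambda` DAG decay factor.
#' @export
read_dataset <- function(dir, lambda = 0.5) {
  seqs <- read_mirna_fasta(file.path(dir, "mirna.fasta"))
  dags <- read_dag_table(file.path(dir, "disease_dags.tsv"), lambda = lambda)
  assoc <- read_association_table(file.path(dir, "associations.tsv"))
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  skip <- c("disease_dags.tsv", "associations.tsv", "groups.tsv", "nodes.tsv")
  aux <- list()
  for (f in files[!basename(files) %in% skip]) {
    df <- utils::read.delim(f, colClasses = "character")
    if (!nrow(df)) next
    rel <- unique(df$relation)
    aux[[rel]] <- df[, c("src_id", "dst_id")]
  }
  groups <- NULL
  gf <- file.path(dir, "groups.tsv")
  if (file.exists(gf)) {
    g <- utils::read.delim(gf, colClasses = c("character", "character",
                                              "integer"))
    groups <- lapply(split(g, g$node_type), function(x)
      stats::setNames(x$group, x$node_id))
  }
  list(assoc = assoc, dags = dags, seqs = seqs, aux_tables = aux,
       groups = groups,
       mirna_ids = sort(names(seqs)),
       disease_ids = sort(names(dags)))
}
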