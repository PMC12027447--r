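#' Disease DAG constructor
#'
#' Represents one disease together with its ancestor closure in a MeSH-style
#' hierarchy as a directed acyclic graph \eqn{DAG_d = (d, T_d, E_d)}. Edges
#' point parent -> child; the disease itself is the unique sink and every
#' node must reach it.
#'
#' @param disease_id character scalar, the root (most specific) term.
#' @param nodes character vector of term ids, must contain `disease_id`.
#' @param edges two-column matrix or data.frame of (parent, child) pairs;
#'   may have zero rows for a bare root.
#' @param lambda semantic contribution factor in (0,1); each step up the
#'   hierarchy decays a term's contribution by this factor.
#' @return an object of class `disease_dag`.
#' @export
disease_dag <- function(disease_id, nodes, edges = NULL, lambda = 0.5) {
  stopifnot(is.character(disease_id), length(disease_id) == 1L)
  nodes <- unique(as.character(nodes))
  if (!disease_id %in% nodes)
    stop("disease_id must be one of the DAG nodes")
  if (!(is.numeric(lambda) && length(lambda) == 1L && lambda > 0 && lambda < 1))
    stop("lambda must lie strictly in (0, 1)")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L,
                    dimnames = list(NULL, c("parent", "child")))
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    mode(edges) <- "character"
    colnames(edges) <- c("parent", "child")
    edges <- unique(edges)
    bad <- !(edges[, 1L] %in% nodes & edges[, 2L] %in% nodes)
    if (any(bad)) stop("edge endpoints outside the node set: ",
                       paste(unique(c(edges[bad, ])), collapse = ", "))
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loop in DAG edges")
  }
  dag <- structure(list(disease_id = disease_id, nodes = nodes,
                        edges = edges, lambda = lambda),
                   class = "disease_dag")
  .validate_dag(dag)
  dag
}

# acyclicity + ancestor-closure check; stops on violation
.validate_dag <- function(dag) {
  n <- length(dag$nodes)
  if (n == 1L) return(invisible(TRUE))
  # reverse reachability from the root along child -> parent
  reach <- dag$disease_id
  repeat {
    up <- dag$edges[dag$edges[, "child"] %in% reach, "parent"]
    new <- setdiff(up, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  if (length(setdiff(dag$nodes, reach)))
    stop("node(s) with no path to the root disease: ",
         paste(setdiff(dag$nodes, reach), collapse = ", "))
  # Kahn topological check for cycles
  edges <- dag$edges
  indeg <- table(factor(edges[, "child"], levels = dag$nodes))
  queue <- dag$nodes[indeg == 0L]
  seen <- 0L
  indeg <- as.integer(indeg); names(indeg) <- dag$nodes
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    ch <- edges[edges[, "parent"] == v, "child"]
    for (c_ in ch) {
      indeg[c_] <- indeg[c_] - 1L
      if (indeg[c_] == 0L) queue <- c(queue, c_)
    }
  }
  if (seen < n) stop("cycle detected in disease DAG")
  invisible(TRUE)
}

#' Semantic values of all terms in a disease DAG
#'
#' The root disease has value 1; every other term t gets
#' \eqn{D_d(t) = \lambda \cdot \max_{t' \in children(t)} D_d(t')}, i.e. the
#' decayed value of its best child on the way down to the disease.
#'
#' @param dag a [disease_dag()].
#' @return named numeric vector over `dag$nodes`, all values in (0, 1].
#' @export
dag_semantic_values <- function(dag) {
  stopifnot(inherits(dag, "disease_dag"))
  # max over children of lambda * D(child) with D(d) = 1 is exactly
  # lambda ^ (fewest parent->child hops from t down to d): BFS upward.
  dist <- stats::setNames(rep(NA_integer_, length(dag$nodes)), dag$nodes)
  dist[dag$disease_id] <- 0L
  frontier <- dag$disease_id
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    up <- unique(dag$edges[dag$edges[, "child"] %in% frontier, "parent"])
    frontier <- up[is.na(dist[up])]
    dist[frontier] <- d
  }
  if (anyNA(dist)) stop("node(s) with no path to the root disease")
  stats::setNames(dag$lambda ^ as.numeric(dist), names(dist))
}

.semantic_total <- function(dag) sum(dag_semantic_values(dag))

.pair_matrix <- function(ids, fun) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    v <- fun(i, j)
    m[i, j] <- v; m[j, i] <- v
  }
  m
}

#' Disease semantic similarity (decay-based variant)
#'
#' Wang-style similarity: shared ancestor terms contribute the sum of their
#' semantic values in both DAGs, normalised by the total semantic values of
#' the two diseases.
#'
#' @param dags named list of [disease_dag()], one per disease.
#' @return symmetric similarity matrix over `names(dags)` with unit diagonal.
#' @export
dss1 <- function(dags) {
  if (!length(dags)) stop("at least one DAG required")
  if (is.null(names(dags)) || any(!nzchar(names(dags))))
    stop("dags must be a named list keyed by disease id")
  vals <- lapply(dags, dag_semantic_values)
  totals <- vapply(vals, sum, numeric(1))
  ids <- names(dags)
  .pair_matrix(ids, function(i, j) {
    shared <- intersect(names(vals[[i]]), names(vals[[j]]))
    if (!length(shared)) return(0)
    sum(vals[[i]][shared] + vals[[j]][shared]) / (totals[i] + totals[j])
  })
}

#' Disease semantic similarity (information-content variant)
#'
#' Term contributions are \eqn{-\log(G(t)/N_{DAG})} where G(t) counts the
#' DAGs in which term t appears; ubiquitous terms contribute nothing, rare
#' terms a lot. Similarity is the shared contribution normalised by the two
#' diseases' totals. The degenerate 0/0 case (every involved term present in
#' every DAG) is reported as 0 with a warning.
#'
#' @inheritParams dss1
#' @export
dss2 <- function(dags) {
  if (!length(dags)) stop("at least one DAG required")
  ids <- names(dags)
  n_dag <- length(dags)
  term_sets <- lapply(dags, function(d) d$nodes)
  counts <- table(unlist(lapply(term_sets, unique)))
  ic <- -log(as.numeric(counts) / n_dag)
  names(ic) <- names(counts)
  totals <- vapply(term_sets, function(ts) sum(ic[ts]), numeric(1))
  warned <- FALSE
  out <- .pair_matrix(ids, function(i, j) {
    shared <- intersect(term_sets[[i]], term_sets[[j]])
    num <- if (length(shared)) 2 * sum(ic[shared]) else 0
    den <- totals[i] + totals[j]
    if (den == 0) {
      if (num != 0) stop("internal inconsistency in term occurrence counts")
      warned <<- TRUE
      return(0)
    }
    num / den
  })
  if (warned)
    warning("dss2: zero total information content for some disease pair(s); similarity reported as 0")
  out
}

#' Gaussian interaction-profile kernel similarity
#'
#' \eqn{S(i,j) = \exp(-\sigma \|IP(i)-IP(j)\|^2)} with the data-adaptive
#' bandwidth \eqn{\sigma = \gamma' / (\frac{1}{N}\sum_k \|IP(k)\|^2)}.
#'
#' @param profiles binary matrix, one row per entity (rownames = ids),
#'   columns indexing the opposite entity set.
#' @param gamma_prime bandwidth scale, default 1.
#' @return symmetric kernel matrix with unit diagonal, entries in (0, 1].
#' @export
gip_kernel <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  if (!nrow(profiles)) stop("at least one profile required")
  if (!all(profiles %in% c(0, 1))) stop("profiles must be binary")
  norms2 <- rowSums(profiles^2)
  if (all(norms2 == 0)) stop("all-zero profile matrix: kernel bandwidth undefined")
  sigma <- gamma_prime / mean(norms2)
  # squared distances via the Gram expansion
  g <- tcrossprod(profiles)
  d2 <- outer(norms2, norms2, "+") - 2 * g
  d2[d2 < 0] <- 0
  s <- exp(-sigma * d2)
  diag(s) <- 1
  dimnames(s) <- list(rownames(profiles), rownames(profiles))
  s
}

#' Needleman-Wunsch global alignment score
#'
#' Classic dynamic program with linear gap penalty over the RNA alphabet
#' (T is normalised to U).
#'
#' @param a,b nucleotide strings over A/C/G/U (T accepted).
#' @param match,mismatch,gap scoring parameters.
#' @return the optimal global alignment score (numeric scalar).
#' @export
nw_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- .nw_chars(a); bv <- .nw_chars(b)
  n <- length(av); m <- length(bv)
  prev <- gap * (0:m)
  if (n == 0L) return(prev[m + 1L])
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- gap * i
    if (m > 0L) {
      sub <- ifelse(av[i] == bv, match, mismatch)
      for (j in seq_len(m)) {
        cur[j + 1L] <- max(prev[j] + sub[j], prev[j + 1L] + gap, cur[j] + gap)
      }
    }
    prev <- cur
  }
  prev[m + 1L]
}

.nw_chars <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(character(0))
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  v[v == "T"] <- "U"
  if (any(!v %in% c("A", "C", "G", "U")))
    stop("invalid nucleotide character: ",
         paste(unique(v[!v %in% c("A", "C", "G", "U")]), collapse = ", "))
  v
}

#' miRNA sequence similarity
#'
#' Pairwise Needleman-Wunsch scores, min-max normalised over the
#' off-diagonal pairs; the diagonal is fixed to 1. If all off-diagonal
#' scores coincide the normalisation is undefined and every off-diagonal
#' entry is set to 0.5 with a warning.
#'
#' @param seqs named character vector of miRNA sequences.
#' @inheritParams nw_score
#' @export
mirna_sequence_similarity <- function(seqs, match = 1, mismatch = -1, gap = -1) {
  if (length(seqs) < 2L) stop("at least two sequences required")
  if (is.null(names(seqs))) stop("seqs must be named by miRNA id")
  ids <- names(seqs)
  raw <- .pair_matrix(ids, function(i, j)
    nw_score(seqs[[i]], seqs[[j]], match, mismatch, gap))
  off <- raw[upper.tri(raw)]
  rng <- range(off)
  out <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  if (rng[1] == rng[2]) {
    warning("mirna_sequence_similarity: degenerate score range; off-diagonal set to 0.5")
    out[upper.tri(out)] <- 0.5
    out[lower.tri(out)] <- 0.5
  } else {
    norm <- (raw - rng[1]) / (rng[2] - rng[1])
    out[upper.tri(out)] <- norm[upper.tri(norm)]
    out[lower.tri(out)] <- norm[lower.tri(norm)]
  }
  out
}

#' miRNA functional similarity from signed disease associations
#'
#' Each miRNA is described over the full ordered disease universe by (a) its
#' signed disease semantic totals, \eqn{(-1)^k \sum_{t \in T_d} D_d(t)} for
#' the diseases it regulates (k = 0 up, k = 1 down), and (b) a
#' cross-similarity block carrying, for every disease in the universe, the
#' signed sum of its semantic similarity (DSS1) to the miRNA's associated
#' diseases. Functional similarity is the cosine of these feature vectors.
#'
#' @param assoc data.frame with columns `mirna`, `disease`, `k` (0/1).
#' @param dss disease-disease semantic similarity matrix (typically [dss1()]).
#' @param dags named list of [disease_dag()] covering every disease in `assoc`.
#' @param mirna_ids optional ordered miRNA universe (defaults to the miRNAs
#'   present in `assoc`).
#' @return symmetric matrix in \[-1, 1\] with unit diagonal; miRNAs with no
#'   associated disease get zero off-diagonal rows and are flagged in the
#'   `"empty_mirnas"` attribute.
#' @export
mirna_functional_similarity <- function(assoc, dss, dags, mirna_ids = NULL) {
  assoc <- validate_association_table(assoc)
  d_universe <- rownames(dss)
  if (is.null(d_universe)) stop("dss must carry disease ids as dimnames")
  if (!all(assoc$disease %in% d_universe))
    stop("disease(s) in assoc missing from dss: ",
         paste(setdiff(assoc$disease, d_universe), collapse = ", "))
  if (!all(assoc$disease %in% names(dags)))
    stop("disease(s) in assoc missing from dags")
  if (is.null(mirna_ids)) mirna_ids <- sort(unique(assoc$mirna))
  totals <- vapply(dags[d_universe], .semantic_total, numeric(1))
  n_m <- length(mirna_ids); n_d <- length(d_universe)
  mf <- matrix(0, n_m, n_d, dimnames = list(mirna_ids, d_universe))
  sign_ind <- matrix(0, n_m, n_d, dimnames = list(mirna_ids, d_universe))
  for (r in seq_len(nrow(assoc))) {
    i <- assoc$mirna[r]; d <- assoc$disease[r]
    if (!i %in% mirna_ids) next
    s <- if (assoc$k[r] == 0) 1 else -1
    mf[i, d] <- s * totals[d]
    sign_ind[i, d] <- s
  }
  mdf <- sign_ind %*% dss[d_universe, d_universe]
  feats <- cbind(mf, mdf)
  norms <- sqrt(rowSums(feats^2))
  empty <- mirna_ids[norms == 0]
  safe <- ifelse(norms == 0, 1, norms)
  unit <- feats / safe
  out <- tcrossprod(unit)
  diag(out) <- 1
  out[abs(out) < 1e-15] <- 0
  attr(out, "empty_mirnas") <- empty
  if (length(empty))
    warning("mirna_functional_similarity: miRNA(s) with no associated disease: ",
            paste(empty, collapse = ", "))
  out
}

#' Interaction profiles from an association table
#'
#' Binary biadjacency rows for one side of a bipartite association set, in
#' the orientation needed by [gip_kernel()].
#'
#' @param assoc data.frame with columns `mirna`, `disease`.
#' @param mirna_ids,disease_ids ordered universes.
#' @param side `"mirna"` (rows = miRNAs over diseases) or `"disease"`.
#' @export
interaction_profiles <- function(assoc, mirna_ids, disease_ids,
                                 side = c("mirna", "disease")) {
  side <- match.arg(side)
  A <- association_matrix(assoc, mirna_ids, disease_ids)
  if (side == "mirna") A else t(A)
}

#' Binary miRNA x disease association matrix
#' @inheritParams interaction_profiles
#' @export
association_matrix <- function(assoc, mirna_ids, disease_ids) {
  assoc <- validate_association_table(assoc, require_k = FALSE)
  A <- matrix(0, length(mirna_ids), length(disease_ids),
              dimnames = list(mirna_ids, disease_ids))
  keep <- assoc$mirna %in% mirna_ids & assoc$disease %in% disease_ids
  A[cbind(assoc$mirna[keep], assoc$disease[keep])] <- 1
  A
}

#' @keywords internal
validate_association_table <- function(assoc, require_k = TRUE) {
  assoc <- as.data.frame(assoc)
  need <- c("mirna", "disease", if (require_k) "k")
  if (!all(need %in% names(assoc)))
    stop("association table needs columns: ", paste(need, collapse = ", "))
  if (!"k" %in% names(assoc)) assoc$k <- 0L
  assoc$mirna <- as.character(assoc$mirna)
  assoc$disease <- as.character(assoc$disease)
  assoc$k <- as.integer(assoc$k)
  if (any(!assoc$k %in% c(0L, 1L))) stop("regulation flag k must be 0 or 1")
  if (anyDuplicated(assoc[, c("mirna", "disease")]))
    stop("duplicate (mirna, disease) pairs in association table")
  assoc
}

#' Check a similarity matrix's contract
#'
#' Symmetry within tolerance, finite entries, and (optionally) unit
#' diagonal and a [lo, hi] range. Used throughout the test-suite and by
#' readers of persisted matrices.
#'
#' @param s matrix; `tol` symmetry tolerance.
#' @param unit_diag require diag == 1; `range` optional c(lo, hi).
#' @export
check_similarity <- function(s, unit_diag = FALSE, range = NULL, tol = 1e-9) {
  if (!is.matrix(s) || nrow(s) != ncol(s)) stop("not a square matrix")
  if (any(!is.finite(s))) stop("non-finite entries in similarity matrix")
  if (max(abs(s - t(s))) > tol) stop("similarity matrix not symmetric")
  if (unit_diag && any(abs(diag(s) - 1) > tol)) stop("diagonal not 1")
  if (!is.null(range) && (min(s) < range[1] - tol || max(s) > range[2] + tol))
    stop("entries outside [", range[1], ", ", range[2], "]")
  invisible(TRUE)
}
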