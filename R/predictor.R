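#' Random negative sampling from the non-associated grid
#'
#' Uniform draw without replacement from the miRNA x disease grid minus the
#' known positives, reproducible by seed.
#'
#' @param positives data.frame with columns `mirna`, `disease`.
#' @param n_neg number of negatives to draw.
#' @param mirna_ids,disease_ids the pair universe.
#' @param seed RNG seed.
#' @return data.frame `mirna`, `disease` of sampled non-associations.
#' @export
negative_sample <- function(positives, n_neg, mirna_ids, disease_ids,
                            seed = 1L) {
  n_m <- length(mirna_ids); n_d <- length(disease_ids)
  pos_idx <- (match(positives$mirna, mirna_ids) - 1L) * n_d +
    match(positives$disease, disease_ids)
  if (anyNA(pos_idx)) stop("positive pair outside the given universe")
  universe <- n_m * n_d
  if (universe <= nrow(positives) + n_neg)
    stop("pair universe too small for requested negative sample")
  free <- setdiff(seq_len(universe), pos_idx)
  set.seed(as.integer(seed))
  pick <- sample(free, n_neg)
  data.frame(mirna = mirna_ids[(pick - 1L) %/% n_d + 1L],
             disease = disease_ids[(pick - 1L) %% n_d + 1L],
             stringsAsFactors = FALSE)
}

#' Balanced labelled pair dataset
#'
#' Positives from the association table plus an equal (or configured)
#' number of sampled negatives.
#'
#' @param assoc association table (`mirna`, `disease`, optional `k`).
#' @inheritParams negative_sample
#' @param n_neg defaults to the number of positives (balanced).
#' @return data.frame `mirna`, `disease`, `label`.
#' @export
build_pair_dataset <- function(assoc, mirna_ids, disease_ids,
                               n_neg = NULL, seed = 1L) {
  assoc <- validate_association_table(assoc, require_k = FALSE)
  if (is.null(n_neg)) n_neg <- nrow(assoc)
  neg <- negative_sample(assoc, n_neg, mirna_ids, disease_ids, seed)
  rbind(data.frame(mirna = assoc$mirna, disease = assoc$disease, label = 1L),
        data.frame(mirna = neg$mirna, disease = neg$disease, label = 0L))
}

#' Pair feature vector(s)
#'
#' Concatenation `[emb_m || fused_m || emb_d || fused_d]` of the two
#' endpoints' final GNN embeddings and their projected fused similarity
#' features.
#'
#' @param emb_m,fused_m,emb_d,fused_d matrices whose rows are aligned to the
#'   pair list (one row per pair).
#' @export
pair_features <- function(emb_m, fused_m, emb_d, fused_d) {
  stopifnot(nrow(emb_m) == nrow(fused_m), nrow(emb_m) == nrow(emb_d),
            nrow(emb_m) == nrow(fused_d))
  cbind(emb_m, fused_m, emb_d, fused_d)
}

# ---- multilayer perceptron -------------------------------------------------

#' Initialise an MLP
#'
#' `n_layers` affine layers (ReLU between, none after the last); the final
#' layer has one output unit whose sigmoid is the association probability.
#'
#' @param in_dim input width; `hidden` hidden width; `n_layers` >= 1.
#' @param seed RNG seed.
#' @export
mlp_init <- function(in_dim, hidden = 1024L, n_layers = 2L, seed = 1L) {
  stopifnot(hidden >= 1L, n_layers >= 1L)
  set.seed(as.integer(seed))
  sizes <- c(in_dim, rep(hidden, n_layers - 1L), 1L)
  lapply(seq_len(n_layers), function(i)
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                 sd = sqrt(2 / sizes[i])),
                    sizes[i], sizes[i + 1L]),
         b = numeric(sizes[i + 1L])))
}

#' MLP forward pass
#' @param z input matrix (n x in_dim); `mlp` from [mlp_init()].
#' @return list `p` (probabilities in (0,1)), `logit`, `cache`.
#' @export
mlp_forward <- function(z, mlp) {
  if (any(!is.finite(z))) stop("non-finite MLP input")
  acts <- list(z)
  a <- z
  L <- length(mlp)
  for (i in seq_len(L)) {
    u <- sweep(a %*% mlp[[i]]$W, 2L, mlp[[i]]$b, "+")
    a <- if (i < L) pmax(u, 0) else u
    acts[[i + 1L]] <- a
  }
  logit <- as.numeric(a)
  list(p = 1 / (1 + exp(-logit)), logit = logit, cache = acts)
}

# reverse-mode gradients through the MLP; d_logit is n x 1
mlp_backward <- function(mlp, cache, d_logit) {
  L <- length(mlp)
  grads <- vector("list", L)
  d_a <- matrix(d_logit, ncol = 1L)
  for (i in rev(seq_len(L))) {
    if (i < L) d_a <- d_a * (cache[[i + 1L]] > 0)  # ReLU
    grads[[i]] <- list(W = crossprod(cache[[i]], d_a), b = colSums(d_a))
    d_a <- d_a %*% t(mlp[[i]]$W)
  }
  list(grads = grads, d_z = d_a)
}

# ---- parameter-tree utilities and Adam ------------------------------------

tree_map <- function(p, f) {
  if (is.list(p)) lapply(p, tree_map, f = f) else f(p)
}
tree_map2 <- function(a, b, f) {
  if (is.list(a)) Map(function(x, y) tree_map2(x, y, f), a, b) else f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  list(params = tree_map2(params, upd, `-`), state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- fold-wise feature construction ---------------------------------------

#' Build the six similarity matrices and fused features for one training fold
#'
#' Everything association-derived (both Gaussian kernels, the functional
#' similarity) is computed from `train_assoc` only; the semantic and
#' sequence similarities depend only on the static DAGs and sequences, so a
#' held-out pair can never alter the result.
#'
#' @param data list with `dags`, `seqs`, and the entity universes
#'   `mirna_ids`, `disease_ids`.
#' @param train_assoc signed association table visible to this fold.
#' @param config a run configuration ([default_config()]).
#' @return list: `sims` (six matrices), `F_m`, `F_d` (fused entity features).
#' @export
build_fold_features <- function(data, train_assoc, config = default_config()) {
  mids <- data$mirna_ids; dids <- data$disease_ids
  train_assoc <- validate_association_table(train_assoc)
  dss1_m <- dss1(data$dags[dids])
  dss2_m <- dss2(data$dags[dids])
  dgs <- gip_kernel(interaction_profiles(train_assoc, mids, dids, "disease"))
  mfs <- mirna_functional_similarity(train_assoc, dss1_m, data$dags,
                                     mirna_ids = mids)
  attr(mfs, "empty_mirnas") <- NULL
  mqs <- mirna_sequence_similarity(data$seqs[mids],
                                   match = config$nw$match,
                                   mismatch = config$nw$mismatch,
                                   gap = config$nw$gap)
  mgs <- gip_kernel(interaction_profiles(train_assoc, mids, dids, "mirna"))
  f_m <- fuse_similarities(list(MFS = mfs, MQS = mqs, MGS = mgs),
                           k_svd = config$fusion$k_svd,
                           mode = config$fusion$mode)$features
  f_d <- fuse_similarities(list(DSS1 = dss1_m, DSS2 = dss2_m, DGS = dgs),
                           k_svd = config$fusion$k_svd,
                           mode = config$fusion$mode)$features
  list(sims = list(DSS1 = dss1_m, DSS2 = dss2_m, DGS = dgs,
                   MFS = mfs, MQS = mqs, MGS = mgs),
       F_m = f_m, F_d = f_d)
}

# ---- end-to-end model ------------------------------------------------------

# assemble h0 from projections + fixed random features for the other types
.assemble_h0 <- function(model, p_m, p_d) {
  h0 <- model$h_other
  h0[model$idx_m_all, ] <- p_m
  h0[model$idx_d_all, ] <- p_d
  h0
}

# one full forward pass over the model for a pair list; returns loss pieces
.model_forward <- function(params, model, pairs_lm, pairs_ld, training = FALSE,
                           keep_cache = FALSE) {
  p_m <- project_features(model$F_m, params$proj_m)
  p_d <- project_features(model$F_d, params$proj_d)
  h0 <- .assemble_h0(model, p_m, p_d)
  fw <- ognn_forward(model$a_hat, h0, params$gnn, model$ognn_cfg,
                     training = training, keep_cache = keep_cache)
  z <- pair_features(fw$h[model$idx_m_all[pairs_lm], , drop = FALSE],
                     p_m[pairs_lm, , drop = FALSE],
                     fw$h[model$idx_d_all[pairs_ld], , drop = FALSE],
                     p_d[pairs_ld, , drop = FALSE])
  mf <- mlp_forward(z, params$mlp)
  list(p = mf$p, z = z, mlp_cache = mf$cache, fw = fw,
       p_m = p_m, p_d = p_d)
}

# full backward pass; returns gradient tree matching params
.model_backward <- function(params, model, fwd, pairs_lm, pairs_ld, y) {
  n <- length(y)
  D <- model$ognn_cfg$dim
  d_logit <- (fwd$p - y) / n
  mb <- mlp_backward(params$mlp, fwd$mlp_cache, d_logit)
  d_z <- mb$d_z
  gm_idx <- model$idx_m_all[pairs_lm]
  gd_idx <- model$idx_d_all[pairs_ld]
  d_emb <- matrix(0, model$n_nodes, D)
  agg_m <- rowsum(d_z[, seq_len(D), drop = FALSE], group = gm_idx)
  d_emb[as.integer(rownames(agg_m)), ] <- agg_m
  agg_d <- rowsum(d_z[, 2 * D + seq_len(D), drop = FALSE], group = gd_idx)
  d_emb[as.integer(rownames(agg_d)), ] <-
    d_emb[as.integer(rownames(agg_d)), , drop = FALSE] + agg_d
  bw <- ognn_backward(model$a_hat, params$gnn, model$ognn_cfg,
                      fwd$fw$cache, d_emb)
  # direct (skip) paths from the pair vector into the projections
  d_pm <- matrix(0, nrow(model$F_m), D)
  agg <- rowsum(d_z[, D + seq_len(D), drop = FALSE], group = pairs_lm)
  d_pm[as.integer(rownames(agg)), ] <- agg
  d_pd <- matrix(0, nrow(model$F_d), D)
  agg <- rowsum(d_z[, 3 * D + seq_len(D), drop = FALSE], group = pairs_ld)
  d_pd[as.integer(rownames(agg)), ] <- agg
  # plus the path through the initial node features
  d_pm <- d_pm + bw$d_h0[model$idx_m_all, , drop = FALSE]
  d_pd <- d_pd + bw$d_h0[model$idx_d_all, , drop = FALSE]
  list(proj_m = list(W = crossprod(model$F_m, d_pm), b = colSums(d_pm)),
       proj_d = list(W = crossprod(model$F_d, d_pd), b = colSums(d_pd)),
       gnn = bw$d_params,
       mlp = mb$grads)
}

#' Fit the full association model on one training fold
#'
#' Rebuilds the six similarity matrices and fused features from the training
#' positives, assembles the heterograph whose miRNA-disease edges are the
#' training positives only (test edges never enter message passing), and
#' trains the projection layers, the ordered GNN gates and the MLP
#' end-to-end by full-batch Adam on binary cross-entropy, with early
#' stopping.
#'
#' @param data list: `assoc` (signed table; only rows matching
#'   `train_pairs` positives are used), `dags`, `seqs`, `aux_tables` (named
#'   list of typed edge tables), `mirna_ids`, `disease_ids`.
#' @param train_pairs data.frame `mirna`, `disease`, `label`.
#' @param config run configuration; see [default_config()].
#' @param seed integer seed controlling every random draw of the fit.
#' @return object of class `gonnmda_model`.
#' @export
fit_gonnmda <- function(data, train_pairs, config = default_config(),
                        seed = 1L) {
  seed <- as.integer(seed)
  mids <- data$mirna_ids; dids <- data$disease_ids
  pos <- train_pairs[train_pairs$label == 1L, ]
  key <- paste(data$assoc$mirna, data$assoc$disease)
  train_assoc <- data$assoc[key %in% paste(pos$mirna, pos$disease), ]
  if (!nrow(train_assoc)) stop("no training positives")
  feats <- build_fold_features(data, train_assoc, config)
  D <- config$embed_dim
  cs <- min(config$gnn$chunk_size, D)
  if (D %% cs != 0L) stop("embed_dim must be divisible by the chunk size")
  ognn_cfg <- ognn_config(layers = config$gnn$layers, dim = D,
                          chunk_size = cs, dropout = config$gnn$dropout)
  tables <- c(list(`miRNA-disease` = data.frame(src_id = train_assoc$mirna,
                                                dst_id = train_assoc$disease)),
              data$aux_tables)
  graph <- build_heterograph(tables,
                             extra_nodes = list(miRNA = mids, disease = dids))
  a_hat <- hetero_adjacency(graph, aggregator = config$gnn$aggregator)
  set.seed(derive_seed(seed, "other-features"))
  h_other <- matrix(stats::rnorm(graph$n_nodes * D, sd = 0.1),
                    graph$n_nodes, D)
  model <- list(graph = graph, a_hat = a_hat, h_other = h_other,
                F_m = feats$F_m[mids, , drop = FALSE],
                F_d = feats$F_d[dids, , drop = FALSE],
                mirna_ids = mids, disease_ids = dids,
                idx_m_all = node_index(graph, "miRNA", mids),
                idx_d_all = node_index(graph, "disease", dids),
                n_nodes = graph$n_nodes,
                ognn_cfg = ognn_cfg, config = config, seed = seed)
  params <- list(
    proj_m = init_projection(ncol(model$F_m), D, derive_seed(seed, "proj-m")),
    proj_d = init_projection(ncol(model$F_d), D, derive_seed(seed, "proj-d")),
    gnn = ognn_init(ognn_cfg, derive_seed(seed, "gnn")),
    mlp = mlp_init(4L * D, hidden = config$mlp$hidden,
                   n_layers = config$mlp$layers,
                   seed = derive_seed(seed, "mlp")))
  all_lm <- match(train_pairs$mirna, mids)
  all_ld <- match(train_pairs$disease, dids)
  if (anyNA(all_lm) || anyNA(all_ld)) stop("training pair outside the universe")
  all_y <- as.numeric(train_pairs$label)
  # carve out a stratified validation slice to monitor for early stopping
  vf <- config$train$val_fraction %||% 0
  val <- integer(0)
  if (vf > 0 && length(all_y) >= 20L) {
    set.seed(derive_seed(seed, "valsplit"))
    for (cl in unique(all_y)) {
      idx <- which(all_y == cl)
      val <- c(val, sample(idx, max(1L, round(vf * length(idx)))))
    }
  }
  fit_idx <- setdiff(seq_along(all_y), val)
  lm_ <- all_lm[fit_idx]; ld_ <- all_ld[fit_idx]; y <- all_y[fit_idx]
  state <- adam_init(params)
  history <- numeric(0)
  best <- Inf; best_params <- params; stale <- 0L
  set.seed(derive_seed(seed, "train"))
  for (epoch in seq_len(config$train$epochs)) {
    fwd <- .model_forward(params, model, lm_, ld_, training = TRUE,
                          keep_cache = TRUE)
    loss <- bce_loss(fwd$p, y)
    monitor <- if (length(val)) {
      vp <- .model_forward(params, model, all_lm[val], all_ld[val],
                           training = FALSE)$p
      bce_loss(vp, all_y[val])
    } else loss
    history <- c(history, loss)
    if (monitor < best - 1e-6) {
      best <- monitor; best_params <- params; stale <- 0L
    } else stale <- stale + 1L
    if (stale > config$train$patience) break
    grads <- .model_backward(params, model, fwd, lm_, ld_, y)
    if (config$train$weight_decay > 0)
      grads <- tree_map2(grads, params, function(g, p)
        g + config$train$weight_decay * p)
    st <- adam_step(params, grads, state, lr = config$train$lr)
    params <- st$params; state <- st$state
  }
  model$params <- best_params
  model$history <- history
  model$final_loss <- best
  class(model) <- "gonnmda_model"
  model
}

#' Score miRNA-disease pairs with a fitted model
#'
#' Deterministic evaluation-mode forward pass (dropout off).
#'
#' @param model a `gonnmda_model`; `pairs` data.frame `mirna`, `disease`.
#' @return numeric vector of association probabilities in (0, 1).
#' @export
score_pairs <- function(model, pairs) {
  stopifnot(inherits(model, "gonnmda_model"))
  lm_ <- match(pairs$mirna, model$mirna_ids)
  ld_ <- match(pairs$disease, model$disease_ids)
  if (anyNA(lm_)) stop("unknown miRNA id(s): ",
                       paste(unique(pairs$mirna[is.na(lm_)]), collapse = ", "))
  if (anyNA(ld_)) stop("unknown disease id(s): ",
                       paste(unique(pairs$disease[is.na(ld_)]), collapse = ", "))
  .model_forward(model$params, model, lm_, ld_, training = FALSE)$p
}

#' Rank candidate miRNAs for one disease
#'
#' @param model a fitted `gonnmda_model`.
#' @param disease_id the query disease.
#' @param candidate_mirnas candidates (default: the model's full miRNA set).
#' @param top number of rows returned (default all candidates).
#' @return data.frame `rank`, `mirna`, `score`, sorted by descending score;
#'   ties broken lexicographically by miRNA id.
#' @export
predict_ranked <- function(model, disease_id, candidate_mirnas = NULL,
                           top = NULL) {
  if (!disease_id %in% model$disease_ids)
    stop("unknown disease: ", disease_id)
  if (is.null(candidate_mirnas)) candidate_mirnas <- model$mirna_ids
  pairs <- data.frame(mirna = candidate_mirnas, disease = disease_id)
  s <- score_pairs(model, pairs)
  ord <- order(-s, candidate_mirnas)
  out <- data.frame(rank = seq_along(ord), mirna = candidate_mirnas[ord],
                    score = s[ord], stringsAsFactors = FALSE)
  if (!is.null(top)) out <- utils::head(out, top)
  out
}
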