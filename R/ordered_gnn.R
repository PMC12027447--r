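#' Ordered GNN configuration
#'
#' Depth, embedding width, gate chunk size and dropout for the ordered
#' message-passing network. Gates are predicted at chunk resolution
#' (`dim / chunk_size` logits per node) and broadcast within chunks, so
#' `dim` must be divisible by `chunk_size`.
#'
#' @param layers number of gated layers K (>= 1).
#' @param dim embedding width D.
#' @param chunk_size gate granularity; divides `dim`.
#' @param dropout rate in \[0, 1), applied to embeddings between layers
#'   during training only.
#' @export
ognn_config <- function(layers = 4L, dim = 1024L, chunk_size = 128L,
                        dropout = 0.2) {
  layers <- as.integer(layers); dim <- as.integer(dim)
  chunk_size <- as.integer(chunk_size)
  if (layers < 1L) stop("layers must be >= 1")
  if (chunk_size < 1L || dim %% chunk_size != 0L)
    stop("dim (", dim, ") must be divisible by chunk_size (", chunk_size, ")")
  if (!(dropout >= 0 && dropout < 1)) stop("dropout must lie in [0, 1)")
  structure(list(layers = layers, dim = dim, chunk_size = chunk_size,
                 n_chunks = dim %/% chunk_size, dropout = dropout),
            class = "ognn_config")
}

#' Neighbour context
#'
#' Mean of neighbour embeddings under the row-normalised adjacency; an
#' isolated node's context is the zero vector.
#'
#' @param a_hat row-normalised adjacency ([hetero_adjacency()]).
#' @param h node embeddings (n x D).
#' @export
neighbor_context <- function(a_hat, h) {
  if (any(!is.finite(h))) stop("non-finite embeddings")
  as.matrix(a_hat %*% h)
}

#' Gate expectation from node state and neighbour context
#'
#' Concatenates `[h ; m]`, applies the layer's affine map to chunk-resolution
#' logits, takes a softmax, then a right-to-left cumulative sum, and
#' broadcasts chunk values across the embedding width. The first chunk of
#' the result is always 1 (total softmax mass) and values are non-increasing
#' along chunks.
#'
#' @param h,m matrices (n x D); `W` (2D x C) and `b` (length C) parameters;
#'   `chunk_size` broadcast width.
#' @return list with `g_hat` (n x D) and intermediates used by the backward
#'   pass (`x`, `s`).
#' @export
gate_expectation <- function(h, m, W, b, chunk_size) {
  x <- cbind(h, m)
  logits <- sweep(x %*% W, 2L, b, "+")
  if (any(!is.finite(logits))) stop("non-finite gate logits")
  # row softmax, numerically stabilised
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  s <- e / rowSums(e)
  g_chunk <- .rev_cumsum_cols(s)
  g_hat <- g_chunk[, rep(seq_len(ncol(s)), each = chunk_size), drop = FALSE]
  list(g_hat = g_hat, x = x, s = s)
}

# right-to-left cumulative sum along columns
.rev_cumsum_cols <- function(s) {
  if (ncol(s) == 1L) return(s)
  out <- s[, rev(seq_len(ncol(s))), drop = FALSE]
  out <- t(apply(out, 1L, cumsum))
  if (nrow(s) == 1L) out <- matrix(out, nrow = 1L)
  out[, rev(seq_len(ncol(s))), drop = FALSE]
}

# left-to-right cumulative sum along columns
.cumsum_cols <- function(s) {
  if (ncol(s) == 1L) return(s)
  out <- t(apply(s, 1L, cumsum))
  if (nrow(s) == 1L) out <- matrix(out, nrow = 1L)
  out
}

#' Soft-OR gate accumulation
#'
#' \eqn{\tilde g^{(k)} = \tilde g^{(k-1)} + (1-\tilde g^{(k-1)})\hat g^{(k)}}:
#' a differentiable OR, monotone non-decreasing across layers, so neurons
#' that once switched to "retain" stay retained.
#'
#' @param g_tilde_prev,g_hat matrices in \[0, 1\].
#' @export
softor <- function(g_tilde_prev, g_hat) {
  if (min(g_tilde_prev) < -1e-12 || max(g_tilde_prev) > 1 + 1e-12 ||
      min(g_hat) < -1e-12 || max(g_hat) > 1 + 1e-12)
    stop("softor inputs must lie in [0, 1]")
  g_tilde_prev + (1 - g_tilde_prev) * g_hat
}

#' Gated embedding update
#'
#' \eqn{h = \tilde g \odot h_{prev} + (1-\tilde g) \odot m}: gated neurons
#' retain the previous layer, the rest accept the neighbour context.
#'
#' @param h_prev,m,g_tilde matrices of identical shape.
#' @export
layer_update <- function(h_prev, m, g_tilde) {
  stopifnot(all(dim(h_prev) == dim(m)), all(dim(h_prev) == dim(g_tilde)))
  g_tilde * h_prev + (1 - g_tilde) * m
}

#' Initialise ordered-GNN parameters
#'
#' Per-layer gate maps W (2D x C) and biases; Gaussian init scaled by fan-in.
#'
#' @param config an [ognn_config()]; `seed` RNG seed.
#' @export
ognn_init <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  d <- config$dim; c_ <- config$n_chunks
  lapply(seq_len(config$layers), function(l)
    list(W = matrix(stats::rnorm(2 * d * c_, sd = 1 / sqrt(2 * d)), 2 * d, c_),
         b = numeric(c_)))
}

#' Ordered-GNN forward pass
#'
#' Runs K gated layers over the graph. The cumulative gate starts at zero
#' (layer 0 holds pure self information), each layer computes a neighbour
#' context, a chunk-resolution gate expectation, accumulates it by soft-OR,
#' and interpolates between retention and the neighbour context. Dropout is
#' applied to embeddings between layers when `training = TRUE`.
#'
#' @param a_hat row-normalised adjacency; `h0` initial features (n x D);
#'   `params` from [ognn_init()]; `config` an [ognn_config()].
#' @param training logical; enables dropout.
#' @param keep_cache keep intermediates for [ognn_backward()].
#' @return list: `h` final embeddings, `g_tilde` final cumulative gate,
#'   `g_tilde_trace` per-layer gates, and `cache` when requested.
#' @export
ognn_forward <- function(a_hat, h0, params, config, training = FALSE,
                         keep_cache = FALSE) {
  stopifnot(inherits(config, "ognn_config"),
            ncol(h0) == config$dim, length(params) == config$layers)
  h <- h0
  gt <- matrix(0, nrow(h0), config$dim)
  cache <- if (keep_cache) vector("list", config$layers) else NULL
  trace <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    m <- neighbor_context(a_hat, h)
    ge <- gate_expectation(h, m, params[[l]]$W, params[[l]]$b,
                           config$chunk_size)
    gt_new <- softor(gt, ge$g_hat)
    h_new <- layer_update(h, m, gt_new)
    mask <- NULL
    if (training && config$dropout > 0) {
      mask <- matrix(stats::rbinom(length(h_new), 1L, 1 - config$dropout),
                     nrow(h_new), ncol(h_new)) / (1 - config$dropout)
      h_new <- h_new * mask
    }
    if (keep_cache)
      cache[[l]] <- list(h_prev = h, m = m, s = ge$s, x = ge$x,
                         g_hat = ge$g_hat, gt_prev = gt, gt = gt_new,
                         mask = mask)
    trace[[l]] <- gt_new
    h <- h_new
    gt <- gt_new
    if (any(!is.finite(h))) stop("ordered GNN state diverged at layer ", l)
  }
  list(h = h, g_tilde = gt, g_tilde_trace = trace, cache = cache)
}

#' Ordered-GNN backward pass
#'
#' Analytic reverse-mode gradients for [ognn_forward()]: given the loss
#' gradient with respect to the final embeddings, returns gradients for
#' every layer's gate parameters and for the initial features. Verified
#' against finite differences in the test-suite.
#'
#' @param a_hat,params,config as in [ognn_forward()].
#' @param cache the forward cache (`keep_cache = TRUE`).
#' @param d_h gradient w.r.t. final embeddings (n x D).
#' @return list: `d_h0` (n x D) and `d_params` (per layer `W`, `b`).
#' @export
ognn_backward <- function(a_hat, params, config, cache, d_h) {
  K <- config$layers
  cs <- config$chunk_size
  at <- Matrix::t(a_hat)
  d_params <- vector("list", K)
  d_gt_carry <- matrix(0, nrow(d_h), ncol(d_h))
  for (l in rev(seq_len(K))) {
    cc <- cache[[l]]
    if (!is.null(cc$mask)) d_h <- d_h * cc$mask
    # h_new = gt * h_prev + (1 - gt) * m
    d_gt <- d_h * (cc$h_prev - cc$m) + d_gt_carry
    d_hp <- d_h * cc$gt
    d_m  <- d_h * (1 - cc$gt)
    # gt = gt_prev + (1 - gt_prev) * g_hat
    d_ghat <- d_gt * (1 - cc$gt_prev)
    d_gt_carry <- d_gt * (1 - cc$g_hat)   # into gt_prev of layer l-1
    # collapse broadcast: chunk gradient = sum over in-chunk dims
    n_chunks <- config$n_chunks
    d_gchunk <- matrix(0, nrow(d_ghat), n_chunks)
    for (j in seq_len(n_chunks))
      d_gchunk[, j] <- rowSums(d_ghat[, (j - 1L) * cs + seq_len(cs),
                                      drop = FALSE])
    # g_chunk[, j] = sum_{c >= j} s[, c]  =>  d_s[, c] = sum_{j <= c} d_gchunk[, j]
    d_s <- .cumsum_cols(d_gchunk)
    # softmax backward
    dot <- rowSums(d_s * cc$s)
    d_logits <- cc$s * (d_s - dot)
    d_params[[l]] <- list(W = crossprod(cc$x, d_logits),
                          b = colSums(d_logits))
    d_x <- d_logits %*% t(params[[l]]$W)
    D <- config$dim
    d_hp <- d_hp + d_x[, seq_len(D), drop = FALSE]
    d_m  <- d_m + d_x[, D + seq_len(D), drop = FALSE]
    # m = a_hat %*% h_prev
    d_hp <- d_hp + as.matrix(at %*% d_m)
    d_h <- d_hp
  }
  list(d_h0 = d_h, d_params = d_params)
}

#' Ungated mean-aggregation baseline
#'
#' Plain K-fold repeated neighbour-plus-self averaging; the over-smoothing
#' comparator for the ordered network.
#'
#' @param a_hat row-normalised adjacency; `h0` features; `layers` depth.
#' @param self_weight mixing weight on the node's own embedding.
#' @export
mean_aggregation_baseline <- function(a_hat, h0, layers, self_weight = 0.5) {
  h <- h0
  for (l in seq_len(layers))
    h <- self_weight * h + (1 - self_weight) * as.matrix(a_hat %*% h)
  h
}

#' Mean pairwise cosine similarity of embedding rows
#'
#' Over-smoothing diagnostic: values near 1 mean the representation has
#' collapsed.
#'
#' @param h embedding matrix; zero rows are dropped.
#' @export
mean_pairwise_cosine <- function(h) {
  n2 <- sqrt(rowSums(h^2))
  h <- h[n2 > 0, , drop = FALSE]
  n2 <- n2[n2 > 0]
  u <- h / n2
  cs <- tcrossprod(u)
  mean(cs[upper.tri(cs)])
}
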