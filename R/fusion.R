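#' Stack per-entity similarity matrices
#'
#' Vertically concatenates similarity blocks that share one entity universe,
#' in the given order (miRNA: functional, sequence, kernel; disease: the two
#' semantic variants then the kernel), producing the (B*n) x n matrix that
#' feeds the truncated SVD.
#'
#' @param blocks named list of square matrices with identical dimnames.
#' @return object of class `stacked_similarity` with fields `ids`, `stacked`,
#'   `block_names`.
#' @export
stack_similarity <- function(blocks) {
  if (!length(blocks)) stop("no blocks to stack")
  ids <- rownames(blocks[[1L]])
  if (is.null(ids)) stop("blocks must carry entity ids as dimnames")
  for (b in blocks) {
    if (!is.matrix(b) || nrow(b) != ncol(b)) stop("blocks must be square matrices")
    if (!identical(rownames(b), ids) || !identical(colnames(b), ids))
      stop("block id sets disagree")
  }
  structure(list(ids = ids,
                 stacked = do.call(rbind, lapply(blocks, unname)),
                 block_names = names(blocks)),
            class = "stacked_similarity")
}

#' Truncated-SVD denoising and reconstruction
#'
#' Computes the rank-`k_svd` best Frobenius approximation
#' \eqn{U_k \Sigma_k V_k^T} of the stacked similarity matrix, and keeps the
#' factors so entity features can be read off.
#'
#' @param stacked a [stack_similarity()] result.
#' @param k_svd number of singular values retained; clamped inputs are the
#'   caller's job -- out-of-range values are rejected here.
#' @return object of class `reconstructed_feature` with the reconstruction,
#'   the truncated factors and the retained/discarded singular values.
#' @export
svd_reconstruct <- function(stacked, k_svd) {
  stopifnot(inherits(stacked, "stacked_similarity"))
  m <- stacked$stacked
  r_max <- min(dim(m))
  if (!(is.numeric(k_svd) && length(k_svd) == 1L && k_svd >= 1 && k_svd <= r_max))
    stop("k_svd must lie in [1, ", r_max, "]")
  k_svd <- as.integer(k_svd)
  s <- svd(m)
  uk <- s$u[, seq_len(k_svd), drop = FALSE]
  dk <- s$d[seq_len(k_svd)]
  vk <- s$v[, seq_len(k_svd), drop = FALSE]
  structure(list(ids = stacked$ids,
                 features = uk %*% (dk * t(vk)),
                 u_k = uk, d_k = dk, v_k = vk,
                 d_all = s$d,
                 n_blocks = nrow(m) / ncol(m),
                 k_svd = k_svd),
            class = "reconstructed_feature")
}

#' Per-entity features from a truncated reconstruction
#'
#' `vk_sigma` (default) takes the rows of \eqn{V_k \Sigma_k}: each entity's
#' coordinates in the denoised right singular basis, width `k_svd`.
#' `block_mean` averages the B reconstructed n x n blocks instead, width n.
#'
#' @param recon a [svd_reconstruct()] result.
#' @param mode `"vk_sigma"` or `"block_mean"`.
#' @return numeric matrix, one row per entity id.
#' @export
entity_features <- function(recon, mode = c("vk_sigma", "block_mean")) {
  stopifnot(inherits(recon, "reconstructed_feature"))
  mode <- match.arg(mode)
  n <- length(recon$ids)
  f <- if (mode == "vk_sigma") {
    recon$v_k %*% diag(recon$d_k, nrow = recon$k_svd)
  } else {
    b <- nrow(recon$features) / n
    out <- matrix(0, n, n)
    for (i in seq_len(b)) out <- out + recon$features[(i - 1L) * n + seq_len(n), ]
    out / b
  }
  rownames(f) <- recon$ids
  f
}

#' Initialise an affine projection
#'
#' Small-variance Gaussian weights with zero bias; the map is trained
#' end-to-end with the rest of the model.
#'
#' @param in_dim,out_dim dimensions; `seed` RNG seed.
#' @export
init_projection <- function(in_dim, out_dim, seed = 1L) {
  set.seed(as.integer(seed))
  list(W = matrix(stats::rnorm(in_dim * out_dim, sd = 1 / sqrt(in_dim)),
                  in_dim, out_dim),
       b = numeric(out_dim))
}

#' Apply an affine projection row-wise
#' @param x matrix (n x in_dim); `proj` a list with `W`, `b`.
#' @export
project_features <- function(x, proj) {
  if (ncol(x) != nrow(proj$W)) stop("projection width mismatch: ",
                                    ncol(x), " vs ", nrow(proj$W))
  out <- x %*% proj$W
  sweep(out, 2L, proj$b, "+")
}

#' Fuse one entity's similarity blocks into projectable features
#'
#' Convenience wrapper: stack, truncate at `k_svd` (clamped to the valid
#' range), and extract per-entity features.
#'
#' @inheritParams stack_similarity
#' @param k_svd requested rank (clamped to `[1, n]`).
#' @param mode see [entity_features()].
#' @export
fuse_similarities <- function(blocks, k_svd = 150L,
                              mode = c("vk_sigma", "block_mean")) {
  st <- stack_similarity(blocks)
  k <- max(1L, min(as.integer(k_svd), min(dim(st$stacked))))
  recon <- svd_reconstruct(st, k)
  list(features = entity_features(recon, match.arg(mode)), recon = recon)
}
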