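test_that("gate expectation: unit first chunk, monotone decay, hand value", {
  set.seed(5)
  n <- 7L; D <- 8L; cs <- 2L; C <- D %/% cs
  h <- matrix(stats::rnorm(n * D), n, D)
  m <- matrix(stats::rnorm(n * D), n, D)
  W <- matrix(stats::rnorm(2 * D * C, sd = 0.5), 2 * D, C)
  ge <- gate_expectation(h, m, W, stats::rnorm(C), cs)
  g <- ge$g_hat
  expect_true(all(abs(g[, 1] - 1) < 1e-12))       # total softmax mass
  expect_true(all(g >= -1e-12 & g <= 1 + 1e-12))
  chunk_vals <- g[, seq(1, D, by = cs), drop = FALSE]
  expect_true(all(diff(t(chunk_vals)) <= 1e-12))  # non-increasing chunks
  # uniform logits over 4 chunks -> (1, .75, .5, .25)
  ge0 <- gate_expectation(h, m, matrix(0, 2 * D, 4L), numeric(4L), cs)
  expect_equal(unname(ge0$g_hat[1, seq(1, D, by = cs)]),
               c(1, 0.75, 0.5, 0.25))
  expect_error(gate_expectation(h * NA, m, W, numeric(C), cs), "non-finite")
})

test_that("softor is a monotone soft OR", {
  a <- matrix(stats::runif(12), 3, 4)
  b <- matrix(stats::runif(12), 3, 4)
  s <- softor(a, b)
  expect_true(all(s >= a - 1e-12 & s >= b - 1e-12))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(softor(matrix(1, 2, 2), b[1:2, 1:2]), matrix(1, 2, 2))
  expect_equal(softor(matrix(0, 2, 2), b[1:2, 1:2]), b[1:2, 1:2])
  expect_equal(softor(matrix(0.5, 1, 1), matrix(0.5, 1, 1)),
               matrix(0.75, 1, 1))
  expect_error(softor(a + 2, b), "\\[0, 1\\]")
})

test_that("layer update interpolates between retention and context", {
  h <- matrix(2, 3, 4); m <- matrix(0, 3, 4)
  expect_equal(layer_update(h, m, matrix(1, 3, 4)), h)
  expect_equal(layer_update(h, m, matrix(0, 3, 4)), m)
  expect_equal(layer_update(h, m, matrix(0.5, 3, 4)), matrix(1, 3, 4))
})

test_that("neighbour context is the neighbour mean; isolated nodes get zero", {
  a <- Matrix::sparseMatrix(i = c(1, 1), j = c(2, 3), x = 0.5, dims = c(4, 4))
  h <- rbind(c(9, 9), c(1, 0), c(0, 1), c(5, 5))
  m <- neighbor_context(a, h)
  expect_equal(m[1, ], c(0.5, 0.5))
  expect_equal(m[4, ], c(0, 0))
  b <- Matrix::sparseMatrix(i = 2, j = 1, x = 1, dims = c(2, 2))
  expect_equal(neighbor_context(b, rbind(c(3, 4), c(0, 0)))[2, ], c(3, 4))
})

test_that("forward pass honours forced gates and accumulates monotonically", {
  n <- 10L
  cfg <- ognn_config(layers = 1L, dim = 8L, chunk_size = 4L, dropout = 0)
  a <- random_a_hat(n, seed = 2L)
  set.seed(3)
  h0 <- matrix(stats::rnorm(n * 8), n, 8)
  # huge positive bias on the first-chunk logit -> g_hat ~ (1, ..., 1):
  # everything retained
  p_keep <- list(list(W = matrix(0, 16, 2), b = c(1e3, -1e3)))
  # note: cumsum makes chunk1 always 1; to force FULL retention push all
  # mass to the last chunk instead (g_hat = 1 everywhere)
  p_all <- list(list(W = matrix(0, 16, 2), b = c(-1e3, 1e3)))
  out_keep <- ognn_forward(a, h0, p_all, cfg)
  expect_equal(out_keep$h, h0, tolerance = 1e-10)
  # all mass on the first chunk -> g_hat = (1, 0) per chunk -> later chunk
  # replaced by the neighbour mean
  out_repl <- ognn_forward(a, h0, p_keep, cfg)
  m <- neighbor_context(a, h0)
  expect_equal(out_repl$h[, 5:8], m[, 5:8], tolerance = 1e-10)
  expect_equal(out_repl$h[, 1:4], h0[, 1:4], tolerance = 1e-10)

  # random weights, K = 4: cumulative gate non-decreasing across layers
  cfg4 <- ognn_config(layers = 4L, dim = 8L, chunk_size = 2L, dropout = 0)
  params <- ognn_init(cfg4, seed = 9L)
  out <- ognn_forward(a, h0, params, cfg4)
  tr <- out$g_tilde_trace
  for (k in 2:4)
    expect_true(all(tr[[k]] >= tr[[k - 1]] - 1e-12))
  # and within a layer, non-increasing along the ordered dimension chunks
  for (k in 1:4) {
    cv <- tr[[k]][, seq(1, 8, by = 2)]
    expect_true(all(diff(t(cv)) <= 1e-12))
  }
})

test_that("forward is permutation-equivariant", {
  n <- 12L
  cfg <- ognn_config(layers = 3L, dim = 8L, chunk_size = 4L, dropout = 0)
  a <- random_a_hat(n, seed = 4L)
  set.seed(6)
  h0 <- matrix(stats::rnorm(n * 8), n, 8)
  params <- ognn_init(cfg, seed = 10L)
  out <- ognn_forward(a, h0, params, cfg)$h
  perm <- sample(n)
  a_p <- a[perm, perm, drop = FALSE]
  out_p <- ognn_forward(a_p, h0[perm, , drop = FALSE], params, cfg)$h
  expect_equal(out_p, out[perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("analytic gradients match finite differences through the whole model", {
  data <- tiny_data()
  cfg <- tiny_config()
  cfg$gnn$dropout <- 0
  cfg$train$epochs <- 1L
  ds <- build_pair_dataset(data$assoc, data$mirna_ids, data$disease_ids,
                           seed = 3L)
  m <- suppressWarnings(fit_gonnmda(data, ds, cfg, seed = 5L))
  params <- m$params
  lm_ <- match(ds$mirna, m$mirna_ids)
  ld_ <- match(ds$disease, m$disease_ids)
  y <- as.numeric(ds$label)
  loss_of <- function(p)
    gonnmda:::bce_loss(gonnmda:::.model_forward(p, m, lm_, ld_)$p, y)
  fwd <- gonnmda:::.model_forward(params, m, lm_, ld_, keep_cache = TRUE)
  gr <- gonnmda:::.model_backward(params, m, fwd, lm_, ld_, y)
  flat <- unlist(params); gflat <- unlist(gr)
  expect_equal(length(flat), length(gflat))
  set.seed(1)
  idx <- sample(length(flat), 60L)
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    (loss_of(utils::relist(replace(flat, i, flat[i] + eps), params)) -
       loss_of(utils::relist(replace(flat, i, flat[i] - eps), params))) /
      (2 * eps)
  }, numeric(1))
  expect_equal(num, unname(gflat[idx]), tolerance = 1e-5)
})

test_that("ungated deep aggregation drifts toward collapse, the ordered network does not", {
  data <- tiny_data()
  tables <- c(list(`miRNA-disease` = data.frame(src_id = data$assoc$mirna,
                                                dst_id = data$assoc$disease)),
              data$aux_tables)
  g <- build_heterograph(tables, extra_nodes = list(miRNA = data$mirna_ids,
                                                    disease = data$disease_ids))
  a <- hetero_adjacency(g)
  set.seed(11)
  h0 <- matrix(stats::rnorm(g$n_nodes * 32, sd = 0.1), g$n_nodes, 32)
  cfg <- ognn_config(layers = 6L, dim = 32L, chunk_size = 8L, dropout = 0)
  h_ord <- ognn_forward(a, h0, ognn_init(cfg, seed = 12L), cfg)$h
  h_base6 <- mean_aggregation_baseline(a, h0, 6L, self_weight = 0)
  c_ord <- mean_pairwise_cosine(h_ord)
  c0 <- mean_pairwise_cosine(h0)
  c6 <- mean_pairwise_cosine(h_base6)
  expect_lt(c_ord, 0.5)          # ordered gates preserve identity
  expect_gt(c6, c0 + 0.2)        # the ungated baseline drifts toward collapse
  expect_gt(c6, c_ord + 0.2)     # and far beyond the ordered network
})
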