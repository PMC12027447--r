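# shared fixtures and independent oracles, all built in code

# chain DAG g -> p -> d (g is the remotest ancestor)
chain_dag <- function(lambda = 0.5) {
  disease_dag("d", c("d", "p", "g"),
              rbind(c("g", "p"), c("p", "d")), lambda = lambda)
}

# diamond: g -> p1 -> d, g -> p2 -> d
diamond_dag <- function(lambda = 0.5) {
  disease_dag("d", c("d", "p1", "p2", "g"),
              rbind(c("g", "p1"), c("g", "p2"), c("p1", "d"), c("p2", "d")),
              lambda = lambda)
}

# two diseases sharing a single parent term
shared_parent_dags <- function(lambda = 0.5) {
  list(d1 = disease_dag("d1", c("d1", "p"), rbind(c("p", "d1")), lambda),
       d2 = disease_dag("d2", c("d2", "p"), rbind(c("p", "d2")), lambda))
}

# exhaustive global-alignment oracle: recursive max over the three moves,
# enumerating every alignment (no DP table); feasible for lengths <= 6
nw_brute <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- strsplit(chartr("T", "U", toupper(a)), "")[[1]]
  bv <- strsplit(chartr("T", "U", toupper(b)), "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (av[i] == bv[j]) match else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# O(n^2) positive-negative pair-counting AUC with midrank ties
auc_paircount <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# small planted dataset + config for model-level tests (memoised)
.fixture_env <- new.env(parent = emptyenv())

tiny_data <- function() {
  if (is.null(.fixture_env$data)) {
    spec <- synthetic_spec(n_mirna = 16L, n_disease = 12L, n_other = 5L,
                           n_groups = 2L, intra = 0.5, inter = 0.05,
                           seed = 7L)
    .fixture_env$data <- make_dataset(spec)
  }
  .fixture_env$data
}

tiny_config <- function() {
  cfg <- desk_config()
  cfg$embed_dim <- 16L
  cfg$gnn$chunk_size <- 4L
  cfg$mlp$hidden <- 16L
  cfg$train$epochs <- 60L
  cfg
}

# random sparse row-normalised operator for pure-GNN tests
random_a_hat <- function(n, p = 0.2, seed = 1L) {
  set.seed(seed)
  a <- matrix(stats::rbinom(n * n, 1, p), n, n)
  a <- 1 * ((a + t(a)) > 0)
  diag(a) <- 0
  deg <- rowSums(a)
  a <- a / ifelse(deg > 0, deg, 1)
  a[deg == 0, ] <- 0
  Matrix::Matrix(a, sparse = TRUE)
}
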