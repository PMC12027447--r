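test_that("semantic values follow the decay-and-max recursion", {
  # bare root
  d0 <- disease_dag("d", "d")
  expect_equal(dag_semantic_values(d0), c(d = 1))
  # chain g -> p -> d at lambda 0.5
  expect_equal(dag_semantic_values(chain_dag()),
               c(d = 1, p = 0.5, g = 0.25))
  # diamond: both paths give g the same decayed value; max rule
  v <- dag_semantic_values(diamond_dag())
  expect_equal(v[["g"]], 0.25)
  expect_equal(v[["p1"]], 0.5)
  # a closer child dominates: g is both a parent of p and of d directly
  dg <- disease_dag("d", c("d", "p", "g"),
                    rbind(c("g", "p"), c("p", "d"), c("g", "d")))
  expect_equal(dag_semantic_values(dg)[["g"]], 0.5)
})

test_that("invalid DAGs are rejected", {
  expect_error(disease_dag("d", c("d", "x"), rbind(c("d", "x"), c("x", "d"))),
               "cycle")
  expect_error(disease_dag("d", c("d", "orphan")), "no path")
  expect_error(disease_dag("d", "d", lambda = 1), "lambda")
})

test_that("dss1 matches hand-computed values and its contract", {
  dags <- shared_parent_dags()
  s <- dss1(dags)
  expect_equal(s["d1", "d2"], 1 / 3)  # (0.5+0.5)/(1.5+1.5)
  expect_equal(diag(s), c(d1 = 1, d2 = 1))
  # identical DAGs give 1
  s_two <- dss1(list(a = chain_dag(), b = chain_dag()))
  expect_equal(s_two["a", "b"], 1)
  # distinct roots sharing all ancestors: numerator over shared terms only
  s2 <- dss1(list(d1 = disease_dag("d1", c("d1", "p"), rbind(c("p", "d1"))),
                  d2 = disease_dag("d2", c("d2", "p"), rbind(c("p", "d2"))),
                  d3 = disease_dag("d3", "d3")))
  expect_equal(s2["d1", "d3"], 0)  # disjoint node sets
  expect_true(all(s2 >= 0 & s2 <= 1))
  check_similarity(s2, unit_diag = TRUE, range = c(0, 1))
})

test_that("dss1 stays in [0,1] with exact unit diagonal on random forests", {
  for (seed in 1:3) {
    spec <- synthetic_spec(n_mirna = 6L, n_disease = 15L, n_other = 2L,
                           seed = seed)
    dags <- make_dag_forest(spec)
    s <- dss1(dags)
    expect_true(all(s >= 0 & s <= 1 + 1e-12))
    expect_equal(unname(diag(s)), rep(1, nrow(s)))
    check_similarity(s)
  }
})

test_that("dss2 uses -log occurrence contributions", {
  # shared parent p occurs in both of 2 DAGs -> contributes -log(1) = 0,
  # so the two distinct-rooted diseases share nothing informative
  dags <- shared_parent_dags()
  s <- dss2(dags)
  expect_equal(s["d1", "d2"], 0)
  # each disease vs itself: its own (unique) root carries -log(1/2) > 0
  expect_equal(s["d1", "d1"], 1)
  # fully identical term multisets across all DAGs -> 0/0 guarded to 0
  same <- list(a = disease_dag("a", c("a", "p"), rbind(c("p", "a"))))
  expect_warning(s1 <- dss2(same), "zero total")
  expect_equal(s1["a", "a"], 0)
})

test_that("GIP kernel matches the hand example and contract", {
  pr <- rbind(e1 = c(1, 0), e2 = c(0, 1))
  s <- gip_kernel(pr)
  # sigma = 1/mean(1,1) = 1; distance^2 = 2
  expect_equal(s["e1", "e2"], exp(-2), tolerance = 1e-12)
  expect_equal(unname(diag(s)), c(1, 1))
  # identical profiles -> 1
  s2 <- gip_kernel(rbind(a = c(1, 1, 0), b = c(1, 1, 0)))
  expect_equal(s2["a", "b"], 1)
  expect_error(gip_kernel(matrix(0, 2, 3)), "bandwidth undefined")
  expect_error(gip_kernel(matrix(0.5, 2, 2)), "binary")
})

test_that("GIP kernel is equivariant to row permutation", {
  set.seed(42)
  pr <- matrix(rbinom(8 * 5, 1, 0.4), 8, 5,
               dimnames = list(paste0("e", 1:8), NULL))
  pr[1, ] <- 1  # ensure non-degenerate
  s <- gip_kernel(pr)
  perm <- sample(8)
  s_perm <- gip_kernel(pr[perm, , drop = FALSE])
  expect_equal(unname(s_perm), unname(s[perm, perm]))
})

test_that("nw_score equals the exhaustive alignment oracle", {
  expect_equal(nw_score("ACGU", "ACGU"), 4)
  expect_equal(nw_score("A", "G"), -1)
  expect_equal(nw_score("", "ACG"), -3)
  expect_equal(nw_score("", ""), 0)
  expect_error(nw_score("AXG", "ACG"), "invalid nucleotide")
  set.seed(99)
  alph <- c("A", "C", "G", "U")
  for (i in 1:40) {
    a <- paste(sample(alph, sample(0:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alph, sample(0:6, 1), replace = TRUE), collapse = "")
    expect_equal(nw_score(a, b), nw_brute(a, b),
                 info = paste(a, "vs", b))
  }
  # non-default scoring too
  for (i in 1:10) {
    a <- paste(sample(alph, sample(1:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alph, sample(1:5, 1), replace = TRUE), collapse = "")
    expect_equal(nw_score(a, b, 2, -3, -2), nw_brute(a, b, 2, -3, -2))
  }
})

test_that("sequence similarity normalises off-diagonal scores to [0,1]", {
  seqs <- c(m1 = "ACGUACGU", m2 = "ACGUACGA", m3 = "UUUUCCCC")
  s <- mirna_sequence_similarity(seqs)
  expect_equal(unname(diag(s)), rep(1, 3))
  off <- s[upper.tri(s)]
  expect_equal(min(off), 0)  # the min-scoring pair hits the floor
  expect_equal(max(off), 1)  # the max-scoring pair hits the ceiling
  check_similarity(s, unit_diag = TRUE, range = c(0, 1))
  # degenerate range -> 0.5 with warning
  expect_warning(sd_ <- mirna_sequence_similarity(c(a = "AC", b = "AC")),
                 "degenerate")
  expect_equal(sd_["a", "b"], 0.5)
})

test_that("functional similarity reflects signed disease profiles", {
  dags <- c(shared_parent_dags(),
            list(d3 = disease_dag("d3", "d3"), d4 = disease_dag("d4", "d4")))
  ds <- dss1(dags)
  # identical signed profiles -> 1
  assoc <- data.frame(mirna = c("m1", "m2"), disease = c("d1", "d1"),
                      k = c(0L, 0L))
  s <- mirna_functional_similarity(assoc, ds, dags)
  expect_equal(s["m1", "m2"], 1)
  # opposite regulation of the same disease -> -1
  assoc2 <- data.frame(mirna = c("m1", "m2"), disease = c("d1", "d1"),
                       k = c(0L, 1L))
  s2 <- mirna_functional_similarity(assoc2, ds, dags)
  expect_equal(s2["m1", "m2"], -1)
  expect_equal(unname(diag(s2)), c(1, 1))
  # disjoint, zero-similarity disease sets -> orthogonal features -> 0
  assoc3 <- data.frame(mirna = c("m1", "m2"), disease = c("d1", "d3"),
                       k = c(0L, 0L))
  s3 <- mirna_functional_similarity(assoc3, ds, dags)
  expect_equal(s3["m1", "m2"], 0)
  # an unassociated miRNA yields a zero off-diagonal row, flagged
  expect_warning(
    s4 <- mirna_functional_similarity(assoc3, ds, dags,
                                      mirna_ids = c("m1", "m2", "m9")),
    "no associated disease")
  expect_equal(attr(s4, "empty_mirnas"), "m9")
  expect_equal(unname(s4["m9", c("m1", "m2")]), c(0, 0))
  expect_equal(s4["m9", "m9"], 1)
})

test_that("association and FASTA readers round-trip the writers", {
  dir <- withr::local_tempdir()
  data <- simulate_dataset(synthetic_spec(n_mirna = 6L, n_disease = 5L,
                                          n_other = 2L, seed = 3L), dir)
  back <- read_dataset(dir)
  expect_equal(back$seqs[order(names(back$seqs))],
               data$seqs[order(names(data$seqs))])
  expect_equal(sort(names(back$dags)), sort(names(data$dags)))
  for (d in names(data$dags)) {
    expect_setequal(back$dags[[d]]$nodes, data$dags[[d]]$nodes)
    expect_equal(dag_semantic_values(back$dags[[d]])[data$dags[[d]]$nodes],
                 dag_semantic_values(data$dags[[d]])[data$dags[[d]]$nodes])
  }
  a1 <- data$assoc[order(data$assoc$mirna, data$assoc$disease), ]
  a2 <- back$assoc[order(back$assoc$mirna, back$assoc$disease), ]
  expect_equal(unname(as.matrix(a1)), unname(as.matrix(a2)))
  # similarity TSV round-trip
  s <- gip_kernel(interaction_profiles(data$assoc, data$mirna_ids,
                                       data$disease_ids, "mirna"))
  f <- file.path(dir, "mgs.tsv")
  write_similarity(s, f)
  expect_equal(read_similarity(f), s, tolerance = 1e-12)
})
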