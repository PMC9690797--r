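test_that("the digestive-system worked example reproduces the published values", {
  dags <- worked_example_dags()
  cm_dsn <- compute_contributions(dags$dsn)
  cm_bgn <- compute_contributions(dags$bgn)

  expect_equal(
    cm_dsn[c("Digestive System Neoplasms", "Digestive System Diseases",
             "Neoplasms by Site", "Neoplasms")],
    c("Digestive System Neoplasms" = 1, "Digestive System Diseases" = 0.5,
      "Neoplasms by Site" = 0.5, "Neoplasms" = 0.25)
  )
  expect_equal(semantic_value(cm_dsn), 2.25)
  expect_equal(semantic_value(cm_bgn), 2.625)

  shared <- intersect(names(cm_dsn), names(cm_bgn))
  expect_setequal(shared, c("Neoplasms", "Neoplasms by Site",
                            "Digestive System Diseases",
                            "Digestive System Neoplasms"))
  expect_equal(sum(cm_dsn[shared]), 2.25)
  expect_equal(sum(cm_bgn[shared]), 1.125)
  expect_equal(round(semantic_similarity(cm_dsn, cm_bgn), 4), 0.6923)
})

test_that("contributions equal delta^(minimum hop count): BFS oracle", {
  # diamond: node reachable by paths of depth 2 and 3 takes the shorter one
  diamond <- disease_dag("f", data.frame(
    child  = c("f", "f", "a", "b", "c"),
    parent = c("a", "b", "top", "c", "top")
  ), delta = 0.5)
  cm <- compute_contributions(diamond)
  expect_equal(unname(cm["top"]), 0.25)  # max(0.25 via a, 0.125 via b-c)

  # random layered DAGs against the BFS oracle
  set.seed(7)
  for (trial in 1:20) {
    n_extra <- sample(3:8, 1)
    nodes <- c("focal", paste0("n", seq_len(n_extra)))
    edges <- data.frame(child = character(0), parent = character(0))
    for (i in seq_len(n_extra)) {
      # each new node becomes parent of >= 1 existing node: acyclic by layers
      kids <- sample(nodes[seq_len(i)], sample(1:min(2, i), 1))
      edges <- rbind(edges, data.frame(child = kids, parent = nodes[i + 1]))
    }
    delta <- runif(1, 0.2, 0.9)
    dag <- disease_dag("focal", edges, delta = delta)
    expect_equal(compute_contributions(dag), bfs_contributions(dag)[dag$nodes],
                 tolerance = 1e-12)
  }
})

test_that("degenerate and invalid DAGs are handled", {
  single <- disease_dag("only", data.frame(child = character(0),
                                           parent = character(0)),
                        nodes = "only")
  expect_equal(semantic_value(single), 1.0)
  expect_equal(semantic_similarity(single, single), 1.0)

  expect_error(disease_dag("a", data.frame(child = c("a", "b"),
                                           parent = c("b", "a"))),
               "cycle")
  expect_error(disease_dag("a", data.frame(child = "b", parent = "c"),
                           nodes = c("a", "b", "c")),
               "not an ancestor")
  expect_error(semantic_value(numeric(0)), "empty")
})

test_that("semantic similarity is symmetric, bounded and grows with shared ancestry", {
  set.seed(11)
  chain_dag <- function(id, terms, delta = 0.5) {
    edges <- data.frame(child = c(id, head(terms, -1)), parent = terms)
    disease_dag(id, edges, delta = delta)
  }
  for (trial in 1:10) {
    shared <- paste0("s", seq_len(sample(1:4, 1)))
    a <- chain_dag("da", c(paste0("a", seq_len(sample(1:3, 1))), shared))
    b <- chain_dag("db", c(paste0("b", seq_len(sample(1:3, 1))), shared))
    s_ab <- semantic_similarity(a, b)
    expect_identical(s_ab, semantic_similarity(b, a))
    expect_gte(s_ab, 0); expect_lte(s_ab, 1)

    # one more shared ancestor on top never decreases the similarity
    a2 <- chain_dag("da", c(paste0("a", seq_len(length(a$nodes) - length(shared) - 1)),
                            shared, "extra"))
    b2 <- chain_dag("db", c(paste0("b", seq_len(length(b$nodes) - length(shared) - 1)),
                            shared, "extra"))
    expect_gte(semantic_similarity(a2, b2), s_ab - 1e-12)
  }

  disjoint_a <- chain_dag("da", "pa")
  disjoint_b <- chain_dag("db", "pb")
  expect_equal(semantic_similarity(disjoint_a, disjoint_b), 0)
})

test_that("the pairwise matrix agrees with elementwise similarity calls", {
  sim <- synthetic_dataset(synthetic_spec(n_lnc = 6, n_dis = 5, n_blocks = 2,
                                          seed = 5))
  S <- sim$Sdis
  expect_true(isSymmetric(unname(S)))
  expect_equal(unname(diag(S)), rep(1, ncol(S)))
  cms <- lapply(sim$dags, compute_contributions)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(S[i, j], semantic_similarity(cms[[i]], cms[[j]]))
    }
  }

  dags <- worked_example_dags()
  S2 <- disease_semantic_matrix(list(A = dags$dsn, B = dags$bgn))
  expect_equal(round(S2["A", "B"], 4), 0.6923)
  S3 <- disease_semantic_matrix(list(A = dags$dsn, B = dags$dsn))
  expect_equal(unname(S3), matrix(1, 2, 2), ignore_attr = TRUE)

  expect_error(disease_semantic_matrix(list(A = dags$dsn, B = NULL)), "'B'")
})

test_that("set-to-disease similarity takes the best match", {
  S <- matrix(c(1, 0.2, 0.7, 0.4,
                0.2, 1, 0.5, 0.3,
                0.7, 0.5, 1, 0.6,
                0.4, 0.3, 0.6, 1), 4, byrow = TRUE,
              dimnames = list(paste0("d", 1:4), paste0("d", 1:4)))
  expect_equal(set_to_disease_similarity("d1", c("d2", "d3", "d4"), S), 0.7)
  expect_equal(set_to_disease_similarity("d1", "d2", S), 0.2)
  expect_equal(set_to_disease_similarity("d1", c("d1", "d2"), S), 1.0)
  expect_error(set_to_disease_similarity("d1", character(0), S), "empty")
  expect_error(set_to_disease_similarity("d9", "d1", S), "d9")
})

test_that("functional similarity matches the best-match average formula", {
  Sdis <- matrix(c(1, 0.6, 0.2,
                   0.6, 1, 0.1,
                   0.2, 0.1, 1), 3, byrow = TRUE,
                 dimnames = list(c("dA", "dB", "dC"), c("dA", "dB", "dC")))
  # l1 -> {dA}, l2 -> {dB, dC}: (0.6 + 0.6 + 0.2) / 3
  Y <- association_matrix(matrix(c(1, 0, 0,
                                   0, 1, 1), 2, byrow = TRUE),
                          c("l1", "l2"), c("dA", "dB", "dC"))
  Sl <- lnc_functional_similarity(Y, Sdis)
  expect_equal(Sl["l1", "l2"], (0.6 + 0.6 + 0.2) / 3)
  expect_equal(unname(diag(Sl)), c(1, 1))

  # identical association rows give similarity 1
  Y2 <- association_matrix(matrix(c(1, 0, 1,
                                    1, 0, 1), 2, byrow = TRUE),
                           c("l1", "l2"), c("dA", "dB", "dC"))
  expect_equal(lnc_functional_similarity(Y2, Sdis)["l1", "l2"], 1)

  # disjoint sets with zero cross-similarity give 0
  Sdis0 <- diag(3); dimnames(Sdis0) <- dimnames(Sdis)
  Y3 <- association_matrix(matrix(c(1, 0, 0,
                                    0, 1, 0), 2, byrow = TRUE),
                           c("l1", "l2"), c("dA", "dB", "dC"))
  expect_equal(lnc_functional_similarity(Y3, Sdis0)["l1", "l2"], 0)

  # all-zero row: self-similarity 1, others 0
  Y4 <- association_matrix(matrix(c(1, 0, 0,
                                    0, 0, 0), 2, byrow = TRUE),
                           c("l1", "l2"), c("dA", "dB", "dC"))
  Sl4 <- lnc_functional_similarity(Y4, Sdis)
  expect_equal(Sl4["l2", "l2"], 1)
  expect_equal(Sl4["l1", "l2"], 0)
})
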