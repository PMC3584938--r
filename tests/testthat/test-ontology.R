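test_that("parse_obo builds the DAG, filters obsolete terms, handles multi-parents", {
  obo <- c("[Term]", "id: R0", "name: biological_process",
           "namespace: biological_process", "",
           "[Term]", "id: A0", "name: a", "namespace: biological_process",
           "is_a: R0 ! root", "",
           "[Term]", "id: B0", "name: b", "namespace: biological_process",
           "is_a: R0", "",
           "[Term]", "id: X0", "name: x", "namespace: biological_process",
           "is_a: A0", "is_a: B0", "",
           "[Term]", "id: OBS", "name: gone",
           "namespace: biological_process", "is_a: R0", "is_obsolete: true")
  dag <- parse_obo(obo)
  expect_equal(nrow(dag$terms), 4)
  expect_equal(dag$roots[["BP"]], "R0")
  expect_false("OBS" %in% dag$terms$id)
  expect_setequal(dag$parents[["X0"]], c("A0", "B0"))
  expect_setequal(go_ancestors(dag, "X0"), c("A0", "B0", "R0"))
})

test_that("parse_obo rejects cycles and unknown is_a targets", {
  cyc <- c("[Term]", "id: R0", "name: biological_process",
           "namespace: biological_process", "",
           "[Term]", "id: A0", "name: a", "namespace: biological_process",
           "is_a: R0", "is_a: B0", "",
           "[Term]", "id: B0", "name: b", "namespace: biological_process",
           "is_a: A0")
  expect_error(parse_obo(cyc), "cycle")
  unk <- c("[Term]", "id: R0", "name: biological_process",
           "namespace: biological_process", "",
           "[Term]", "id: A0", "name: a", "namespace: biological_process",
           "is_a: NOPE")
  expect_error(parse_obo(unk), "unknown id NOPE")
})

test_that("ancestors and propagation match hand closures on D0", {
  dag <- d0_dag()
  expect_setequal(go_ancestors(dag, d0$A1), c(d0$A, d0$R))
  expect_equal(go_ancestors(dag, d0$R, include_self = TRUE), d0$R)
  expect_setequal(go_propagate(dag, d0$A1), c(d0$A1, d0$A, d0$R))
  expect_equal(go_propagate(dag, character(0)), character(0))
  expect_setequal(go_propagate(dag, c(d0$A1, d0$B)),
                  c(d0$A1, d0$A, d0$B, d0$R))
  expect_error(go_ancestors(dag, "GO:9999999"), "unknown term")
})

test_that("propagation is idempotent and monotone on random DAGs", {
  set.seed(11)
  for (rep in 1:10) {
    dag <- random_dag()
    pool <- dag$terms$id
    S <- sample(pool, 3)
    T <- union(S, sample(pool, 2))
    pS <- go_propagate(dag, S)
    expect_setequal(go_propagate(dag, pS), pS)
    expect_true(all(pS %in% go_propagate(dag, T)))
    expect_setequal(pS, oracle_propagate(dag, S))
  }
})

test_that("edge distance matches D0 hand counts and is a metric", {
  dag <- d0_dag()
  expect_equal(go_edge_distance(dag, d0$A1, d0$A), 1)
  expect_equal(go_edge_distance(dag, d0$A1, d0$A1), 0)
  expect_equal(go_edge_distance(dag, d0$A1, d0$B), 3)
  set.seed(12)
  for (rep in 1:5) {
    dag <- random_dag(n_terms = 10)
    D <- oracle_edge_distance_matrix(dag)
    ids <- dag$terms$id
    for (pair in replicate(8, sample(ids, 2), simplify = FALSE)) {
      d12 <- go_edge_distance(dag, pair[1], pair[2])
      expect_equal(d12, unname(D[pair[1], pair[2]]))
      expect_equal(d12, go_edge_distance(dag, pair[2], pair[1]))  # symmetry
    }
    # triangle inequality on the oracle matrix (sanity of the metric)
    trip <- sample(ids, 3)
    expect_lte(D[trip[1], trip[3]], D[trip[1], trip[2]] + D[trip[2], trip[3]])
  }
})

test_that("term statistics follow the recursive frequency definition", {
  dag <- d0_dag()
  st <- compute_term_stats(dag, annotation_counts(d0_db()))
  freq <- setNames(st$freq, st$term)
  expect_equal(unname(freq[c(d0$A1, d0$A2, d0$A, d0$B, d0$R)]),
               c(2, 1, 3, 1, 4))
  p <- setNames(st$p, st$term)
  ic <- setNames(st$ic, st$term)
  expect_equal(unname(p[d0$A1]), 0.5)
  expect_equal(unname(ic[d0$A1]), log10(2), tolerance = 1e-12)
  expect_equal(unname(ic[d0$R]), 0)
})

test_that("a single chain with annotations only at the leaf gives IC 0 everywhere", {
  obo <- c("[Term]", "id: R0", "name: biological_process",
           "namespace: biological_process", "",
           "[Term]", "id: X0", "name: x", "namespace: biological_process",
           "is_a: R0")
  dag <- parse_obo(obo)
  st <- compute_term_stats(dag, c(X0 = 5))
  expect_equal(st$p[st$term == "X0"], 1)
  expect_equal(st$ic[st$term == "X0"], 0)
  expect_error(compute_term_stats(dag, c(X0 = 0)), "freq\\(root\\) = 0")
})

test_that("recursive frequencies equal the path-counting oracle and are monotone", {
  set.seed(13)
  for (rep in 1:8) {
    dag <- random_dag(n_terms = sample(5:15, 1))
    pool <- setdiff(dag$terms$id, dag$roots[["BP"]])
    counts <- setNames(sample(0:3, length(pool), replace = TRUE), pool)
    counts[sample(length(counts), 1)] <- counts[sample(length(counts), 1)] + 1
    if (sum(counts) == 0) counts[1] <- 1
    st <- compute_term_stats(dag, counts[counts > 0])
    freq <- setNames(st$freq, st$term)
    expect_equal(freq[dag$terms$id], oracle_freq(dag, counts[counts > 0]),
                 tolerance = 1e-12)
    for (child in names(dag$parents)) {
      for (par in dag$parents[[child]]) {
        expect_gte(freq[[par]], freq[[child]])
      }
    }
  }
})

test_that("unique-protein mode counts distinct proteins at-or-below each term", {
  dag <- d0_dag()
  db <- d0_db()
  st <- compute_term_stats(dag, annotation_counts(db), mode = "unique",
                           db = db)
  freq <- setNames(st$freq, st$term)
  # p2 annotated with both A1 and B is counted once at R in this mode
  expect_equal(unname(freq[c(d0$A1, d0$A, d0$R)]), c(2, 3, 3))
})

test_that("shared-ancestor IC matches hand enumeration on D0", {
  dag <- d0_dag()
  st <- d0_stats()
  expect_equal(max_shared_ancestor_ic(dag, st, d0$A1, d0$A2),
               -log10(0.75), tolerance = 1e-9)
  expect_equal(max_shared_ancestor_ic(dag, st, d0$A1, d0$A1),
               log10(2), tolerance = 1e-9)
  expect_equal(max_shared_ancestor_ic(dag, st, d0$A1, d0$B), 0)
})

test_that("OBO writing round-trips through the parser", {
  set.seed(14)
  for (dag in list(d0_dag(), random_dag())) {
    back <- parse_obo(write_obo(dag))
    expect_equal(back$terms[order(back$terms$id), ],
                 dag$terms[order(dag$terms$id), ])
    expect_equal(lapply(back$parents[back$terms$id], sort),
                 lapply(dag$parents[back$terms$id], sort))
  }
})
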