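test_that("PFP raw scores reproduce the hand-evaluated co-occurrence sums", {
  db <- d0_db()
  hits <- tb_hits("p2", 1e-3)                 # annotations {A1, B}
  s <- pfp_raw_scores(hits, db)
  sc <- setNames(s$score, s$term)
  expect_equal(unname(sc[d0$A1]), 10, tolerance = 1e-9)
  expect_equal(unname(sc[d0$B]), 7.5, tolerance = 1e-9)

  expect_equal(nrow(pfp_raw_scores(tb_hits(character(0), numeric(0)), db)), 0)

  at_ceiling <- pfp_raw_scores(tb_hits("p2", 100), db)
  expect_equal(nrow(at_ceiling), 0)           # E >= ceiling dropped
  just_under <- pfp_raw_scores(tb_hits("p2", 99.999), db)
  expect_true(all(just_under$score < 1e-4))   # -log10(E) + b ~ 0
})

test_that("parent transfer adds freq-proportional shares to every ancestor", {
  dag <- d0_dag()
  st <- d0_stats()
  raw <- tb_pred(d0$A1, 10)
  tr <- pfp_parent_transfer(raw, dag, st)
  sc <- setNames(tr$score, tr$term)
  expect_equal(unname(sc[d0$A]), 10 * 2 / 3, tolerance = 1e-9)
  expect_equal(unname(sc[d0$R]), 10 * 2 / 4, tolerance = 1e-9)
  expect_equal(unname(sc[d0$A1]), 10)

  zero <- pfp_parent_transfer(tb_pred(d0$A1, 0), dag, st)
  expect_equal(sum(zero$score), 0)
  root_only <- pfp_parent_transfer(tb_pred(d0$R, 5), dag, st)
  expect_equal(root_only$term, d0$R)          # root transfers nothing
})

test_that("PFP scores never decrease when a hit annotated with the term is added", {
  set.seed(41)
  for (rep in 1:10) {
    inst <- random_instance()
    fa <- sample(unique(inst$db$term), 1)
    base <- pfp_raw_scores(inst$hits, inst$db)
    carrier <- sample(unique(inst$db$protein[inst$db$term == fa]), 1)
    extra <- tibble::tibble(query = "T1", subject = paste0(carrier, "_dup"),
                            pident = 50, evalue = 1e-8)
    # duplicate the carrier protein under a new subject id so the hit list
    # grows without changing the co-occurrence table
    db2 <- gopred:::new_annotation_db(dplyr::bind_rows(
      inst$db,
      dplyr::mutate(inst$db[inst$db$protein == carrier, ],
                    protein = paste0(carrier, "_dup"))))
    with_hit <- pfp_raw_scores(dplyr::bind_rows(inst$hits, extra), db2)
    s0 <- base$score[base$term == fa]
    s1 <- with_hit$score[with_hit$term == fa]
    expect_gte(if (length(s1)) s1 else 0, if (length(s0)) s0 else 0)
  }
})

test_that("empirical p-values use inclusive counts with an add-one floor", {
  expect_equal(gopred:::empirical_p(c(1, 2, 3, 4), 3), 0.5)
  expect_equal(gopred:::empirical_p(c(1, 2, 3, 4), 5), 1 / 5)
  expect_equal(gopred:::empirical_p(c(1, 2, 3, 4), 0), 1)
})

test_that("calibration fractions are valid and confidence is monotone in the p-value", {
  cf <- calib_fixture()
  cal <- suppressMessages(build_calibration(cf$bench, cf$truth, cf$dag))
  tab <- tidy(cal)
  for (k in c("conf_k0", "conf_k2", "conf_k4")) {
    expect_true(all(tab[[k]] >= 0 & tab[[k]] <= 1))
    expect_true(all(diff(tab[[k]]) <= 1e-9))   # non-increasing in p
  }
  # correctness widens with the allowed edge distance
  expect_true(all(tab$conf_k4 >= tab$conf_k0 - 1e-9))

  conf <- pfp_confidence(tb_pred(c(d0$A1, d0$A1), c(5, 5)), cal)
  expect_equal(conf$score[1], conf$score[2])   # determinism on equal input
  expect_true(all(conf$score >= 0 & conf$score <= 1))
  expect_error(pfp_confidence(tb_pred(d0$A1, 5), NULL), "raw score")
})

test_that("ESG weights and two-level mixing reproduce the hand example", {
  db2 <- gopred:::new_annotation_db(tibble::tibble(
    protein = c("h1", "h2", "g1"),
    term = c(d0$A1, d0$B, d0$A2),
    namespace = "BP", evidence = list("EXP", "EXP", "EXP")))
  l1 <- tb_hits(c("h1", "h2"), c(1e-4, 1e-2))
  one <- esg_scores(build_hit_graph("T1", l1), db2)
  sc <- setNames(one$score, one$term)
  expect_equal(unname(sc[d0$A1]), 4 / 6, tolerance = 1e-9)
  expect_equal(unname(sc[d0$B]), 2 / 6, tolerance = 1e-9)

  l2 <- tibble::tibble(query = "h1", subject = "g1", pident = 50,
                       evalue = 1e-6)
  two <- esg_scores(build_hit_graph("T1", l1, level2 = l2), db2, a = 0.5)
  sc2 <- setNames(two$score, two$term)
  expect_equal(unname(sc2[c(d0$A1, d0$A2, d0$B)]), rep(1 / 3, 3),
               tolerance = 1e-9)

  solo <- esg_scores(build_hit_graph("T1", tb_hits("h1", 1e-5)), db2)
  expect_equal(solo$score, 1.0)
})

test_that("ESG total score is bounded by the largest annotation set", {
  set.seed(43)
  for (rep in 1:10) {
    inst <- random_instance()
    g <- build_hit_graph("T1", inst$hits, level2 = inst$level2)
    s <- esg_scores(g, inst$db)
    sizes <- lengths(split(inst$db$term, inst$db$protein))
    expect_lte(sum(s$score), max(sizes) + 1e-9)
    expect_true(all(s$score >= 0 & s$score <= 1 + 1e-9))
  }
})

test_that("GOtcha I-scores reproduce hand sums and respect the hierarchy", {
  dag <- d0_dag()
  db2 <- gopred:::new_annotation_db(tibble::tibble(
    protein = c("h1", "h2"), term = c(d0$A1, d0$B),
    namespace = "BP", evidence = list("EXP", "EXP")))
  hits <- tb_hits(c("h1", "h2"), c(1e-5, 1e-3))
  g <- gotcha_scores(hits, db2, dag)
  sc <- setNames(g$score, g$term)
  expect_equal(unname(sc[d0$A1]), 0.625, tolerance = 1e-9)
  expect_equal(unname(sc[d0$B]), 0.375, tolerance = 1e-9)
  expect_equal(unname(sc[d0$R]), 1.0)

  expect_equal(nrow(gotcha_scores(tb_hits(c("h1", "h2"), c(1, 50)), db2, dag)),
               0)

  set.seed(44)
  for (rep in 1:8) {
    inst <- random_instance()
    g <- gotcha_scores(inst$hits, inst$db, inst$dag)
    if (!nrow(g)) next
    sc <- setNames(g$score, g$term)
    expect_true(all(sc >= 0 & sc <= 1 + 1e-12))
    for (tm in g$term) {
      for (par in inst$dag$parents[[tm]]) {
        expect_gte(sc[[par]] + 1e-12, sc[[tm]])
      }
    }
  }
})

test_that("the BLAST baseline takes the maximum identity per annotated term", {
  db <- d0_db()
  hits <- tibble::tibble(query = "T1", subject = c("p1", "p2"),
                         pident = c(80, 60), evalue = 1e-5)
  s <- blast_baseline(hits, db)
  sc <- setNames(s$score, s$term)
  expect_equal(unname(sc[d0$A1]), 0.80)
  expect_equal(unname(sc[d0$B]), 0.60)

  # a hit with no usable (non-IEA) annotation yields no predictions
  empty_db <- parse_gaf(c("!gaf-version: 2.1",
    paste(c("GP", "q1", "q1", "", d0$A1, "x", "IEA", "", "P", "", "",
            "protein", "t", "d", "s"), collapse = "\t")))
  expect_equal(nrow(blast_baseline(tb_hits("q1", 1e-30), empty_db)), 0)
})

test_that("Prior predictions use pseudocounted frequencies, identically per target", {
  st <- d0_stats()
  pr <- prior_predictions(st, n_max = 2)
  expect_equal(pr$term, c(d0$R, d0$A))
  expect_equal(pr$score, c(1.0, 0.8), tolerance = 1e-9)
  expect_equal(prior_predictions(st, n_max = 1)$term, d0$R)

  db <- d0_db()
  hits <- tibble::tibble(query = c("T1", "T2"), subject = "p1",
                         pident = 50, evalue = 1e-5)
  preds <- predict_targets(hits, db, stats = st, method = "prior")
  t1 <- preds[preds$target == "T1", c("term", "score")]
  t2 <- preds[preds$target == "T2", c("term", "score")]
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("Prior enrichment rescales imports for PFP and keeps them for ESG", {
  preds <- tb_pred(c(d0$A1, d0$A), c(0.9, 0.6), target = "T1")
  prior <- tb_pred(c(d0$R, d0$A, d0$B), c(1.0, 0.8, 0.4))
  out <- enrich_with_prior(preds, prior, mode = "pfp")
  sc <- setNames(out$score, out$term)
  expect_equal(unname(sc[d0$R]), 0.9, tolerance = 1e-9)  # mapped 1.0 -> 0.9
  expect_equal(unname(sc[d0$B]), 0.6, tolerance = 1e-9)  # mapped 0.4 -> 0.6
  expect_equal(out$term, c(d0$R, d0$A1, d0$A, d0$B))     # score then lex id

  esg <- enrich_with_prior(preds, prior, mode = "esg")
  sce <- setNames(esg$score, esg$term)
  expect_equal(unname(sce[d0$R]), 1.0)
  expect_equal(unname(sce[d0$B]), 0.4)

  noop <- enrich_with_prior(preds, tb_pred(d0$A1, 0.7), mode = "esg")
  expect_equal(as.data.frame(noop[, c("term", "score")]),
               as.data.frame(preds[, c("term", "score")]))
})

test_that("truncation keeps the k best terms with lexicographic tie-breaks", {
  preds <- tb_pred(c("GO:3", "GO:1", "GO:2"), c(0.9, 0.5, 0.5),
                   target = "T1")
  out <- truncate_predictions(preds, k = 2)
  expect_equal(out$term, c("GO:3", "GO:1"))
  expect_equal(nrow(truncate_predictions(preds, k = 10)), 3)

  set.seed(45)
  big <- tb_pred(sprintf("GO:%04d", 1:1200), runif(1200), target = "T1")
  expect_equal(nrow(truncate_predictions(big)), 1000)
})
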