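test_that("confusion counts at a threshold follow the propagated set algebra", {
  dag <- d0_dag()
  pred <- tb_pred(c(d0$A1, d0$B), c(0.9, 0.4))
  hi <- confusion_at_threshold(pred, d0$A1, dag, 0.5)
  expect_equal(hi[, c("tp", "fp", "fn")], tibble::tibble(tp = 2L, fp = 0L,
                                                         fn = 0L))
  expect_equal(hi$precision, 1)
  expect_equal(hi$recall, 1)

  lo <- confusion_at_threshold(pred, d0$A1, dag, 0.3)
  expect_equal(lo$tp, 2L)
  expect_equal(lo$fp, 1L)
  expect_equal(lo$precision, 2 / 3)
  expect_equal(lo$tn, 1L)             # only A2 is a true negative
  expect_equal(lo$specificity, 0.5)

  none <- confusion_at_threshold(pred, d0$A1, dag, 0.95)
  expect_equal(none$recall, 0)
  expect_error(confusion_at_threshold(pred, character(0), dag, 0.5),
               "empty truth")
})

test_that("threshold curves average precision only over predicting targets", {
  dag <- d0_dag()
  preds <- tb_pred(c(d0$A1, d0$A, d0$R), c(1, 1, 1), target = "T1")
  truth <- tibble::tibble(target = c("T1", "T2"), term = d0$A1)
  cv <- threshold_curves(preds, truth, dag, taus = c(0.5, 1))
  # T2 has no predictions: excluded from precision, recall counted as 0
  expect_equal(cv$n_precision_targets, c(1L, 1L))
  expect_equal(cv$precision, c(1, 1))
  expect_equal(cv$recall, c(0.5, 0.5))

  perfect <- threshold_curves(preds, truth[truth$target == "T1", ], dag,
                              taus = c(0.2, 0.9))
  expect_equal(perfect$precision, c(1, 1))
  expect_equal(perfect$recall, c(1, 1))
})

test_that("recall is non-increasing and TN non-decreasing in the threshold", {
  set.seed(51)
  for (rep in 1:5) {
    inst <- random_instance()
    preds <- dplyr::mutate(
      blast_baseline(inst$hits, inst$db), target = "T1", .before = 1)
    if (!nrow(preds)) next
    taus <- seq(0.05, 1, by = 0.05)
    cv <- threshold_curves(preds, inst$truth, inst$dag, taus = taus)
    expect_true(all(diff(cv$recall) <= 1e-12))
    tns <- vapply(taus, function(tau) {
      confusion_at_threshold(preds[, c("term", "score")],
                             inst$truth$term, inst$dag, tau)$tn
    }, 0L)
    expect_true(all(diff(tns) >= 0))
    # TP + FN is conserved at |propagate(truth) \ root|
    tpfn <- vapply(taus, function(tau) {
      cc <- confusion_at_threshold(preds[, c("term", "score")],
                                   inst$truth$term, inst$dag, tau)
      cc$tp + cc$fn
    }, 0L)
    T_size <- length(setdiff(go_propagate(inst$dag, unique(inst$truth$term)),
                             inst$dag$roots[["BP"]]))
    expect_true(all(tpfn == T_size))
  }
})

test_that("top-N evaluation includes all terms tied with the N-th score", {
  dag <- d0_dag()
  preds <- tb_pred(c(d0$A1, d0$B, d0$A2), c(0.9, 0.9, 0.5), target = "T1")
  truth <- tibble::tibble(target = "T1", term = c(d0$A1, d0$B))
  cv <- topn_curves(preds, truth, dag, n_grid = c(1, 10))
  # N = 1 takes both tied terms plus ancestors: {A1, B, A} = exactly truth
  expect_equal(cv$recall[1], 1)
  expect_equal(cv$precision[1], 1)
  # N beyond the list takes everything
  expect_equal(cv$recall[2], 1)
  expect_lt(cv$precision[2], 1)
})

test_that("weighted precision and recall follow the IC sums", {
  dag <- d0_dag()
  st <- d0_stats()
  preds <- tb_pred(c(d0$A1, d0$B), c(0.9, 0.4), target = "T1")
  truth <- tibble::tibble(target = "T1", term = d0$A1)
  w <- weighted_curves(preds, truth, st, dag, taus = 0.3)
  ic <- setNames(st$ic, st$term)
  expect_equal(w$w_precision,
               (ic[[d0$A1]] + ic[[d0$A]]) /
                 (ic[[d0$A1]] + ic[[d0$A]] + ic[[d0$B]]),
               tolerance = 1e-9)
  expect_equal(w$w_recall, 1, tolerance = 1e-9)

  ident <- weighted_curves(preds, truth, st, dag, taus = 0.5)
  expect_equal(ident$w_precision, 1)
  expect_equal(ident$w_recall, 1)

  wrong <- weighted_curves(tb_pred(d0$B, 0.9, target = "T1"), truth, st, dag,
                           taus = 0.5)
  expect_equal(wrong$w_precision, 0)   # TP empty, FP has positive IC
})

test_that("semantic metrics are zero on identical sets and match hand values", {
  dag <- d0_dag()
  st <- d0_stats()
  truth <- tibble::tibble(target = "T1", term = d0$A1)
  same <- semantic_curves(tb_pred(d0$A1, 1, target = "T1"), truth, st, dag,
                          taus = 0.5)
  expect_equal(same$similarity, log10(2), tolerance = 1e-9)
  expect_equal(same$s_precision, 0, tolerance = 1e-12)
  expect_equal(same$s_recall, 0, tolerance = 1e-12)

  cross <- semantic_curves(tb_pred(d0$B, 1, target = "T1"), truth, st, dag,
                           taus = 0.5)
  expect_equal(cross$similarity, 0)
  expect_equal(cross$s_precision, -log10(0.25), tolerance = 1e-9)
  expect_equal(cross$s_recall, log10(2), tolerance = 1e-9)

  # adding the true term to the predictions drives semantic recall to 0
  both <- semantic_curves(tb_pred(c(d0$B, d0$A1), c(1, 1), target = "T1"),
                          truth, st, dag, taus = 0.5)
  expect_equal(both$s_recall, 0, tolerance = 1e-12)

  set.seed(52)
  for (rep in 1:5) {
    inst <- random_instance()
    stats <- compute_term_stats(inst$dag, annotation_counts(inst$db))
    terms <- unique(inst$truth$term)
    eq <- semantic_curves(tb_pred(terms, rep(1, length(terms)),
                                  target = "T1"),
                          inst$truth, stats, inst$dag, taus = 0.5)
    if (is.na(eq$s_precision)) next   # all truth terms lacked defined IC
    expect_equal(eq$s_precision, 0, tolerance = 1e-12)
    expect_equal(eq$s_recall, 0, tolerance = 1e-12)
  }
})

test_that("evaluable terms require the stated number of annotated targets", {
  dag <- d0_dag()
  truth <- tibble::tibble(target = sprintf("T%d", 1:5),
                          term = c(d0$A1, d0$A1, d0$A1, d0$A2, d0$B))
  et <- evaluable_terms(truth, dag, min_targets = 4)
  # A is in the propagated truth of T1-T4 (4 targets); A1 only 3
  expect_true(d0$A %in% et$term)
  expect_false(d0$A1 %in% et$term)
  expect_true(d0$R %in% et$term)     # root hits all 5
  expect_equal(nrow(evaluable_terms(truth, dag, min_targets = 6)), 0)
})

test_that("term-centric F1 is the maximum harmonic mean over cutoffs", {
  dag <- d0_dag()
  truth <- tibble::tibble(target = c("T1", "T2", "T3"),
                          term = c(d0$A1, d0$A1, d0$B))
  # perfect detector of A1 at high scores
  preds <- dplyr::bind_rows(
    tb_pred(d0$A1, 0.9, target = "T1"),
    tb_pred(d0$A1, 0.8, target = "T2"),
    tb_pred(d0$B, 0.9, target = "T3"))
  f1 <- per_term_f1(preds, truth, dag, terms = d0$A1)
  expect_equal(f1$f1, 1)

  # detector that also fires on the negative target: P = 2/3, R = 1
  noisy <- dplyr::bind_rows(preds[1:2, ], tb_pred(d0$A1, 0.9, target = "T3"))
  f1n <- per_term_f1(noisy, truth, dag, terms = d0$A1)
  expect_equal(f1n$f1, 2 * (2 / 3) * 1 / ((2 / 3) + 1), tolerance = 1e-9)

  none <- per_term_f1(tb_pred(character(0), numeric(0), target = character(0)),
                      truth, dag, terms = d0$A1)
  expect_equal(none$f1, 0)
  expect_error(per_term_f1(preds, truth, dag, terms = d0$A2), "no target")
})

test_that("per-target Fmax handles empty and perfect prediction sets", {
  dag <- d0_dag()
  truth <- tibble::tibble(target = "T1", term = d0$A1)
  perfect <- tb_pred(c(d0$A1, d0$A), c(0.9, 0.9), target = "T1")
  fm <- target_fmax(perfect, truth, dag)
  expect_equal(fm$fmax, 1)
  empty <- target_fmax(tb_pred(character(0), numeric(0),
                               target = character(0)), truth, dag)
  expect_equal(empty$fmax, 0)
})

test_that("ranking AUC is 1 for a perfect leaf ranking and 0 for an inverted one", {
  dag <- d0_dag()
  truth <- tibble::tibble(target = "T1", term = d0$A1)
  up <- prediction_auc(tb_pred(c(d0$A1, d0$A2, d0$B), c(1, 0.1, 0.1),
                               target = "T1"), truth, dag)
  expect_equal(up$auc, 1)
  down <- prediction_auc(tb_pred(c(d0$A1, d0$A2, d0$B), c(0.1, 1, 0.9),
                                 target = "T1"), truth, dag)
  expect_equal(down$auc, 0)
  flat <- prediction_auc(tb_pred(character(0), numeric(0),
                                 target = character(0)), truth, dag)
  expect_equal(flat$auc, 0.5)        # all-tied scores
})
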