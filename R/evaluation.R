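#' @name evaluation
#' @title CAFA-style evaluation of GO prediction sets
#' @description
#' All set-based metrics share the same construction: the predicted terms at
#' a score cutoff and the true terms are propagated to the namespace root,
#' the root itself is excluded (it is implied by any annotation and would
#' uniformly inflate precision), and confusion counts are taken against the
#' universe of all namespace terms minus the root. "Above the threshold" is
#' implemented as `score >= tau`, so `tau = 1` retains scores of exactly 1
#' (the Prior's root score and GOtcha's I(root)).
NULL

# ---- shared set machinery ---------------------------------------------------

ns_terms <- function(dag, namespace) {
  dag$terms$id[dag$terms$namespace == namespace]
}

# Precompute, for one target's predictions, the propagated set at every
# distinct score level (scores descending, sets cumulative).
closure_index <- function(pred, dag, drop_root = NULL) {
  if (is.null(pred) || !nrow(pred)) {
    return(list(scores = numeric(0), sets = list(), n_terms = integer(0)))
  }
  o <- order(-pred$score, pred$term)
  term <- pred$term[o]
  score <- pred$score[o]
  uscore <- unique(score)
  sets <- vector("list", length(uscore))
  n_terms <- integer(length(uscore))
  acc <- character(0)
  cum <- 0L
  for (k in seq_along(uscore)) {
    sel <- score == uscore[[k]]
    cum <- cum + sum(sel)
    acc <- unique(c(acc, go_propagate(dag, term[sel])))
    sets[[k]] <- acc
    n_terms[[k]] <- cum
  }
  if (!is.null(drop_root)) sets <- lapply(sets, setdiff, y = drop_root)
  list(scores = uscore, sets = sets, n_terms = n_terms)
}

set_at_tau <- function(ci, tau) {
  k <- sum(ci$scores >= tau)
  if (k == 0) character(0) else ci$sets[[k]]
}

n_pred_at_tau <- function(ci, tau) {
  k <- sum(ci$scores >= tau)
  if (k == 0) 0L else ci$n_terms[[k]]
}

confusion_counts <- function(P, T, n_universe) {
  tp <- length(intersect(P, T))
  fp <- length(P) - tp
  fn <- length(T) - tp
  tn <- n_universe - (tp + fp + fn)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

f1_of <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Confusion counts for one target at one threshold
#'
#' Predicted terms with `score >= tau` and the true terms are propagated to
#' the root; the root is excluded (unless `include_root`) and counts are
#' taken against all namespace terms minus the root.
#'
#' @param pred tibble `term`, `score` for one target.
#' @param truth_terms character vector of true terms (pre-propagation).
#' @param dag a [go_dag].
#' @param tau score threshold in (0, 1].
#' @param namespace `"BP"` or `"MF"`.
#' @param include_root count the namespace root as an ordinary term?
#' @return one-row tibble: `threshold`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `specificity`, `f1`.
#' @export
confusion_at_threshold <- function(pred, truth_terms, dag, tau,
                                   namespace = "BP", include_root = FALSE) {
  assert_namespace(namespace)
  if (!length(truth_terms)) {
    stop("empty truth set: recall is undefined", call. = FALSE)
  }
  root <- if (include_root) character(0) else dag$roots[[namespace]]
  universe <- setdiff(ns_terms(dag, namespace), root)
  P <- setdiff(go_propagate(dag, pred$term[pred$score >= tau]), root)
  T <- setdiff(go_propagate(dag, truth_terms), root)
  cc <- confusion_counts(P, T, length(universe))
  mutate(cc, threshold = tau, f1 = f1_of(.data$precision, .data$recall),
         .before = 1)
}

# Common loop over (target, cutoff-set) pairs used by the threshold and
# top-N sweeps. `pick_set(ci, x)` returns the propagated prediction set at
# sweep point x; `n_at(ci, x)` the number of unpropagated predictions kept.
sweep_curves <- function(preds, truth, dag, grid, namespace, include_root,
                         pick_set, n_at, grid_name) {
  assert_namespace(namespace)
  root <- if (include_root) character(0) else dag$roots[[namespace]]
  n_universe <- length(setdiff(ns_terms(dag, namespace), root))
  truth_sets <- split(truth$term, truth$target)
  empty_truth <- names(truth_sets)[lengths(truth_sets) == 0]
  if (length(empty_truth)) {
    gp_log("skipping ", length(empty_truth), " target(s) with empty truth")
    truth_sets <- truth_sets[lengths(truth_sets) > 0]
  }
  targets <- names(truth_sets)
  pred_split <- split(preds[, c("term", "score")], preds$target)
  cis <- lapply(targets, function(tg) {
    closure_index(pred_split[[tg]], dag, drop_root = root)
  })
  T_sets <- lapply(targets, function(tg) {
    setdiff(go_propagate(dag, unique(truth_sets[[tg]])), root)
  })
  rows <- lapply(grid, function(x) {
    prec <- rec <- spec <- numeric(0)
    for (i in seq_along(targets)) {
      P <- pick_set(cis[[i]], x)
      cc <- confusion_counts(P, T_sets[[i]], n_universe)
      if (n_at(cis[[i]], x) > 0 && !is.na(cc$precision)) {
        prec <- c(prec, cc$precision)
      }
      rec <- c(rec, cc$recall %||% 0)
      spec <- c(spec, cc$specificity)
    }
    p <- if (length(prec)) mean(prec) else NA_real_
    r <- mean(rec)
    tibble(!!grid_name := x,
           precision = p, recall = r,
           specificity = mean(spec, na.rm = TRUE),
           f1 = f1_of(p, r),
           n_targets = length(targets),
           n_precision_targets = length(prec))
  })
  out <- bind_rows(rows)
  structure(out, class = c("gopred_curves", class(out)),
            sweep = grid_name, namespace = namespace)
}

#' Threshold sweep: average precision, recall and specificity
#'
#' For each threshold, per-target confusion counts are computed as in
#' [confusion_at_threshold()] and averaged: precision over targets with at
#' least one prediction at the threshold (0/0 is undefined, the CAFA
#' convention), recall and specificity over all evaluable targets (a target
#' with no surviving prediction counts recall 0).
#'
#' @param preds tibble `target`, `term`, `score`.
#' @param truth tibble `target`, `term` (pre-propagation truth).
#' @param dag a [go_dag].
#' @param taus thresholds; default `seq(0.01, 1, by = 0.01)`.
#' @param namespace `"BP"` or `"MF"`.
#' @param include_root count the root as an ordinary term?
#' @return a `gopred_curves` tibble: `threshold`, `precision`, `recall`,
#'   `specificity`, `f1`, `n_targets`, `n_precision_targets`.
#' @export
threshold_curves <- function(preds, truth, dag, taus = seq(0.01, 1, by = 0.01),
                             namespace = "BP", include_root = FALSE) {
  sweep_curves(preds, truth, dag, taus, namespace, include_root,
               pick_set = set_at_tau, n_at = n_pred_at_tau,
               grid_name = "threshold")
}

#' Top-N sweep (rank-based evaluation)
#'
#' For each N, the prediction set is the N highest-scoring terms of a target
#' -- including every term tied with the N-th score -- plus their ancestors.
#' With `n_grid = seq(1, 1000, by = 5)` this is the rank sweep used to
#' evaluate unscaled PFP raw scores, where thresholds on \[0, 1\] do not
#' apply.
#'
#' @inheritParams threshold_curves
#' @param n_grid rank cutoffs; default `1:20`.
#' @return a `gopred_curves` tibble keyed by `n`.
#' @export
topn_curves <- function(preds, truth, dag, n_grid = 1:20,
                        namespace = "BP", include_root = FALSE) {
  pick <- function(ci, n) {
    if (!length(ci$scores)) return(character(0))
    k <- match(TRUE, ci$n_terms >= n)
    if (is.na(k)) k <- length(ci$sets)
    ci$sets[[k]]
  }
  n_at <- function(ci, n) if (length(ci$scores)) 1L else 0L
  sweep_curves(preds, truth, dag, as.numeric(n_grid), namespace, include_root,
               pick_set = pick, n_at = n_at, grid_name = "n")
}

#' Information-content-weighted precision and recall
#'
#' Confusion sets are built exactly as in [confusion_at_threshold()];
#' weighted precision is `sum IC(TP) / sum IC(TP u FP)` and weighted recall
#' `sum IC(TP) / sum IC(TP u FN)`. Terms with undefined IC are dropped from
#' the sums (logged); a target-threshold point whose denominator is zero is
#' skipped.
#'
#' @inheritParams threshold_curves
#' @param stats a `go_term_stats` tibble supplying IC values.
#' @return a `gopred_curves` tibble: `threshold`, `w_precision`,
#'   `w_recall`, `n_targets`.
#' @export
weighted_curves <- function(preds, truth, stats, dag,
                            taus = seq(0.01, 1, by = 0.01),
                            namespace = "BP", include_root = FALSE) {
  assert_namespace(namespace)
  ic <- stats_lookup(stats)
  root <- if (include_root) character(0) else dag$roots[[namespace]]
  truth_sets <- split(truth$term, truth$target)
  truth_sets <- truth_sets[lengths(truth_sets) > 0]
  targets <- names(truth_sets)
  pred_split <- split(preds[, c("term", "score")], preds$target)
  cis <- lapply(targets, function(tg) {
    closure_index(pred_split[[tg]], dag, drop_root = root)
  })
  T_sets <- lapply(targets, function(tg) {
    setdiff(go_propagate(dag, unique(truth_sets[[tg]])), root)
  })
  ic_sum <- function(terms) {
    v <- ic[terms]
    sum(v[!is.na(v)])
  }
  n_dropped <- 0L
  rows <- lapply(taus, function(tau) {
    wp <- wr <- numeric(0)
    for (i in seq_along(targets)) {
      P <- set_at_tau(cis[[i]], tau)
      T <- T_sets[[i]]
      tp <- ic_sum(intersect(P, T))
      d_p <- ic_sum(P)
      d_r <- ic_sum(union(intersect(P, T), setdiff(T, P)))
      if (d_p > 0) wp <- c(wp, tp / d_p)
      if (d_r > 0) wr <- c(wr, tp / d_r)
    }
    tibble(threshold = tau,
           w_precision = if (length(wp)) mean(wp) else NA_real_,
           w_recall = if (length(wr)) mean(wr) else NA_real_,
           n_targets = length(targets))
  })
  out <- bind_rows(rows)
  structure(out, class = c("gopred_curves", class(out)),
            sweep = "threshold", namespace = namespace)
}

# max IC over common ancestors; 0 (no warning) when none has a defined IC
msa_ic_quiet <- function(dag, ic, t1, t2) {
  common <- intersect(c(t1, dag$ancestors[[t1]]), c(t2, dag$ancestors[[t2]]))
  v <- ic[common]
  v <- v[!is.na(v)]
  if (!length(v)) 0 else max(v)
}

#' Semantic similarity, semantic precision and semantic recall
#'
#' Operates on the unpropagated predicted and true term sets. Per target and
#' threshold: similarity is the mean over all (true, predicted) pairs of the
#' maximum shared-ancestor IC; semantic precision is the mean over predicted
#' terms of `IC(pred) - best shared-ancestor IC against any true term`
#' (how much information a prediction overshoots what it shares with the
#' truth); semantic recall is the analogous deficit of the true terms. Both
#' are 0 for identical sets. Targets with no prediction at a threshold are
#' excluded from that threshold's means.
#'
#' @inheritParams weighted_curves
#' @return a `gopred_curves` tibble: `threshold`, `similarity`,
#'   `s_precision`, `s_recall`, `n_targets`.
#' @export
semantic_curves <- function(preds, truth, stats, dag,
                            taus = seq(0.01, 1, by = 0.01),
                            namespace = "BP") {
  assert_namespace(namespace)
  ic <- stats_lookup(stats)
  truth_sets <- split(truth$term, truth$target)
  truth_sets <- lapply(truth_sets[lengths(truth_sets) > 0], unique)
  targets <- names(truth_sets)
  pred_split <- split(preds[, c("term", "score")], preds$target)
  # per target: predicted terms sorted by score desc + pairwise msa matrix
  per_target <- lapply(targets, function(tg) {
    pr <- pred_split[[tg]]
    tt <- truth_sets[[tg]]
    tt <- tt[!is.na(ic[tt])]
    if (is.null(pr) || !nrow(pr) || !length(tt)) return(NULL)
    pr <- pr[order(-pr$score, pr$term), ]
    pr <- pr[!is.na(ic[pr$term]), ]
    if (!nrow(pr)) return(NULL)
    M <- matrix(0, nrow(pr), length(tt),
                dimnames = list(pr$term, tt))
    for (i in seq_len(nrow(pr))) {
      for (j in seq_along(tt)) {
        M[i, j] <- msa_ic_quiet(dag, ic, pr$term[[i]], tt[[j]])
      }
    }
    list(score = pr$score, term = pr$term, truth = tt, M = M)
  })
  keep <- !vapply(per_target, is.null, TRUE)
  per_target <- per_target[keep]
  rows <- lapply(taus, function(tau) {
    sim <- sp <- sr <- numeric(0)
    for (pt in per_target) {
      sel <- pt$score >= tau
      if (!any(sel)) next
      M <- pt$M[sel, , drop = FALSE]
      sim <- c(sim, mean(M))
      sp <- c(sp, mean(ic[pt$term[sel]] - apply(M, 1, max)))
      sr <- c(sr, mean(ic[pt$truth] - apply(M, 2, max)))
    }
    tibble(threshold = tau,
           similarity = if (length(sim)) mean(sim) else NA_real_,
           s_precision = if (length(sp)) mean(sp) else NA_real_,
           s_recall = if (length(sr)) mean(sr) else NA_real_,
           n_targets = length(sim))
  })
  out <- bind_rows(rows)
  structure(out, class = c("gopred_curves", class(out)),
            sweep = "threshold", namespace = namespace)
}

#' Terms annotating at least `min_targets` targets
#'
#' A term is evaluable for the term-centric F1 analysis when the propagated
#' truth of at least `min_targets` targets contains it (i.e. the term or any
#' descendant annotates them).
#'
#' @param truth tibble `target`, `term`.
#' @param dag a [go_dag].
#' @param min_targets minimum number of annotated targets (default 25).
#' @return tibble `term`, `n_targets`, most-annotated first.
#' @export
evaluable_terms <- function(truth, dag, min_targets = 25) {
  stopifnot(min_targets >= 1)
  truth_sets <- split(truth$term, truth$target)
  prop <- lapply(truth_sets, function(ts) go_propagate(dag, unique(ts)))
  counts <- table(unlist(prop, use.names = FALSE))
  out <- tibble(term = names(counts), n_targets = as.integer(counts)) |>
    filter(.data$n_targets >= min_targets) |>
    arrange(desc(.data$n_targets), .data$term)
  out
}

#' Term-centric F1 (maximum harmonic mean over cutoffs)
#'
#' For one GO term, targets whose propagated truth contains the term are the
#' positives. At each cutoff a target counts as predicted-positive when its
#' propagated prediction set contains the term (equivalently: it predicted
#' the term or any descendant at or above the cutoff). The term's F1 is the
#' maximum over cutoffs of the harmonic mean of precision and recall.
#'
#' @param preds tibble `target`, `term`, `score`.
#' @param truth tibble `target`, `term`.
#' @param dag a [go_dag].
#' @param terms term id(s) to evaluate; default: [evaluable_terms()] with
#'   `min_targets`.
#' @param taus cutoffs; default `seq(0.01, 1, by = 0.01)`.
#' @param min_targets used only when `terms` is `NULL`.
#' @return tibble `term`, `n_targets`, `f1`, `threshold` (the maximising
#'   cutoff).
#' @export
per_term_f1 <- function(preds, truth, dag, terms = NULL,
                        taus = seq(0.01, 1, by = 0.01), min_targets = 25) {
  if (is.null(terms)) {
    terms <- evaluable_terms(truth, dag, min_targets)$term
  }
  truth_sets <- split(truth$term, truth$target)
  targets <- names(truth_sets)
  prop_truth <- lapply(truth_sets, function(ts) go_propagate(dag, unique(ts)))
  pred_split <- split(preds[, c("term", "score")], preds$target)
  rows <- lapply(terms, function(tm) {
    desc <- descendants_with_self(dag, tm)
    pos <- vapply(targets, function(tg) tm %in% prop_truth[[tg]], TRUE)
    if (!any(pos)) {
      stop("term ", tm, " annotates no target in the truth set",
           call. = FALSE)
    }
    # best score at which the target's propagated predictions contain `tm`
    m <- vapply(targets, function(tg) {
      pr <- pred_split[[tg]]
      if (is.null(pr) || !nrow(pr)) return(-Inf)
      sc <- pr$score[pr$term %in% desc]
      if (!length(sc)) -Inf else max(sc)
    }, 0)
    best <- 0
    best_tau <- taus[[1]]
    for (tau in taus) {
      tp <- sum(pos & m >= tau)
      fp <- sum(!pos & m >= tau)
      fn <- sum(pos) - tp
      p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      r <- tp / (tp + fn)
      f1 <- f1_of(p, r)
      if (f1 > best) { best <- f1; best_tau <- tau }
    }
    tibble(term = tm, n_targets = sum(pos), f1 = best, threshold = best_tau)
  })
  bind_rows(rows)
}

descendants_with_self <- function(dag, term) {
  check_terms(dag, term)
  acc <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(dag$children[frontier], use.names = FALSE)),
                   acc)
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  acc
}

#' Per-target maximum F1 over cutoffs (Fmax)
#'
#' For each target, sweeps the cutoffs and reports the maximum harmonic mean
#' of precision and recall of the propagated prediction set against the
#' propagated truth (root excluded). A target with an empty prediction set
#' at every cutoff has Fmax 0.
#'
#' @inheritParams threshold_curves
#' @return tibble `target`, `fmax`, `threshold`.
#' @export
target_fmax <- function(preds, truth, dag, taus = seq(0.01, 1, by = 0.01),
                        namespace = "BP", include_root = FALSE) {
  assert_namespace(namespace)
  root <- if (include_root) character(0) else dag$roots[[namespace]]
  n_universe <- length(setdiff(ns_terms(dag, namespace), root))
  truth_sets <- split(truth$term, truth$target)
  truth_sets <- truth_sets[lengths(truth_sets) > 0]
  pred_split <- split(preds[, c("term", "score")], preds$target)
  rows <- lapply(names(truth_sets), function(tg) {
    ci <- closure_index(pred_split[[tg]], dag, drop_root = root)
    T <- setdiff(go_propagate(dag, unique(truth_sets[[tg]])), root)
    best <- 0
    best_tau <- taus[[1]]
    for (tau in taus) {
      cc <- confusion_counts(set_at_tau(ci, tau), T, n_universe)
      f1 <- f1_of(cc$precision, cc$recall)
      if (f1 > best) { best <- f1; best_tau <- tau }
    }
    tibble(target = tg, fmax = best, threshold = best_tau)
  })
  bind_rows(rows)
}

#' Per-target ranking AUC over maximally specific terms
#'
#' A ranking diagnostic used to check that a predictor recovers planted
#' homology signal: for each target, the universe is the set of leaf terms
#' (terms without children) of the namespace, the positives are the target's
#' true terms among them (pre-propagation truth), every leaf missing from
#' the prediction list scores 0, and the AUC is the Mann-Whitney probability
#' that a positive leaf outranks a negative one (ties count 1/2). Leaves are
#' used because ancestor terms are implied by any annotation, so scorers
#' that favour general terms would receive structural credit unrelated to
#' the target.
#'
#' @param preds tibble `target`, `term`, `score`.
#' @param truth tibble `target`, `term` (pre-propagation).
#' @param dag a [go_dag].
#' @param namespace `"BP"` or `"MF"`.
#' @return tibble `target`, `auc`, `n_pos`; targets with no positive or no
#'   negative leaf are skipped.
#' @export
prediction_auc <- function(preds, truth, dag, namespace = "BP") {
  assert_namespace(namespace)
  leaves <- dag$terms$id[dag$terms$namespace == namespace &
                           lengths(dag$children[dag$terms$id]) == 0]
  truth_sets <- split(truth$term, truth$target)
  pred_split <- split(preds[, c("term", "score")], preds$target)
  rows <- lapply(names(truth_sets), function(tg) {
    pos <- intersect(unique(truth_sets[[tg]]), leaves)
    n_pos <- length(pos)
    n_neg <- length(leaves) - n_pos
    if (n_pos == 0 || n_neg == 0) return(NULL)
    sc <- setNames(numeric(length(leaves)), leaves)
    pr <- pred_split[[tg]]
    if (!is.null(pr) && nrow(pr)) {
      pr <- pr |> filter(.data$term %in% leaves)
      sc[pr$term] <- pr$score
    }
    rk <- rank(sc)
    auc <- (sum(rk[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    tibble(target = tg, auc = auc, n_pos = n_pos)
  })
  bind_rows(rows)
}
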