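#' PFP scoring parameters
#'
#' @param b additive constant in the PFP hit weight `(-log10(E) + b)`;
#'   the default 2 equals `log10(e_ceiling)` for the default ceiling of 100,
#'   which keeps the weight non-negative for every retrieved hit.
#' @param e_ceiling E-value ceiling; hits at or above it are ignored.
#' @param e_floor lower clamp applied to E-values before `-log10` so that
#'   E = 0 (reported for perfect hits) stays finite.
#' @return a list of class `pfp_params`.
#' @export
pfp_params <- function(b = 2, e_ceiling = 100, e_floor = 1e-180) {
  stopifnot(e_ceiling > 0, e_floor > 0)
  structure(list(b = b, e_ceiling = e_ceiling, e_floor = e_floor),
            class = "pfp_params")
}

# direct annotation sets per protein for one namespace
annot_sets <- function(db, namespace) {
  d <- db |> filter(.data$namespace == !!namespace)
  split(d$term, d$protein)
}

one_target_hits <- function(hits) {
  if ("query" %in% names(hits) && length(unique(hits$query)) > 1) {
    stop("hits contain more than one query; score one target at a time ",
         "or use predict_targets()", call. = FALSE)
  }
  hits
}

empty_scores <- function() tibble(term = character(0), score = numeric(0))

sort_scores <- function(df) arrange(df, desc(.data$score), .data$term)

#' PFP raw scores (annotation transfer weighted by co-occurrence)
#'
#' For one target, accumulates over every search hit `i` (E-value below the
#' ceiling) and every direct GO annotation `fj` of that hit the contribution
#' `(-log10(E_i) + b) * P(fa | fj)` to each candidate term `fa`, where
#' `P(fa|fj)` is the co-occurrence conditional probability from the
#' annotation database. Because `P(f|f) = 1`, a hit's own annotations
#' contribute their full weight; co-occurring terms that annotate no hit can
#' still be scored, which is how PFP predicts beyond the literal hit
#' annotations.
#'
#' @param hits hit tibble for one target (columns `subject`, `evalue`; a
#'   `query` column, if present, must be constant).
#' @param db an [annotation_db].
#' @param params a [pfp_params()] list.
#' @param namespace `"BP"` or `"MF"`.
#' @return tibble with columns `term`, `score` (raw, >= 0), highest first.
#' @export
pfp_raw_scores <- function(hits, db, params = pfp_params(), namespace = "BP") {
  assert_namespace(namespace)
  hits <- one_target_hits(hits)
  hits <- hits |> filter(.data$evalue < params$e_ceiling)
  if (!nrow(hits)) return(empty_scores())
  cm <- cooccurrence_matrix(db, namespace)
  if (is.null(cm$P)) return(empty_scores())
  ann <- annot_sets(db, namespace)
  w <- -log10(pmax(hits$evalue, params$e_floor)) + params$b
  v <- setNames(numeric(length(cm$terms)), cm$terms)
  for (i in seq_len(nrow(hits))) {
    fj <- ann[[hits$subject[[i]]]]
    if (length(fj)) v[fj] <- v[fj] + w[[i]]
  }
  s <- as.numeric(cm$P %*% v)
  names(s) <- cm$terms
  s <- s[s > 0]
  sort_scores(tibble(term = names(s), score = unname(s)))
}

#' Transfer PFP raw scores to parental terms
#'
#' Each directly scored term `fa` passes to every proper ancestor `fp` the
#' amount `s(fa) * freq(fa) / freq(fp)` -- the proportion of annotation mass
#' of the ancestor attributable to `fa`. The final raw score of a term is
#' its direct score plus everything it receives; ancestors absent from the
#' input appear in the output.
#'
#' @param raw tibble `term`, `score` from [pfp_raw_scores()].
#' @param dag a [go_dag].
#' @param stats a `go_term_stats` tibble covering the scored terms; a term
#'   missing from it (or with zero frequency) transfers nothing, with a log
#'   message.
#' @return tibble `term`, `score`, highest first.
#' @export
pfp_parent_transfer <- function(raw, dag, stats) {
  if (!nrow(raw)) return(empty_scores())
  check_terms(dag, raw$term)
  freq <- stats_lookup(stats, "freq")
  out <- setNames(raw$score, raw$term)
  n_skip <- 0L
  for (i in seq_len(nrow(raw))) {
    fa <- raw$term[[i]]
    ffa <- freq[fa]
    if (is.na(ffa) || ffa == 0) { n_skip <- n_skip + 1L; next }
    for (fp in dag$ancestors[[fa]]) {
      ffp <- freq[fp]
      if (is.na(ffp) || ffp == 0) { n_skip <- n_skip + 1L; next }
      add <- raw$score[[i]] * unname(ffa) / unname(ffp)
      out[fp] <- (if (fp %in% names(out)) out[[fp]] else 0) + add
    }
  }
  if (n_skip > 0) {
    gp_log("parent transfer skipped ", n_skip,
           " term(s) without usable frequency")
  }
  sort_scores(tibble(term = names(out), score = unname(out)))
}

# Empirical p-value P[X >= x] against a background sample, with a 1/(n+1)
# floor when the observed score exceeds every background value.
empirical_p <- function(background, x) {
  n <- length(background)
  cnt <- sum(background >= x)
  if (cnt > 0) cnt / n else 1 / (n + 1)
}

# weighted pool-adjacent-violators, enforcing non-increasing values
pava_decreasing <- function(v, w) {
  ok <- !is.na(v)
  if (!any(ok)) return(v)
  vv <- v[ok]; ww <- w[ok]
  blocks <- lapply(seq_along(vv), function(i) list(v = vv[[i]], w = ww[[i]]))
  i <- 1
  while (i < length(blocks)) {
    if (blocks[[i]]$v < blocks[[i + 1]]$v - 1e-12) {
      wsum <- blocks[[i]]$w + blocks[[i + 1]]$w
      merged <- list(v = (blocks[[i]]$v * blocks[[i]]$w +
                          blocks[[i + 1]]$v * blocks[[i + 1]]$w) / wsum,
                     w = wsum, span = c(blocks[[i]]$span %||% i,
                                        blocks[[i + 1]]$span %||% (i + 1)))
      blocks <- append(blocks[-c(i, i + 1)], list(merged), after = i - 1)
      i <- max(1, i - 1)
    } else i <- i + 1
  }
  fit <- numeric(length(vv))
  pos <- 1
  for (b in blocks) {
    span <- length(b$span %||% 1)
    fit[pos:(pos + span - 1)] <- b$v
    pos <- pos + span
  }
  res <- v
  res[ok] <- fit
  # carry pooled values across empty bins
  for (i in seq_along(res)) {
    if (is.na(res[[i]])) res[[i]] <- if (i > 1) res[[i - 1]] else max(fit)
  }
  res
}

#' Build a PFP confidence calibration table
#'
#' From benchmark predictions with known truth, stores per-term background
#' raw-score samples (for empirical p-values) and, per p-value bin, the
#' fraction of benchmark predictions whose term lies within edge distance
#' k of a true term, for k in 0, 2, 4.
#'
#' @param bench_preds benchmark raw predictions: tibble `target`, `term`,
#'   `score`.
#' @param truth benchmark truth: tibble `target`, `term`.
#' @param dag a [go_dag].
#' @param bins number of equal-width p-value bins on \[0, 1\] (default 10),
#'   or a numeric vector of strictly increasing bin edges.
#' @param min_background a term with fewer than this many background samples
#'   falls back to the global pooled background (default 5, logged).
#' @return an object of class `pfp_calibration`.
#' @export
build_calibration <- function(bench_preds, truth, dag, bins = 10,
                              min_background = 5) {
  stopifnot(nrow(bench_preds) > 0, nrow(truth) > 0)
  check_terms(dag, unique(c(bench_preds$term, truth$term)))
  edges <- if (length(bins) == 1) seq(0, 1, length.out = bins + 1) else bins
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing",
                                  call. = FALSE)
  truth_sets <- split(truth$term, truth$target)
  dmax <- 4L
  dist_k <- vapply(seq_len(nrow(bench_preds)), function(i) {
    ts <- truth_sets[[bench_preds$target[[i]]]]
    if (is.null(ts)) return(Inf)
    dist_to_set(dag, bench_preds$term[[i]], ts, max_d = dmax)
  }, 0)
  background <- split(bench_preds$score, bench_preds$term)
  pooled <- bench_preds$score
  n_fallback <- 0L
  p <- vapply(seq_len(nrow(bench_preds)), function(i) {
    bg <- background[[bench_preds$term[[i]]]]
    if (length(bg) < min_background) {
      n_fallback <<- n_fallback + 1L
      bg <- pooled
    }
    empirical_p(bg, bench_preds$score[[i]])
  }, 0)
  if (n_fallback > 0) {
    gp_log(n_fallback, " benchmark prediction(s) used the pooled background")
  }
  bin <- bin_index(p, edges)
  tab <- tibble(bin = seq_len(length(edges) - 1),
                lo = edges[-length(edges)], hi = edges[-1])
  frac_at <- function(kk) {
    vapply(tab$bin, function(b) {
      sel <- bin == b
      if (!any(sel)) NA_real_ else mean(dist_k[sel] <= kk)
    }, 0)
  }
  tab$n <- vapply(tab$bin, function(b) sum(bin == b), 0)
  for (kk in c(0, 2, 4)) tab[[paste0("frac_k", kk)]] <- frac_at(kk)
  for (kk in c(0, 2, 4)) {
    tab[[paste0("conf_k", kk)]] <-
      pava_decreasing(tab[[paste0("frac_k", kk)]], tab$n)
  }
  structure(list(background = background, pooled = pooled, edges = edges,
                 table = tab, min_background = min_background),
            class = "pfp_calibration")
}

bin_index <- function(p, edges) {
  idx <- findInterval(p, edges, left.open = TRUE)  # p in (lo, hi]
  pmin(pmax(idx, 1L), length(edges) - 1L)          # p = 0 -> first bin
}

#' @export
print.pfp_calibration <- function(x, ...) {
  cat("<pfp_calibration> ", length(x$background), " term backgrounds, ",
      length(x$pooled), " pooled samples, ",
      nrow(x$table), " p-value bins\n", sep = "")
  invisible(x)
}

#' PFP confidence scores from calibrated p-values
#'
#' Maps each raw score to its term-specific empirical p-value (pooled
#' background for sparsely sampled terms) and looks up the calibrated
#' fraction-correct of that p-value's bin. The bin fractions are isotonically
#' pooled at calibration time, so confidence is non-increasing in the
#' p-value. The ranking confidence uses exact-term correctness (k = 0) by
#' default; the k = 2 and k = 4 fractions are returned as columns.
#'
#' @param raw tibble `term`, `score` of raw scores (after parent transfer).
#' @param calibration a `pfp_calibration` from [build_calibration()].
#' @param k edge distance whose calibrated fraction becomes the ranking
#'   score: 0 (default), 2 or 4.
#' @return tibble `term`, `raw`, `p_value`, `conf_k0`, `conf_k2`, `conf_k4`,
#'   `score`, highest score first.
#' @export
pfp_confidence <- function(raw, calibration, k = 0) {
  if (missing(calibration) || is.null(calibration) ||
      !inherits(calibration, "pfp_calibration")) {
    stop("no calibration table available; build one with ",
         "build_calibration() or rank predictions by the raw score",
         call. = FALSE)
  }
  if (!k %in% c(0, 2, 4)) stop("k must be 0, 2 or 4", call. = FALSE)
  if (!nrow(raw)) {
    return(tibble(term = character(0), raw = numeric(0), p_value = numeric(0),
                  conf_k0 = numeric(0), conf_k2 = numeric(0),
                  conf_k4 = numeric(0), score = numeric(0)))
  }
  p <- vapply(seq_len(nrow(raw)), function(i) {
    bg <- calibration$background[[raw$term[[i]]]]
    if (is.null(bg) || length(bg) < calibration$min_background) {
      bg <- calibration$pooled
    }
    empirical_p(bg, raw$score[[i]])
  }, 0)
  bin <- bin_index(p, calibration$edges)
  out <- tibble(term = raw$term, raw = raw$score, p_value = p,
                conf_k0 = calibration$table$conf_k0[bin],
                conf_k2 = calibration$table$conf_k2[bin],
                conf_k4 = calibration$table$conf_k4[bin])
  out$score <- out[[paste0("conf_k", k)]]
  sort_scores(out)
}

#' ESG scores from a two-level hit graph
#'
#' Each level-1 hit distributes its normalised weight to the GO terms
#' annotating it; a hit that seeded a level-2 search splits its weight
#' between its own annotations (fraction `a`) and its level-2 hits'
#' annotations (fraction `1 - a`, spread by the level-2 weights). A hit
#' without a level-2 search gives its full weight to its own annotations, so
#' one-level ESG is well defined. Scores lie in \[0, 1\].
#'
#' @param graph a [build_hit_graph()] result.
#' @param db an [annotation_db].
#' @param a level mixing weight in \[0, 1\] (default 0.5).
#' @param namespace `"BP"` or `"MF"`.
#' @return tibble `term`, `score`, highest first.
#' @export
esg_scores <- function(graph, db, a = 0.5, namespace = "BP") {
  stopifnot(a >= 0, a <= 1)
  assert_namespace(namespace)
  ann <- annot_sets(db, namespace)
  s <- new.env(parent = emptyenv())
  bump <- function(terms, by) {
    for (f in terms) assign(f, (get0(f, s) %||% 0) + by, envir = s)
  }
  l1 <- graph$level1
  for (i in seq_len(nrow(l1))) {
    wi <- l1$weight[[i]]
    if (wi <= 0) next
    subj <- l1$subject[[i]]
    l2 <- graph$level2[[subj]]
    if (!is.null(l2) && sum(l2$weight) > 0) {
      bump(ann[[subj]], wi * a)
      for (j in seq_len(nrow(l2))) {
        if (l2$weight[[j]] <= 0) next
        bump(ann[[l2$subject[[j]]]], wi * (1 - a) * l2$weight[[j]])
      }
    } else {
      bump(ann[[subj]], wi)
    }
  }
  terms <- ls(s)
  if (!length(terms)) return(empty_scores())
  sort_scores(tibble(term = terms,
                     score = unname(vapply(terms, get, 0, envir = s))))
}

#' GOtcha I-scores
#'
#' Every hit contributes `max(0, -log10(E))` to each GO term annotating it
#' and to all ancestors of those terms; the per-term sums are normalised by
#' the root's sum, giving the I-score in \[0, 1\] with I(root) = 1.
#' Hits with E-value >= 1 carry no mass (the clamp keeps I-scores
#' non-negative).
#'
#' @param hits hit tibble for one target (`subject`, `evalue`).
#' @param db an [annotation_db].
#' @param dag a [go_dag].
#' @param namespace `"BP"` or `"MF"`.
#' @param e_floor lower E-value clamp before `-log10`.
#' @return tibble `term`, `score`; empty when no hit carries positive mass.
#' @export
gotcha_scores <- function(hits, db, dag, namespace = "BP", e_floor = 1e-180) {
  assert_namespace(namespace)
  hits <- one_target_hits(hits)
  ann <- annot_sets(db, namespace)
  r <- new.env(parent = emptyenv())
  mass <- pmax(0, -log10(pmax(hits$evalue, e_floor)))
  for (i in seq_len(nrow(hits))) {
    if (mass[[i]] <= 0) next
    terms <- ann[[hits$subject[[i]]]]
    if (is.null(terms) || !length(terms)) next
    for (f in go_propagate(dag, terms)) {
      assign(f, (get0(f, r) %||% 0) + mass[[i]], envir = r)
    }
  }
  root <- dag$roots[[namespace]]
  rroot <- get0(root, r) %||% 0
  if (rroot <= 0) return(empty_scores())
  terms <- ls(r)
  sort_scores(tibble(term = terms,
                     score = unname(vapply(terms, get, 0, envir = r)) / rroot))
}

#' BLAST baseline scores
#'
#' A term's score is the maximum percent sequence identity (divided by 100)
#' over the hits directly annotated with it; only direct, evidence-filtered
#' annotations are used, so a target whose hits carry no usable annotation
#' gets an empty prediction set.
#'
#' @param hits hit tibble for one target (`subject`, `pident`).
#' @param db an [annotation_db].
#' @param namespace `"BP"` or `"MF"`.
#' @return tibble `term`, `score` in \[0, 1\].
#' @export
blast_baseline <- function(hits, db, namespace = "BP") {
  assert_namespace(namespace)
  hits <- one_target_hits(hits)
  ann <- annot_sets(db, namespace)
  s <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(hits))) {
    val <- hits$pident[[i]] / 100
    for (f in ann[[hits$subject[[i]]]]) {
      assign(f, max(get0(f, s) %||% 0, val), envir = s)
    }
  }
  terms <- ls(s)
  if (!length(terms)) return(empty_scores())
  sort_scores(tibble(term = terms,
                     score = unname(vapply(terms, get, 0, envir = s))))
}

#' Prior predictions from database term frequencies
#'
#' Target-independent baseline: every term of the namespace is scored
#' `(freq(c) + 1) / (freq(root) + 1)` (a pseudo count of 1) and the `n_max`
#' highest-frequency terms form the prediction list assigned to every
#' target.
#'
#' @param stats a `go_term_stats` tibble from [compute_term_stats()].
#' @param n_max number of terms kept (default 1000).
#' @param namespace `"BP"` or `"MF"`.
#' @return tibble `term`, `score`, highest first.
#' @export
prior_predictions <- function(stats, n_max = 1000, namespace = "BP") {
  assert_namespace(namespace)
  st <- stats |> filter(.data$namespace == !!namespace)
  if (!nrow(st)) stop("no stats for namespace ", namespace, call. = FALSE)
  root_freq <- max(st$freq)
  st |>
    mutate(score = (.data$freq + 1) / (root_freq + 1)) |>
    select("term", "score") |>
    sort_scores() |>
    slice_head(n = n_max) |>
    as_tibble()
}

#' Enrich a method's predictions with Prior terms
#'
#' Terms present in the Prior list but absent from a target's predictions
#' are imported. For PFP (whose scores are on the expected-accuracy scale),
#' imported frequency scores are linearly rescaled from the Prior list's
#' \[min, max\] onto the target's own score \[min, max\]; for ESG (already
#' on \[0, 1\], like the Prior frequencies) they are kept as-is. The merged
#' list is re-sorted and truncated to `n_max` terms per target. A target
#' with no predictions receives the Prior list unrescaled (logged).
#'
#' @param preds tibble `target`, `term`, `score` (scores in \[0, 1\]).
#' @param prior tibble `term`, `score` from [prior_predictions()].
#' @param mode `"pfp"` (rescale imports) or `"esg"` (keep imports as-is).
#' @param n_max truncation limit after merging (default 1000).
#' @return tibble `target`, `term`, `score`.
#' @export
enrich_with_prior <- function(preds, prior, mode = c("pfp", "esg"),
                              n_max = 1000) {
  mode <- match.arg(mode)
  targets <- unique(preds$target)
  out <- lapply(targets, function(tg) {
    cur <- preds |> filter(.data$target == tg)
    imp <- prior |> filter(!.data$term %in% cur$term)
    if (nrow(imp)) {
      if (mode == "pfp") {
        if (!nrow(cur)) {
          gp_log("target ", tg, " has no predictions; Prior used unrescaled")
        } else {
          pr_rng <- range(prior$score)
          pd_rng <- range(cur$score)
          imp$score <- if (diff(pr_rng) > 0) {
            pd_rng[1] + (imp$score - pr_rng[1]) / diff(pr_rng) * diff(pd_rng)
          } else {
            gp_log("degenerate Prior score range; imports mapped to the ",
                   "target's minimum score")
            rep(pd_rng[1], nrow(imp))
          }
        }
      }
      imp <- mutate(imp, target = tg)
    }
    bind_rows(cur, imp) |> select("target", "term", "score")
  })
  truncate_predictions(bind_rows(out), k = n_max)
}

#' Truncate prediction lists
#'
#' Keeps the `k` highest-scoring terms per target; ties at the boundary are
#' broken by lexicographic term id, so truncation is deterministic.
#'
#' @param preds tibble with columns `term`, `score` and optionally `target`.
#' @param k maximum list length per target (default 1000).
#' @return the truncated tibble, sorted by score (descending) then term.
#' @export
truncate_predictions <- function(preds, k = 1000) {
  stopifnot(k >= 1)
  if ("target" %in% names(preds)) {
    preds |>
      group_by(.data$target) |>
      arrange(desc(.data$score), .data$term, .by_group = TRUE) |>
      slice_head(n = k) |>
      ungroup() |>
      as_tibble()
  } else {
    sort_scores(preds) |> slice_head(n = k) |> as_tibble()
  }
}

#' Run a prediction method over every target in a hit table
#'
#' Convenience wrapper looping the per-target scorers over the queries of a
#' parsed hit table and returning one tidy prediction set.
#'
#' @param hits parsed level-1 hits (tibble with `query`, `subject`,
#'   `pident`, `evalue`).
#' @param db an [annotation_db].
#' @param dag a [go_dag] (needed by gotcha / pfp variants).
#' @param stats a `go_term_stats` (needed by pfp variants and prior).
#' @param method one of `"pfp"`, `"pfp-raw"`, `"esg"`, `"gotcha"`,
#'   `"blast"`, `"prior"`, `"pfp+prior"`, `"esg+prior"`.
#' @param level2 optional level-2 hit table for ESG (queries are level-1
#'   subjects).
#' @param params a [pfp_params()] list.
#' @param esg_a ESG level mixing weight.
#' @param calibration optional `pfp_calibration`; when absent, `"pfp"`
#'   falls back to per-target max-normalised raw scores (logged).
#' @param namespace `"BP"` or `"MF"`.
#' @param n_max per-target truncation limit.
#' @return tibble `target`, `term`, `score`, with a `method` attribute.
#' @export
predict_targets <- function(hits, db, dag = NULL, stats = NULL,
                            method = c("pfp", "pfp-raw", "esg", "gotcha",
                                       "blast", "prior", "pfp+prior",
                                       "esg+prior"),
                            level2 = NULL, params = pfp_params(),
                            esg_a = 0.5, calibration = NULL,
                            namespace = "BP", n_max = 1000) {
  method <- match.arg(method)
  targets <- unique(hits$query)
  need_stats <- method %in% c("pfp", "pfp-raw", "prior", "pfp+prior",
                              "esg+prior")
  if (need_stats && is.null(stats)) {
    stop("method ", method, " requires `stats`", call. = FALSE)
  }
  if (method %in% c("pfp", "pfp-raw", "gotcha", "pfp+prior") && is.null(dag)) {
    stop("method ", method, " requires `dag`", call. = FALSE)
  }
  pfp_for <- function(tg) {
    raw <- pfp_raw_scores(hits |> filter(.data$query == tg), db,
                          params, namespace)
    pfp_parent_transfer(raw, dag, stats)
  }
  score_one <- function(tg) {
    switch(method,
      "pfp-raw" = pfp_for(tg),
      "pfp" = , "pfp+prior" = {
        tr <- pfp_for(tg)
        if (!is.null(calibration)) {
          pfp_confidence(tr, calibration)[, c("term", "score")]
        } else if (nrow(tr)) {
          mutate(tr, score = .data$score / max(.data$score))
        } else tr
      },
      "esg" = , "esg+prior" = {
        g <- build_hit_graph(tg, hits |> filter(.data$query == tg),
                             level2 = level2, e_ceiling = params$e_ceiling,
                             e_floor = params$e_floor)
        esg_scores(g, db, a = esg_a, namespace = namespace)
      },
      "gotcha" = gotcha_scores(hits |> filter(.data$query == tg), db, dag,
                               namespace = namespace,
                               e_floor = params$e_floor),
      "blast" = blast_baseline(hits |> filter(.data$query == tg), db,
                               namespace = namespace),
      "prior" = prior_predictions(stats, n_max = n_max,
                                  namespace = namespace))
  }
  if (method %in% c("pfp", "pfp+prior") && is.null(calibration)) {
    gp_log("no calibration supplied; PFP scores are max-normalised raw scores")
  }
  res <- bind_rows(lapply(targets, function(tg) {
    sc <- score_one(tg)
    if (nrow(sc)) mutate(sc, target = tg, .before = 1) else NULL
  }))
  if (!nrow(res)) {
    res <- tibble(target = character(0), term = character(0),
                  score = numeric(0))
  }
  if (method %in% c("pfp+prior", "esg+prior")) {
    prior <- prior_predictions(stats, n_max = n_max, namespace = namespace)
    res <- enrich_with_prior(res, prior,
                             mode = if (method == "pfp+prior") "pfp" else "esg",
                             n_max = n_max)
    # enrichment may add targets' missing lists only for targets present in
    # res; targets with empty original predictions still get the prior list
    missing <- setdiff(targets, unique(res$target))
    if (length(missing)) {
      res <- bind_rows(res, bind_rows(lapply(missing, function(tg) {
        mutate(prior, target = tg, .before = 1)
      })))
    }
  }
  res <- truncate_predictions(res, k = n_max)
  attr(res, "method") <- method
  res
}
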