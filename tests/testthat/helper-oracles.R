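# Independent brute-force oracles. These deliberately avoid the package's
# precomputed closures and vectorised paths: ancestors by repeated parent
# expansion, frequencies by directed-path counting, distances by
# Floyd-Warshall, scores by literal nested loops.

oracle_ancestors <- function(dag, term) {
  acc <- character(0)
  frontier <- term
  repeat {
    ps <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    new <- setdiff(ps, acc)
    if (!length(new)) return(acc)
    acc <- c(acc, new)
    frontier <- new
  }
}

oracle_propagate <- function(dag, terms) {
  out <- character(0)
  for (t in terms) out <- union(out, c(t, oracle_ancestors(dag, t)))
  out
}

# number of distinct directed is_a paths from `from` up to `to`
oracle_npaths <- function(dag, from, to) {
  if (from == to) return(1L)
  sum(vapply(dag$parents[[from]], function(p) oracle_npaths(dag, p, to), 0L))
}

# literal child-sum recursion expands to sum over descendants of
# annot * (number of upward paths)
oracle_freq <- function(dag, annot_counts) {
  ids <- dag$terms$id
  annot <- setNames(numeric(length(ids)), ids)
  annot[names(annot_counts)] <- annot_counts
  vapply(setNames(ids, ids), function(c) {
    sum(vapply(ids, function(d) annot[[d]] * oracle_npaths(dag, d, c), 0))
  }, 0)
}

oracle_edge_distance_matrix <- function(dag) {
  ids <- dag$terms$id
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (child in ids) {
    for (p in dag$parents[[child]]) {
      D[child, p] <- 1
      D[p, child] <- 1
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_cooccur <- function(db, fa, fj, ns = "BP") {
  sets <- list()
  d <- db[db$namespace == ns, ]
  for (i in seq_len(nrow(d))) {
    sets[[d$protein[[i]]]] <- union(sets[[d$protein[[i]]]] %||% character(0),
                                    d$term[[i]])
  }
  n_fj <- 0; n_both <- 0
  for (p in names(sets)) {
    if (fj %in% sets[[p]]) {
      n_fj <- n_fj + 1
      if (fa %in% sets[[p]]) n_both <- n_both + 1
    }
  }
  if (n_fj == 0) 0 else n_both / n_fj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_annots <- function(db, protein, ns = "BP") {
  unique(db$term[db$protein == protein & db$namespace == ns])
}

oracle_pfp_raw <- function(hits, db, b = 2, e_ceiling = 100,
                           e_floor = 1e-180, ns = "BP") {
  candidates <- sort(unique(db$term[db$namespace == ns]))
  s <- setNames(numeric(length(candidates)), candidates)
  for (fa in candidates) {
    for (i in seq_len(nrow(hits))) {
      if (hits$evalue[[i]] >= e_ceiling) next
      w <- -log10(max(hits$evalue[[i]], e_floor)) + b
      for (fj in oracle_annots(db, hits$subject[[i]], ns)) {
        s[[fa]] <- s[[fa]] + w * oracle_cooccur(db, fa, fj, ns)
      }
    }
  }
  s[s > 0]
}

oracle_pfp_transfer <- function(raw_scores, dag, freq) {
  out <- raw_scores
  for (fa in names(raw_scores)) {
    if (is.na(freq[[fa]]) || freq[[fa]] == 0) next
    for (fp in oracle_ancestors(dag, fa)) {
      if (is.na(freq[[fp]]) || freq[[fp]] == 0) next
      add <- raw_scores[[fa]] * freq[[fa]] / freq[[fp]]
      out[[fp]] <- (if (fp %in% names(out)) out[[fp]] else 0) + add
    }
  }
  out
}

oracle_search_weights <- function(ev, e_ceiling = 100, e_floor = 1e-180) {
  keep <- ev < e_ceiling
  m <- -log10(pmax(ev[keep], e_floor))
  m[m < 0] <- 0
  w <- if (sum(m) > 0) m / sum(m) else rep(0, length(m))
  list(keep = which(keep), w = w)
}

# naive two-level enumerator over every annotated term
oracle_esg <- function(target, l1, l2_tbl, db, a = 0.5, e_ceiling = 100,
                       e_floor = 1e-180, ns = "BP") {
  terms <- sort(unique(db$term[db$namespace == ns]))
  s <- setNames(numeric(length(terms)), terms)
  sw1 <- oracle_search_weights(l1$evalue, e_ceiling, e_floor)
  for (k in seq_along(sw1$keep)) {
    i <- sw1$keep[[k]]
    wi <- sw1$w[[k]]
    if (wi <= 0) next
    subj <- l1$subject[[i]]
    l2 <- if (!is.null(l2_tbl)) l2_tbl[l2_tbl$query == subj, ] else NULL
    has_l2 <- FALSE
    if (!is.null(l2) && nrow(l2)) {
      sw2 <- oracle_search_weights(l2$evalue, e_ceiling, e_floor)
      has_l2 <- length(sw2$keep) > 0 && sum(sw2$w) > 0
    }
    for (f in terms) {
      if (has_l2) {
        contrib <- a * (f %in% oracle_annots(db, subj, ns))
        for (k2 in seq_along(sw2$keep)) {
          j <- sw2$keep[[k2]]
          contrib <- contrib + (1 - a) * sw2$w[[k2]] *
            (f %in% oracle_annots(db, l2$subject[[j]], ns))
        }
      } else {
        contrib <- as.numeric(f %in% oracle_annots(db, subj, ns))
      }
      s[[f]] <- s[[f]] + wi * contrib
    }
  }
  s[s > 0]
}

oracle_gotcha <- function(hits, db, dag, ns = "BP", e_floor = 1e-180) {
  ids <- dag$terms$id
  r <- setNames(numeric(length(ids)), ids)
  for (i in seq_len(nrow(hits))) {
    m <- max(0, -log10(max(hits$evalue[[i]], e_floor)))
    if (m <= 0) next
    ann <- oracle_annots(db, hits$subject[[i]], ns)
    if (!length(ann)) next
    for (f in oracle_propagate(dag, ann)) r[[f]] <- r[[f]] + m
  }
  root <- dag$roots[[ns]]
  if (r[[root]] <= 0) return(numeric(0))
  out <- r[r > 0] / r[[root]]
  out
}

oracle_blast <- function(hits, db, ns = "BP") {
  s <- numeric(0)
  for (i in seq_len(nrow(hits))) {
    for (f in oracle_annots(db, hits$subject[[i]], ns)) {
      cur <- if (f %in% names(s)) s[[f]] else 0
      s[f] <- max(cur, hits$pident[[i]] / 100)
    }
  }
  if (!length(s)) return(numeric(0))
  s[sort(names(s))]
}

oracle_prior <- function(dag, freq, ns = "BP", n_max = 1000) {
  ids <- dag$terms$id[dag$terms$namespace == ns]
  root <- dag$roots[[ns]]
  sc <- (freq[ids] + 1) / (freq[[root]] + 1)
  sc <- sc[order(-sc, names(sc))]
  head(sc, n_max)
}

# explicit set-enumeration confusion counts
oracle_confusion <- function(pred, truth_terms, dag, tau, ns = "BP") {
  root <- dag$roots[[ns]]
  universe <- setdiff(dag$terms$id[dag$terms$namespace == ns], root)
  P <- setdiff(oracle_propagate(dag, pred$term[pred$score >= tau]), root)
  T <- setdiff(oracle_propagate(dag, unique(truth_terms)), root)
  tp <- fp <- fn <- tn <- 0
  for (u in universe) {
    inP <- u %in% P; inT <- u %in% T
    if (inP && inT) tp <- tp + 1
    else if (inP) fp <- fp + 1
    else if (inT) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_msa_ic <- function(dag, ic, t1, t2) {
  common <- intersect(c(t1, oracle_ancestors(dag, t1)),
                      c(t2, oracle_ancestors(dag, t2)))
  v <- ic[common]
  v <- v[!is.na(v)]
  if (!length(v)) 0 else max(v)
}

oracle_semantic <- function(pred_terms, truth_terms, dag, ic) {
  pred_terms <- pred_terms[!is.na(ic[pred_terms])]
  truth_terms <- truth_terms[!is.na(ic[truth_terms])]
  M <- outer(pred_terms, truth_terms,
             Vectorize(function(p, t) oracle_msa_ic(dag, ic, p, t)))
  list(similarity = mean(M),
       s_precision = mean(ic[pred_terms] - apply(M, 1, max)),
       s_recall = mean(ic[truth_terms] - apply(M, 2, max)))
}
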