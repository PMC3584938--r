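#' Gene Ontology DAG over is_a edges
#'
#' A `go_dag` holds the non-obsolete terms of one or more GO namespaces
#' (Biological Process `"BP"`, Molecular Function `"MF"`) together with the
#' `is_a` parent edges between them. Annotation with a term implies annotation
#' with every ancestor, so most operations in the package work on the
#' ancestral closure this object provides. Only `is_a` edges are represented;
#' `relationship:` lines (e.g. part_of) are ignored at parse time.
#'
#' @section Structure:
#' A list of class `go_dag` with elements
#' \describe{
#'   \item{terms}{tibble with columns `id`, `name`, `namespace`}
#'   \item{parents}{named list, term id to character vector of parent ids}
#'   \item{children}{named list, inverse of `parents`}
#'   \item{roots}{named character vector, one root id per namespace}
#'   \item{ancestors}{named list, term id to its proper ancestor ids
#'     (transitive closure, excluding the term itself)}
#' }
#' @name go_dag
NULL

long_ns <- c(BP = "biological_process", MF = "molecular_function",
             CC = "cellular_component")
short_ns <- setNames(names(long_ns), long_ns)

new_go_dag <- function(terms, parents) {
  ids <- terms$id
  parents <- parents[ids]
  names(parents) <- ids

  # cycle check + topological order (parents before children)
  n_par <- lengths(parents)
  children <- vector("list", length(ids))
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  topo <- character(0)
  queue <- ids[n_par == 0]
  remaining <- setNames(n_par, ids)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(ids)) {
    bad <- setdiff(ids, topo)[[1]]
    stop("cycle detected in is_a graph involving term ", bad, call. = FALSE)
  }

  # roots: one parentless term per namespace; disambiguate by namespace name
  roots <- character(0)
  for (ns in unique(terms$namespace)) {
    cand <- ids[n_par == 0 & terms$namespace == ns]
    if (length(cand) == 0) {
      stop("namespace ", ns, " has no parentless root term", call. = FALSE)
    }
    if (length(cand) > 1) {
      named <- cand[terms$name[match(cand, ids)] == long_ns[[ns]]]
      if (length(named) != 1) {
        stop("namespace ", ns, " has ", length(cand),
             " parentless terms and none (or several) named '",
             long_ns[[ns]], "'", call. = FALSE)
      }
      cand <- named
    }
    roots[[ns]] <- cand
  }
  # every term must reach its namespace root
  anc <- vector("list", length(ids))
  names(anc) <- ids
  for (id in topo) {
    ps <- parents[[id]]
    anc[[id]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  ns_of <- setNames(terms$namespace, ids)
  for (id in ids) {
    r <- roots[[ns_of[[id]]]]
    if (id != r && !r %in% anc[[id]]) {
      stop("term ", id, " does not reach its namespace root ", r,
           call. = FALSE)
    }
  }

  structure(list(terms = terms, parents = parents, children = children,
                 roots = roots, ancestors = anc, topo = topo),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag> ", nrow(x$terms), " terms, ",
      sum(lengths(x$parents)), " is_a edges\n", sep = "")
  for (ns in names(x$roots)) {
    cat("  ", ns, ": root ", x$roots[[ns]], " (",
        sum(x$terms$namespace == ns), " terms)\n", sep = "")
  }
  invisible(x)
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (tags: `id`, `name`, `namespace`, `is_a`,
#' `is_obsolete`) and builds the is_a DAG for the requested namespaces.
#' Obsolete terms, terms of other namespaces, and is_a edges that cross
#' namespaces are dropped (counts are reported via `message()`); any other
#' tag, including `relationship: part_of`, is ignored. An `is_a` reference to
#' an id that never appears in the file is an error, as is any cycle.
#'
#' @param x path to an OBO file, or a character vector of OBO text lines.
#' @param namespaces namespaces to keep, a subset of `c("BP","MF","CC")`.
#' @return a [go_dag].
#' @examples
#' obo <- c("[Term]", "id: GO:1", "name: biological_process",
#'          "namespace: biological_process",
#'          "[Term]", "id: GO:2", "name: child",
#'          "namespace: biological_process", "is_a: GO:1 ! root")
#' dag <- parse_obo(obo)
#' @export
parse_obo <- function(x, namespaces = c("BP", "MF")) {
  lines <- as_lines(x)
  stanza_starts <- which(trimws(lines) == "[Term]")
  recs <- list()
  other_stanza <- which(grepl("^\\[", trimws(lines)) & trimws(lines) != "[Term]")
  bounds <- sort(c(stanza_starts, other_stanza, length(lines) + 1L))
  n_partof <- 0L
  for (s in stanza_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):e]
    tag <- sub("^([^:]+):.*$", "\\1", block)
    val <- trimws(sub("^[^:]+:", "", block))
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    get1 <- function(t) { i <- which(tag == t); if (length(i)) val[[i[1]]] else NA_character_ }
    n_partof <- n_partof + sum(tag == "relationship" & grepl("part_of", val))
    recs[[length(recs) + 1L]] <- list(
      id = get1("id"), name = get1("name"),
      namespace = get1("namespace"),
      is_a = val[tag == "is_a"],
      obsolete = identical(get1("is_obsolete"), "true"))
  }
  if (!length(recs)) stop("no [Term] stanzas found", call. = FALSE)
  if (n_partof > 0) {
    gp_log("ignoring ", n_partof, " part_of relationship line(s); ",
           "only is_a edges are used")
  }
  ids_all <- vapply(recs, `[[`, "", "id")
  ns_all <- short_ns[vapply(recs, `[[`, "", "namespace")]
  obs <- vapply(recs, `[[`, TRUE, "obsolete")
  keep <- !obs & !is.na(ns_all) & ns_all %in% namespaces
  n_drop_obs <- sum(obs)
  n_drop_ns <- sum(!keep & !obs)
  if (n_drop_obs + n_drop_ns > 0) {
    gp_log("dropped ", n_drop_obs, " obsolete and ", n_drop_ns,
           " out-of-namespace term(s)")
  }
  recs_k <- recs[keep]
  ids <- ids_all[keep]
  if (anyDuplicated(ids)) {
    stop("duplicate term id ", ids[duplicated(ids)][1], call. = FALSE)
  }
  ns <- unname(ns_all[keep])
  ns_of <- setNames(ns, ids)
  parents <- vector("list", length(ids))
  names(parents) <- ids
  n_cross <- 0L
  for (i in seq_along(recs_k)) {
    ps <- recs_k[[i]]$is_a
    for (p in ps) {
      if (!p %in% ids_all) {
        stop("term ", ids[[i]], " has is_a to unknown id ", p, call. = FALSE)
      }
    }
    ps <- ps[ps %in% ids]                       # dropped targets vanish
    cross <- ps[ns_of[ps] != ns[[i]]]
    n_cross <- n_cross + length(cross)
    parents[[i]] <- unique(setdiff(ps, cross))
  }
  if (n_cross > 0) gp_log("dropped ", n_cross, " cross-namespace is_a edge(s)")
  terms <- tibble(id = ids,
                  name = vapply(recs_k, `[[`, "", "name"),
                  namespace = ns)
  new_go_dag(terms, parents)
}

#' Write a go_dag back to OBO 1.2 text
#'
#' Emits the subset of OBO used by [parse_obo()] so that
#' `parse_obo(write_obo(dag))` round-trips exactly.
#'
#' @param dag a [go_dag].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly, the character vector of OBO lines.
#' @export
write_obo <- function(dag, path = NULL) {
  ord <- order(dag$terms$id)
  out <- c("format-version: 1.2", "")
  for (i in ord) {
    id <- dag$terms$id[[i]]
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", dag$terms$name[[i]]),
             paste0("namespace: ", long_ns[[dag$terms$namespace[[i]]]]),
             if (length(dag$parents[[id]]))
               paste0("is_a: ", sort(dag$parents[[id]])),
             "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

check_terms <- function(dag, terms) {
  bad <- setdiff(terms, dag$terms$id)
  if (length(bad)) {
    stop("unknown term(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
}

#' Ancestors of a term
#'
#' Transitive closure over is_a edges up to (and including) the namespace
#' root.
#'
#' @param dag a [go_dag].
#' @param term a term id present in `dag`.
#' @param include_self include `term` itself in the result?
#' @return character vector of term ids.
#' @export
go_ancestors <- function(dag, term, include_self = FALSE) {
  check_terms(dag, term)
  a <- dag$ancestors[[term]]
  if (include_self) unique(c(term, a)) else a
}

#' Propagate a term set to the root
#'
#' Returns the union of each term's ancestors-with-self: the annotation set
#' implied by annotating the given terms. Idempotent and monotone.
#'
#' @param dag a [go_dag].
#' @param terms character vector of term ids (may be empty).
#' @return character vector of term ids.
#' @export
go_propagate <- function(dag, terms) {
  if (!length(terms)) return(character(0))
  check_terms(dag, terms)
  unique(c(terms, unlist(dag$ancestors[terms], use.names = FALSE)))
}

#' Edge distance between two terms
#'
#' Minimum number of is_a edges on any path between `t1` and `t2` on the
#' undirected skeleton of the DAG (0 iff the terms are identical). Used by
#' the PFP confidence calibration at distances 0, 2 and 4.
#'
#' @param dag a [go_dag].
#' @param t1,t2 term ids in the same namespace.
#' @return a non-negative integer.
#' @export
go_edge_distance <- function(dag, t1, t2) {
  check_terms(dag, c(t1, t2))
  ns <- setNames(dag$terms$namespace, dag$terms$id)
  if (ns[[t1]] != ns[[t2]]) {
    stop("terms ", t1, " and ", t2, " are in different namespaces",
         call. = FALSE)
  }
  dist_to_set(dag, t1, t2, max_d = Inf)
}

# BFS distance from `from` to the nearest member of `to` on the undirected
# is_a skeleton; Inf if farther than max_d.
dist_to_set <- function(dag, from, to, max_d = Inf) {
  if (from %in% to) return(0L)
  seen <- from
  frontier <- from
  d <- 0L
  while (length(frontier) && d < max_d) {
    d <- d + 1L
    nxt <- unique(unlist(c(dag$parents[frontier], dag$children[frontier]),
                         use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) return(Inf)
    if (any(nxt %in% to)) return(d)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Inf
}

#' Per-term annotation statistics: frequency, probability, information content
#'
#' Computes, for every term of the requested namespace(s), the recursive
#' frequency `freq(c) = annot(c) + sum of freq over children of c`, the
#' probability `p(c) = freq(c) / freq(root)` and the information content
#' `ic(c) = -log10(p(c))`. The recursion sums children's frequencies
#' literally, so a gene product annotated under a multi-parent descendant is
#' counted once per path; the alternative `mode = "unique"` counts distinct
#' proteins annotated at or below each term instead (it requires `db`).
#'
#' @param dag a [go_dag].
#' @param annot_counts direct annotation counts: a named numeric vector or a
#'   data frame with columns `term` and `annot`. Terms absent from it count 0.
#' @param mode `"recursive"` (default, the literal child-sum recursion) or
#'   `"unique"` (distinct proteins at-or-below each term).
#' @param db an [annotation_db], required for `mode = "unique"`.
#' @param namespaces namespaces to compute; defaults to every namespace of
#'   `dag` holding at least one annotation. A requested namespace whose root
#'   frequency is 0 is an error.
#' @return a tibble of class `go_term_stats` with columns `term`,
#'   `namespace`, `annot`, `freq`, `p`, `ic`. Terms with zero frequency get
#'   `NA` for `p` and `ic` and are excluded from IC-based metrics.
#' @export
compute_term_stats <- function(dag, annot_counts, mode = c("recursive", "unique"),
                               db = NULL, namespaces = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(annot_counts)) {
    annot_counts <- setNames(annot_counts$annot, annot_counts$term)
  }
  if (any(annot_counts < 0) || any(annot_counts != floor(annot_counts))) {
    stop("annotation counts must be non-negative integers", call. = FALSE)
  }
  check_terms(dag, names(annot_counts))
  ids <- dag$terms$id
  annot <- setNames(numeric(length(ids)), ids)
  annot[names(annot_counts)] <- annot_counts

  freq <- setNames(numeric(length(ids)), ids)
  if (mode == "recursive") {
    for (id in rev(dag$topo)) {           # children before parents
      ch <- dag$children[[id]]
      freq[[id]] <- annot[[id]] + sum(freq[ch])
    }
  } else {
    if (is.null(db)) stop("mode = 'unique' requires `db`", call. = FALSE)
    below <- proteins_below(dag, db)
    freq[] <- vapply(ids, function(id) length(below[[id]]), 0)
  }

  ns_of <- setNames(dag$terms$namespace, ids)
  if (is.null(namespaces)) {
    tot <- tapply(freq, ns_of[ids], sum)
    namespaces <- names(tot)[tot > 0]
    if (!length(namespaces)) {
      stop("no annotations in any namespace (freq(root) = 0)", call. = FALSE)
    }
  }
  out <- list()
  for (ns in namespaces) {
    root <- dag$roots[[ns]]
    if (is.null(root)) stop("namespace ", ns, " not in dag", call. = FALSE)
    if (freq[[root]] == 0) {
      stop("no annotations in namespace ", ns, " (freq(root) = 0)",
           call. = FALSE)
    }
    sel <- ids[ns_of == ns]
    p <- freq[sel] / freq[[root]]
    p[freq[sel] == 0] <- NA_real_
    out[[ns]] <- tibble(term = sel, namespace = ns,
                        annot = unname(annot[sel]), freq = unname(freq[sel]),
                        p = unname(p), ic = -log10(unname(p)))
  }
  res <- bind_rows(out)
  structure(res, class = c("go_term_stats", class(res)),
            roots = dag$roots[namespaces], mode = mode)
}

# protein sets annotated at-or-below each term (for mode = "unique")
proteins_below <- function(dag, db) {
  sets <- lapply(setNames(dag$terms$id, dag$terms$id), function(id) {
    character(0)
  })
  direct <- split(db$protein, db$term)
  for (tm in names(direct)) {
    for (a in c(tm, dag$ancestors[[tm]])) {
      sets[[a]] <- c(sets[[a]], direct[[tm]])
    }
  }
  lapply(sets, unique)
}

stats_lookup <- function(stats, col = "ic") {
  setNames(stats[[col]], stats$term)
}

#' Maximum information content of a shared ancestor (Resnik similarity)
#'
#' The semantic similarity of two terms: the largest IC among the common
#' ancestors (ancestors-with-self) of `t1` and `t2`. Equals `ic(t1)` when
#' `t1 == t2` or when `t1` is an ancestor of `t2`.
#'
#' @param dag a [go_dag].
#' @param stats a `go_term_stats` tibble from [compute_term_stats()] (or any
#'   data frame with `term` and `ic` columns).
#' @param t1,t2 term ids in the same namespace.
#' @return the IC value (>= 0); 0 with a warning when no common ancestor has
#'   a defined IC.
#' @export
max_shared_ancestor_ic <- function(dag, stats, t1, t2) {
  check_terms(dag, c(t1, t2))
  common <- intersect(go_ancestors(dag, t1, include_self = TRUE),
                      go_ancestors(dag, t2, include_self = TRUE))
  ic <- stats_lookup(stats)[common]
  ic <- ic[!is.na(ic)]
  if (!length(ic)) {
    warning("no common ancestor of ", t1, " and ", t2,
            " has a defined IC; returning 0", call. = FALSE)
    return(0)
  }
  max(ic)
}

#' Build per-term statistics from an external probability table
#'
#' CAFA-style evaluations sometimes use organiser-provided prior
#' probabilities rather than frequencies computed from a local annotation
#' database. This helper turns a per-term probability table into the
#' `go_term_stats` shape the evaluation functions accept
#' (`ic = -log10(p)`).
#'
#' @param dag a [go_dag].
#' @param probs data frame with columns `term` and `p` (probabilities in
#'   (0, 1]).
#' @return a `go_term_stats` tibble (with `annot` and `freq` set to `NA`).
#' @export
term_stats_from_probabilities <- function(dag, probs) {
  check_terms(dag, probs$term)
  if (any(probs$p <= 0 | probs$p > 1)) {
    stop("probabilities must lie in (0, 1]", call. = FALSE)
  }
  ns_of <- setNames(dag$terms$namespace, dag$terms$id)
  res <- tibble(term = probs$term, namespace = unname(ns_of[probs$term]),
                annot = NA_real_, freq = NA_real_, p = probs$p,
                ic = -log10(probs$p))
  structure(res, class = c("go_term_stats", class(res)),
            roots = dag$roots, mode = "external")
}
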