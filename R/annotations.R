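#' Protein-to-GO annotation database
#'
#' An `annotation_db` is a tibble with one row per (protein, term) pair and
#' columns `protein`, `term`, `namespace` (`"BP"`/`"MF"`/`"CC"`) and
#' `evidence` (a list column holding the set of evidence codes seen for the
#' pair). It is the source of direct per-term counts, per-protein annotation
#' counts and the co-occurrence conditional probabilities used by PFP.
#'
#' @name annotation_db
NULL

new_annotation_db <- function(df) {
  df <- as_tibble(df)
  structure(df, class = c("annotation_db", class(df)))
}

#' Parse a GAF 2.x gene association file
#'
#' Rows whose evidence code is in `exclude_evidence` (IEA by default,
#' matching the non-IEA convention of experimental truth sets) and rows whose
#' qualifier contains `NOT` are dropped. Comment lines starting with `!` are
#' skipped. The remaining rows are grouped per (protein, term); evidence
#' codes are merged into a set, so each pair appears once.
#'
#' @param x path to a GAF file, or a character vector of its lines.
#' @param exclude_evidence evidence codes to drop; default `"IEA"`. Use
#'   `character(0)` to keep everything.
#' @param namespaces aspects to keep (GAF column 9: P = BP, F = MF, C = CC).
#' @param strict if `TRUE` (default) a row with fewer than 15 columns is an
#'   error naming the line; if `FALSE` it is skipped with a log message.
#' @return an [annotation_db].
#' @export
parse_gaf <- function(x, exclude_evidence = "IEA",
                      namespaces = c("BP", "MF"), strict = TRUE) {
  lines <- as_lines(x)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  rows <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- lengths(fields) < 15
  if (any(short)) {
    if (strict) {
      stop("malformed GAF row (<15 columns) at line ", rows[which(short)[1]],
           call. = FALSE)
    }
    gp_log("skipping ", sum(short), " malformed GAF row(s)")
    fields <- fields[!short]
  }
  if (!length(fields)) {
    return(new_annotation_db(tibble(protein = character(0),
                                    term = character(0),
                                    namespace = character(0),
                                    evidence = list())))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  aspect_map <- c(P = "BP", F = "MF", C = "CC")
  df <- tibble(protein = col(2), qualifier = col(4), term = col(5),
               evidence = col(7), namespace = unname(aspect_map[col(9)]))
  df <- df |>
    filter(!grepl("(^|\\|)NOT($|\\|)", .data$qualifier),
           !.data$evidence %in% exclude_evidence,
           .data$namespace %in% namespaces) |>
    group_by(.data$protein, .data$term, .data$namespace) |>
    summarise(evidence = list(sort(unique(.data$evidence))), .groups = "drop") |>
    arrange(.data$protein, .data$term)
  new_annotation_db(df[, c("protein", "term", "namespace", "evidence")])
}

#' Write an annotation database as GAF 2.1
#'
#' Emits one row per (protein, term, evidence code), 17 tab-separated
#' columns, so that `parse_gaf(write_gaf(db), exclude_evidence = character(0))`
#' round-trips exactly.
#'
#' @param db an [annotation_db].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly, the character vector of GAF lines.
#' @export
write_gaf <- function(db, path = NULL) {
  aspect <- c(BP = "P", MF = "F", CC = "C")
  rows <- df_unnest_evidence(db)
  out <- c("!gaf-version: 2.1",
           vapply(seq_len(nrow(rows)), function(i) {
             paste(c("GP", rows$protein[[i]], rows$protein[[i]], "",
                     rows$term[[i]], "GO_REF:0000000", rows$evidence[[i]], "",
                     aspect[[rows$namespace[[i]]]], "", "", "protein",
                     "taxon:0000", "20110101", "gopred", "", ""),
                   collapse = "\t")
           }, ""))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

df_unnest_evidence <- function(db) {
  tidyr::unnest(as_tibble(db), "evidence") |>
    arrange(.data$protein, .data$term, .data$evidence)
}

#' Direct annotation counts per term
#'
#' Number of distinct proteins directly annotated with each term of a
#' namespace (no propagation). This is the `annot(c)` input of
#' [compute_term_stats()].
#'
#' @param db an [annotation_db].
#' @param namespace `"BP"` or `"MF"`.
#' @return tibble with columns `term`, `annot`.
#' @export
annotation_counts <- function(db, namespace = "BP") {
  assert_namespace(namespace)
  db |>
    filter(.data$namespace == !!namespace) |>
    distinct(.data$protein, .data$term) |>
    count(.data$term, name = "annot") |>
    as_tibble()
}

#' Per-protein annotation counts (Nfunc)
#'
#' The number of GO annotations each protein carries in a namespace.
#'
#' @inheritParams annotation_counts
#' @return tibble with columns `protein`, `n_func`.
#' @export
nfunc <- function(db, namespace = "BP") {
  assert_namespace(namespace)
  db |>
    filter(.data$namespace == !!namespace) |>
    distinct(.data$protein, .data$term) |>
    count(.data$protein, name = "n_func") |>
    as_tibble()
}

#' Co-occurrence conditional probability P(fa | fj)
#'
#' The fraction of proteins annotated with `fj` that are also annotated with
#' `fa`, computed over direct (unpropagated) annotations of one namespace.
#' `P(f|f) = 1` for every annotated term. Returns 0 (with a log message) when
#' `fj` annotates no protein, and 0 for cross-namespace pairs.
#'
#' @param db an [annotation_db].
#' @param fa,fj term ids.
#' @param namespace `"BP"` or `"MF"`.
#' @return a probability in \[0, 1\].
#' @export
cooccurrence_probability <- function(db, fa, fj, namespace = "BP") {
  assert_namespace(namespace)
  d <- db |> filter(.data$namespace == !!namespace)
  with_fj <- unique(d$protein[d$term == fj])
  if (!length(with_fj)) {
    gp_log("term ", fj, " annotates no protein in ", namespace,
           "; P(", fa, "|", fj, ") = 0")
    return(0)
  }
  with_both <- intersect(with_fj, unique(d$protein[d$term == fa]))
  length(with_both) / length(with_fj)
}

# Sparse co-occurrence machinery for PFP: P[fa, fj] = |fa & fj| / |fj| over
# all directly annotated terms of the namespace.
cooccurrence_matrix <- function(db, namespace = "BP") {
  d <- db |>
    filter(.data$namespace == !!namespace) |>
    distinct(.data$protein, .data$term)
  terms <- sort(unique(d$term))
  prots <- sort(unique(d$protein))
  if (!length(terms)) {
    return(list(P = NULL, terms = character(0)))
  }
  M <- Matrix::sparseMatrix(i = match(d$term, terms),
                            j = match(d$protein, prots),
                            x = 1,
                            dims = c(length(terms), length(prots)),
                            dimnames = list(terms, prots))
  joint <- Matrix::tcrossprod(M)            # |fa & fj|
  cnt <- Matrix::diag(joint)                # |fj|
  P <- joint %*% Matrix::Diagonal(x = 1 / cnt)
  dimnames(P) <- list(terms, terms)
  list(P = P, terms = terms, count = setNames(cnt, terms))
}

#' Full co-occurrence table
#'
#' All nonzero conditional probabilities `P(fa|fj)` between directly
#' annotated terms of a namespace.
#'
#' @inheritParams annotation_counts
#' @return tibble with columns `fa`, `fj`, `p` (only nonzero entries).
#' @export
cooccurrence_table <- function(db, namespace = "BP") {
  cm <- cooccurrence_matrix(db, namespace)
  if (is.null(cm$P)) return(tibble(fa = character(0), fj = character(0),
                                   p = numeric(0)))
  tp <- methods::as(cm$P, "TsparseMatrix")
  tibble(fa = cm$terms[tp@i + 1L], fj = cm$terms[tp@j + 1L], p = tp@x) |>
    filter(.data$p > 0) |>
    arrange(.data$fj, .data$fa)
}
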