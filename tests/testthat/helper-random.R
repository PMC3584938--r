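# Random small instances for property and equivalence tests. Everything is
# built through the public parsers (OBO / tibbles) so the parsing paths get
# exercised too.

random_dag <- function(n_terms = 12, p_extra_parent = 0.3) {
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  lines <- c("format-version: 1.2", "",
             "[Term]", paste0("id: ", ids[1]), "name: biological_process",
             "namespace: biological_process", "")
  for (i in seq_len(n_terms)[-1]) {
    parents <- ids[sample.int(i - 1, 1)]
    if (i > 2 && stats::runif(1) < p_extra_parent) {
      extra <- sample(setdiff(ids[seq_len(i - 1)], parents), 1)
      parents <- c(parents, extra)
    }
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: t", i), "namespace: biological_process",
               paste0("is_a: ", parents), "")
  }
  parse_obo(lines)
}

random_db <- function(dag, n_proteins = 6, max_annot = 3) {
  pool <- setdiff(dag$terms$id, dag$roots[["BP"]])
  rows <- lapply(seq_len(n_proteins), function(i) {
    k <- sample.int(min(max_annot, length(pool)), 1)
    tibble::tibble(protein = sprintf("p%02d", i),
                   term = sample(pool, k),
                   namespace = "BP", evidence = list("EXP"))
  })
  gopred:::new_annotation_db(dplyr::arrange(dplyr::bind_rows(rows),
                                            protein, term))
}

random_hits <- function(db, n_hits = 5, query = "T1") {
  subjects <- sample(unique(db$protein), min(n_hits, length(unique(db$protein))))
  tibble::tibble(query = query, subject = subjects,
                 pident = round(stats::runif(length(subjects), 20, 95), 1),
                 evalue = 10^stats::runif(length(subjects), -20, 1))
}

random_instance <- function() {
  dag <- random_dag(n_terms = sample(6:20, 1))
  db <- random_db(dag, n_proteins = sample(3:10, 1))
  hits <- random_hits(db, n_hits = sample(2:8, 1))
  l2 <- dplyr::bind_rows(lapply(unique(hits$subject), function(s) {
    if (stats::runif(1) < 0.5) return(NULL)
    h <- random_hits(db, n_hits = sample(1:3, 1), query = s)
    h[h$subject != s, ]
  }))
  if (!is.null(l2) && nrow(l2) == 0) l2 <- NULL
  truth <- tibble::tibble(
    target = "T1",
    term = sample(setdiff(dag$terms$id, dag$roots[["BP"]]),
                  sample(1:3, 1)))
  list(dag = dag, db = db, hits = hits, level2 = l2, truth = truth)
}
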