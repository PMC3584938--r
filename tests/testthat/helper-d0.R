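# Shorthand for the D0 micro-dataset used across tests.
d0 <- list(R = "GO:0000001", A = "GO:0000002", B = "GO:0000003",
           A1 = "GO:0000004", A2 = "GO:0000005")

d0_stats <- function() {
  dag <- d0_dag()
  compute_term_stats(dag, annotation_counts(d0_db()))
}

# tibble builders
tb_pred <- function(terms, scores, target = NULL) {
  out <- tibble::tibble(term = terms, score = scores)
  if (!is.null(target)) out <- dplyr::mutate(out, target = target, .before = 1)
  out
}

tb_hits <- function(subjects, evalues, pident = 50, query = "T1") {
  tibble::tibble(query = query, subject = subjects, pident = pident,
                 evalue = evalues)
}

calib_fixture <- function() {
  dag <- d0_dag()
  set.seed(42)
  bench <- dplyr::bind_rows(lapply(1:30, function(i) {
    tibble::tibble(target = sprintf("B%02d", i),
                   term = sample(c(d0$A1, d0$A2, d0$B, d0$A), 2),
                   score = stats::runif(2, 0, 20))
  }))
  truth <- tibble::tibble(target = sprintf("B%02d", 1:30),
                          term = sample(c(d0$A1, d0$B), 30, replace = TRUE))
  list(dag = dag, bench = bench, truth = truth)
}
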