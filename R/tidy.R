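#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PFP calibration table
#'
#' One row per p-value bin with its raw and isotonically pooled
#' fraction-correct at edge distances 0, 2 and 4.
#'
#' @param x a `pfp_calibration`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.pfp_calibration <- function(x, ...) {
  as_tibble(x$table)
}

#' @rdname tidy.pfp_calibration
#' @return `glance()`: a one-row tibble with the number of calibrated
#'   terms, background samples and bins.
#' @export
glance.pfp_calibration <- function(x, ...) {
  tibble(n_terms = length(x$background),
         n_samples = length(x$pooled),
         n_bins = nrow(x$table),
         min_background = x$min_background)
}

#' Tidy a GO DAG
#'
#' @param x a [go_dag].
#' @param ... unused.
#' @return one row per is_a edge: `child`, `parent`, `namespace`.
#' @export
tidy.go_dag <- function(x, ...) {
  ns <- setNames(x$terms$namespace, x$terms$id)
  edges <- tibble(child = rep(names(x$parents), lengths(x$parents)),
                  parent = unlist(x$parents, use.names = FALSE))
  mutate(edges, namespace = unname(ns[.data$child]))
}

#' @rdname tidy.go_dag
#' @return `glance()`: one row with term/edge/root counts per namespace.
#' @export
glance.go_dag <- function(x, ...) {
  tibble(namespace = names(x$roots),
         root = unname(x$roots),
         n_terms = unname(vapply(names(x$roots),
                                 function(ns) sum(x$terms$namespace == ns),
                                 0L)),
         n_edges = unname(vapply(names(x$roots), function(ns) {
           sum(lengths(x$parents[x$terms$id[x$terms$namespace == ns]]))
         }, 0L)))
}

#' Tidy a hit graph
#'
#' @param x a `hit_graph`.
#' @param ... unused.
#' @return one row per hit with `level`, `seed` (the level-1 subject that
#'   seeded a level-2 search, `NA` at level 1), `subject`, `pident`,
#'   `evalue`, `weight`.
#' @export
tidy.hit_graph <- function(x, ...) {
  l1 <- mutate(x$level1, level = 1L, seed = NA_character_, .before = 1)
  l2 <- bind_rows(lapply(names(x$level2), function(s) {
    mutate(x$level2[[s]], level = 2L, seed = s, .before = 1)
  }))
  bind_rows(l1, l2)
}
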