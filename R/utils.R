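#' @importFrom rlang %||% .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows count distinct filter group_by left_join
#'   mutate n pull rename row_number select slice_head summarise ungroup desc
#' @importFrom stats runif setNames
#' @importFrom utils head
#' @importFrom ggplot2 autoplot
#' @importFrom generics tidy glance
NULL

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

gp_log <- function(...) {
  if (!isTRUE(getOption("gopred.quiet", FALSE))) message("gopred: ", ...)
}

# Read `x` as lines: a path to a file, or a character vector already holding
# the text (multi-element, or single element containing a newline).
as_lines <- function(x) {
  if (is.character(x) && length(x) == 1 && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

assert_namespace <- function(namespace) {
  if (!namespace %in% c("BP", "MF", "CC")) {
    stop("unknown namespace '", namespace, "' (expected BP, MF or CC)",
         call. = FALSE)
  }
  namespace
}
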