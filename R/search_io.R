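#' Parse BLAST/PSI-BLAST tabular output (outfmt 6)
#'
#' Reads 12-column tabular lines (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`). Self-hits
#' (`qseqid == sseqid`) are dropped; duplicate (query, subject) pairs keep
#' the row with the lowest E-value (first occurrence position). Original
#' within-query order is otherwise preserved.
#'
#' @param x path to a tabular file, or a character vector of its lines.
#' @return tibble with columns `query`, `subject`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`.
#' @export
parse_blast_tabular <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble(query = character(0), subject = character(0),
                  pident = numeric(0), length = integer(0),
                  mismatch = integer(0), gapopen = integer(0),
                  qstart = integer(0), qend = integer(0),
                  sstart = integer(0), send = integer(0),
                  evalue = numeric(0), bitscore = numeric(0))
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 12)) {
    stop("expected 12 tab-separated columns at line ",
         which(lengths(fields) != 12)[1], call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      stop("non-numeric ", what, " at line ", which(is.na(v))[1],
           call. = FALSE)
    }
    v
  }
  df <- tibble(query = col(1), subject = col(2),
               pident = num(3, "percent identity"),
               length = as.integer(num(4, "length")),
               mismatch = as.integer(num(5, "mismatch")),
               gapopen = as.integer(num(6, "gapopen")),
               qstart = as.integer(num(7, "qstart")),
               qend = as.integer(num(8, "qend")),
               sstart = as.integer(num(9, "sstart")),
               send = as.integer(num(10, "send")),
               evalue = num(11, "E-value"),
               bitscore = num(12, "bitscore"))
  if (any(df$evalue < 0)) {
    stop("negative E-value at line ", which(df$evalue < 0)[1], call. = FALSE)
  }
  if (any(df$pident < 0 | df$pident > 100)) {
    stop("percent identity outside [0, 100] at line ",
         which(df$pident < 0 | df$pident > 100)[1], call. = FALSE)
  }
  df <- df |> filter(.data$query != .data$subject)
  # duplicate (query, subject): keep lowest E-value, stable position
  df |>
    mutate(.pos = row_number()) |>
    group_by(.data$query, .data$subject) |>
    dplyr::slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$.pos) |>
    select(-".pos")
}

#' Write hits as BLAST tabular outfmt-6 lines
#'
#' @param hits a tibble as returned by [parse_blast_tabular()].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly, the character vector of lines.
#' @export
write_blast_tabular <- function(hits, path = NULL) {
  defaults <- list(length = 100L, mismatch = 0L, gapopen = 0L, qstart = 1L,
                   qend = 100L, sstart = 1L, send = 100L, bitscore = 100)
  for (col in names(defaults)) {
    if (!col %in% names(hits)) hits[[col]] <- defaults[[col]]
  }
  out <- vapply(seq_len(nrow(hits)), function(i) {
    paste(c(hits$query[[i]], hits$subject[[i]],
            formatC(hits$pident[[i]], format = "fg"),
            hits$length[[i]], hits$mismatch[[i]], hits$gapopen[[i]],
            hits$qstart[[i]], hits$qend[[i]], hits$sstart[[i]],
            hits$send[[i]],
            formatC(hits$evalue[[i]], format = "g", digits = 6),
            formatC(hits$bitscore[[i]], format = "fg")),
          collapse = "\t")
  }, "")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Two-level hit graph for ESG
#'
#' Assembles the level-1 hits of one target, plus (optionally) the level-2
#' hit lists seeded by each level-1 subject, into the weighted graph ESG
#' consumes. Hits with E-value at or above `e_ceiling` are removed at both
#' levels. Each retained hit carries a normalised weight: its
#' `-log10(E)` (E-values clamped below at `e_floor` so perfect hits stay
#' finite) divided by the sum over hits of the same search; hits with
#' nonpositive `-log10(E)` (E-value > 1) carry weight 0 and contribute no
#' mass to the normalisation.
#'
#' @param target the target (query) id.
#' @param level1 hits for this target: a tibble with at least `subject`,
#'   `pident`, `evalue` (a `query` column, if present, must match `target`).
#' @param level2 optional level-2 searches: either a parsed tabular tibble
#'   whose queries are level-1 subject ids, or a named list of hit tibbles
#'   keyed by level-1 subject id.
#' @param e_ceiling E-value ceiling; hits with `E >= e_ceiling` are dropped
#'   (default 100, the PSI-BLAST retrieval ceiling PFP assumes).
#' @param e_floor lower clamp applied to E-values before `-log10`.
#' @return an object of class `hit_graph`: a list with `target`, `level1`
#'   (tibble `subject`, `pident`, `evalue`, `weight`) and `level2` (named
#'   list of such tibbles).
#' @export
build_hit_graph <- function(target, level1, level2 = NULL,
                            e_ceiling = 100, e_floor = 1e-180) {
  stopifnot(e_ceiling > 0, e_floor > 0)
  if ("query" %in% names(level1)) {
    extra <- setdiff(unique(level1$query), target)
    if (length(extra)) {
      stop("level-1 hits contain queries other than the target: ",
           paste(head(extra, 3), collapse = ", "), call. = FALSE)
    }
  }
  l1 <- weight_search(level1, e_ceiling, e_floor)
  l2 <- list()
  if (!is.null(level2)) {
    if (is.data.frame(level2)) {
      level2 <- split(level2, level2$query)
    }
    for (s in intersect(l1$subject, names(level2))) {
      w <- weight_search(level2[[s]], e_ceiling, e_floor)
      if (nrow(w)) l2[[s]] <- w
    }
  }
  structure(list(target = target, level1 = l1, level2 = l2),
            class = "hit_graph")
}

weight_search <- function(hits, e_ceiling, e_floor) {
  h <- as_tibble(hits)[, c("subject", "pident", "evalue")]
  h <- h |> filter(.data$evalue < e_ceiling)
  mass <- -log10(pmax(h$evalue, e_floor))
  mass[mass < 0] <- 0
  tot <- sum(mass)
  h$weight <- if (tot > 0) mass / tot else rep(0, nrow(h))
  h
}

#' @export
print.hit_graph <- function(x, ...) {
  cat("<hit_graph> target ", x$target, ": ", nrow(x$level1),
      " level-1 hit(s), ", length(x$level2),
      " with a level-2 search\n", sep = "")
  invisible(x)
}
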