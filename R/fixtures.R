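#' The D0 micro-dataset
#'
#' A five-term ontology (root R; A and B are children of R; A1 and A2 are
#' children of A) with three proteins annotated p1:(A1), p2:(A1, B),
#' p3:(A2). Its recursive frequencies are A1 = 2, A2 = 1, A = 3, B = 1,
#' R = 4, which makes every scoring and evaluation rule in the package
#' checkable by hand. The same dataset ships as OBO and GAF files under
#' `inst/extdata/` (`d0.obo`, `d0.gaf`) and parses back to exactly these
#' objects.
#'
#' @return `d0_dag()` a [go_dag]; `d0_db()` an [annotation_db].
#' @export
d0_dag <- function() {
  parse_obo(system.file("extdata", "d0.obo", package = "gopred",
                        mustWork = TRUE))
}

#' @rdname d0_dag
#' @export
d0_db <- function() {
  parse_gaf(system.file("extdata", "d0.gaf", package = "gopred",
                        mustWork = TRUE))
}

#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the structure the homology-based predictors
#' assume: targets whose true annotation is carried by a hidden donor
#' protein, a searchable annotation database containing relatives of that
#' donor, and two-level search results whose E-values separate signal from
#' noise. The seed fully determines every output.
#'
#' @param seed integer seed; one derived stream per artifact (ontology,
#'   database, searches) so components can be regenerated independently.
#' @param depth,branching shape of the generated ontology below the root.
#' @param multi_parent_frac fraction of non-root terms given a second
#'   parent (rewires the tree into a DAG).
#' @param namespace namespace of the generated ontology.
#' @param n_proteins number of database proteins.
#' @param annots_per_protein integer range (length 2) of direct annotations
#'   sampled per protein.
#' @param leaf_bias sampling weight of leaf terms relative to internal
#'   terms when drawing annotations.
#' @param iea_frac fraction of annotation rows given the IEA evidence code
#'   (to exercise evidence filtering).
#' @param n_targets number of prediction targets.
#' @param sigma probability that a sampled hit is a signal hit (shares a
#'   direct annotation term with the target's donor).
#' @param n_hits integer range of level-1 hits per target.
#' @param signal_log10e,noise_log10e log10 E-value ranges for signal and
#'   noise hits; the noise range deliberately crosses 0 so some hits have
#'   E > 1 and exercise the clamping rules.
#' @param level2_fanout number of level-2 hits generated per level-1 hit.
#' @return a list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, depth = 4, branching = 3,
                           multi_parent_frac = 0.1, namespace = "BP",
                           n_proteins = 200,
                           annots_per_protein = c(1, 3), leaf_bias = 4,
                           iea_frac = 0.2, n_targets = 50, sigma = 0.9,
                           n_hits = c(5, 10),
                           signal_log10e = c(-50, -10),
                           noise_log10e = c(-3, 1),
                           level2_fanout = 3) {
  stopifnot(depth >= 1, branching >= 1, sigma >= 0, sigma <= 1,
            multi_parent_frac >= 0, multi_parent_frac <= 1,
            iea_frac >= 0, iea_frac <= 1, n_proteins >= 2, n_targets >= 1)
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a synthetic ontology
#'
#' A rooted tree of the given depth and branching factor, optionally
#' rewired into a DAG by giving a fraction of non-root terms a second
#' parent one level up. Deterministic under the config seed.
#'
#' @param config a [fixture_config()].
#' @return a [go_dag].
#' @export
make_ontology <- function(config) {
  local_seed(config$seed + 101L, {
    ns <- config$namespace
    root <- "GO:1000000"
    ids <- root
    names_ <- long_ns[[ns]]
    parents <- list()
    parents[[root]] <- character(0)
    level <- root
    counter <- 0L
    levels <- list(root)
    for (d in seq_len(config$depth)) {
      nxt <- character(0)
      for (p in level) {
        for (b in seq_len(config$branching)) {
          counter <- counter + 1L
          id <- sprintf("GO:%07d", 1000000L + counter)
          ids <- c(ids, id)
          names_ <- c(names_, sprintf("synthetic term %d", counter))
          parents[[id]] <- p
          nxt <- c(nxt, id)
        }
      }
      levels[[d + 1L]] <- nxt
      level <- nxt
    }
    # extra parents: a random same-depth-minus-one term other than the parent
    if (config$multi_parent_frac > 0 && config$depth >= 1) {
      for (d in seq_len(config$depth)) {
        pool <- levels[[d]]
        if (length(pool) < 2) next
        for (id in levels[[d + 1L]]) {
          if (runif(1) < config$multi_parent_frac) {
            extra <- sample(setdiff(pool, parents[[id]]), 1)
            parents[[id]] <- c(parents[[id]], extra)
          }
        }
      }
    }
    terms <- tibble(id = ids, name = names_,
                    namespace = rep(config$namespace, length(ids)))
    new_go_dag(terms, parents)
  })
}

# leaf-biased term sampler (never the root)
sample_terms <- function(dag, config, n) {
  ids <- dag$terms$id
  root <- dag$roots[[config$namespace]]
  pool <- setdiff(ids, root)
  w <- ifelse(lengths(dag$children[pool]) == 0, config$leaf_bias, 1)
  sample(pool, n, replace = FALSE, prob = w[seq_along(pool)])
}

#' Generate a synthetic annotation database
#'
#' Each protein receives 1 or more direct annotations drawn from a
#' leaf-biased distribution over non-root terms; a configurable fraction of
#' rows carries the IEA evidence code, the rest EXP.
#'
#' @param dag a [go_dag] (typically from [make_ontology()]).
#' @param config a [fixture_config()].
#' @return an [annotation_db] including IEA rows (filter with
#'   [parse_gaf()] semantics downstream via the `evidence` column, or write
#'   and re-parse).
#' @export
make_annotation_db <- function(dag, config) {
  local_seed(config$seed + 202L, {
    rows <- lapply(seq_len(config$n_proteins), function(i) {
      k <- sample(config$annots_per_protein[1]:config$annots_per_protein[2], 1)
      terms <- sample_terms(dag, config, k)
      ev <- ifelse(runif(k) < config$iea_frac, "IEA", "EXP")
      tibble(protein = sprintf("P%05d", i), term = terms,
             namespace = config$namespace, evidence = as.list(ev))
    })
    df <- bind_rows(rows) |> arrange(.data$protein, .data$term)
    new_annotation_db(df)
  })
}

drop_iea <- function(db) {
  keep <- !vapply(db$evidence, function(e) all(e == "IEA"), TRUE)
  new_annotation_db(db[keep, ])
}

#' Simulate two-level search results for synthetic targets
#'
#' Each target's truth is the direct annotation set of a hidden donor
#' protein (a clone of a database protein, excluded from the searchable
#' database). Level-1 hits are, with probability `sigma`, signal hits --
#' database proteins sharing a direct annotation term with the donor, with
#' E-values drawn log-uniform from the strong range -- and otherwise random
#' proteins with E-values from the weak range (occasionally above 1, which
#' exercises the clamping rules). Each level-1 hit seeds `level2_fanout`
#' level-2 hits drawn the same way around the level-1 hit's annotations.
#'
#' @param db an [annotation_db] (the searchable database).
#' @param truth tibble `target`, `term`: each target's donor annotation set
#'   (as produced by [make_bundle()], or any direct term sets).
#' @param config a [fixture_config()].
#' @return list with `level1` and `level2` hit tibbles in
#'   [parse_blast_tabular()] layout.
#' @export
simulate_search <- function(db, truth, config) {
  local_seed(config$seed + 303L, {
    ns <- config$namespace
    ann <- annot_sets(db, ns)
    prots <- names(ann)
    term_index <- split(rep(names(ann), lengths(ann)),
                        unlist(ann, use.names = FALSE))
    sharing <- function(terms) unique(unlist(term_index[terms],
                                             use.names = FALSE))
    draw_e <- function(rng) 10^runif(1, rng[1], rng[2])
    mk_row <- function(q, s, e, signal) {
      tibble(query = q, subject = s,
             pident = round(runif(1, if (signal) 40 else 20,
                                  if (signal) 95 else 40), 1),
             length = 100L, mismatch = 10L, gapopen = 1L,
             qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
             evalue = signif(e, 4), bitscore = round(runif(1, 30, 300), 1))
    }
    l1 <- list(); l2 <- list()
    for (tg in unique(truth$target)) {
      tt <- truth$term[truth$target == tg]
      pool <- sharing(tt)
      n <- sample(config$n_hits[1]:config$n_hits[2], 1)
      seen <- character(0)
      for (h in seq_len(n)) {
        signal <- length(pool) > 0 && runif(1) < config$sigma
        subj <- if (signal) sample(pool, 1) else sample(prots, 1)
        if (subj %in% seen) next
        seen <- c(seen, subj)
        e <- draw_e(if (signal) config$signal_log10e else config$noise_log10e)
        l1[[length(l1) + 1L]] <- mk_row(tg, subj, e, signal)
        # level-2 search seeded by this hit
        pool2 <- setdiff(sharing(ann[[subj]]), subj)
        seen2 <- character(0)
        for (g in seq_len(config$level2_fanout)) {
          sig2 <- length(pool2) > 0 && runif(1) < 0.8
          s2 <- if (sig2) sample(pool2, 1) else sample(prots, 1)
          if (s2 %in% seen2 || s2 == subj) next
          seen2 <- c(seen2, s2)
          e2 <- draw_e(if (sig2) c(-30, -5) else config$noise_log10e)
          l2[[length(l2) + 1L]] <- mk_row(subj, s2, e2, sig2)
        }
      }
    }
    list(level1 = bind_rows(l1),
         level2 = if (length(l2)) distinct(bind_rows(l2), .data$query,
                                           .data$subject, .keep_all = TRUE)
                  else NULL)
  })
}

#' Generate a complete synthetic benchmark bundle
#'
#' Writes ontology (OBO), annotations (GAF), level-1 and level-2 hits
#' (BLAST tabular), truth (TSV) and a JSON manifest recording the
#' configuration, and returns the in-memory objects. The bundle is the
#' single input needed to run every predictor and metric end to end.
#'
#' @param config a [fixture_config()].
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory only.
#' @return list with `dag`, `db` (IEA rows included), `truth`, `hits`
#'   (level 1), `hits_level2`, `config`, and `paths` (named file paths, or
#'   `NULL`).
#' @export
make_bundle <- function(config = fixture_config(), out_dir = NULL) {
  dag <- make_ontology(config)
  db <- make_annotation_db(dag, config)
  truth <- local_seed(config$seed + 404L, {
    usable <- drop_iea(db)
    donors <- sample(unique(usable$protein), config$n_targets, replace = TRUE)
    ann <- annot_sets(usable, config$namespace)
    bind_rows(lapply(seq_len(config$n_targets), function(i) {
      tibble(target = sprintf("T%05d", i), term = ann[[donors[[i]]]])
    }))
  })
  searchable <- drop_iea(db)
  hits <- simulate_search(searchable, truth, config)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(obo = file.path(out_dir, "ontology.obo"),
               gaf = file.path(out_dir, "annotations.gaf"),
               hits = file.path(out_dir, "hits_level1.tsv"),
               hits_level2 = file.path(out_dir, "hits_level2.tsv"),
               truth = file.path(out_dir, "truth.tsv"),
               manifest = file.path(out_dir, "manifest.json"))
    write_obo(dag, paths[["obo"]])
    write_gaf(db, paths[["gaf"]])
    write_blast_tabular(hits$level1, paths[["hits"]])
    if (!is.null(hits$level2)) {
      write_blast_tabular(hits$level2, paths[["hits_level2"]])
    } else {
      paths <- paths[names(paths) != "hits_level2"]
    }
    write_truth(truth, paths[["truth"]])
    jsonlite::write_json(unclass(config), paths[["manifest"]],
                         auto_unbox = TRUE)
  }
  list(dag = dag, db = db, truth = truth, hits = hits$level1,
       hits_level2 = hits$level2, config = config, paths = paths)
}

#' Read and write truth files (target TAB GO-term TSV)
#'
#' @param x path to a truth TSV (columns: target id, term id, no header).
#' @return `read_truth()`: tibble `target`, `term`.
#' @export
read_truth <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(tibble(target = character(0),
                                    term = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("truth rows need two tab-separated columns (line ",
         which(lengths(parts) < 2)[1], ")", call. = FALSE)
  }
  tibble(target = vapply(parts, `[[`, "", 1),
         term = vapply(parts, `[[`, "", 2))
}

#' @rdname read_truth
#' @param truth tibble `target`, `term`.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  writeLines(paste(truth$target, truth$term, sep = "\t"), path)
  invisible(path)
}

#' Read and write prediction files (target TAB term TAB score TSV)
#'
#' The reader tolerates CAFA submission headers by skipping lines starting
#' with `AUTHOR`, `MODEL`, `KEYWORDS` or `END`. The writer emits scores
#' with six decimals.
#'
#' @param x path to a prediction TSV, or its lines.
#' @return `read_predictions()`: tibble `target`, `term`, `score`.
#' @export
read_predictions <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(AUTHOR|MODEL|KEYWORDS|END)", lines)]
  if (!length(lines)) return(tibble(target = character(0),
                                    term = character(0), score = numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    stop("prediction rows need three tab-separated columns (line ",
         which(lengths(parts) < 3)[1], ")", call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  if (anyNA(score)) {
    stop("non-numeric score at line ", which(is.na(score))[1], call. = FALSE)
  }
  tibble(target = vapply(parts, `[[`, "", 1),
         term = vapply(parts, `[[`, "", 2), score = score)
}

#' @rdname read_predictions
#' @param preds tibble `target`, `term`, `score`.
#' @param path output file.
#' @export
write_predictions <- function(preds, path) {
  writeLines(sprintf("%s\t%s\t%.6f", preds$target, preds$term, preds$score),
             path)
  invisible(path)
}
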