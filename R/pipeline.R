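#' @title End-to-end pipeline
#' @description
#' Orchestrates screen -> score -> filter -> pharmacophore with one
#' configuration object carrying the method defaults, and produces a
#' machine-readable report with the per-stage funnel counts.
#' @name pipeline
NULL

#' Pipeline configuration with method defaults
#'
#' Defaults are the method's stated operating values: triplet edges
#' 8-12 A, environment radius 4.5 A, fragment window 50-300 Da, collision
#' clearance 1 A, buriedness 5 atoms within 5 A, fitness threshold 0.4,
#' cluster diameter 3 A, decoy multiplicity 2, network 32/16 ReLU +
#' sigmoid, Adam, batch 50, 500 epochs.
#'
#' @param ... Named overrides of any default.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_edge = 8, max_edge = 12, edge_tol = 2.0, dedup_tol = 0.5,
    env_radius = 4.5, min_mw = 50, max_mw = 300, max_cuts = 3,
    min_clearance = 1.0, burial_radius = 5.0, min_mean_contacts = 5.0,
    score_threshold = 0.4, max_diameter = 3.0, query_tolerance = 1.5,
    query_top = 4, decoy_multiplicity = 2, hidden = c(32, 16),
    epochs = 500, batch_size = 50, lr = 1e-3, seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("run_config: unknown option(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Run the full fragment-seeding pipeline
#'
#' Stages: (1) triplet screening of the target against the database;
#' (2) target-FRASE construction and nativeness scoring; (3) collision /
#' buriedness / score filtering; (4) pharmacophore feature perception and
#' clustering; (5) query assembly from the `query_top` largest clusters.
#' Deterministic under `config$seed`.
#'
#' @param target_protein Target protein atom data.frame (apo).
#' @param db A `frase_db`.
#' @param model A trained `nativeness_model`.
#' @param config A [run_config()].
#' @return List of class `run_report`: `counts` (funnel: triplets,
#'   seeded, scored, post_collision, post_buriedness, post_score,
#'   features, clusters), `clusters` (table), `query`, `survivors`.
#' @export
run_pipeline <- function(target_protein, db, model, config = run_config()) {
  if (is.null(db) || length(db$frases) == 0) {
    stop("run_pipeline: configuration error - empty or missing FRASE database")
  }
  rt <- residue_table(target_protein)
  tts <- enumerate_triplets(rt, config$min_edge, config$max_edge)
  seeded <- screen(target_protein, db, config$min_edge, config$max_edge,
                   config$edge_tol, config$dedup_tol)
  counts <- c(target_triplets = length(tts), seeded = length(seeded))

  tfrases <- lapply(seeded, function(s)
    make_target_frase(target_protein, s$fragment, config$env_radius,
                      provenance = s$source_id %||% "target"))
  scoreable <- !vapply(tfrases, is.null, TRUE)
  scores <- rep(NA_real_, length(seeded))
  if (any(scoreable)) {
    scores[scoreable] <- score_frases(model, tfrases[scoreable])
  }
  counts["scored"] <- sum(scoreable)
  for (i in seq_along(seeded)) seeded[[i]]$score <- scores[i]

  keep <- which(scoreable)
  filt <- apply_filters(seeded[keep], target_protein, scores[keep],
                        filter_config(config$min_clearance,
                                      config$burial_radius,
                                      config$min_mean_contacts,
                                      config$score_threshold))
  counts <- c(counts, filt$counts[c("post_collision", "post_buriedness",
                                    "post_score")])

  clusters <- NULL; query <- NULL
  feats <- do.call(rbind, c(
    list(data.frame(ftype = character(), x = numeric(), y = numeric(),
                    z = numeric(), source = character())),
    lapply(filt$survivors, function(s)
      perceive_features(s$fragment, source = s$source_id %||% "seed"))))
  counts["features"] <- nrow(feats)
  if (nrow(feats) > 0) {
    clusters <- cluster_features(feats, config$max_diameter, seed = config$seed)
    counts["clusters"] <- nrow(clusters)
    top <- utils::head(clusters$cluster_id, config$query_top)
    query <- build_query(clusters, top, config$query_tolerance)
  } else {
    counts["clusters"] <- 0L
  }
  structure(list(counts = counts, clusters = clusters, query = query,
                 survivors = filt$survivors, config = unclass(config)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report funnel:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-16s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Serialize a run report to canonical JSON
#'
#' Identical inputs and seed give byte-identical JSON, which is the
#' determinism contract checked by the test suite.
#'
#' @param report A `run_report`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
report_json <- function(report, path = NULL) {
  obj <- list(
    counts = as.list(report$counts),
    clusters = if (is.null(report$clusters)) list() else
      report$clusters[, c("cluster_id", "ftype", "size", "x", "y", "z")],
    query = if (is.null(report$query)) list() else
      as.data.frame(report$query)[, c("ftype", "x", "y", "z", "radius")],
    survivors = lapply(report$survivors, function(s) list(
      source = s$source_id %||% "", score = round(s$score, 10),
      rmsd = round(s$alignment_rmsd, 10)))
  )
  js <- jsonlite::toJSON(obj, digits = 10, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
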