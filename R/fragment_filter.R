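#' @title Post-screening fragment filters
#' @description
#' Seeded fragments are reduced to a high-confidence set by three
#' predicates applied in order: no collision with the protein (every
#' fragment heavy atom at least 1 A from every protein heavy atom),
#' sufficient buriedness (on average at least 5 protein heavy atoms within
#' 5 A per fragment heavy atom), and a nativeness score of at least 0.4.
#' All bounds are inclusive; hydrogens and alpha markers are excluded from
#' all distance counts. The predicates are pure, so the outcome is
#' order-independent; the stated order is kept for funnel logging.
#' @name fragment_filter
NULL

#' Filter configuration with method defaults
#'
#' @param min_clearance Minimum fragment-protein heavy-atom distance in
#'   Angstrom (default 1.0).
#' @param burial_radius Contact-counting radius in Angstrom (default 5.0).
#' @param min_mean_contacts Minimum mean protein-atom contacts per
#'   fragment atom (default 5.0).
#' @param score_threshold Minimum nativeness score (default 0.4).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_clearance = 1.0, burial_radius = 5.0,
                          min_mean_contacts = 5.0, score_threshold = 0.4) {
  stopifnot(min_clearance > 0, burial_radius > 0, min_mean_contacts > 0,
            score_threshold >= 0)
  structure(list(min_clearance = min_clearance, burial_radius = burial_radius,
                 min_mean_contacts = min_mean_contacts,
                 score_threshold = score_threshold),
            class = "filter_config")
}

# pairwise distance matrix between fragment heavy atoms and protein heavy atoms
frag_prot_dist <- function(fragment, protein) {
  fa <- fragment$atoms
  keep <- fa$element != "H" & !fa$is_alpha
  fxyz <- as.matrix(fa[keep, c("x", "y", "z"), drop = FALSE])
  pk <- protein$element != "H"
  pxyz <- as.matrix(protein[pk, c("x", "y", "z"), drop = FALSE])
  if (nrow(fxyz) == 0) stop("fragment has no heavy atoms")
  if (nrow(pxyz) == 0) return(matrix(Inf, nrow(fxyz), 0))
  d2 <- outer(rowSums(fxyz^2), rowSums(pxyz^2), "+") - 2 * fxyz %*% t(pxyz)
  sqrt(pmax(d2, 0))
}

#' Collision filter
#'
#' Passes iff every fragment heavy atom is at least `min_clearance` away
#' from every protein heavy atom (inclusive bound).
#'
#' @param fragment A [frase_mol()] in the target frame.
#' @param protein Protein atom data.frame.
#' @param min_clearance Clearance in Angstrom (default 1.0).
#' @return Logical.
#' @export
collision_filter <- function(fragment, protein, min_clearance = 1.0) {
  d <- frag_prot_dist(fragment, protein)
  if (ncol(d) == 0) return(TRUE)
  min(d) >= min_clearance
}

#' Buriedness filter
#'
#' Passes iff the mean (over fragment heavy atoms) count of protein heavy
#' atoms within `burial_radius` is at least `min_mean_contacts`. The bound
#' is on the average, not a per-atom minimum.
#'
#' @inheritParams collision_filter
#' @param burial_radius Counting radius in Angstrom (default 5.0).
#' @param min_mean_contacts Mean-contact threshold (default 5.0).
#' @return Logical.
#' @export
buriedness_filter <- function(fragment, protein, burial_radius = 5.0,
                              min_mean_contacts = 5.0) {
  d <- frag_prot_dist(fragment, protein)
  if (ncol(d) == 0) return(FALSE)
  mean(rowSums(d <= burial_radius)) >= min_mean_contacts
}

#' Apply the filter funnel to seeded fragments
#'
#' Sequential collision -> buriedness -> score filtering with per-stage
#' survivor counts.
#'
#' @param seeded List of `seeded_fragment` objects (see [screen()]).
#' @param protein Target protein atom data.frame.
#' @param scores Numeric vector of nativeness scores parallel to `seeded`
#'   (may be `NULL` if every element carries a `score`).
#' @param config A [filter_config()].
#' @return List with `survivors` (the surviving `seeded_fragment`s, scores
#'   attached) and `counts` (named funnel: input, post_collision,
#'   post_buriedness, post_score).
#' @export
apply_filters <- function(seeded, protein, scores = NULL,
                          config = filter_config()) {
  if (is.null(scores)) scores <- vapply(seeded, function(s) s$score, 1)
  stopifnot(length(scores) == length(seeded))
  counts <- c(input = length(seeded))
  pass1 <- vapply(seeded, function(s)
    collision_filter(s$fragment, protein, config$min_clearance), TRUE)
  counts["post_collision"] <- sum(pass1)
  pass2 <- pass1 & vapply(seeded, function(s)
    buriedness_filter(s$fragment, protein, config$burial_radius,
                      config$min_mean_contacts), TRUE)
  counts["post_buriedness"] <- sum(pass2)
  pass3 <- pass2 & (scores >= config$score_threshold)
  counts["post_score"] <- sum(pass3)
  surv <- seeded[pass3]
  sc <- scores[pass3]
  for (i in seq_along(surv)) surv[[i]]$score <- sc[i]
  list(survivors = surv, counts = counts)
}
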