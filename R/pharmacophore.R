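#' @title Pharmacophore model construction
#' @description
#' Surviving fragments are converted into six types of pharmacophoric
#' features (H-bond donor HBD, acceptor HBA, positive/negative ionizable
#' Pos/Neg, aromatic Ar, hydrophobic-aliphatic Hyd), clustered per type by
#' k-means under a 3 A maximum member-distance (diameter) constraint,
#' ranked by cluster size, and assembled into an exportable query.
#' @name pharmacophore
NULL

pharm_types <- c("HBD", "HBA", "Pos", "Neg", "Ar", "Hyd")

#' Perceive pharmacophoric features on a fragment
#'
#' Placement rules: one Ar feature at each aromatic-ring centroid; one Hyd
#' feature at the centroid of each connected group of purely aliphatic
#' carbons; HBD/HBA on each qualifying atom; Pos on each positive
#' ionizable atom; Neg at the centroid of each negative ionizable group
#' (e.g. the two carboxylate oxygens yield one feature).
#'
#' @param fragment A [frase_mol()] with connectivity.
#' @param source Provenance string recorded on each feature.
#' @return data.frame with columns `ftype`, `x`, `y`, `z`, `source`
#'   (zero rows for a featureless fragment).
#' @export
perceive_features <- function(fragment, source = "fragment") {
  M <- assign_ligand_atom_types(fragment)
  at <- fragment$atoms
  feats <- list()
  add <- function(ftype, xyz) {
    feats[[length(feats) + 1]] <<- data.frame(
      ftype = ftype, x = xyz[1], y = xyz[2], z = xyz[3], source = source,
      stringsAsFactors = FALSE)
  }
  usable <- at$element != "H" & !at$is_alpha

  for (r in aromatic_rings(fragment)) {
    add("Ar", colMeans(as.matrix(at[r, c("x", "y", "z")])))
  }
  for (i in which(usable & M[, "H-bond Donor"])) {
    add("HBD", as.numeric(at[i, c("x", "y", "z")]))
  }
  for (i in which(usable & M[, "H-bond Acceptor"])) {
    add("HBA", as.numeric(at[i, c("x", "y", "z")]))
  }
  for (i in which(usable & M[, "Positive Ionizable"])) {
    add("Pos", as.numeric(at[i, c("x", "y", "z")]))
  }
  # negative ionizable atoms grouped by their attached central atom
  negs <- which(usable & M[, "Negative Ionizable"])
  if (length(negs)) {
    grp <- vapply(negs, function(i) {
      nb <- atom_neighbours(fragment, i)
      ctr <- nb$idx[at$element[nb$idx] %in% c("C", "P", "S", "N")]
      as.integer(if (length(ctr)) min(ctr) else i)
    }, 1L)
    for (g in unique(grp)) {
      add("Neg", colMeans(as.matrix(at[negs[grp == g], c("x", "y", "z"),
                                       drop = FALSE])))
    }
  }
  # hydrophobic: connected groups of aliphatic carbons carrying no polar type
  polar <- M[, "H-bond Donor"] | M[, "H-bond Acceptor"] |
    M[, "Positive Ionizable"] | M[, "Negative Ionizable"]
  hyd <- which(usable & M[, "Aliphatic Carbon"] & !polar)
  if (length(hyd)) {
    g <- mol_graph(fragment)
    sub <- igraph::induced_subgraph(g, hyd)
    comp <- igraph::components(sub)$membership
    orig <- as.integer(igraph::V(sub)$name)
    for (cid in unique(comp)) {
      add("Hyd", colMeans(as.matrix(at[orig[comp == cid], c("x", "y", "z"),
                                       drop = FALSE])))
    }
  }
  if (length(feats) == 0) {
    return(data.frame(ftype = character(), x = numeric(), y = numeric(),
                      z = numeric(), source = character()))
  }
  do.call(rbind, feats)
}

# max pairwise distance within a coordinate block
cluster_diameter <- function(xyz) {
  if (nrow(xyz) < 2) return(0)
  max(stats::dist(xyz))
}

#' Cluster pharmacophoric features under a diameter bound
#'
#' Features are clustered independently per type on their 3D coordinates.
#' For each type, k-means is run with k increasing from 1 (10 restarts per
#' k, seeded) until every cluster's maximum member-member distance is at
#' most `max_diameter`. Clusters are ranked by size (descending), ties
#' broken by compactness (smaller mean distance to centroid first).
#'
#' @param features Feature data.frame from [perceive_features()] (rows
#'   from several fragments may be concatenated).
#' @param max_diameter Diameter bound in Angstrom (default 3.0).
#' @param seed Integer seed making the clustering reproducible.
#' @return data.frame of clusters: `cluster_id`, `ftype`, `size`, `x`,
#'   `y`, `z` (centroid), `compactness`; the assignment of each input
#'   feature is in `attr(, "membership")` (cluster_id per feature row).
#' @export
cluster_features <- function(features, max_diameter = 3.0, seed = 1) {
  stopifnot(nrow(features) > 0)
  membership <- integer(nrow(features))
  rows <- list()
  next_id <- 0L
  for (ft in unique(features$ftype)) {
    sel <- which(features$ftype == ft)
    xyz <- as.matrix(features[sel, c("x", "y", "z"), drop = FALSE])
    uniq <- unique(round(xyz, 9))
    assign_local <- NULL
    for (k in seq_len(nrow(xyz))) {
      if (k >= nrow(uniq)) {
        # one cluster per distinct point; diameter 0 by construction
        assign_local <- match(
          apply(round(xyz, 9), 1, paste, collapse = ","),
          apply(uniq, 1, paste, collapse = ","))
        break
      }
      set.seed(seed + k)
      km <- stats::kmeans(xyz, centers = k, nstart = 10, iter.max = 100)
      diam_ok <- all(vapply(seq_len(k), function(cl)
        cluster_diameter(xyz[km$cluster == cl, , drop = FALSE]) <=
          max_diameter + 1e-9, TRUE))
      if (diam_ok) { assign_local <- km$cluster; break }
    }
    for (cl in sort(unique(assign_local))) {
      next_id <- next_id + 1L
      mem <- sel[assign_local == cl]
      cxyz <- colMeans(as.matrix(features[mem, c("x", "y", "z"), drop = FALSE]))
      dctr <- sqrt(rowSums(sweep(as.matrix(
        features[mem, c("x", "y", "z"), drop = FALSE]), 2, cxyz)^2))
      membership[mem] <- next_id
      rows[[next_id]] <- data.frame(
        cluster_id = next_id, ftype = ft, size = length(mem),
        x = cxyz[1], y = cxyz[2], z = cxyz[3],
        compactness = mean(dctr), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$size, out$compactness, out$cluster_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "membership") <- membership
  out
}

#' Assemble a pharmacophore query from selected clusters
#'
#' The selection is an explicit user choice (e.g. the centroids adjacent
#' to a pocket of interest); each selected centroid becomes one typed
#' query feature with the given tolerance radius.
#'
#' @param clusters Cluster table from [cluster_features()].
#' @param selected_ids `cluster_id` values to retain (>= 1 required).
#' @param tolerance Feature tolerance radius in Angstrom (default 1.5,
#'   half the cluster diameter bound).
#' @return Object of class `pharm_query`: data.frame with `ftype`, `x`,
#'   `y`, `z`, `radius`, `cluster_id`.
#' @export
build_query <- function(clusters, selected_ids, tolerance = 1.5) {
  if (length(selected_ids) == 0) stop("build_query: select at least one cluster")
  miss <- setdiff(selected_ids, clusters$cluster_id)
  if (length(miss)) stop("build_query: unknown cluster id(s): ",
                         paste(miss, collapse = ", "))
  sel <- clusters[match(selected_ids, clusters$cluster_id), , drop = FALSE]
  q <- data.frame(ftype = sel$ftype, x = sel$x, y = sel$y, z = sel$z,
                  radius = tolerance, cluster_id = sel$cluster_id,
                  stringsAsFactors = FALSE)
  rownames(q) <- NULL
  class(q) <- c("pharm_query", "data.frame")
  q
}

#' Export / import a pharmacophore query
#'
#' JSON (canonical schema: type, x, y, z, radius) or a simple line-based
#' interchange text format (`type x y z radius`). Round-trip lossless.
#'
#' @param query A [build_query()] result.
#' @param path Output path.
#' @param format `"json"` or `"txt"`.
#' @return `read_query` returns the restored `pharm_query`.
#' @export
export_query <- function(query, path, format = c("json", "txt")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      lapply(seq_len(nrow(query)), function(i) list(
        type = query$ftype[i], x = query$x[i], y = query$y[i],
        z = query$z[i], radius = query$radius[i])),
      path, digits = NA, auto_unbox = TRUE)
  } else {
    writeLines(sprintf("%s %.6f %.6f %.6f %.3f", query$ftype, query$x,
                       query$y, query$z, query$radius), path)
  }
  invisible(path)
}

#' @rdname export_query
#' @export
read_query <- function(path, format = c("json", "txt")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    q <- data.frame(ftype = obj$type, x = obj$x, y = obj$y, z = obj$z,
                    radius = obj$radius, stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(readLines(path), " +")
    m <- do.call(rbind, parts)
    q <- data.frame(ftype = m[, 1], x = as.numeric(m[, 2]),
                    y = as.numeric(m[, 3]), z = as.numeric(m[, 4]),
                    radius = as.numeric(m[, 5]), stringsAsFactors = FALSE)
  }
  class(q) <- c("pharm_query", "data.frame")
  q
}
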