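#' @title Nativeness scoring
#' @description
#' A FRASE is featurized into a 377-element interaction fingerprint: for
#' every (ligand type m, protein type n) pair, the sum over all ligand
#' atom i / protein atom j pairs of delta(m,i) * delta(n,j) * w(d_ij),
#' where w(d) = exp(-(d - 3)^2) for d <= 10 A and 0 beyond. A small dense
#' network (377 -> 32 ReLU -> 16 ReLU -> 1 sigmoid, Adam, binary
#' cross-entropy) is trained to separate true FRASEs from decoys obtained
#' by shuffling fragments between FRASEs; its sigmoid output is the
#' nativeness score.
#' @name nativeness
NULL

#' Gaussian distance weight
#'
#' `w(d) = exp(-(d - optimum)^2)` for `d <= cutoff`, 0 beyond. Maximal at
#' the 3 A interaction optimum and strictly decreasing towards the 10 A
#' cutoff.
#'
#' @param d Distances in Angstrom (vector or matrix).
#' @param optimum Optimum distance (default 3).
#' @param cutoff Hard cutoff (default 10).
#' @return Weights of the same shape as `d`.
#' @export
distance_weight <- function(d, optimum = 3, cutoff = 10) {
  w <- exp(-(d - optimum)^2)
  w[d > cutoff] <- 0
  w
}

#' Interaction fingerprint of a FRASE
#'
#' Distance-weighted sum of typed ligand-protein atom pairs, flattened in
#' ligand-type-major order: element `l = (m - 1) * 13 + n` corresponds to
#' ligand type `m` and protein type `n`, so the vector has 29 x 13 = 377
#' named elements. Multi-typed atoms contribute to every matching element;
#' hydrogens and alpha markers contribute nothing.
#'
#' @param frase A `frase`.
#' @param optimum,cutoff Distance-weight parameters in Angstrom.
#' @param hard_count If `TRUE`, use the unweighted 5 A contact-count
#'   variant (each pair within `hard_cutoff` counts 1) instead of the
#'   Gaussian weight.
#' @param hard_cutoff Cutoff for the hard-count variant (default 5).
#' @return Named numeric vector of length 377, all entries >= 0.
#' @export
interaction_fingerprint <- function(frase, optimum = 3, cutoff = 10,
                                    hard_count = FALSE, hard_cutoff = 5) {
  lv <- ligand_type_vocab(); pv <- protein_type_vocab()
  L <- assign_ligand_atom_types(frase$fragment)
  P <- assign_protein_atom_types(frase$environment)
  keepl <- frase$fragment$atoms$element != "H" & !frase$fragment$atoms$is_alpha
  keepp <- frase$environment$element != "H"
  L <- L[keepl, , drop = FALSE]
  P <- P[keepp, , drop = FALSE]
  lxyz <- as.matrix(frase$fragment$atoms[keepl, c("x", "y", "z"), drop = FALSE])
  pxyz <- as.matrix(frase$environment[keepp, c("x", "y", "z"), drop = FALSE])
  nm <- as.vector(t(outer(lv, pv, paste, sep = " | ")))
  if (nrow(L) == 0 || nrow(P) == 0) {
    return(stats::setNames(numeric(length(lv) * length(pv)), nm))
  }
  d2 <- outer(rowSums(lxyz^2), rowSums(pxyz^2), "+") - 2 * lxyz %*% t(pxyz)
  d <- sqrt(pmax(d2, 0))
  W <- if (hard_count) (d <= hard_cutoff) * 1 else distance_weight(d, optimum, cutoff)
  Fmat <- t(L * 1) %*% W %*% (P * 1)   # 29 x 13
  stats::setNames(as.vector(t(Fmat)), nm)
}

#' Generate decoy FRASEs by fragment shuffling
#'
#' For each true FRASE, `multiplicity` decoys are built by pairing its
#' environment with a fragment drawn uniformly from a different FRASE; the
#' foreign fragment is rigidly translated so its centroid coincides with
#' the native fragment's centroid (optionally also randomly rotated).
#'
#' @param frases List of true `frase` objects (>= 2 with distinct
#'   fragments).
#' @param multiplicity Decoys per true FRASE (default 2).
#' @param seed Integer seed; the decoy set is reproducible under it.
#' @param rotate If `TRUE`, apply a uniform random rotation about the
#'   centroid as well (default `FALSE`).
#' @return List of `frase` objects labeled `"decoy"`.
#' @export
generate_decoys <- function(frases, multiplicity = 2, seed = 1, rotate = FALSE) {
  n <- length(frases)
  if (n < 2) stop("generate_decoys: need at least 2 frases")
  sig <- vapply(frases, function(f) paste(
    f$fragment$atoms$element, round(f$fragment$atoms$x, 3),
    round(f$fragment$atoms$y, 3), round(f$fragment$atoms$z, 3),
    collapse = ";"), "")
  if (length(unique(sig)) < 2) {
    stop("generate_decoys: all fragments are identical; shuffling is meaningless")
  }
  set.seed(seed)
  cent <- function(mol) colMeans(as.matrix(
    mol$atoms[mol$atoms$element != "H", c("x", "y", "z"), drop = FALSE]))
  out <- list()
  for (i in seq_len(n)) {
    pool <- setdiff(seq_len(n), i)
    donors <- pool[sample.int(length(pool), multiplicity,
                              replace = multiplicity > length(pool))]
    for (j in donors) {
      frag <- frases[[j]]$fragment
      shift <- cent(frases[[i]]$fragment) - cent(frag)
      R <- if (rotate) random_rotation() else diag(3)
      frag2 <- apply_transform_mol(frag, diag(3), shift)
      if (rotate) {
        c0 <- cent(frag2)
        frag2 <- apply_transform_mol(frag2, R, c0 - as.vector(c0 %*% t(R)))
      }
      out[[length(out) + 1]] <- new_frase(
        frag2, frases[[i]]$environment, label = "decoy",
        provenance = paste0(frases[[i]]$provenance, "+frag:",
                            frases[[j]]$id %||% j),
        id = sprintf("D%05d", length(out) + 1L))
    }
  }
  out
}

# uniform random rotation matrix (QR of a Gaussian matrix, det corrected)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# ---- dense network: 377 -> h1 ReLU -> h2 ReLU -> 1 sigmoid ------------------

mlp_init <- function(n_in, hidden = c(32, 16), seed = 1) {
  set.seed(seed)
  dims <- c(n_in, hidden, 1)
  layers <- list()
  for (k in seq_len(length(dims) - 1)) {
    layers[[k]] <- list(
      W = matrix(stats::rnorm(dims[k] * dims[k + 1], sd = sqrt(2 / dims[k])),
                 dims[k], dims[k + 1]),
      b = rep(0, dims[k + 1]))
  }
  layers
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  nl <- length(layers)
  for (k in seq_len(nl)) {
    Z <- sweep(acts[[k]] %*% layers[[k]]$W, 2, layers[[k]]$b, "+")
    acts[[k + 1]] <- if (k < nl) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  acts
}

# one Adam step on a minibatch; returns updated layers + moments
mlp_step <- function(layers, mstate, X, y, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, t = 1) {
  acts <- mlp_forward(layers, X)
  nl <- length(layers)
  nb <- nrow(X)
  # BCE with sigmoid output: dZ_out = (p - y) / n
  delta <- (acts[[nl + 1]] - y) / nb
  for (k in nl:1) {
    gW <- t(acts[[k]]) %*% delta
    gb <- colSums(delta)
    if (k > 1) {
      delta <- (delta %*% t(layers[[k]]$W)) * (acts[[k]] > 0)
    }
    for (nm in c("W", "b")) {
      g <- if (nm == "W") gW else gb
      mstate[[k]][[nm]]$m <- beta1 * mstate[[k]][[nm]]$m + (1 - beta1) * g
      mstate[[k]][[nm]]$v <- beta2 * mstate[[k]][[nm]]$v + (1 - beta2) * g^2
      mhat <- mstate[[k]][[nm]]$m / (1 - beta1^t)
      vhat <- mstate[[k]][[nm]]$v / (1 - beta2^t)
      layers[[k]][[nm]] <- layers[[k]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, mstate = mstate)
}

#' Train the nativeness classifier
#'
#' Featurizes true FRASEs and decoys, z-scales features (parameters stored
#' with the model), holds out a random fraction for accuracy reporting,
#' and trains the dense network with Adam on binary cross-entropy.
#' Fully deterministic under `seed`.
#'
#' @param true_frases,decoys Lists of `frase` objects.
#' @param hidden Hidden layer sizes (default `c(32, 16)`).
#' @param epochs Training epochs (default 500).
#' @param batch_size Minibatch size (default 50).
#' @param lr Adam learning rate (default 1e-3).
#' @param holdout Fraction held out for the accuracy report (default 0.1).
#' @param seed Integer seed.
#' @param fingerprints Optional precomputed feature matrix
#'   (rows = c(true, decoys)) to skip featurization.
#' @param labels Optional 0/1 vector overriding the class labels implied
#'   by the two lists (requires `fingerprints`); used e.g. for
#'   label-permutation null checks.
#' @return Object of class `nativeness_model`: layers, scaler, config and
#'   `holdout_accuracy`.
#' @export
train_model <- function(true_frases = NULL, decoys = NULL, hidden = c(32, 16),
                        epochs = 500, batch_size = 50, lr = 1e-3,
                        holdout = 0.1, seed = 1, fingerprints = NULL,
                        labels = NULL) {
  if (is.null(labels) && (length(true_frases) == 0 || length(decoys) == 0)) {
    stop("train_model: both classes must be non-empty")
  }
  X <- if (!is.null(fingerprints)) fingerprints else
    t(vapply(c(true_frases, decoys), interaction_fingerprint,
             numeric(length(ligand_type_vocab()) * length(protein_type_vocab()))))
  y <- if (!is.null(labels)) {
    if (is.null(fingerprints)) stop("train_model: labels require fingerprints")
    stopifnot(length(labels) == nrow(X), all(labels %in% c(0, 1)),
              any(labels == 0), any(labels == 1))
    labels
  } else c(rep(1, length(true_frases)), rep(0, length(decoys)))
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")

  set.seed(seed)
  n <- nrow(Xs)
  ho <- sample(n, max(1, round(holdout * n)))
  Xtr <- Xs[-ho, , drop = FALSE]; ytr <- y[-ho]
  Xho <- Xs[ho, , drop = FALSE]; yho <- y[ho]

  layers <- mlp_init(ncol(Xs), hidden, seed = seed + 1)
  mstate <- lapply(layers, function(l) list(
    W = list(m = l$W * 0, v = l$W * 0), b = list(m = l$b * 0, v = l$b * 0)))
  t_adam <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample(nrow(Xtr))
    starts <- seq(1, length(ord), by = batch_size)
    for (s in starts) {
      bi <- ord[s:min(s + batch_size - 1, length(ord))]
      t_adam <- t_adam + 1
      st <- mlp_step(layers, mstate, Xtr[bi, , drop = FALSE],
                     matrix(ytr[bi], ncol = 1), lr, t = t_adam)
      layers <- st$layers; mstate <- st$mstate
      if (!all(vapply(layers, function(l) all(is.finite(l$W)), TRUE))) {
        stop("train_model: non-finite weights during training")
      }
    }
  }
  pho <- mlp_forward(layers, Xho)[[length(layers) + 1]]
  acc <- mean((pho > 0.5) == (yho == 1))
  structure(list(layers = layers, mu = mu, sigma = sg,
                 config = list(hidden = hidden, epochs = epochs,
                               batch_size = batch_size, lr = lr, seed = seed),
                 holdout_accuracy = acc),
            class = "nativeness_model")
}

#' @export
print.nativeness_model <- function(x, ...) {
  cat("nativeness_model:", paste(c(length(x$mu), x$config$hidden, 1),
                                 collapse = "-"),
      sprintf("net, held-out accuracy %.3f\n", x$holdout_accuracy))
  invisible(x)
}

#' Score FRASEs with a trained nativeness model
#'
#' @param model A `nativeness_model`.
#' @param frases A single `frase` or a list of them; alternatively pass a
#'   precomputed fingerprint matrix via `fingerprints`.
#' @param fingerprints Optional numeric matrix (rows = FRASEs).
#' @return Numeric vector of nativeness scores in (0, 1).
#' @export
score_frases <- function(model, frases = NULL, fingerprints = NULL) {
  X <- if (!is.null(fingerprints)) {
    if (is.null(dim(fingerprints))) matrix(fingerprints, nrow = 1) else fingerprints
  } else {
    if (inherits(frases, "frase")) frases <- list(frases)
    t(vapply(frases, interaction_fingerprint, numeric(length(model$mu))))
  }
  if (ncol(X) != length(model$mu)) {
    stop("score_frases: fingerprint length ", ncol(X),
         " does not match model input ", length(model$mu))
  }
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sigma, "/")
  as.vector(mlp_forward(model$layers, Xs)[[length(model$layers) + 1]])
}

#' Serialize / load a nativeness model as JSON
#'
#' Stores configuration, scaler and weights in one portable text file.
#'
#' @param model A `nativeness_model`.
#' @param path File path.
#' @return `read_model` returns the restored `nativeness_model`.
#' @export
write_model <- function(model, path) {
  obj <- list(config = model$config, mu = model$mu, sigma = model$sigma,
              holdout_accuracy = model$holdout_accuracy,
              layers = lapply(model$layers, function(l)
                list(W = as.vector(l$W), dim = dim(l$W), b = l$b)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) unlist(x, use.names = FALSE)
  layers <- lapply(obj$layers, function(l)
    list(W = matrix(num(l$W), num(l$dim)[1], num(l$dim)[2]), b = num(l$b)))
  cfg <- obj$config
  cfg$hidden <- num(cfg$hidden)
  structure(list(layers = layers, mu = num(obj$mu), sigma = num(obj$sigma),
                 config = cfg,
                 holdout_accuracy = num(obj$holdout_accuracy)),
            class = "nativeness_model")
}
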