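#' Connectome objects
#'
#' A connectome is the weighted multigraph of neural fibers between `E`
#' cortical regions: a symmetric nonnegative matrix `weights` of fiber
#' densities (dimensionless, zero diagonal) and a symmetric matrix
#' `distances` of inter-region Euclidean distances in millimetres.
#' Optionally it carries region `labels` and `homotopic_pairs`, a perfect
#' matching of left/right mirror regions used to tie local couplings.
#'
#' @param weights E x E symmetric nonnegative matrix, zero diagonal.
#' @param distances E x E symmetric nonnegative matrix (mm), zero diagonal.
#' @param labels optional character vector of E region names.
#' @param homotopic_pairs optional 2-column integer matrix, each row one
#'   (left, right) pair; together the rows must cover every region exactly
#'   once.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, distances, labels = NULL,
                       homotopic_pairs = NULL) {
  check_square(weights, "weights")
  check_square(distances, "distances")
  if (!identical(dim(weights), dim(distances)))
    stop("weights are ", nrow(weights), "x", ncol(weights),
         " but distances are ", nrow(distances), "x", ncol(distances))
  E <- nrow(weights)
  check_sym_nonneg(weights, "weights")
  check_sym_nonneg(distances, "distances")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != E) stop("need ", E, " labels, got ", length(labels))
  }
  if (!is.null(homotopic_pairs)) {
    homotopic_pairs <- as.matrix(homotopic_pairs)
    storage.mode(homotopic_pairs) <- "integer"
    if (ncol(homotopic_pairs) != 2L || nrow(homotopic_pairs) != E / 2L ||
        !setequal(as.vector(homotopic_pairs), seq_len(E)) ||
        anyDuplicated(as.vector(homotopic_pairs)))
      stop("homotopic_pairs must be a perfect matching over the ", E,
           " region indices")
  }
  structure(list(n_regions = E, weights = unname(weights),
                 distances = unname(distances), labels = labels,
                 homotopic_pairs = homotopic_pairs),
            class = "connectome")
}

check_square <- function(m, name) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("'", name, "' must be a numeric matrix")
  if (nrow(m) != ncol(m))
    stop("'", name, "' is not square: ", nrow(m), "x", ncol(m))
  invisible(m)
}

check_sym_nonneg <- function(m, name) {
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite ", name, " entry at (", bad[1, 1], ",", bad[1, 2], ")")
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("negative ", name, " entry at (", bad[1, 1], ",", bad[1, 2], "): ",
         m[bad[1, , drop = FALSE]])
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("'", name, "' must be symmetric")
  if (any(diag(m) != 0))
    stop("'", name, "' must have a zero diagonal")
  invisible(m)
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", x$n_regions, " regions, ",
      sum(upper_tri_vec(x$weights) > 0), " edges",
      if (!is.null(x$homotopic_pairs)) ", homotopic pairing" else "",
      "\n", sep = "")
  invisible(x)
}

#' Load a connectome from delimited-text matrix files
#'
#' Reads fiber-density weights and Euclidean distances (mm) from plain-text
#' square matrices. The raw weight matrix `W` is made symmetric by averaging
#' with its transpose, `(W + t(W))/2`, and its diagonal is zeroed; distances
#' are treated the same way. A JSON sidecar (written by [write_connectome()])
#' holding labels and homotopic pairing is picked up automatically when
#' present next to the weights file.
#'
#' @param weights_path path to the weights matrix file.
#' @param distances_path path to the distances matrix file.
#' @param sidecar_path optional explicit path to the JSON sidecar; default
#'   looks for `<weights_path>.json`.
#' @return a [connectome()].
#' @export
load_connectome <- function(weights_path, distances_path,
                            sidecar_path = NULL) {
  W <- read_matrix_text(weights_path)
  D <- read_matrix_text(distances_path)
  check_square(W, "weights")
  check_square(D, "distances")
  if (!identical(dim(W), dim(D)))
    stop("size mismatch: weights ", nrow(W), "x", ncol(W),
         " vs distances ", nrow(D), "x", ncol(D))
  for (nm in c("weights", "distances")) {
    m <- if (nm == "weights") W else D
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-finite ", nm, " entry at (", bad[1, 1], ",", bad[1, 2], ")")
    bad <- which(m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("negative ", nm, " entry at (", bad[1, 1], ",", bad[1, 2], ")")
  }
  W <- (W + t(W)) / 2; diag(W) <- 0
  D <- (D + t(D)) / 2; diag(D) <- 0
  labels <- NULL; pairs <- NULL
  if (is.null(sidecar_path)) {
    cand <- paste0(weights_path, ".json")
    if (file.exists(cand)) sidecar_path <- cand
  }
  if (!is.null(sidecar_path) && file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    labels <- side$labels
    if (!is.null(side$homotopic_pairs))
      pairs <- matrix(as.integer(side$homotopic_pairs), ncol = 2L)
  }
  connectome(W, D, labels = labels, homotopic_pairs = pairs)
}

#' Write a connectome to delimited-text matrix files
#'
#' Emits weights and distances with 9 significant digits plus a JSON sidecar
#' (`<weights_path>.json`) with labels and homotopic pairing when present.
#'
#' @param c a [connectome()].
#' @param weights_path,distances_path output file paths.
#' @return invisibly, the weights path.
#' @export
write_connectome <- function(c, weights_path, distances_path) {
  stopifnot(inherits(c, "connectome"))
  write_matrix_text(c$weights, weights_path)
  write_matrix_text(c$distances, distances_path)
  if (!is.null(c$labels) || !is.null(c$homotopic_pairs)) {
    side <- list()
    if (!is.null(c$labels)) side$labels <- c$labels
    if (!is.null(c$homotopic_pairs))
      side$homotopic_pairs <- c$homotopic_pairs
    jsonlite::write_json(side, paste0(weights_path, ".json"),
                         auto_unbox = FALSE)
  }
  invisible(weights_path)
}

#' Normalize connectome weights
#'
#' Rescales fiber densities so that the network has unit average connection
#' weight. With `method = "edge"` (the default) the mean of the nonzero
#' off-diagonal upper-triangle weights becomes 1; with `method = "degree"`
#' the mean row sum (average weighted degree) becomes 1. The zero pattern
#' and symmetry are preserved, and the operation is idempotent.
#'
#' @param c a [connectome()].
#' @param method `"edge"` (mean nonzero edge weight 1) or `"degree"` (mean
#'   row-sum 1).
#' @return the rescaled [connectome()].
#' @export
normalize_weights <- function(c, method = c("edge", "degree")) {
  stopifnot(inherits(c, "connectome"))
  method <- match.arg(method)
  W <- c$weights
  ut <- upper_tri_vec(W)
  if (all(ut == 0)) stop("cannot normalize an all-zero weight matrix")
  scale <- switch(method,
    edge = mean(ut[ut > 0]),
    degree = mean(rowSums(W)))
  c$weights <- W / scale
  c
}

#' Synthesize a hemispherically symmetric connectome
#'
#' Generates a stand-in anatomical network for testing and desk-scale
#' experiments (it substitutes for tractography-derived connectomes, which
#' are outside the package's scope). `E/2` region barycenters are drawn
#' uniformly in one half of a 140 x 180 x 120 mm bounding box and mirrored
#' across the midsagittal plane, giving homotopic pairs `(i, i + E/2)`.
#' Weights decay exponentially with distance (length scale 40 mm) with
#' multiplicative log-normal jitter, are symmetrized, the weakest 20% of
#' edges are pruned, and the result is passed through [normalize_weights()].
#' Distances are exact pairwise Euclidean distances.
#'
#' @param E even number of regions, at least 4.
#' @param seed integer seed; output is a deterministic function of `(E, seed)`.
#' @param jitter_sd standard deviation of the log-normal weight jitter on the
#'   log scale.
#' @param prune_frac fraction of weakest edges set to zero.
#' @return a [connectome()] with labels and `homotopic_pairs`.
#' @export
synthesize_connectome <- function(E, seed = 1L, jitter_sd = 0.5,
                                  prune_frac = 0.2) {
  if (length(E) != 1L || E != round(E) || E < 4L || E %% 2L != 0L)
    stop("'E' must be an even integer >= 4")
  E <- as.integer(E)
  half <- E %/% 2L
  with_seed(seed, {
    # left-hemisphere barycenters; x is the lateral axis, midline at x = 70
    xyz <- cbind(runif(half, 5, 65), runif(half, 0, 180), runif(half, 0, 120))
    mirrored <- xyz
    mirrored[, 1] <- 140 - mirrored[, 1]
    pos <- rbind(xyz, mirrored)
    D <- as.matrix(stats::dist(pos))
    W <- exp(-D / 40) * exp(matrix(rnorm(E * E, sd = jitter_sd), E, E))
    W <- (W + t(W)) / 2
    diag(W) <- 0
    ut <- upper_tri_vec(W)
    thr <- quantile(ut, prune_frac)
    W[W <= thr] <- 0
    dimnames(W) <- dimnames(D) <- NULL
    labels <- c(paste0("region", seq_len(half), "_L"),
                paste0("region", seq_len(half), "_R"))
    cn <- connectome(W, D, labels = labels,
                     homotopic_pairs = cbind(seq_len(half), half + seq_len(half)))
    normalize_weights(cn)
  })
}

#' Interaction delays from distances and conduction velocity
#'
#' Converts inter-region Euclidean distances (mm) into spike-propagation
#' delays `tau = D / v` in seconds, with `v` in m/s. `v = Inf` is the
#' zero-delay (instantaneous coupling) sentinel.
#'
#' @param c a [connectome()].
#' @param v spike-propagation velocity in m/s, or `Inf` for no delays.
#' @return an E x E symmetric matrix of delays in seconds (zero diagonal).
#' @export
compute_delays <- function(c, v) {
  stopifnot(inherits(c, "connectome"))
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
    stop("'v' must be a positive velocity in m/s (Inf for zero delays)")
  if (is.infinite(v))
    return(matrix(0, c$n_regions, c$n_regions))
  (c$distances / 1000) / v
}
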