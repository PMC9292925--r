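#' Construct a voxel map
#'
#' Container for per-subject feature maps on a regular voxel lattice:
#' typically log-normalized current density per frequency band.
#'
#' @param values numeric array, subjects x voxels x bands (a subjects x
#'   voxels matrix is promoted to a single-band array).
#' @param coords_mm numeric matrix, voxels x 3, lattice coordinates in mm.
#' @param band_names character vector, one per band slab.
#' @param subject_ids character vector, one per subject row.
#' @param spacing_mm lattice spacing in mm (default 5).
#' @param normalized logical flag: values are log fractions of total density
#'   (output of [normalize_log_map()]).
#' @return A `voxel_map` list.
#' @export
voxel_map <- function(values, coords_mm, band_names = NULL, subject_ids = NULL,
                      spacing_mm = 5, normalized = FALSE) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L)
  coords_mm <- as.matrix(coords_mm)
  if (ncol(coords_mm) != 3L || nrow(coords_mm) != dim(values)[2]) {
    stop("coords_mm must be voxels x 3 and match the values array", call. = FALSE)
  }
  if (anyDuplicated(as.data.frame(coords_mm))) {
    stop("voxel coordinates must be unique", call. = FALSE)
  }
  if (is.null(band_names)) band_names <- paste0("band", seq_len(dim(values)[3]))
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(dim(values)[1]))
  stopifnot(
    length(band_names) == dim(values)[3],
    length(subject_ids) == dim(values)[1]
  )
  structure(
    list(
      values = values, coords_mm = coords_mm,
      band_names = as.character(band_names),
      subject_ids = as.character(subject_ids),
      spacing_mm = spacing_mm, normalized = normalized
    ),
    class = "voxel_map"
  )
}

band_index <- function(map, band) {
  if (is.numeric(band)) return(as.integer(band))
  i <- match(band, map$band_names)
  if (is.na(i)) stop("unknown band: ", band, call. = FALSE)
  i
}

#' Extract a subjects x voxels matrix for one band
#' @param map a `voxel_map`.
#' @param band band name or index.
#' @return numeric matrix.
#' @export
band_matrix <- function(map, band) {
  map$values[, , band_index(map, band), drop = TRUE]
}

# column-standardize; constant columns -> all-zero with attribute
standardize_cols <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  const <- s <= 0 | !is.finite(s)
  s[const] <- 1
  out <- sweep(Xc, 2, s, "/")
  out[, const] <- 0
  attr(out, "constant") <- const
  out
}

#' Voxelwise Pearson correlation map
#'
#' Correlates each voxel's values across subjects with a behavioural score;
#' this equals the standardized slope of the simple regression of the map on
#' the score. Constant voxels get r = 0 and are flagged.
#'
#' @param map a `voxel_map`.
#' @param scores numeric vector, one per subject (aligned with
#'   `map$subject_ids`).
#' @param band band name or index (default first band).
#' @param score_name label stored in the result.
#' @return A `stat_map` list: `r` (per voxel), `band`, `score_name`,
#'   `n_subjects`, `constant_voxels` (logical), plus the map's coords.
#' @export
voxelwise_correlation <- function(map, scores, band = 1L, score_name = "score") {
  X <- band_matrix(map, band)
  n <- nrow(X)
  if (length(scores) != n) stop("scores must align with map subjects", call. = FALSE)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(scores) == 0) stop("scores are constant", call. = FALSE)
  Xs <- standardize_cols(X)
  s <- as.numeric(scale(scores))
  r <- as.numeric(crossprod(Xs, s)) / (n - 1)
  structure(
    list(
      r = r, band = map$band_names[band_index(map, band)],
      score_name = score_name, n_subjects = n,
      constant_voxels = attr(Xs, "constant"),
      coords_mm = map$coords_mm, spacing_mm = map$spacing_mm
    ),
    class = "stat_map"
  )
}

#' Max-statistic permutation correction
#'
#' Family-wise error control over all voxels by the randomization method:
#' subject labels of the score vector are permuted; for each permutation the
#' maximum of |r| across voxels is recorded; the critical value is the
#' empirical (1 - alpha) quantile of that null max distribution, and each
#' voxel's corrected p is `(1 + #{permutation max >= |r_obs|}) / (B + 1)`
#' (two-sided, observed statistic included so p > 0).
#'
#' @param map a `voxel_map`.
#' @param scores per-subject score vector.
#' @param band band name or index.
#' @param n_permutations number of random permutations (default 5000).
#' @param alpha FWER level (default 0.05).
#' @param seed optional integer seed for the permutation stream.
#' @param score_name label.
#' @return A `permutation_result` list: `stat_map`, `null_max`, `critical_r`
#'   (type-1 empirical quantile), `corrected_p`, `n_permutations`, `alpha`,
#'   `seed`.
#' @export
permutation_correct <- function(map, scores, band = 1L, n_permutations = 5000,
                                alpha = 0.05, seed = NULL, score_name = "score") {
  if (n_permutations < 99) stop("n_permutations must be >= 99", call. = FALSE)
  if (1 / (n_permutations + 1) > alpha) {
    warning("n_permutations too small to resolve alpha = ", alpha,
            "; minimum attainable p is ", signif(1 / (n_permutations + 1), 3))
  }
  sm <- voxelwise_correlation(map, scores, band, score_name)
  X <- band_matrix(map, band)
  n <- nrow(X)
  Xs <- standardize_cols(X)
  s <- as.numeric(scale(scores))
  if (!is.null(seed)) set.seed(seed)
  perm_idx <- vapply(seq_len(n_permutations), function(i) sample.int(n), integer(n))
  S <- matrix(s[perm_idx], nrow = n)
  R <- crossprod(Xs, S) / (n - 1) # voxels x permutations
  null_max <- apply(abs(R), 2, max)
  critical_r <- as.numeric(stats::quantile(null_max, 1 - alpha, type = 1))
  abs_r <- abs(sm$r)
  corrected_p <- (1 + colSums(outer(null_max, abs_r, ">="))) / (n_permutations + 1)
  structure(
    list(
      stat_map = sm, null_max = null_max, critical_r = critical_r,
      corrected_p = corrected_p, n_permutations = n_permutations,
      alpha = alpha, seed = seed
    ),
    class = "permutation_result"
  )
}

neighbour_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  )
  g[keep, , drop = FALSE]
}

#' Extract contiguous supra-threshold clusters
#'
#' Groups voxels with |r| >= threshold into connected components on the
#' lattice (positive and negative voxels clustered separately, so each
#' cluster is sign-homogeneous). Every supra-threshold voxel belongs to
#' exactly one cluster.
#'
#' @param stat a `stat_map` from [voxelwise_correlation()].
#' @param threshold nonnegative |r| cutoff, e.g. the permutation
#'   `critical_r`.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (all diagonal
#'   neighbours, the default notion of "contiguous").
#' @return A tibble, one row per cluster, sorted by size then |peak r|:
#'   `cluster_id`, `band`, `score_name`, `size`, `sign`, `peak_voxel`,
#'   `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `peak_r`, `mean_r`, `min_abs_r`,
#'   `voxel_ids` (list column).
#' @export
find_clusters <- function(stat, threshold, connectivity = 26) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  r <- stat$r
  supra <- which(abs(r) >= threshold & abs(r) > 0)
  empty <- tibble::tibble(
    cluster_id = integer(), band = character(), score_name = character(),
    size = integer(), sign = integer(), peak_voxel = integer(),
    peak_x_mm = numeric(), peak_y_mm = numeric(), peak_z_mm = numeric(),
    peak_r = numeric(), mean_r = numeric(), min_abs_r = numeric(),
    voxel_ids = list()
  )
  if (length(supra) == 0L) return(empty)
  ijk <- round(stat$coords_mm / stat$spacing_mm)
  offs <- neighbour_offsets(connectivity)
  dims_span <- apply(ijk, 2, function(z) diff(range(z))) + 3
  key <- function(m) (m[, 1] - min(ijk[, 1]) + 1) +
    dims_span[1] * ((m[, 2] - min(ijk[, 2]) + 1) +
    dims_span[2] * (m[, 3] - min(ijk[, 3]) + 1))
  labels <- integer(0)
  memb <- integer(0)
  next_label <- 0L
  for (sgn in c(1, -1)) {
    idx <- supra[sign(r[supra]) == sgn]
    if (length(idx) == 0L) next
    keys <- key(ijk[idx, , drop = FALSE])
    edges <- NULL
    for (o in seq_len(nrow(offs))) {
      nb <- key(sweep(ijk[idx, , drop = FALSE], 2, -offs[o, ]))
      hit <- match(nb, keys)
      ok <- which(!is.na(hit))
      if (length(ok)) edges <- rbind(edges, cbind(ok, hit[ok]))
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    labels <- c(labels, comp + next_label)
    memb <- c(memb, idx)
    next_label <- next_label + max(comp)
  }
  rows <- lapply(unique(labels), function(lb) {
    vox <- memb[labels == lb]
    pk <- vox[which.max(abs(r[vox]))]
    tibble::tibble(
      band = stat$band, score_name = stat$score_name,
      size = length(vox), sign = as.integer(sign(r[pk])),
      peak_voxel = pk,
      peak_x_mm = stat$coords_mm[pk, 1],
      peak_y_mm = stat$coords_mm[pk, 2],
      peak_z_mm = stat$coords_mm[pk, 3],
      peak_r = r[pk], mean_r = mean(r[vox]),
      min_abs_r = min(abs(r[vox])),
      voxel_ids = list(sort(vox))
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size, -abs(out$peak_r)), ]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  tibble::as_tibble(out)
}

#' Spherical region-of-interest extraction
#'
#' Selects all voxels within `radius_mm` (inclusive, Euclidean) of a centre
#' coordinate and returns each subject's unweighted mean value over them.
#' On a full 5-mm lattice a 10-mm sphere centred on a voxel contains 33
#' voxels.
#'
#' @param map a `voxel_map`.
#' @param center_mm numeric length-3 coordinate in mm.
#' @param radius_mm sphere radius in mm (default 10).
#' @param band band name or index.
#' @return A list: `voxel_ids` and `values` (named per-subject mean vector).
#' @export
sphere_roi <- function(map, center_mm, radius_mm = 10, band = 1L) {
  stopifnot(length(center_mm) == 3L, radius_mm >= 0)
  d2 <- colSums((t(map$coords_mm) - as.numeric(center_mm))^2)
  ids <- which(d2 <= radius_mm^2 + 1e-9)
  if (length(ids) == 0L) stop("empty ROI: no voxel within radius of centre", call. = FALSE)
  X <- band_matrix(map, band)
  vals <- rowMeans(X[, ids, drop = FALSE])
  names(vals) <- map$subject_ids
  list(voxel_ids = ids, values = vals)
}

#' Cluster table for reporting
#'
#' Joins corrected p-values onto a cluster table (p of the peak voxel).
#'
#' @param clusters tibble from [find_clusters()].
#' @param perm a `permutation_result`.
#' @return The cluster tibble with a `corrected_p` column (peak voxel's).
#' @export
cluster_report <- function(clusters, perm) {
  if (nrow(clusters) == 0L) {
    clusters$corrected_p <- numeric(0)
    return(clusters)
  }
  clusters$corrected_p <- perm$corrected_p[clusters$peak_voxel]
  clusters
}
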