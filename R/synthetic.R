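#' Specify a planted effect cluster
#'
#' A spherical set of lattice voxels whose values carry a subject-level
#' latent neural trait. The latent is driven by one personality trait
#' (path `a`) and drives one behavioural latent (path `b`, the planted
#' behavioural-neural correlation when noise terms keep unit variances).
#'
#' @param center integer triple: lattice index (1-based) of the centre voxel.
#' @param radius_mm sphere radius in mm (default 5: centre + face
#'   neighbours on a 5-mm lattice).
#' @param band band name the effect lives in (default `"delta"`).
#' @param trait personality trait driving the latent (column of the trait
#'   table).
#' @param a personality-to-neural path coefficient.
#' @param behaviour `"rt"` (risk propensity) or `"cov"` (pump variability).
#' @param b neural-to-behaviour path; with default noise this is the planted
#'   correlation between cluster voxels and the behavioural latent.
#' @return A `planted_cluster` list.
#' @export
planted_cluster <- function(center, radius_mm = 5, band = "delta",
                            trait = "extraversion", a = 0.5,
                            behaviour = c("rt", "cov"), b = 0.35) {
  behaviour <- match.arg(behaviour)
  stopifnot(length(center) == 3L, radius_mm >= 0)
  if (!band %in% eeg_bands()$band) stop("unknown band: ", band, call. = FALSE)
  structure(
    list(center = as.integer(center), radius_mm = radius_mm, band = band,
         trait = trait, a = a, behaviour = behaviour, b = b),
    class = "planted_cluster"
  )
}

default_clusters <- function() {
  list(
    acc = planted_cluster(center = c(4, 7, 9), radius_mm = 5, band = "delta",
                          trait = "extraversion", a = 0.5,
                          behaviour = "rt", b = 0.35),
    dlpfc = planted_cluster(center = c(3, 8, 10), radius_mm = 5, band = "delta",
                            trait = "openness", a = 0.5,
                            behaviour = "cov", b = 0.35)
  )
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: 20-trial balloon
#' sessions with integer-uniform explosion thresholds on \[2, 28\] (mean 15),
#' a 12 x 12 x 12 voxel lattice at 5-mm spacing with spatially smooth
#' background noise, two planted delta-band clusters (a risk-linked
#' "ACC-like" and a variability-linked "DLPFC-like" cluster), and a
#' personality -> neural latent -> behaviour chain with unit-variance
#' standardized latents.
#'
#' @param n_subjects number of subjects.
#' @param n_trials balloon trials per session (default 20).
#' @param threshold_low,threshold_high integer-uniform support of explosion
#'   thresholds (defaults 2 and 28, mean 15).
#' @param grid_dims lattice shape (default c(12, 12, 12)).
#' @param voxel_spacing mm between lattice points (default 5).
#' @param cluster_specs list of [planted_cluster()]s.
#' @param noise_sds list: `neural` (sd of the latent's own noise; default
#'   `sqrt(1 - a^2)` per cluster so latents have unit variance), `behaviour`
#'   (default `sqrt(1 - b^2)` per cluster), `voxel` (per-voxel noise on top
#'   of the cluster latent), `background` (marginal sd of background
#'   voxels).
#' @param policy `"iid"` or `"adaptive"` pumping policy.
#' @param shared_thresholds if `TRUE`, one threshold sequence is drawn and
#'   yoked across subjects.
#' @param smooth_fwhm_mm Gaussian smoothing FWHM for the background noise
#'   field (default 30 mm), emulating the centimetre-scale spatial
#'   smoothness of source-localized current-density maps; 0 disables
#'   smoothing. The default reproduces a max-statistic corrected threshold
#'   consistent with whole-map correction over a realistically smooth
#'   field; see the methods vignette.
#' @param mu_base,mu_scale affine map from the risk latent to each subject's
#'   intended mean pumps, clipped to `mu_range`.
#' @param sigma_base,sigma_scale affine map from the variability latent to
#'   the intended pump SD, clipped to `sigma_range`.
#' @param mu_range,sigma_range clipping bounds.
#' @param seed RNG seed used by [simulate_cohort()].
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_subjects = 104, n_trials = 20,
                       threshold_low = 2, threshold_high = 28,
                       grid_dims = c(12, 12, 12), voxel_spacing = 5,
                       cluster_specs = default_clusters(),
                       noise_sds = list(voxel = 0.15, background = 1),
                       policy = c("iid", "adaptive"),
                       shared_thresholds = FALSE,
                       smooth_fwhm_mm = 30,
                       mu_base = 11, mu_scale = 5,
                       sigma_base = 3, sigma_scale = 1,
                       mu_range = c(2, 25), sigma_range = c(0.5, 8),
                       seed = 1L) {
  policy <- match.arg(policy)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (threshold_low < 2) stop("threshold_low must be >= 2", call. = FALSE)
  if (threshold_high < threshold_low) {
    stop("threshold_high must be >= threshold_low", call. = FALSE)
  }
  if (any(grid_dims < 1)) stop("grid dims must be positive", call. = FALSE)
  ns <- noise_sds
  ns$voxel <- ns$voxel %||% 0.15
  ns$background <- ns$background %||% 1
  if (any(unlist(ns) < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  for (cl in cluster_specs) {
    if (any(cl$center < 1) || any(cl$center > grid_dims)) {
      stop("cluster centre outside grid", call. = FALSE)
    }
  }
  structure(
    list(
      n_subjects = n_subjects, n_trials = n_trials,
      threshold_low = threshold_low, threshold_high = threshold_high,
      grid_dims = as.integer(grid_dims), voxel_spacing = voxel_spacing,
      cluster_specs = cluster_specs, noise_sds = ns, policy = policy,
      shared_thresholds = shared_thresholds, smooth_fwhm_mm = smooth_fwhm_mm,
      mu_base = mu_base, mu_scale = mu_scale,
      sigma_base = sigma_base, sigma_scale = sigma_scale,
      mu_range = mu_range, sigma_range = sigma_range, seed = seed
    ),
    class = "sim_config"
  )
}

#' Draw explosion thresholds
#'
#' One integer threshold per trial, uniform on
#' `[threshold_low, threshold_high]`. With the default support 2-28 the
#' distribution's expected value is 15 pumps. Draws come from the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param config a `sim_config` (only the threshold fields and `n_trials`
#'   are used).
#' @return Integer vector of length `n_trials`.
#' @export
generate_thresholds <- function(config) {
  lo <- config$threshold_low
  hi <- config$threshold_high
  if (lo < 2 || hi < lo) stop("invalid threshold support", call. = FALSE)
  lo + sample.int(hi - lo + 1L, config$n_trials, replace = TRUE) - 1L
}

#' Simulate one subject's BART session
#'
#' Intended pumps per trial are `max(1, round(Normal(mu_t, sigma)))`. Under
#' the `"iid"` policy `mu_t` is constant; under `"adaptive"` it increases by
#' 1 after a safe trial and decreases by 1 (floor 1) after an explosion,
#' emulating small-step strategic adjustment. Recorded pumps are capped at
#' the trial's threshold and the balloon explodes iff intended pumps reach
#' the threshold.
#'
#' @param mu intended mean pumps (>= 1).
#' @param sigma intended pump SD (>= 0).
#' @param thresholds integer vector of explosion thresholds.
#' @param policy `"iid"` or `"adaptive"`.
#' @param subject_id identifier.
#' @return A `bart_session` tibble.
#' @export
simulate_bart_subject <- function(mu, sigma, thresholds,
                                  policy = c("iid", "adaptive"),
                                  subject_id = "s1") {
  policy <- match.arg(policy)
  if (mu < 1) stop("mu must be >= 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (length(thresholds) == 0L) stop("thresholds must be nonempty", call. = FALSE)
  n <- length(thresholds)
  pumps <- integer(n)
  exploded <- logical(n)
  mu_t <- mu
  for (i in seq_len(n)) {
    intended <- max(1L, as.integer(round(stats::rnorm(1, mu_t, sigma))))
    exploded[i] <- intended >= thresholds[i]
    pumps[i] <- min(intended, thresholds[i])
    if (policy == "adaptive") {
      mu_t <- if (exploded[i]) max(1, mu_t - 1) else mu_t + 1
    }
  }
  bart_session(subject_id, pumps, exploded)
}

# voxel ids (linear index into the lattice enumeration) within radius_mm of
# a lattice-centre, plus the coords table for the full grid
lattice_coords <- function(grid_dims, spacing) {
  g <- expand.grid(
    i = seq_len(grid_dims[1]), j = seq_len(grid_dims[2]), k = seq_len(grid_dims[3])
  )
  as.matrix(g) * spacing
}

cluster_voxel_ids <- function(coords_mm, center_ijk, radius_mm, spacing) {
  center_mm <- as.numeric(center_ijk) * spacing
  d2 <- colSums((t(coords_mm) - center_mm)^2)
  which(d2 <= radius_mm^2 + 1e-9)
}

# separable Gaussian smoothing of a voxel field laid out on the lattice;
# field: subjects x voxels matrix, lattice enumeration as in lattice_coords()
smooth_field <- function(field, grid_dims, fwhm_vox) {
  if (fwhm_vox <= 0) return(field)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  kern_mat <- function(d) {
    K <- outer(seq_len(d), seq_len(d), function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    K / rowSums(K)
  }
  Ks <- lapply(grid_dims, kern_mat)
  conv_axis <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    ap <- array(Ks[[axis]] %*% matrix(ap, d[1], d[2] * d[3]), d)
    aperm(ap, order(perm))
  }
  out <- field
  for (s in seq_len(nrow(field))) {
    a <- array(out[s, ], dim = grid_dims)
    for (ax in 1:3) a <- conv_axis(a, ax)
    out[s, ] <- as.numeric(a)
  }
  # restore approximate unit marginal scale after smoothing
  out / stats::sd(as.numeric(out))
}

trait_names <- function() {
  c("extraversion", "agreeableness", "conscientiousness", "neuroticism",
    "openness", "self_control")
}

#' Simulate a full cohort
#'
#' Generates, per subject: (1) standardized personality latents (reported on
#' a 1-5 Likert-like scale as `3 + 0.6 z`, clipped); (2) one latent neural
#' value per planted cluster, `a * z_trait + sqrt(1 - a^2) * noise` (unit
#' variance); (3) behavioural latents — risk propensity and pump
#' variability — as `b * latent + sqrt(1 - b^2) * noise`; (4) BART sessions
#' via an affine, clipped map of the behavioural latents onto the pumping
#' policy's mean and SD; (5) voxel maps whose planted voxels carry the
#' cluster latent plus per-voxel noise while background voxels carry
#' spatially smoothed independent noise, exponentiated to positive densities
#' and passed through [normalize_log_map()]. Ground truth (latents, planted
#' voxel ids, paths) is returned separately so pipeline inputs never leak
#' it.
#'
#' @param config a [sim_config()].
#' @return A `simulated_cohort` list: `sessions` (long tibble), `traits`
#'   tibble, `maps` (`voxel_map`), `ground_truth` (list: `latents` tibble,
#'   `clusters` tibble with planted voxel ids, `paths` tibble), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("s%03d", seq_len(n))
  tn <- trait_names()

  z <- matrix(stats::rnorm(n * length(tn)), n, length(tn),
              dimnames = list(NULL, tn))
  likert <- 3 + 0.6 * z
  likert[likert < 1] <- 1
  likert[likert > 5] <- 5

  specs <- config$cluster_specs
  nc <- length(specs)
  latents <- matrix(0, n, nc)
  cl_names <- if (nc > 0) names(specs) %||% paste0("cluster", seq_len(nc)) else character(0)
  if (nc > 0 && is.null(names(specs))) names(specs) <- cl_names
  for (k in seq_len(nc)) {
    cl <- specs[[k]]
    if (!cl$trait %in% tn) stop("unknown trait in cluster spec: ", cl$trait, call. = FALSE)
    ns_neural <- config$noise_sds$neural %||% sqrt(max(0, 1 - cl$a^2))
    latents[, k] <- cl$a * z[, cl$trait] + ns_neural * stats::rnorm(n)
  }
  colnames(latents) <- cl_names

  beh <- list(rt = NULL, cov = NULL)
  beh_src <- c(rt = NA_character_, cov = NA_character_)
  for (k in seq_len(nc)) {
    cl <- specs[[k]]
    if (!is.na(beh_src[cl$behaviour])) next # first cluster per behaviour drives it
    ns_beh <- config$noise_sds$behaviour %||% sqrt(max(0, 1 - cl$b^2))
    lat_sd <- stats::sd(latents[, k])
    zlat <- if (lat_sd > 0) (latents[, k] - mean(latents[, k])) / lat_sd else latents[, k] * 0
    beh[[cl$behaviour]] <- cl$b * zlat + ns_beh * stats::rnorm(n)
    beh_src[cl$behaviour] <- cl_names[k]
  }
  if (is.null(beh$rt)) beh$rt <- stats::rnorm(n)
  if (is.null(beh$cov)) beh$cov <- stats::rnorm(n)

  mu <- pmin(config$mu_range[2],
             pmax(config$mu_range[1], config$mu_base + config$mu_scale * beh$rt))
  sigma <- pmin(config$sigma_range[2],
                pmax(config$sigma_range[1],
                     config$sigma_base + config$sigma_scale * beh$cov))

  shared <- if (config$shared_thresholds) generate_thresholds(config) else NULL
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    thr <- shared %||% generate_thresholds(config)
    sessions[[i]] <- simulate_bart_subject(mu[i], sigma[i], thr,
                                           config$policy, ids[i])
  }
  sessions_long <- do.call(rbind, sessions)

  coords <- lattice_coords(config$grid_dims, config$voxel_spacing)
  V <- nrow(coords)
  bands <- eeg_bands()$band
  nb <- length(bands)
  raw <- array(0, dim = c(n, V, nb))
  fwhm_vox <- config$smooth_fwhm_mm / config$voxel_spacing
  for (b in seq_len(nb)) {
    bg <- matrix(stats::rnorm(n * V), n, V)
    bg <- smooth_field(bg, config$grid_dims, fwhm_vox)
    # zero spatial mean per subject: total-density normalization then adds
    # no subject-level offset, so planted correlations survive it intact
    bg <- bg - rowMeans(bg)
    raw[, , b] <- config$noise_sds$background * bg
  }
  planted <- vector("list", nc)
  for (k in seq_len(nc)) {
    cl <- specs[[k]]
    vids <- cluster_voxel_ids(coords, cl$center, cl$radius_mm, config$voxel_spacing)
    bi <- match(cl$band, bands)
    for (v in vids) {
      raw[, v, bi] <- latents[, k] + config$noise_sds$voxel * stats::rnorm(n)
    }
    peak <- vids[which.min(colSums((t(coords[vids, , drop = FALSE]) -
                                      as.numeric(cl$center) * config$voxel_spacing)^2))]
    planted[[k]] <- tibble::tibble(
      cluster = cl_names[k], band = cl$band, behaviour = cl$behaviour,
      trait = cl$trait, a = cl$a, b = cl$b,
      peak_voxel = peak, n_voxels = length(vids), voxel_ids = list(vids)
    )
  }
  maps <- normalize_log_map(
    voxel_map(exp(raw), coords, bands, ids, config$voxel_spacing)
  )

  scores <- score_cohort(sessions)$scores
  scores <- scores[match(ids, scores$subject_id), ]
  traits <- tibble::as_tibble(cbind(
    tibble::tibble(subject_id = ids),
    tibble::as_tibble(likert),
    tibble::tibble(rt = scores$rt, cov = scores$cov)
  ))

  gt_lat <- tibble::as_tibble(cbind(
    tibble::tibble(subject_id = ids),
    tibble::as_tibble(latents),
    tibble::tibble(risk_latent = beh$rt, variability_latent = beh$cov,
                   mu = mu, sigma = sigma)
  ))

  structure(
    list(
      sessions = sessions_long,
      traits = traits,
      maps = maps,
      ground_truth = list(
        latents = gt_lat,
        clusters = do.call(rbind, planted),
        paths = tibble::tibble(
          cluster = cl_names,
          trait = vapply(specs, `[[`, character(1), "trait"),
          a = vapply(specs, `[[`, numeric(1), "a"),
          behaviour = vapply(specs, `[[`, character(1), "behaviour"),
          b = vapply(specs, `[[`, numeric(1), "b")
        )
      ),
      config = config
    ),
    class = "simulated_cohort"
  )
}

#' Write a simulated cohort to plain-text files
#'
#' Sessions and traits as CSV, the voxel map via [write_voxel_map()], and
#' ground truth as a separate sidecar CSV pair so pipeline inputs never
#' contain it.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    sessions = file.path(dir, "sessions.csv"),
    traits = file.path(dir, "traits.csv"),
    maps = file.path(dir, "maps"),
    ground_truth = file.path(dir, "ground_truth_latents.csv"),
    ground_truth_clusters = file.path(dir, "ground_truth_clusters.csv")
  )
  write_bart_sessions(cohort$sessions, paths$sessions)
  utils::write.csv(cohort$traits, paths$traits, row.names = FALSE)
  write_voxel_map(cohort$maps, paths$maps)
  utils::write.csv(cohort$ground_truth$latents, paths$ground_truth, row.names = FALSE)
  gtc <- cohort$ground_truth$clusters
  gtc$voxel_ids <- vapply(gtc$voxel_ids, paste, character(1), collapse = ";")
  utils::write.csv(gtc, paths$ground_truth_clusters, row.names = FALSE)
  invisible(paths)
}
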