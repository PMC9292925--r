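#' Pipeline configuration
#'
#' Bundles paths and parameters for the end-to-end run: score the BART
#' sessions, map each behavioural score onto the voxel lattice with
#' max-statistic permutation correction, extract sphere ROIs around detected
#' cluster peaks, merge them into the trait table, and run commonality and
#' mediation analyses.
#'
#' @param sessions_csv,traits_csv,maps_dir input paths (see [write_cohort()]
#'   for the layouts).
#' @param out_dir output directory for stage TSVs and the run report.
#' @param band band analysed (default `"delta"`).
#' @param scores behavioural score columns to map (default `c("rt", "cov")`).
#' @param alpha FWER level (default 0.05).
#' @param n_permutations randomizations per map (default 5000).
#' @param connectivity cluster connectivity: 6, 18 or 26.
#' @param roi_radius_mm sphere ROI radius (default 10).
#' @param n_bootstrap mediation bootstrap resamples (default 10000).
#' @param x_names predictors for the mediation stage (default the Big-5
#'   subscales plus self-control).
#' @param seed master seed; stage seeds are `seed + stage offset`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sessions_csv, traits_csv, maps_dir, out_dir,
                            band = "delta", scores = c("rt", "cov"),
                            alpha = 0.05, n_permutations = 5000,
                            connectivity = 26, roi_radius_mm = 10,
                            n_bootstrap = 10000,
                            x_names = c("extraversion", "agreeableness",
                                        "conscientiousness", "neuroticism",
                                        "openness", "self_control"),
                            seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_permutations < 99 || n_bootstrap < 1) stop("counts must be positive", call. = FALSE)
  structure(
    list(sessions_csv = sessions_csv, traits_csv = traits_csv,
         maps_dir = maps_dir, out_dir = out_dir, band = band, scores = scores,
         alpha = alpha, n_permutations = n_permutations,
         connectivity = connectivity, roi_radius_mm = roi_radius_mm,
         n_bootstrap = n_bootstrap, x_names = x_names, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Validate pipeline inputs
#'
#' Checks the sessions CSV schema, trait CSV schema, voxel-map layout and
#' subject alignment across the three inputs. Reports all violations and
#' never silently fixes anything.
#'
#' @param sessions_csv,traits_csv,maps_dir input paths.
#' @return tibble of violations (`input`, `problem`); zero rows when valid.
#' @export
validate_inputs <- function(sessions_csv, traits_csv, maps_dir) {
  probs <- list()
  note <- function(input, problem) {
    probs[[length(probs) + 1]] <<- tibble::tibble(input = input, problem = problem)
  }
  sess <- traits <- map <- NULL
  if (!file.exists(sessions_csv)) {
    note("sessions", "file missing")
  } else {
    d <- utils::read.csv(sessions_csv, nrows = 5)
    miss <- setdiff(c("subject_id", "trial_index", "pumps", "exploded"), names(d))
    if (length(miss)) {
      note("sessions", paste("missing columns:", paste(miss, collapse = ", ")))
    } else {
      sess <- read_bart_sessions(sessions_csv)
    }
  }
  if (!file.exists(traits_csv)) {
    note("traits", "file missing")
  } else {
    traits <- tryCatch(read_traits(traits_csv), error = function(e) {
      note("traits", conditionMessage(e)); NULL
    })
  }
  map <- tryCatch(read_voxel_map(maps_dir), error = function(e) {
    note("maps", conditionMessage(e)); NULL
  })
  if (!is.null(sess) && !is.null(traits)) {
    if (length(intersect(unique(sess$subject_id), traits$subject_id)) == 0L) {
      note("alignment", "sessions and traits share no subject ids")
    }
  }
  if (!is.null(map) && !is.null(traits)) {
    if (length(intersect(map$subject_ids, traits$subject_id)) == 0L) {
      note("alignment", "maps and traits share no subject ids")
    }
  }
  if (length(probs) == 0L) {
    return(tibble::tibble(input = character(), problem = character()))
  }
  do.call(rbind, probs)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: (1) score BART sessions; (2) per behavioural
#' score, voxelwise correlation with max-statistic permutation correction on
#' the configured band and cluster extraction at the corrected threshold;
#' (3) sphere-ROI extraction around each detected cluster peak, appended to
#' the trait table as `roi_<score>_<band>` columns; (4) trait correlation
#' table; (5) commonality analysis of the two behavioural scores against
#' each ROI; (6) mediation models (each personality trait -> ROI ->
#' behaviour). Identical config and seed give identical reports. Subjects
#' are aligned by id intersection with a warning when any are dropped.
#'
#' @param config a [pipeline_config()].
#' @return A `run_report` list: `scores`, `cluster_table`,
#'   `correlation_table`, `commonality_table`, `mediation_table`,
#'   `n_subjects`, `config_hash`, `seeds`, `package_version`, `timestamp`,
#'   `output_files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  viol <- validate_inputs(config$sessions_csv, config$traits_csv, config$maps_dir)
  if (nrow(viol) > 0L) {
    stop("input validation failed:\n",
         paste(sprintf("  [%s] %s", viol$input, viol$problem), collapse = "\n"),
         call. = FALSE)
  }
  sessions <- read_bart_sessions(config$sessions_csv)
  traits <- read_traits(config$traits_csv)
  map <- read_voxel_map(config$maps_dir)

  ids <- Reduce(intersect, list(unique(sessions$subject_id), traits$subject_id,
                                map$subject_ids))
  n_all <- length(unique(c(sessions$subject_id, traits$subject_id, map$subject_ids)))
  if (length(ids) < n_all) {
    warning(n_all - length(ids), " subject id(s) dropped by alignment",
            call. = FALSE)
  }
  sessions <- sessions[sessions$subject_id %in% ids, ]
  traits <- traits[match(ids, traits$subject_id), ]
  keep <- match(ids, map$subject_ids)
  map$values <- map$values[keep, , , drop = FALSE]
  map$subject_ids <- ids

  scored <- score_cohort(sessions)
  scores_tbl <- scored$scores[match(ids, scored$scores$subject_id), ]
  traits$rt <- scores_tbl$rt
  traits$cov <- scores_tbl$cov

  cluster_tables <- list()
  roi_cols <- character(0)
  seed_map <- config$seed + 100L
  for (sc in config$scores) {
    perm <- permutation_correct(map, traits[[sc]], band = config$band,
                                n_permutations = config$n_permutations,
                                alpha = config$alpha, seed = seed_map,
                                score_name = sc)
    seed_map <- seed_map + 1L
    cl <- cluster_report(
      find_clusters(perm$stat_map, perm$critical_r, config$connectivity), perm
    )
    cluster_tables[[sc]] <- cl
    if (nrow(cl) > 0L) {
      peak <- unlist(cl[1, c("peak_x_mm", "peak_y_mm", "peak_z_mm")])
      roi <- sphere_roi(map, peak, config$roi_radius_mm, config$band)
      col <- paste0("roi_", sc, "_", config$band)
      traits[[col]] <- unname(roi$values[ids])
      roi_cols <- c(roi_cols, col)
    }
  }
  cluster_table <- do.call(rbind, cluster_tables)

  num_cols <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))],
                      character(0))
  corr <- correlation_table(traits, num_cols, num_cols)

  commonality <- NULL
  if (length(roi_cols)) {
    commonality <- do.call(rbind, lapply(roi_cols, function(col) {
      res <- commonality_two_predictors(traits[[col]], traits$rt, traits$cov)
      cbind(tibble::tibble(y = col, x1 = "rt", x2 = "cov"), commonality_tidy(res))
    }))
  }

  med <- NULL
  if (length(roi_cols)) {
    med <- do.call(rbind, lapply(seq_along(roi_cols), function(i) {
      sc <- config$scores[i]
      mediation_table(traits, config$x_names, roi_cols[i], sc,
                      n_bootstrap = config$n_bootstrap,
                      seed = config$seed + 1000L * i)
    }))
  }

  report <- list(
    scores = scores_tbl,
    score_summary = scored$summary,
    cluster_table = cluster_table,
    trait_table = traits,
    correlation_table = corr,
    commonality_table = commonality,
    mediation_table = med,
    n_subjects = length(ids),
    config_hash = rlang::hash(unclass(config)),
    seeds = list(master = config$seed),
    package_version = as.character(utils::packageVersion("neurotrait")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    files$scores <- write_tsv_report(scores_tbl, file.path(config$out_dir, "bart_scores.tsv"))
    if (!is.null(cluster_table)) {
      files$clusters <- write_tsv_report(cluster_table, file.path(config$out_dir, "clusters.tsv"))
    }
    if (!is.null(commonality)) {
      files$commonality <- write_tsv_report(commonality, file.path(config$out_dir, "commonality.tsv"))
    }
    if (!is.null(med)) {
      files$mediation <- write_tsv_report(med, file.path(config$out_dir, "mediation.tsv"))
    }
    files$traits <- write_tsv_report(traits, file.path(config$out_dir, "trait_table.tsv"))
    rep_lines <- c(
      "neurotrait run report",
      paste("package version:", report$package_version),
      paste("config hash:", report$config_hash),
      paste("master seed:", config$seed),
      paste("subjects analysed:", report$n_subjects),
      paste("band:", config$band),
      paste("permutations:", config$n_permutations, "alpha:", config$alpha),
      paste("clusters detected:",
            if (is.null(cluster_table)) 0 else nrow(cluster_table)),
      paste("timestamp (UTC):", report$timestamp)
    )
    writeLines(rep_lines, file.path(config$out_dir, "run_report.txt"))
    files$report <- file.path(config$out_dir, "run_report.txt")
    report$output_files <- files
  }
  class(report) <- "run_report"
  report
}
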