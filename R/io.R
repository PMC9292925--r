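#' Write / read BART sessions CSV
#'
#' Dialect: columns `subject_id`, `trial_index` (1-based), `pumps`,
#' `exploded` (0/1).
#'
#' @param sessions long data frame (`subject_id`, `trial`, `pumps`,
#'   `exploded`).
#' @param path CSV path.
#' @return `write_bart_sessions`: the path, invisibly. `read_bart_sessions`:
#'   a long tibble with `subject_id`, `trial`, `pumps`, `exploded`
#'   (logical).
#' @export
write_bart_sessions <- function(sessions, path) {
  out <- data.frame(
    subject_id = sessions$subject_id,
    trial_index = sessions$trial,
    pumps = sessions$pumps,
    exploded = as.integer(sessions$exploded)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bart_sessions
#' @export
read_bart_sessions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index", "pumps", "exploded")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("sessions CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tibble::tibble(
    subject_id = as.character(d$subject_id),
    trial = as.integer(d$trial_index),
    pumps = as.integer(d$pumps),
    exploded = d$exploded != 0
  )
}

#' Read a trait table CSV
#' @param path CSV path with a `subject_id` column plus numeric trait /
#'   score columns.
#' @return tibble.
#' @export
read_traits <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(d)) {
    stop("traits CSV missing subject_id column", call. = FALSE)
  }
  d$subject_id <- as.character(d$subject_id)
  if (anyDuplicated(d$subject_id)) stop("duplicate subject_id in traits", call. = FALSE)
  tibble::as_tibble(d)
}

#' Write / read a voxel map as plain text
#'
#' Layout under a directory stem: `values.tsv` (long: `subject_id`, `voxel`,
#' `band`, `value`), `coords.tsv` (`voxel`, `x_mm`, `y_mm`, `z_mm`) and
#' `meta.json` (`spacing_mm`, `normalized`, `band_names`, `subject_ids`).
#'
#' @param map a `voxel_map`.
#' @param dir directory to create/populate.
#' @return `write_voxel_map`: the directory, invisibly. `read_voxel_map`:
#'   a `voxel_map`.
#' @export
write_voxel_map <- function(map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(map$values)
  long <- data.frame(
    subject_id = rep(map$subject_ids, times = dims[2] * dims[3]),
    voxel = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    band = rep(map$band_names, each = dims[1] * dims[2]),
    value = as.numeric(map$values)
  )
  utils::write.table(long, file.path(dir, "values.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  coords <- data.frame(voxel = seq_len(dims[2]), x_mm = map$coords_mm[, 1],
                       y_mm = map$coords_mm[, 2], z_mm = map$coords_mm[, 3])
  utils::write.table(coords, file.path(dir, "coords.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(spacing_mm = map$spacing_mm, normalized = map$normalized,
         band_names = map$band_names, subject_ids = map$subject_ids),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_voxel_map
#' @export
read_voxel_map <- function(dir) {
  vpath <- file.path(dir, "values.tsv")
  cpath <- file.path(dir, "coords.tsv")
  mpath <- file.path(dir, "meta.json")
  for (p in c(vpath, cpath, mpath)) {
    if (!file.exists(p)) stop("voxel map file missing: ", p, call. = FALSE)
  }
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  long <- utils::read.delim(vpath, stringsAsFactors = FALSE)
  coords <- utils::read.delim(cpath)
  sids <- meta$subject_ids
  bnames <- meta$band_names
  n <- length(sids); V <- nrow(coords); nb <- length(bnames)
  vals <- array(NA_real_, dim = c(n, V, nb))
  si <- match(long$subject_id, sids)
  bi <- match(long$band, bnames)
  vals[cbind(si, long$voxel, bi)] <- long$value
  if (anyNA(vals)) stop("voxel map values incomplete", call. = FALSE)
  voxel_map(vals, as.matrix(coords[, c("x_mm", "y_mm", "z_mm")]),
            bnames, sids, meta$spacing_mm, isTRUE(meta$normalized))
}

#' Write a tibble as TSV
#' @param x data frame (list columns are collapsed with `;`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]])) x[[j]] <- vapply(x[[j]], paste, character(1), collapse = ";")
  }
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
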