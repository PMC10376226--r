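#' Write a hop trial to CSV
#'
#' Two files, one per clock: `<base>_emg.csv` with columns `time_s`, the 7
#' muscle channels and `vGRF` at the EMG rate, and `<base>_mocap.csv` with
#' `time_s`, `ankle_vz`, `knee_flexion` at the mocap rate. Full double
#' precision, so the round trip with [read_trial()] is lossless well below
#' 1e-9.
#'
#' @param trial A `hop_trial`.
#' @param base Path prefix (without the `_emg.csv` / `_mocap.csv` suffixes).
#' @return `base`, invisibly.
#' @export
write_trial <- function(trial, base) {
  stopifnot(inherits(trial, "hop_trial"))
  emg_path <- paste0(base, "_emg.csv")
  moc_path <- paste0(base, "_mocap.csv")
  df <- as.data.frame(trial$signals)
  for (col in names(df)) df[[col]] <- format(df[[col]], digits = 17, trim = TRUE)
  write.csv(df, emg_path, row.names = FALSE, quote = FALSE)
  dm <- as.data.frame(trial$mocap)
  for (col in names(dm)) dm[[col]] <- format(dm[[col]], digits = 17, trim = TRUE)
  write.csv(dm, moc_path, row.names = FALSE, quote = FALSE)
  invisible(base)
}

#' Read a hop trial written by [write_trial()]
#'
#' @param base Path prefix used by [write_trial()].
#' @param subject_id,group,limb,trial Identity labels to attach (may come
#'   from a cohort manifest).
#' @param fs_emg,fs_mocap Sampling rates; inferred from the time columns when
#'   `NULL`.
#' @return A `hop_trial`.
#' @export
read_trial <- function(base, subject_id = NA_character_, group = NA_character_,
                       limb = NA_character_, trial = NA_integer_,
                       fs_emg = NULL, fs_mocap = NULL) {
  emg_path <- paste0(base, "_emg.csv")
  moc_path <- paste0(base, "_mocap.csv")
  for (p in c(emg_path, moc_path)) {
    if (!file.exists(p)) stop(sprintf("read_trial: file not found: %s", p),
                              call. = FALSE)
  }
  sig <- tryCatch(read.csv(emg_path), error = function(e) {
    stop(sprintf("read_trial: malformed trial file %s (%s)", emg_path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (nrow(sig) == 0 || ncol(sig) < 2) {
    stop(sprintf("read_trial: empty or malformed trial file %s", emg_path),
         call. = FALSE)
  }
  need <- c("time_s", MUSCLES, "vGRF")
  missing_cols <- setdiff(need, names(sig))
  if (length(missing_cols)) {
    stop(sprintf("read_trial: missing channel column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  lens <- vapply(sig[need], length, integer(1))
  if (length(unique(lens)) != 1 || anyNA(sig[need])) {
    stop("read_trial: inconsistent channel lengths or missing samples",
         call. = FALSE)
  }
  moc <- read.csv(moc_path)
  need_m <- c("time_s", "ankle_vz", "knee_flexion")
  missing_m <- setdiff(need_m, names(moc))
  if (length(missing_m)) {
    stop(sprintf("read_trial: missing mocap column(s): %s",
                 paste(missing_m, collapse = ", ")), call. = FALSE)
  }
  fs_emg <- fs_emg %||% round(1 / stats::median(diff(sig$time_s)))
  fs_mocap <- fs_mocap %||% round(1 / stats::median(diff(moc$time_s)))
  new_hop_trial(subject_id = subject_id, group = group, limb = limb,
                trial = trial, fs_emg = fs_emg, fs_mocap = fs_mocap,
                signals = tibble::as_tibble(sig[need]),
                mocap = tibble::as_tibble(moc[need_m]))
}

#' Write a cohort to a directory
#'
#' Writes every trial in the CSV dialect of [write_trial()] plus a JSON
#' manifest (`manifest.json`) listing subjects, limbs, trials, file prefixes,
#' ground-truth events and the subject outcome table, along with the
#' generating configuration.
#'
#' @param cohort A `hop_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hop_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::map(cohort$trials, function(tr) {
    base <- file.path(dir, sprintf("%s_%s_t%d", tr$subject_id, tr$limb, tr$trial))
    write_trial(tr, base)
    list(subject_id = tr$subject_id, group = tr$group, limb = tr$limb,
         trial = tr$trial, base = basename(base), truth = tr$truth)
  })
  cfg <- cohort$config
  cfg$muscles <- as.list(cfg$muscles)
  manifest <- list(schema_version = "1.0",
                   config = unclass(cfg),
                   trials = entries,
                   outcomes = cohort$outcomes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and trial CSVs.
#' @return A `hop_cohort`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("read_cohort: no manifest.json found",
                                call. = FALSE)
  man <- jsonlite::read_json(mpath)
  trials <- purrr::map(man$trials, function(e) {
    tr <- read_trial(file.path(dir, e$base), e$subject_id, e$group, e$limb,
                     as.integer(e$trial),
                     fs_emg = man$config$fs_emg, fs_mocap = man$config$fs_mocap)
    tr$truth <- lapply(e$truth, as.integer)
    tr
  })
  truth <- purrr::map_dfr(trials, function(tr) {
    tibble::tibble(subject_id = tr$subject_id, group = tr$group,
                   limb = tr$limb, trial = tr$trial,
                   t0 = tr$truth$t0, t1 = tr$truth$t1, t2 = tr$truth$t2,
                   t3 = tr$truth$t3, n_samples = nrow(tr$signals))
  })
  outcomes <- dplyr::bind_rows(lapply(man$outcomes, function(o) {
    tibble::as_tibble(lapply(o, function(v) if (is.null(v)) NA else v))
  }))
  structure(list(trials = trials, truth = truth, outcomes = outcomes,
                 config = man$config),
            class = "hop_cohort")
}

#' Write classification results to JSON
#'
#' Versioned JSON document with per-muscle counts, rates and (when present)
#' critical-rate verdicts.
#'
#' @param results A `hop_classification` tibble (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  doc <- list(schema_version = "1.0",
              results = if (nrow(results) == 0) list() else results)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read classification results written by [write_results()]
#'
#' @param path JSON path.
#' @return A tibble of results (zero rows for an empty result set).
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(doc$results) == 0) return(tibble::tibble())
  out <- tibble::as_tibble(doc$results)
  class(out) <- c("hop_classification", class(out))
  out
}

#' Write an analysis configuration as YAML
#'
#' Key/value configuration with units embedded in the key names (e.g.
#' `bandpass_low_hz`), readable by [read_config()].
#'
#' @param config Named list of settings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config`: the named list of settings.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
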