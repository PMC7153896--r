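#' Write trajectories as CSV in the "time"/"koor" dialect
#'
#' One file per cell (named `<id>.csv`, columns `time` in minutes and
#' `koor` in micrometres from the lane centre) plus a `manifest.csv`
#' describing each track's lane.
#'
#' @param tracks Named list of [lane_trajectory()] objects.
#' @param dir Output directory (created if missing).
#' @param manifest Optional manifest data.frame with a row per track
#'   (columns `id`, `lane_length`, `width`, `tip_shape`, `source`); a
#'   minimal one is derived from track attributes when omitted.
#' @return Invisibly, the manifest path.
#' @export
write_trajectories <- function(tracks, dir, manifest = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(tracks)
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_along(tracks))
  if (is.null(manifest)) {
    manifest <- data.frame(
      id = ids,
      lane_length = vapply(tracks, function(t) {
        L <- attr(t, "lane_length"); if (is.null(L)) NA_real_ else L
      }, 0),
      width = NA_real_, tip_shape = NA_character_, source = "unknown")
  }
  manifest$file <- paste0(manifest$id, ".csv")
  for (k in seq_along(tracks)) {
    utils::write.csv(data.frame(time = tracks[[k]]$time,
                                koor = tracks[[k]]$koor),
                     file.path(dir, paste0(ids[k], ".csv")),
                     row.names = FALSE)
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

.read_one_trajectory <- function(path, lane_length = NA_real_, id = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time", "koor") %in% names(d)))
    stop("missing 'time'/'koor' columns in ", path)
  if (is.null(id)) id <- sub("\\.csv$", "", basename(path))
  .validate_track_rows(d, path)
  lane_trajectory(d$time, d$koor, lane_length = lane_length, cell_id = id)
}

.validate_track_rows <- function(d, label) {
  bad <- which(!is.finite(d$time) | !is.finite(d$koor))
  if (length(bad) > 0)
    stop(sprintf("%s: malformed values at rows %s", label,
                 paste(utils::head(bad, 5), collapse = ", ")))
  dts <- diff(d$time)
  nm <- which(dts <= 0)
  if (length(nm) > 0)
    stop(sprintf("%s: non-monotone time at row %d", label, nm[1] + 1))
  if (length(dts) > 0 && max(dts) - min(dts) > 1e-6 * max(dts)) {
    off <- which(abs(dts - stats::median(dts)) > 1e-6 * max(dts))[1]
    stop(sprintf("%s: gap or mixed sampling interval at row %d (dt = %g)",
                 label, off + 1, dts[off]))
  }
  invisible(TRUE)
}

#' Read trajectory tables in the "time"/"koor" dialect
#'
#' Accepts (i) a manifest CSV whose rows name one trajectory file each
#' (columns `file` plus lane metadata), (ii) a directory containing
#' per-cell CSVs and optionally a `manifest.csv`, or (iii) a single CSV
#' with `time` and `koor` columns, either one cell or several when a cell
#' id column (`cell`, `cell_id` or `id`) is present. Malformed rows (gaps,
#' non-monotone time, non-numeric entries) are rejected with the offending
#' row number.
#'
#' @param path Manifest CSV, directory, or single trajectory CSV.
#' @return List with `tracks` (named list of [lane_trajectory()]) and
#'   `manifest` (data.frame, possibly minimal).
#' @export
read_trajectories <- function(path) {
  if (dir.exists(path)) {
    mp <- file.path(path, "manifest.csv")
    if (file.exists(mp)) return(read_trajectories(mp))
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0) stop("no CSV files in ", path)
    tracks <- lapply(files, .read_one_trajectory)
    names(tracks) <- vapply(tracks, function(t) attr(t, "cell_id"), "")
    manifest <- data.frame(id = names(tracks), lane_length = NA_real_,
                           width = NA_real_, tip_shape = NA_character_,
                           source = "unknown", file = basename(files))
    return(list(tracks = tracks, manifest = manifest))
  }
  d <- utils::read.csv(path)
  if ("file" %in% names(d)) {           # manifest
    base <- dirname(path)
    tracks <- vector("list", nrow(d))
    for (k in seq_len(nrow(d))) {
      L <- if ("lane_length" %in% names(d)) d$lane_length[k] else NA_real_
      id <- if ("id" %in% names(d)) as.character(d$id[k]) else NULL
      tracks[[k]] <- .read_one_trajectory(file.path(base, d$file[k]),
                                          lane_length = L, id = id)
    }
    names(tracks) <- vapply(tracks, function(t) attr(t, "cell_id"), "")
    if (anyDuplicated(names(tracks)))
      stop("duplicate track ids in manifest")
    return(list(tracks = tracks, manifest = d))
  }
  if (!all(c("time", "koor") %in% names(d)))
    stop("missing 'time'/'koor' columns in ", path)
  idcol <- intersect(c("cell", "cell_id", "id"), names(d))
  if (length(idcol) > 0) {
    sp <- split(d, d[[idcol[1]]])
    tracks <- lapply(names(sp), function(nm) {
      .validate_track_rows(sp[[nm]], paste0(path, " [", nm, "]"))
      lane_trajectory(sp[[nm]]$time, sp[[nm]]$koor, cell_id = nm)
    })
    names(tracks) <- names(sp)
  } else {
    tracks <- list(.read_one_trajectory(path))
    names(tracks) <- attr(tracks[[1]], "cell_id")
  }
  manifest <- data.frame(id = names(tracks), lane_length = NA_real_,
                         width = NA_real_, tip_shape = NA_character_,
                         source = "unknown", file = basename(path))
  list(tracks = tracks, manifest = manifest)
}

#' Run the full trajectory-quantification pipeline
#'
#' Executes, per lane length: track filtering, spatial occupancy and speed
#' profiles with change-point estimation of the repolarization distance
#' xi0, velocity spectra with log-normal peak fits; then pools the speed
#' distribution, regresses the migration period on lane length (skipped
#' with a notice when fewer than three lengths are present) and extracts
#' reversal-time statistics inside the xi0 tip regions.
#'
#' @param input A list with `tracks` and `manifest` (as returned by
#'   [read_trajectories()] or [generate_ensemble()]), or a path accepted
#'   by [read_trajectories()].
#' @param xi0 Reversal-region width, micrometres (default 55).
#' @param bin_width Spatial bin width, micrometres (default 5).
#' @param min_duration Track-filter minimum duration, minutes.
#' @param out_dir Optional directory for CSV artifacts and a JSON metadata
#'   sidecar.
#' @param seed Seed recorded in the metadata (the pipeline itself is
#'   deterministic).
#' @return An object of class `lane_report`: list with `filter`,
#'   `profiles`, `changepoints`, `speed_distribution`, `spectra`,
#'   `period_fit` (or NULL), `reversals`, `reversal_summary`, `xi0_mean`
#'   and `notices`.
#' @export
run_pipeline <- function(input, xi0 = 55, bin_width = 5, min_duration = 2160,
                         out_dir = NULL, seed = NULL) {
  if (is.character(input)) input <- read_trajectories(input)
  tracks <- input$tracks
  manifest <- input$manifest
  stopifnot(!is.null(tracks), !is.null(manifest))
  lane_of <- stats::setNames(manifest$lane_length, manifest$id)
  for (nm in names(tracks)) {
    if (is.na(attr(tracks[[nm]], "lane_length")) && nm %in% names(lane_of))
      attr(tracks[[nm]], "lane_length") <- lane_of[[nm]]
  }
  notices <- character(0)
  flt <- filter_tracks(tracks, min_duration = min_duration, xi0 = xi0)
  tracks <- flt$tracks
  lengths <- sort(unique(vapply(tracks, function(t) attr(t, "lane_length"), 0)))
  profiles <- list(); cps <- list(); spectra <- list(); revs <- list()
  period_rows <- list()
  for (L in lengths) {
    sel <- tracks[vapply(tracks, function(t) attr(t, "lane_length") == L, TRUE)]
    key <- as.character(L)
    profiles[[key]] <- spatial_profiles(sel, lane_length = L,
                                        bin_width = bin_width)
    cps[[key]] <- tryCatch(fit_changepoints(profiles[[key]]),
                           error = function(e) {
                             notices <<- c(notices, paste0("changepoint L=", L,
                                                           ": ", e$message))
                             NULL
                           })
    spectra[[key]] <- velocity_spectrum(sel)
    period_rows[[key]] <- data.frame(lane_length = L,
                                     period = spectra[[key]]$period_T)
    region <- reversal_region(L, xi0)
    ev <- lapply(sel, detect_reversals, region = region)
    ev <- do.call(rbind, c(ev, list(make.row.names = FALSE)))
    if (!is.null(ev) && nrow(ev) > 0) ev$lane_length <- L
    revs[[key]] <- ev
  }
  period_fit <- NULL
  if (length(lengths) >= 3) {
    period_fit <- period_vs_length(do.call(rbind, period_rows))
  } else {
    notices <- c(notices,
                 "period-vs-length regression skipped: fewer than 3 lane lengths")
  }
  reversals <- do.call(rbind, c(revs, list(make.row.names = FALSE)))
  rev_summary <- NULL
  if (!is.null(reversals) && nrow(reversals) > 0) {
    rev_summary <- data.frame(
      n_events = nrow(reversals),
      mean_t_R = mean(reversals$t_R),
      median_t_R = stats::median(reversals$t_R),
      mode_t_R = reversal_time_mode(reversals$t_R))
  }
  xi0s <- unlist(lapply(cps, function(c)
    if (is.null(c) || c$fully_ramped) NULL else c(c$xi0_left, c$xi0_right)))
  report <- structure(list(
    filter = flt$report, profiles = profiles, changepoints = cps,
    speed_distribution = speed_distribution(tracks),
    spectra = spectra, period_fit = period_fit,
    reversals = reversals, reversal_summary = rev_summary,
    xi0_mean = if (length(xi0s) > 0) mean(xi0s) else NA_real_,
    lane_lengths = lengths, xi0 = xi0, bin_width = bin_width,
    notices = notices), class = "lane_report")
  if (!is.null(out_dir)) .write_report(report, out_dir, seed)
  report
}

.write_report <- function(report, out_dir, seed) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (key in names(report$profiles))
    utils::write.csv(report$profiles[[key]],
                     file.path(out_dir, paste0("profile_L", key, ".csv")),
                     row.names = FALSE)
  utils::write.csv(report$speed_distribution,
                   file.path(out_dir, "speed_distribution.csv"),
                   row.names = FALSE)
  spectra_df <- do.call(rbind, lapply(names(report$spectra), function(key) {
    s <- report$spectra[[key]]
    data.frame(lane_length = as.numeric(key), frequency = s$frequencies,
               amplitude = s$mean_amplitude)
  }))
  utils::write.csv(spectra_df, file.path(out_dir, "spectra.csv"),
                   row.names = FALSE)
  if (!is.null(report$reversals))
    utils::write.csv(report$reversals, file.path(out_dir, "reversals.csv"),
                     row.names = FALSE)
  cps_df <- do.call(rbind, lapply(names(report$changepoints), function(key) {
    c <- report$changepoints[[key]]
    if (is.null(c)) return(NULL)
    data.frame(lane_length = as.numeric(key), xi0_left = c$xi0_left,
               xi0_right = c$xi0_right, plateau_speed = c$plateau_speed,
               fully_ramped = c$fully_ramped)
  }))
  if (!is.null(cps_df))
    utils::write.csv(cps_df, file.path(out_dir, "changepoints.csv"),
                     row.names = FALSE)
  meta <- list(package = "microlane",
               version = as.character(utils::packageVersion("microlane")),
               xi0 = report$xi0, bin_width = report$bin_width,
               seed = if (is.null(seed)) NA else seed,
               lane_lengths = report$lane_lengths,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(report$period_fit))
    meta$period_fit <- list(slope = report$period_fit$slope,
                            x_intercept = report$period_fit$x_intercept,
                            v_c = report$period_fit$v_c)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.lane_report <- function(x, ...) {
  cat("microlane analysis report\n")
  cat(sprintf("  lane lengths: %s um\n", paste(x$lane_lengths, collapse = ", ")))
  if (!is.na(x$xi0_mean))
    cat(sprintf("  mean tip-to-changepoint distance xi0: %.1f um\n", x$xi0_mean))
  if (!is.null(x$period_fit))
    cat(sprintf("  dT/dL = %.4f h/um, x-intercept %.1f um, v_c = %.3f um/min\n",
                x$period_fit$slope, x$period_fit$x_intercept, x$period_fit$v_c))
  if (!is.null(x$reversal_summary))
    cat(sprintf("  reversals (xi0 = %g um): n = %d, mean t_R = %.1f min, mode = %.0f min\n",
                x$xi0, x$reversal_summary$n_events, x$reversal_summary$mean_t_R,
                x$reversal_summary$mode_t_R))
  for (nt in x$notices) cat("  note:", nt, "\n")
  invisible(x)
}
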