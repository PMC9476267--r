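#' Read GPS fixes from CSV or GPX
#'
#' Reads a fix table with columns `cow_id`, `timestamp` (ISO-8601, UTC
#' assumed), `x`, `y` (metres in a planar projection). Duplicate
#' (cow, timestamp) rows are dropped with a warning; rows are sorted by cow
#' and time. GPX track files are accepted read-only: trackpoint `lon`/`lat`
#' are mapped onto `x`/`y` unchanged (a documented planar assumption; feed
#' projected GPX only).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"gpx"`.
#' @return A tibble of fixes sorted by `cow_id`, `timestamp`.
#' @export
read_fixes <- function(path, format = c("auto", "csv", "gpx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fix file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else "csv"
  fixes <- if (format == "gpx") read_fixes_gpx(path) else read_fixes_csv(path)
  n0 <- nrow(fixes)
  fixes <- dplyr::distinct(fixes, .data$cow_id, .data$timestamp,
                           .keep_all = TRUE)
  if (nrow(fixes) < n0)
    warning(sprintf("dropped %d duplicate (cow_id, timestamp) row(s)",
                    n0 - nrow(fixes)), call. = FALSE)
  dplyr::arrange(fixes, .data$cow_id, .data$timestamp)
}

read_fixes_csv <- function(path) {
  fixes <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                           col_types = readr::cols(.default = readr::col_guess()))
  assert_columns(fixes, c("cow_id", "timestamp", "x", "y"), "fix table")
  raw <- fixes$timestamp
  if (!inherits(raw, "POSIXct")) {
    parsed <- as.POSIXct(as.character(raw), tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                        "%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS"),
                         optional = TRUE)
    bad <- which(is.na(parsed) & !is.na(raw))
    if (length(bad) > 0)
      stop("unparseable timestamp at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
    fixes$timestamp <- parsed
  }
  fixes$cow_id <- as.character(fixes$cow_id)
  fixes
}

read_fixes_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stop("GPX file contains no tracks", call. = FALSE)
  rows <- purrr::map_dfr(trks, function(trk) {
    name <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    tibble::tibble(
      cow_id = if (is.na(name) || name == "") "track1" else name,
      timestamp = as.POSIXct(
        xml2::xml_text(xml2::xml_find_first(pts, "./time")),
        tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ"),
      x = as.numeric(xml2::xml_attr(pts, "lon")),
      y = as.numeric(xml2::xml_attr(pts, "lat")))
  })
  rows
}

#' Write fixes as CSV (and GPX)
#'
#' `write_fixes()` writes the interchange CSV (ISO-8601 UTC timestamps).
#' `write_fixes_gpx()` writes one `<trk>` per cow with `x`/`y` stored in the
#' `lon`/`lat` attributes, the inverse of the [read_fixes()] GPX mapping.
#'
#' @param fixes a fix tibble.
#' @param path output path.
#' @param config_hash optional provenance hash written as a leading `#`
#'   comment line.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path, config_hash = NULL) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (!is.null(config_hash))
    writeLines(sprintf("# grazemix config_hash=%s", config_hash), path)
  readr::write_csv(out, path, append = !is.null(config_hash),
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
write_fixes_gpx <- function(fixes, path) {
  esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             "<gpx version=\"1.1\" creator=\"grazemix\">")
  for (id in unique(fixes$cow_id)) {
    f <- fixes[fixes$cow_id == id, ]
    lines <- c(lines, "<trk>", sprintf("<name>%s</name>", esc(id)), "<trkseg>")
    lines <- c(lines, sprintf(
      "<trkpt lat=\"%.10g\" lon=\"%.10g\"><time>%s</time></trkpt>",
      f$y, f$x, format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")))
    lines <- c(lines, "</trkseg>", "</trk>")
  }
  writeLines(c(lines, "</gpx>"), path)
  invisible(path)
}

#' Build per-cow trajectories with step statistics
#'
#' Orders fixes within cow and derives, for each arriving fix, the elapsed
#' time `dt` (s), `step_length` (m, Euclidean), `speed` (m/s), absolute
#' `heading` (rad, counterclockwise from +x) and relative `turn_angle`
#' (rad in (-pi, pi]). The turning angle is undefined (NA) for the first
#' step of a cow and across gaps longer than `gap_tolerance`; distances
#' still accumulate across gaps.
#'
#' @param fixes fix tibble (`cow_id`, `timestamp`, `x`, `y`).
#' @param gap_tolerance seconds; `dt` beyond this flags a gap (default
#'   2 x 300 s).
#' @return The fix tibble with step-statistic columns appended; cows with a
#'   single fix keep `NA` statistics and are listed in the
#'   `single_fix_cows` attribute.
#' @export
build_trajectory <- function(fixes, gap_tolerance = 600) {
  assert_columns(fixes, c("cow_id", "timestamp", "x", "y"), "fixes")
  if (any(!is.finite(fixes$x) | !is.finite(fixes$y)))
    stop("fix coordinates must be finite", call. = FALSE)
  traj <- dplyr::arrange(tibble::as_tibble(fixes), .data$cow_id,
                         .data$timestamp)
  traj <- dplyr::group_by(traj, .data$cow_id)
  traj <- dplyr::mutate(traj,
    dt = as.numeric(.data$timestamp) - dplyr::lag(as.numeric(.data$timestamp)),
    step_length = sqrt((.data$x - dplyr::lag(.data$x))^2 +
                         (.data$y - dplyr::lag(.data$y))^2),
    speed = .data$step_length / .data$dt,
    heading = atan2(.data$y - dplyr::lag(.data$y),
                    .data$x - dplyr::lag(.data$x)),
    gap = !is.na(.data$dt) & .data$dt > gap_tolerance,
    turn_angle = wrap_angle(.data$heading - dplyr::lag(.data$heading)))
  traj <- dplyr::mutate(traj,
    turn_angle = ifelse(.data$gap | dplyr::lag(.data$gap, default = TRUE),
                        NA_real_, .data$turn_angle))
  traj <- dplyr::ungroup(traj)
  counts <- dplyr::count(traj, .data$cow_id)
  singles <- counts$cow_id[counts$n < 2]
  if (length(singles) > 0)
    warning(sprintf("%d cow(s) have fewer than 2 fixes and carry no steps",
                    length(singles)), call. = FALSE)
  attr(traj, "single_fix_cows") <- singles
  attr(traj, "gap_tolerance") <- gap_tolerance
  traj
}

#' Flag GPS outlier fixes by speed and turning angle
#'
#' Scans each cow's fixes in time order, measuring the incoming speed from
#' the last *accepted* fix, so a single teleport-and-return spike flags
#' exactly the displaced fix and not its innocent successor. A fix is
#' flagged when the incoming speed exceeds `speed_max`, or when the
#' incoming and outgoing speeds both exceed `spike_speed` while the turning
#' angle at the fix exceeds `turn_min_deg` in magnitude (the spike
#' signature of an out-and-back position error).
#'
#' @param traj a trajectory (or plain fix) tibble.
#' @param speed_max hard sustained-speed gate, m/s (default 2.5).
#' @param spike_speed spike-rule speed, m/s (default 1.5).
#' @param turn_min_deg spike-rule minimum |turning angle|, degrees
#'   (default 150).
#' @return A logical vector along the rows of `traj`; the input is not
#'   modified.
#' @export
detect_outliers <- function(traj, speed_max = 2.5, spike_speed = 1.5,
                            turn_min_deg = 150) {
  stopifnot(speed_max > 0, spike_speed > 0, turn_min_deg > 0)
  if (nrow(traj) == 0) return(logical(0))
  assert_columns(traj, c("cow_id", "timestamp", "x", "y"), "traj")
  turn_min <- turn_min_deg * pi / 180
  flags <- logical(nrow(traj))
  ord <- order(traj$cow_id, traj$timestamp)
  for (ids in split(ord, traj$cow_id[ord])) {
    n <- length(ids)
    if (n < 2) next
    x <- traj$x[ids]; y <- traj$y[ids]
    tt <- as.numeric(traj$timestamp[ids])
    # fast path: nothing can trip either rule
    naive <- sqrt(diff(x)^2 + diff(y)^2) / diff(tt)
    if (all(naive <= spike_speed)) next
    f <- logical(n)
    last <- 1L
    for (i in 2:n) {
      dt_in <- tt[i] - tt[last]
      d_in <- sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2)
      v_in <- d_in / dt_in
      if (v_in > speed_max) { f[i] <- TRUE; next }
      if (v_in > spike_speed && i < n) {
        dt_out <- tt[i + 1] - tt[i]
        d_out <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
        if (d_out / dt_out > spike_speed) {
          h_in <- atan2(y[i] - y[last], x[i] - x[last])
          h_out <- atan2(y[i + 1] - y[i], x[i + 1] - x[i])
          if (abs(wrap_angle(h_out - h_in)) > turn_min) {
            f[i] <- TRUE; next
          }
        }
      }
      last <- i
    }
    flags[ids] <- f
  }
  flags
}

#' Remove flagged fixes and rebuild step statistics
#'
#' @param traj a trajectory tibble.
#' @param flags logical vector from [detect_outliers()].
#' @param gap_tolerance passed to [build_trajectory()]; defaults to the
#'   tolerance stored on `traj` when present.
#' @return A rebuilt trajectory on the retained fixes.
#' @export
remove_and_rebuild <- function(traj, flags, gap_tolerance = NULL) {
  if (length(flags) != nrow(traj))
    stop("flags must align with the rows of traj", call. = FALSE)
  gap_tolerance <- gap_tolerance %||% attr(traj, "gap_tolerance") %||% 600
  kept <- traj[!flags, setdiff(names(traj),
                               c("dt", "step_length", "speed", "heading",
                                 "gap", "turn_angle"))]
  if (nrow(kept) == 0) {
    warning("all fixes flagged; returning an empty trajectory",
            call. = FALSE)
    return(kept)
  }
  build_trajectory(kept, gap_tolerance = gap_tolerance)
}
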