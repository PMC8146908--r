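#' Parse NMEA 0183 position sentences
#'
#' Decodes GGA and RMC sentences from a GNSS text log into decimal-degree
#' fixes (WGS84 assumed; south/west negative). Sentences with a failing
#' checksum or malformed fields are skipped with a warning. Timestamps are
#' UTC seconds of day, the resolution the sentences carry.
#'
#' @param x A file path or a character vector of sentences.
#' @return A tibble with `timestamp` (s UTC), `lat`, `lon` (decimal
#'   degrees), `quality` (GGA fix indicator; `NA` for RMC), `sentence`.
#' @examples
#' parse_nmea("$GPGGA,123519,4807.038,N,01131.000,E,1,08,0.9,545.4,M,46.9,M,,*47")
#' @export
parse_nmea <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x, warn = FALSE) else x
  empty <- tibble::tibble(timestamp = numeric(0), lat = numeric(0),
                          lon = numeric(0), quality = integer(0),
                          sentence = character(0))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty)
  fixes <- list()
  skipped <- 0L
  for (ln in lines) {
    f <- parse_nmea_line(ln)
    if (is.null(f)) next             # not a positional sentence: ignore
    if (identical(f, "bad")) { skipped <- skipped + 1L; next }
    fixes[[length(fixes) + 1L]] <- f
  }
  if (skipped > 0)
    warning(sprintf("skipped %d malformed or checksum-failing NMEA sentence(s)",
                    skipped), call. = FALSE)
  if (length(fixes) == 0) {
    if (skipped > 0 || length(lines) > 0)
      abort("no valid NMEA position sentence in a non-empty stream",
            class = "sv_parse_error")
    return(empty)
  }
  dplyr::bind_rows(fixes)
}

parse_nmea_line <- function(ln) {
  if (!startsWith(ln, "$")) return("bad")
  star <- regexpr("*", ln, fixed = TRUE)
  body <- if (star > 0) substr(ln, 2, star - 1) else substr(ln, 2, nchar(ln))
  if (star > 0) {
    want <- suppressWarnings(strtoi(substr(ln, star + 1, star + 2), 16L))
    got <- Reduce(bitwXor, utf8ToInt(body), 0L)
    if (is.na(want) || want != got) return("bad")
  }
  f <- strsplit(body, ",", fixed = TRUE)[[1]]
  type <- substr(f[1], 3, 5)
  if (!type %in% c("GGA", "RMC")) return(NULL)
  parse_pos <- function(tstr, lats, lath, lons, lonh, quality) {
    tsec <- nmea_time(tstr)
    lat <- nmea_deg(lats, lath)
    lon <- nmea_deg(lons, lonh)
    if (anyNA(c(tsec, lat, lon))) return("bad")
    if (abs(lat) > 90 || abs(lon) > 180) return("bad")
    tibble::tibble(timestamp = tsec, lat = lat, lon = lon,
                   quality = quality, sentence = type)
  }
  if (type == "GGA") {
    if (length(f) < 7) return("bad")
    q <- suppressWarnings(as.integer(f[7]))
    parse_pos(f[2], f[3], f[4], f[5], f[6], if (is.na(q)) NA_integer_ else q)
  } else {
    if (length(f) < 7) return("bad")
    if (!identical(f[3], "A")) return("bad")  # void fix
    parse_pos(f[2], f[4], f[5], f[6], f[7], NA_integer_)
  }
}

nmea_time <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) || nchar(sub("\\..*", "", s)) < 6) return(NA_real_)
  hh <- floor(v / 1e4); mm <- floor((v - hh * 1e4) / 100)
  ss <- v - hh * 1e4 - mm * 100
  hh * 3600 + mm * 60 + ss
}

# ddmm.mmmm (+ hemisphere letter) -> signed decimal degrees
nmea_deg <- function(s, hemi) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) || !hemi %in% c("N", "S", "E", "W")) return(NA_real_)
  deg <- floor(v / 100)
  dec <- deg + (v - deg * 100) / 60
  if (hemi %in% c("S", "W")) -dec else dec
}

#' Attach the nearest-in-time GPS fix to each frame result
#'
#' Each frame receives the fix whose timestamp is nearest its own, provided
#' the gap is at most `max_gap` seconds (default 2 s — one logging interval
#' of the deployed monitor); otherwise the frame stays untagged
#' (`lat`/`lon` = NA).
#'
#' @param results Data frame of per-frame results with a `timestamp` column
#'   (see [summarize_frames()]); both inputs time-sorted.
#' @param fixes Tibble from [parse_nmea()].
#' @param max_gap Maximum |frame time - fix time| in seconds.
#' @return `results` with `lat`, `lon` and `fix_timestamp` columns.
#' @export
tag_frames <- function(results, fixes, max_gap = 2) {
  results <- tibble::as_tibble(results)
  lat <- lon <- ft <- rep(NA_real_, nrow(results))
  if (nrow(fixes) > 0 && nrow(results) > 0) {
    o <- order(fixes$timestamp)
    fixes <- fixes[o, , drop = FALSE]
    pos <- findInterval(results$timestamp, fixes$timestamp)
    for (i in seq_len(nrow(results))) {
      cand <- unique(pmin(pmax(c(pos[i], pos[i] + 1L), 1L), nrow(fixes)))
      dt <- abs(fixes$timestamp[cand] - results$timestamp[i])
      j <- cand[which.min(dt)]
      if (min(dt) <= max_gap) {
        lat[i] <- fixes$lat[j]; lon[i] <- fixes$lon[j]
        ft[i] <- fixes$timestamp[j]
      }
    }
  }
  results$lat <- lat; results$lon <- lon; results$fix_timestamp <- ft
  results
}

#' Summarize per-bulb detections into per-frame yield rows
#'
#' @param bulbs Tibble of detections from [detect_bulbs()] (rows from many
#'   frames may be concatenated); needs `frame_id`, `timestamp`,
#'   `diameter_mm`, `size_class`.
#' @param frames Optional tibble (`frame_id`, `timestamp`) enumerating all
#'   processed frames, so frames with zero detections still appear.
#' @param names Size-class names in increasing order.
#' @return Tibble with `frame_id`, `timestamp`, `n_small`, `n_medium`,
#'   `n_large`, `mean_diameter_mm`.
#' @export
summarize_frames <- function(bulbs, frames = NULL,
                             names = c("small", "medium", "large")) {
  bulbs <- tibble::as_tibble(bulbs)
  base <- if (!is.null(frames)) {
    tibble::as_tibble(frames)[, c("frame_id", "timestamp")]
  } else {
    dplyr::distinct(bulbs[, c("frame_id", "timestamp")])
  }
  counts <- bulbs |>
    dplyr::mutate(size_class = factor(as.character(.data$size_class),
                                      levels = names)) |>
    dplyr::group_by(.data$frame_id) |>
    dplyr::summarise(
      n_small = sum(.data$size_class == names[1], na.rm = TRUE),
      n_medium = sum(.data$size_class == names[2], na.rm = TRUE),
      n_large = sum(.data$size_class == names[3], na.rm = TRUE),
      mean_diameter_mm = mean(.data$diameter_mm),
      .groups = "drop")
  out <- dplyr::left_join(base, counts, by = "frame_id")
  out |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                ~ ifelse(is.na(.x), 0L, as.integer(.x)))) |>
    dplyr::arrange(.data$frame_id)
}

#' Export a geo-tagged yield map
#'
#' Writes (a) a CSV with one row per frame (`frame_id`, `timestamp`, `lat`,
#' `lon`, `n_small`, `n_medium`, `n_large`, `mean_diameter_mm`; untagged
#' frames keep empty lat/lon) and (b) optionally a GeoJSON (RFC 7946)
#' FeatureCollection of Point features carrying the same properties, from
#' which untagged frames are omitted.
#'
#' @param results Tibble from [summarize_frames()] + [tag_frames()].
#' @param csv_path Output CSV path.
#' @param geojson_path Optional output GeoJSON path.
#' @return Invisibly, the written paths.
#' @export
export_yield_map <- function(results, csv_path, geojson_path = NULL) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0)
    abort("no frame results to export", class = "sv_domain_error")
  need <- c("frame_id", "timestamp", "n_small", "n_medium", "n_large",
            "mean_diameter_mm")
  stopifnot(all(need %in% colnames(results)))
  if (!"lat" %in% colnames(results)) results$lat <- NA_real_
  if (!"lon" %in% colnames(results)) results$lon <- NA_real_
  cols <- c("frame_id", "timestamp", "lat", "lon", "n_small", "n_medium",
            "n_large", "mean_diameter_mm")
  tryCatch(
    utils::write.csv(as.data.frame(results[, cols]), csv_path,
                     row.names = FALSE, na = ""),
    error = function(e) abort(paste0("cannot write ", csv_path, ": ",
                                     conditionMessage(e)),
                              class = "sv_io_error"))
  paths <- csv_path
  if (!is.null(geojson_path)) {
    tagged <- results[!is.na(results$lat) & !is.na(results$lon), , drop = FALSE]
    features <- lapply(seq_len(nrow(tagged)), function(i) {
      r <- tagged[i, ]
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(r$lon, r$lat)),
           properties = list(frame_id = r$frame_id, timestamp = r$timestamp,
                             n_small = r$n_small, n_medium = r$n_medium,
                             n_large = r$n_large,
                             mean_diameter_mm = r$mean_diameter_mm))
    })
    doc <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(doc, geojson_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    paths <- c(paths, geojson_path)
  }
  invisible(paths)
}
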