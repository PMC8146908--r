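gga_munich <- "$GPGGA,123519,4807.038,N,01131.000,E,1,08,0.9,545.4,M,46.9,M,,*47"

test_that("GGA and RMC sentences decode to decimal degrees", {
  fixes <- parse_nmea(gga_munich)
  expect_identical(nrow(fixes), 1L)
  expect_equal(fixes$lat, 48 + 7.038 / 60, tolerance = 1e-9)
  expect_equal(fixes$lon, 11 + 31 / 60, tolerance = 1e-9)
  expect_equal(fixes$timestamp, 12 * 3600 + 35 * 60 + 19)
  expect_identical(fixes$quality, 1L)

  # southern / western hemispheres are negative (no checksum is tolerated)
  s <- parse_nmea("$GPGGA,000001,4530.000,S,07322.500,W,1,05,1.0,30.0,M,0.0,M,,")
  expect_equal(s$lat, -45.5)
  expect_equal(s$lon, -(73 + 22.5 / 60))

  rmc <- parse_nmea("$GPRMC,123519,A,4807.038,N,01131.000,E,022.4,084.4,230394,003.1,W")
  expect_equal(rmc$lat, 48 + 7.038 / 60)
  expect_identical(rmc$sentence, "RMC")
})

test_that("malformed sentences are skipped, empty streams are empty", {
  expect_identical(nrow(parse_nmea(character(0))), 0L)

  corrupted <- sub("\\*47", "*48", gga_munich)
  expect_warning(fixes <- parse_nmea(c(gga_munich, corrupted)),
                 "skipped 1")
  expect_identical(nrow(fixes), 1L)

  # unknown sentence types are ignored silently
  expect_identical(nrow(parse_nmea(c(gga_munich, "$GPGSV,1,1,00*79"))), 1L)

  expect_error(suppressWarnings(parse_nmea(c(corrupted, corrupted))),
               class = "sv_parse_error")
})

test_that("frames get the nearest fix within the gap ceiling", {
  res <- tibble::tibble(frame_id = 0:2, timestamp = c(10, 20, 30),
                        n_small = 1L, n_medium = 0L, n_large = 0L,
                        mean_diameter_mm = 40)
  fixes <- tibble::tibble(timestamp = c(9.4, 11.2, 28.9),
                          lat = c(45.1, 45.2, 45.3),
                          lon = c(-73.1, -73.2, -73.3),
                          quality = 1L, sentence = "GGA")
  tagged <- tag_frames(res, fixes, max_gap = 2)
  expect_equal(tagged$lat, c(45.1, NA, 45.3))  # 9.4 nearer than 11.2; 20 has no fix
  expect_equal(tagged$fix_timestamp, c(9.4, NA, 28.9))

  none <- tag_frames(res, fixes[0, ], max_gap = 2)
  expect_true(all(is.na(none$lat)))
})

test_that("yield-map export conserves counts and round-trips", {
  bulbs <- tibble::tibble(
    frame_id = c(0L, 0L, 0L, 1L, 2L),
    timestamp = c(0, 0, 0, 2.5, 5),
    diameter_mm = c(38, 40, 60, 48, 50),
    size_class = c("small", "small", "large", "medium", "medium"))
  frames <- tibble::tibble(frame_id = 0:3, timestamp = c(0, 2.5, 5, 7.5))
  res <- summarize_frames(bulbs, frames)
  expect_identical(nrow(res), 4L)
  expect_identical(res$n_small[1], 2L)
  expect_identical(res$n_large[1], 1L)
  expect_identical(res$n_medium[2], 1L)
  expect_identical(res$n_small[4] + res$n_medium[4] + res$n_large[4], 0L)
  expect_equal(sum(res$n_small + res$n_medium + res$n_large), nrow(bulbs))

  fixes <- tibble::tibble(timestamp = c(0, 2.5), lat = c(45.123456, 45.2),
                          lon = c(-73.654321, -73.4), quality = 1L,
                          sentence = "GGA")
  tagged <- tag_frames(res, fixes, max_gap = 1)
  csv <- file.path(withr::local_tempdir(), "ym.csv")
  gj <- sub("csv$", "geojson", csv)
  export_yield_map(tagged, csv, gj)

  back <- utils::read.csv(csv)
  expect_identical(nrow(back), 4L)  # untagged frames keep a CSV row
  expect_equal(sum(back$n_small + back$n_medium + back$n_large), nrow(bulbs))
  expect_equal(round(back$lat[1], 6), round(tagged$lat[1], 6))
  expect_equal(round(back$lon[1], 6), round(tagged$lon[1], 6))

  doc <- jsonlite::read_json(gj)
  expect_identical(doc$type, "FeatureCollection")
  expect_identical(length(doc$features), 2L)  # untagged frames omitted
  f1 <- doc$features[[1]]
  expect_identical(f1$geometry$type, "Point")
  expect_equal(f1$geometry$coordinates[[1]], tagged$lon[1])
  expect_equal(as.numeric(f1$properties$n_small), 2)

  expect_error(export_yield_map(res[0, ], csv), class = "sv_domain_error")
})

test_that("generated NMEA logs parse back to the simulated track", {
  spec <- scene_spec(width = 64, height = 64, n_bulbs = 0, seed = 3)
  sq <- generate_sequence(spec, n_frames = 4, fix_interval = 2.5)
  dir <- withr::local_tempdir()
  paths <- write_sequence(sq, dir)
  fixes <- parse_nmea(paths$nmea)
  expect_identical(nrow(fixes), nrow(sq$fixes))
  expect_equal(fixes$lat, sq$fixes$lat, tolerance = 1e-5)
  expect_equal(fixes$lon, sq$fixes$lon, tolerance = 1e-5)
  expect_equal(fixes$timestamp, sq$fixes$timestamp, tolerance = 1e-3)
})
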