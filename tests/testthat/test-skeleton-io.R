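test_that("MAK JSON write/read round-trips trajectories in both units", {
  tr <- clean_walk("healthy", 2)$trajectory
  f_m <- withr::local_tempfile(fileext = ".json")
  f_mm <- withr::local_tempfile(fileext = ".json")
  write_mak_json(tr, f_m, units = "m")
  write_mak_json(tr, f_mm, units = "mm")
  back_m <- read_mak_json(f_m)
  back_mm <- read_mak_json(f_mm)
  expect_equal(back_m$times, tr$times, tolerance = 1e-12)
  for (j in names(tr$joints)) {
    expect_equal(back_m$joints[[j]], tr$joints[[j]], tolerance = 1e-12,
                 ignore_attr = TRUE)
    # mm stream scales by exactly 1000 on disk, identical in memory
    expect_equal(back_mm$joints[[j]], tr$joints[[j]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # second round trip is value-stable
  f2 <- withr::local_tempfile(fileext = ".json")
  write_mak_json(back_m, f2, units = "m")
  expect_identical(read_mak_json(f2)$joints, back_m$joints)
})

test_that("reader returns depth values as serialized for a tiny stream", {
  mk_frame <- function(t, z) list(t = t, joints = list(
    ANKLE_RIGHT = c(0.1, 0.08, z), ANKLE_LEFT = c(-0.1, 0.08, z),
    HIP_LEFT = c(-0.1, 0.9, z), HIP_RIGHT = c(0.1, 0.9, z)))
  z <- c(4.50, 4.48, 4.46)
  doc <- list(trial_id = "t1", fps_nominal = 30, units = "m",
              frames = lapply(1:3, function(i) mk_frame((i - 1) / 30, z[i])))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  got <- read_mak_json(f)
  expect_equal(got$joints$ANKLE_RIGHT[, "z"], z)
  # same stream serialized in millimeters reads back identically
  doc_mm <- doc
  doc_mm$units <- "mm"
  doc_mm$frames <- lapply(doc$frames, function(fr) {
    fr$joints <- lapply(fr$joints, function(p) p * 1000); fr
  })
  f_mm <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc_mm, f_mm, auto_unbox = TRUE, digits = NA)
  expect_equal(read_mak_json(f_mm)$joints$ANKLE_RIGHT[, "z"], z)
})

test_that("reader drops incomplete frames and enforces stream contracts", {
  mk_frame <- function(t, joints) list(t = t, joints = joints)
  full <- list(ANKLE_RIGHT = c(0, 0, 4), ANKLE_LEFT = c(0, 0, 4),
               HIP_LEFT = c(0, 1, 4), HIP_RIGHT = c(0, 1, 4))
  frames <- lapply(0:9, function(i) mk_frame(i / 30, full))
  frames[[4]]$joints$ANKLE_LEFT <- NULL       # one incomplete frame
  doc <- list(trial_id = "x", fps_nominal = 30, units = "m", frames = frames)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  got <- read_mak_json(f)
  expect_equal(got$load_report$frames_dropped, 1L)
  expect_length(got$times, 9L)

  # required joints absent in most frames is a hard error
  doc_bad <- doc
  doc_bad$frames <- lapply(doc$frames, function(fr) {
    fr$joints$HIP_LEFT <- NULL; fr
  })
  jsonlite::write_json(doc_bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_mak_json(f), "required joints")

  # non-monotone timestamps name the offending index
  doc_ts <- doc
  doc_ts$frames[[6]]$t <- doc_ts$frames[[2]]$t
  jsonlite::write_json(doc_ts, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_mak_json(f), "non-monotone.*6")

  writeLines("{not json", f)
  expect_error(read_mak_json(f), "malformed JSON")
  expect_error(read_mak_json("/nonexistent/file.json"), "not found")
})

test_that("marker CSV round-trips and names missing markers", {
  set.seed(42)
  n <- 100
  times <- (0:(n - 1)) / 100
  markers <- lapply(stats::setNames(nm = c("LASI", "RASI", "LPSI", "RPSI")),
                    function(m) matrix(stats::rnorm(3 * n), n, 3))
  ms <- marker_trajectory_set(times, markers)
  f <- withr::local_tempfile(fileext = ".csv")
  write_marker_csv(ms, f)
  back <- read_marker_csv(f)
  expect_equal(back$times, ms$times, tolerance = 1e-12)
  for (m in names(markers))
    expect_equal(back$markers[[m]], ms$markers[[m]], tolerance = 1e-12,
                 ignore_attr = TRUE)

  df <- utils::read.csv(f, check.names = FALSE)
  utils::write.csv(df[, !grepl("RPSI", names(df))], f, row.names = FALSE)
  expect_error(read_marker_csv(f), "missing marker RPSI")

  lines <- readLines(f)
  lines[5] <- paste0(lines[5], ",0.1")       # ragged row
  writeLines(lines, f)
  expect_error(read_marker_csv(f), "line 5")
})

test_that("axis role maps follow the two-system convention", {
  mak <- axis_roles_for("MAK")
  moc <- axis_roles_for("MoCap")
  expect_equal(mak$ml_axis, "x")
  expect_equal(mak$ap_axis, "z")
  expect_equal(mak$depth_axis, "z")
  expect_equal(moc$ap_axis, "x")
  expect_equal(moc$ml_axis, "z")
  expect_equal(mak$v_axis, "y")
  expect_equal(moc$v_axis, "y")
  for (r in list(mak, moc))
    expect_setequal(c(r$ap_axis, r$ml_axis, r$v_axis), c("x", "y", "z"))
  expect_error(axis_roles_for("vicon"), "unknown system")
  expect_error(axis_roles("x", "x", "y"), "permutation")
})
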