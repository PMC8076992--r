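test_that("segments_csv parsing groups, sorts and validates sessions", {
  seg <- make_session(c("awake", "light"), c(10, 300),
                      "2019-03-04 22:50:00")
  path <- withr::local_tempfile(fileext = ".csv")
  df <- seg
  df$start <- format(df$start, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(df, path, row.names = FALSE)

  ss <- read_sessions(path)
  expect_equal(nrow(ss), 2L)
  expect_equal(sum(ss$duration_min), 310)
  expect_equal(ss$stage, c("awake", "light"))

  # shuffled rows parse to the identical session
  utils::write.csv(df[c(2, 1), ], path, row.names = FALSE)
  ss2 <- read_sessions(path)
  expect_equal(tibble::as_tibble(ss2), tibble::as_tibble(ss))
})

test_that("non-contiguous sessions are rejected and logged, or repaired", {
  seg <- make_session(c("light", "deep"), c(100, 50), "2019-03-04 23:00:00")
  seg$start[2] <- seg$start[2] + 5 * 60  # 5-min gap
  good <- make_session(c("light", "rem"), c(200, 60), "2019-03-05 23:00:00",
                       session = "ok")
  path <- withr::local_tempfile(fileext = ".csv")
  df <- dplyr::bind_rows(seg, good)
  df$start <- format(df$start, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(df, path, row.names = FALSE)

  ss <- suppressMessages(read_sessions(path))
  expect_equal(unique(ss$session_id), "ok")
  rej <- rejected_sessions(ss)
  expect_equal(nrow(rej), 1L)
  expect_match(rej$reason, "contiguous")

  repaired <- suppressMessages(
    read_sessions(path, on_noncontiguous = "repair"))
  expect_setequal(unique(repaired$session_id), c("sess1", "ok"))
  expect_equal(repaired$duration_min[repaired$session_id == "sess1"], 100)
})

test_that("unknown stage labels and bad durations are hard errors", {
  seg <- make_session(c("light", "nrem3"), c(100, 50),
                      "2019-03-04 23:00:00")
  expect_error(as_sleep_sessions(seg), "nrem3")
  seg2 <- make_session(c("light", "deep"), c(100, 0), "2019-03-04 23:00:00")
  expect_error(as_sleep_sessions(seg2), "duration")
})

test_that("jsonl dialect reconstructs contiguous segments from one object", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  obj <- list(participant_id = "p1", site_id = "s1", session_id = "n1",
              start = "2019-03-04T23:00:00",
              segments = data.frame(stage = c("awake", "light", "rem"),
                                    duration_min = c(10, 200, 60)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, dataframe = "rows"),
             path)
  ss <- read_sessions(path, dialect = "jsonl")
  expect_equal(nrow(ss), 3L)
  expect_equal(as.numeric(diff(ss$start), units = "mins"), c(10, 200))
})

test_that("PHQ-8 reader scores complete records and flags incomplete ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- data.frame(participant_id = c("a", "b", "c"),
                     completion_ts = "2019-06-01T10:00:00",
                     item1 = c(1, 3, 1), item2 = c(1, 3, 0),
                     item3 = c(2, 3, 1), item4 = c(0, 3, 2),
                     item5 = c(0, 3, NA), item6 = c(1, 3, 0),
                     item7 = c(0, 3, 1), item8 = c(1, 3, 3))
  utils::write.csv(rows, path, row.names = FALSE)
  ph <- read_phq8(path)
  expect_equal(ph$total, c(6L, 24L, NA))
  expect_equal(ph$sleep_subscore, c(2L, 3L, 1L))
  expect_equal(ph$complete, c(TRUE, TRUE, FALSE))

  rows$item2[1] <- 4
  utils::write.csv(rows, path, row.names = FALSE)
  expect_error(read_phq8(path), "row 1")
})

test_that("demographics enums are validated with fixed reference levels", {
  d <- as_demographics(data.frame(
    participant_id = "a", site_id = "s1", age = 44, gender = "male",
    education = "degree_or_above", income = "not_mentioned"))
  expect_equal(levels(d$gender)[1], "female")
  expect_equal(levels(d$education)[1], "below_degree")
  expect_equal(levels(d$income)[1], "lt15k")
  expect_error(as_demographics(data.frame(
    participant_id = "a", site_id = "s1", age = 44, gender = "m",
    education = "degree_or_above", income = "lt15k")), "gender")
  expect_error(as_demographics(data.frame(
    participant_id = "a", site_id = "s1", age = -1, gender = "male",
    education = "degree_or_above", income = "lt15k")), "age")
})

test_that("write_table round-trips values and renders missing as empty", {
  path <- withr::local_tempfile(fileext = ".csv")
  # empty list of records -> header-only CSV
  empty <- tibble::tibble(feature = character(), beta1 = numeric())
  write_table(empty, path)
  expect_equal(nrow(read_table(path)), 0L)

  fx <- worked_fixture_nights()
  fv <- extract_features(fx, as.POSIXct("2019-03-15 10:00:00", tz = "UTC"))
  fv$REM_L <- NA_real_
  write_table(fv, path)
  raw <- readLines(path)
  expect_true(grepl(",,", raw[2], fixed = TRUE))  # empty REM_L cell

  back <- read_table(path)
  for (f in setdiff(sleep_feature_names(), "REM_L")) {
    expect_equal(back[[f]], fv[[f]], tolerance = 1e-6)
  }
  expect_true(is.na(back$REM_L))
  expect_equal(back$n_nights, fv$n_nights)  # integers exact
})
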