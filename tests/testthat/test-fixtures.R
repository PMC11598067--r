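# The packaged reference tables and the annotation readers/writers.

printed_table1 <- data.frame(
  bunch_id = sprintf("Bunch_%02d", 1:10),
  n_total = c(47, 52, 36, 39, 55, 51, 63, 52, 76, 40),
  r_mean_total_mm = c(10.1, 9.3, 9.3, 9.2, 9.5, 10.1, 9.8, 10.1, 9.5, 9.5),
  r_sd_total_mm = c(0.35, 0.52, 0.44, 0.59, 0.57, 0.36, 0.42, 0.45, 0.40,
                    0.38),
  stringsAsFactors = FALSE)

printed_visible <- rbind(
  c(30, 28, 26), c(37, 32, 41), c(21, 25, 24), c(23, 23, 21),
  c(31, 31, 27), c(32, 35, 29), c(33, 39, 34), c(30, 34, 29),
  c(41, 43, 48), c(29, 24, 24))
printed_radius_px <- rbind(
  c(25, 23, 21), c(21, 21, 19), c(24, 23, 19), c(25, 22, 19),
  c(24, 23, 22), c(23, 22, 25), c(22, 21, 22), c(22, 21, 21),
  c(20, 20, 19), c(22, 21, 20))
printed_diffs <- rbind(
  c(0, 0, 0), c(-5, 3, -3), c(-1, -1, -1), c(-1, 0, -1), c(-3, -3, -6),
  c(1, 2, -3), c(-2, -3, -3), c(-2, 1, 0), c(-3, -1, -3), c(-5, -1, 0))

test_that("ground-truth loader reproduces every printed cell", {
  gt <- load_table1()
  expect_identical(nrow(gt$bunches), 10L)
  expect_identical(nrow(gt$views), 30L)
  expect_equal(gt$bunches$bunch_id, printed_table1$bunch_id)
  expect_equal(gt$bunches$n_total, printed_table1$n_total)
  expect_equal(gt$bunches$r_mean_total_mm, printed_table1$r_mean_total_mm)
  expect_equal(gt$bunches$r_sd_total_mm, printed_table1$r_sd_total_mm)
  for (b in 1:10) {
    for (v in 1:3) {
      row <- gt$views[gt$views$bunch_id == printed_table1$bunch_id[b] &
                      gt$views$view_index == v, ]
      expect_identical(nrow(row), 1L)
      expect_equal(row$n_visible, printed_visible[b, v])
      expect_equal(row$r_mean_px, printed_radius_px[b, v])
    }
  }
  expect_equal(sum(gt$bunches$n_total), 511)
})

test_that("estimate loader reconstructs counts from authoritative differences", {
  est <- load_table2()
  expect_identical(nrow(est), 30L)
  gt <- load_table1()$views
  for (b in 1:10) {
    for (v in 1:3) {
      id <- printed_table1$bunch_id[b]
      row <- est[est$bunch_id == id & est$view_index == v, ]
      expect_equal(row$diff, printed_diffs[b, v])
      expect_equal(row$n_est, printed_visible[b, v] + printed_diffs[b, v])
    }
  }
  expect_equal(sum(est$diff), -44)
  # the two internally inconsistent printed cells are flagged, the rest pass
  bad <- est[!est$consistent, ]
  expect_identical(nrow(bad), 2L)
  expect_setequal(paste(bad$bunch_id, bad$view_index),
                  c("Bunch_06 3", "Bunch_08 2"))
  expect_equal(bad$n_est_printed[bad$bunch_id == "Bunch_06"], 36)
  expect_equal(bad$n_est[bad$bunch_id == "Bunch_06"], 26)
})

test_that("annotation files round-trip losslessly in CSV and JSON", {
  views <- load_table1()$views
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_annotations(views, path)
    back <- read_annotations(path)
    expect_equal(back$bunch_id, views$bunch_id)
    expect_equal(back$view_index, views$view_index)
    expect_equal(back$n_visible, views$n_visible)
    expect_equal(back$r_mean_px, views$r_mean_px)
  }
})

test_that("JSON annotations carry per-berry radius lists", {
  rec <- data.frame(bunch_id = c("A", "A"), view_index = c(1L, 2L),
                    n_visible = c(2L, 3L), r_mean_px = c(20.5, 21))
  rec$radii_px <- list(c(20, 21), c(19.5, 21, 22.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(rec, path)
  back <- read_annotations(path)
  expect_equal(back$radii_px[[2]], c(19.5, 21, 22.5))
})

test_that("empty record sets are written and read as valid empty files", {
  empty <- data.frame(bunch_id = character(), view_index = integer(),
                      n_visible = integer(), r_mean_px = numeric())
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_annotations(empty, path)
    expect_identical(nrow(read_annotations(path)), 0L)
  }
})

test_that("schema violations are rejected with explicit errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(bunch_id = "A", view_index = 1,
                              n_visible = -1, r_mean_px = 20),
                   path, row.names = FALSE)
  expect_error(read_annotations(path), "negative")

  utils::write.csv(data.frame(bunch_id = "A", view_index = 5,
                              n_visible = 3, r_mean_px = 20),
                   path, row.names = FALSE)
  expect_error(read_annotations(path), "view_index")

  utils::write.csv(data.frame(x = 1), path, row.names = FALSE)
  expect_error(read_annotations(path), "missing column")

  expect_error(write_annotations(data.frame(bunch_id = "A"), path),
               "missing column")
})
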