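test_that("tables round-trip through CSV and config files cell-for-cell", {
  tbl <- small_table()
  csv <- withr::local_tempfile(fileext = ".csv")
  cfg <- withr::local_tempfile(fileext = ".yaml")
  write_indicator_table(tbl, csv)
  write_chdi_config(tbl$specs, scoring_config(seed = 3), cfg)

  back <- read_indicator_table(csv, cfg)
  expect_identical(back$units, tbl$units)
  expect_identical(colnames(back$values), colnames(tbl$values))
  expect_equal(back$values, tbl$values, tolerance = 0)

  conf <- read_chdi_config(cfg)
  expect_s3_class(conf$scoring, "scoring_config")
  expect_identical(conf$scoring$seed, 3L)
  expect_identical(conf$specs$q1$direction, "cost")
  expect_identical(conf$specs$a1$scale, "ordinal")
})

test_that("reader rejects malformed tables with informative errors", {
  tbl <- small_table(n = 10)
  csv <- withr::local_tempfile(fileext = ".csv")
  cfg <- withr::local_tempfile(fileext = ".yaml")
  write_chdi_config(tbl$specs, NULL, cfg)

  # column present in the file but not declared
  df <- data.frame(unit = tbl$units, tbl$values, mystery = 1)
  utils::write.csv(df, csv, row.names = FALSE)
  expect_error(read_indicator_table(csv, cfg), "mystery")

  # declared indicator absent from the file
  df <- data.frame(unit = tbl$units, tbl$values[, -1])
  utils::write.csv(df, csv, row.names = FALSE)
  expect_error(read_indicator_table(csv, cfg), "r1")

  # non-numeric cell in a numeric column
  df <- data.frame(unit = tbl$units, tbl$values)
  df$r2[3] <- "lots"
  utils::write.csv(df, csv, row.names = FALSE)
  expect_error(read_indicator_table(csv, cfg), "non-numeric")

  # undeclared ordinal level
  df <- data.frame(unit = tbl$units, tbl$values)
  df$a1[2] <- 99
  utils::write.csv(df, csv, row.names = FALSE)
  expect_error(read_indicator_table(csv, cfg), "undeclared")
})

test_that("missing cells are rejected unless incomplete units are dropped", {
  tbl <- small_table(n = 12)
  tbl$values[4, 2] <- NA
  expect_error(validate_indicator_table(tbl), "H04")
  expect_message(kept <- validate_indicator_table(tbl,
                                                  drop_incomplete_units = TRUE),
                 "dropping 1")
  expect_identical(nrow(kept$values), 11L)
  expect_false("H04" %in% kept$units)
})

test_that("duplicate units and absent domains are rejected", {
  tbl <- small_table(n = 8)
  expect_error(indicator_table(tbl$values, tbl$specs,
                               units = rep("H01", 8)), "duplicate unit")
  keep <- names(tbl$specs)[1:6]            # drops all quality indicators
  expect_error(indicator_table(tbl$values[, keep], tbl$specs[keep],
                               units = tbl$units), "quality_and_safety")
})

test_that("direction adjustment negates cost columns, once", {
  tbl <- small_table(n = 20)
  before <- tbl$values
  adj <- apply_direction(tbl)
  expect_true(attr(adj, "direction_adjusted"))
  expect_equal(adj$values[, "q1"], -before[, "q1"])
  expect_equal(adj$values[, "r1"], before[, "r1"])   # benefit untouched
  # idempotent
  twice <- apply_direction(adj)
  expect_equal(twice$values, adj$values, tolerance = 0)
  # reversed ranking preserved
  expect_identical(order(adj$values[, "q2"]), rev(order(before[, "q2"])))
})
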