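test_that("the reference fixture holds every printed cell", {
  ref <- reference_tables()
  expect_equal(sum(ref$table_id == "T1"), 15) # 12 tapered cells + 3 blocks
  expect_equal(sum(ref$table_id == "T2"), 36) # 12 cells x 3 quantities
  expect_equal(sum(ref$table_id == "T3"), 12) # 3 heights x 4 quantities
  expect_equal(
    ref$value[ref$table_id == "T3" & ref$quantity == "alpha3_limit"],
    c(11.0, 15.0, 19.3)
  )
  expect_true(all(ref$value[ref$quantity == "area_lost"] < 0))
})

test_that("replication covers every fixture cell and checks formula-anchored rows", {
  rep <- replicate_study()
  ref <- reference_tables()
  expect_equal(nrow(rep), nrow(ref))
  expect_true(all(!is.na(rep$model_value)))
  expect_equal(rep$abs_deviation, abs(rep$model_value - rep$paper_value))

  # angles and base lengths are anchored to the half-arcsine formula and must
  # match the printed values; areas carry deviations only
  checked <- rep[!is.na(rep$within_tol), ]
  expect_equal(nrow(checked), 12)
  expect_true(all(checked$table_id == "T3"))
  expect_true(all(checked$within_tol))
  expect_true(all(checked$abs_deviation[checked$quantity == "alpha3_limit"] <= 0.05))
  expect_equal(
    rep$model_value[rep$quantity == "groove_base_length"],
    rep(3.41, 3)
  )
  expect_true(all(is.na(rep$within_tol[rep$table_id %in% c("T1", "T2")])))

  # zero-taper block cells are desk-exact even though areas are not asserted
  blocks <- rep[rep$table_id == "T1" & rep$taper == 0, ]
  expect_equal(blocks$model_value, blocks$paper_value, tolerance = 1e-12)
})

test_that("replicated model output reproduces the published qualitative trends", {
  rep <- replicate_study()
  t1 <- rep[rep$table_id == "T1", ]
  for (h in unique(t1$height)) {
    sub <- t1[t1$height == h, ]
    sub <- sub[order(sub$taper), ]
    expect_true(all(diff(sub$model_value) < 0)) # area falls with taper
  }
  for (tp in unique(t1$taper)) {
    sub <- t1[t1$taper == tp, ]
    sub <- sub[order(sub$height), ]
    expect_true(all(diff(sub$model_value) > 0)) # area rises with height
  }
  gains <- rep[rep$table_id == "T2" & rep$quantity == "net_gain", ]
  expect_true(all(gains$model_value > 0))
  best <- gains[which.max(gains$model_value), ]
  expect_equal(c(best$height, best$taper), c(5, 18))
})

test_that("reports serialise deterministically and the CSV round-trips", {
  rep <- replicate_study()
  csv <- emit_report(rep, format = "csv")
  back <- readr::read_csv(I(csv), show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep))
  expect_equal(back$model_value, rep$model_value, tolerance = 1e-12)
  expect_equal(back$quantity, rep$quantity)

  js <- emit_report(rep, format = "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(nrow(parsed), nrow(rep))

  md <- emit_report(rep, format = "markdown")
  lines <- strsplit(md, "\n")[[1]]
  expect_equal(sum(grepl("total_area", lines)), 15)
  expect_equal(sum(grepl("net_gain", lines)), 12)
  expect_equal(sum(grepl("alpha3_limit", lines)), 3)
  # reference values rendered at printed precision
  expect_true(any(grepl("\\| 19.3 \\|", lines)))

  # identical input, identical document
  expect_identical(emit_report(rep, format = "csv"), csv)
})

test_that("an empty row set yields a valid header-only document", {
  empty <- replicate_study()[0, ]
  csv <- emit_report(empty, format = "csv")
  expect_match(csv, "^table_id,height,taper,quantity")
  md <- emit_report(empty, format = "markdown")
  expect_match(md, "## T1")
  expect_error(emit_report(tibble::tibble(a = 1)), "lacks column")
})

test_that("reports can be written to disk", {
  rep <- replicate_study()
  path <- withr::local_tempfile(fileext = ".csv")
  emit_report(rep, format = "csv", path = path)
  expect_true(file.exists(path))
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep))
})
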