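test_that("CSV round trip preserves fields and missingness", {
  rs <- make_records(6, seed = 3)
  rs$latitude[2] <- NA
  rs$longitude[2] <- NA
  rs$geocode_error_km[4] <- NA
  rs$morph[rs$sex == "female"][1] <- "cenea"
  rs$morph_group[rs$sex == "female"][1] <- "cenea"
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rs, path)
  back <- read_records(path)
  expect_equal(nrow(back), 6)
  for (col in c("voucher_id", "sex", "morph", "subspecies", "country")) {
    expect_identical(back[[col]], rs[[col]])
  }
  for (col in c("latitude", "longitude", "geocode_error_km")) {
    expect_equal(back[[col]], rs[[col]], tolerance = 1e-9)
  }
  expect_true(is.na(back$latitude[2]) && is.na(back$longitude[2]))
})

test_that("blank coordinate cells become missing, not zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "voucher_id,sex,morph,morph_group,subspecies,country,locality,latitude,longitude,geocode_error_km",
    "A1,female,,,,Kenya,site,1.5,36.2,10",
    "A2,male,,,,Kenya,site,,36.0,5",
    "A3,male,,,,Kenya,site,-2.0,35.1,"
  ), path)
  rs <- read_records(path)
  expect_equal(nrow(rs), 3)
  # lone longitude on row 2 is dropped to keep the both-or-neither invariant
  expect_true(is.na(rs$latitude[2]) && is.na(rs$longitude[2]))
  expect_true(is.na(rs$geocode_error_km[3]))
  expect_false(any(rs$latitude == 0, na.rm = TRUE))
})

test_that("duplicate voucher ids are a hard error naming both rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "voucher_id,sex,latitude,longitude,geocode_error_km",
    "BMNH933783,male,1,36,5",
    "X1,male,2,36,5",
    "BMNH933783,female,3,36,5"
  ), path)
  expect_error(read_records(path), "BMNH933783.*1 and 3")
})

test_that("unparseable coordinates are collected as problems, not errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "voucher_id,sex,latitude,longitude,geocode_error_km",
    "A1,male,not-a-number,36,5",
    "A2,male,2,36,5"
  ), path)
  rs <- read_records(path)
  pr <- record_problems(rs)
  expect_equal(nrow(pr), 2)  # unparseable latitude + lone-longitude drop
  expect_true(any(pr$voucher_id == "A1" & pr$field == "latitude"))
  expect_true(is.na(rs$latitude[1]) && is.na(rs$longitude[1]))
})

test_that("unknown CSV columns are preserved through a round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "voucher_id,sex,latitude,longitude,geocode_error_km,drawer",
    "A1,male,1,36,5,D-17"
  ), path)
  rs <- read_records(path)
  expect_identical(rs$drawer, "D-17")
  out <- withr::local_tempfile(fileext = ".csv")
  write_records(rs, out)
  expect_identical(read_records(out)$drawer, "D-17")
})

test_that("morph on a non-female record warns but does not fail", {
  df <- data.frame(voucher_id = "A1", sex = "male", morph = "cenea",
                   latitude = 1, longitude = 36, geocode_error_km = 5)
  expect_warning(rs <- record_set(df), "not sexed female")
  expect_equal(nrow(rs), 1)
})

test_that("geocode filter is strict at the threshold and drops missing", {
  rs <- make_records(4, seed = 1, error_km = c(39.9, 40.0, 40.1, 10))
  rs$latitude[4] <- NA
  rs$longitude[4] <- NA
  kept <- filter_geocoded(rs, 40)
  expect_identical(kept$voucher_id, "V001")  # 39.9 in, 40.0 out, missing out
  # infinite threshold on a fully geocoded set is the identity
  rs2 <- make_records(10, seed = 2)
  expect_identical(filter_geocoded(rs2, Inf)$voucher_id, rs2$voucher_id)
})

test_that("geocode filter is idempotent and monotone in the threshold", {
  rs <- make_records(50, seed = 7, error_km = runif(50, 0, 80))
  for (thr in c(10, 40, 60)) {
    f1 <- filter_geocoded(rs, thr)
    expect_identical(filter_geocoded(f1, thr)$voucher_id, f1$voucher_id)
  }
  small <- filter_geocoded(rs, 20)$voucher_id
  large <- filter_geocoded(rs, 50)$voucher_id
  expect_true(all(small %in% large))
})

test_that("tabulations count correctly, sort by count then key, and are
           permutation invariant", {
  rs <- make_records(0)
  expect_equal(nrow(tabulate_records(rs, "country")), 0)

  df <- data.frame(
    voucher_id = paste0("V", 1:5),
    sex = "male",
    country = c("Kenya", "Uganda", "Kenya", "Kenya", "Uganda"),
    latitude = 1:5, longitude = 31:35, geocode_error_km = 1
  )
  rs <- record_set(df)
  tab <- tabulate_records(rs, "country")
  expect_identical(tab$key, c("Kenya", "Uganda"))
  expect_identical(tab$count, c(3L, 2L))

  # brute-force dictionary oracle + permutation invariance
  rs2 <- make_records(200, seed = 11)
  tab2 <- tabulate_records(rs2, "country")
  oracle <- sort(table(rs2$country), decreasing = TRUE)
  expect_equal(sum(tab2$count), nrow(rs2))
  expect_equal(stats::setNames(tab2$count, tab2$key),
               stats::setNames(as.integer(oracle), names(oracle))[tab2$key])
  perm <- with_local_seed(5, rs2[sample(nrow(rs2)), ])
  tab3 <- tabulate_records(record_set(perm), "country")
  expect_identical(tab2, tab3)
})
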