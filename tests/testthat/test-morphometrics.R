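test_that("ratio suite computes available ratios and lists the rest as missing", {
  v <- vertebra_specimen("X-1", lengths_mm = c(coW = 12, coH = 10))
  r <- compute_ratio_suite(v, decimals = 1)
  expect_equal(unname(r$ratios["coW/coH"]), 1.2)
  expect_true(all(r$ratios > 0))
  # names partition the fixed vocabulary
  expect_length(intersect(names(r$ratios), r$missing), 0)
  expect_setequal(c(names(r$ratios), r$missing),
                  names(paleosnake:::RATIO_DEFS))

  only_cl <- vertebra_specimen("X-2", lengths_mm = c(cL = 50))
  r2 <- compute_ratio_suite(only_cl, 1)
  expect_length(r2$ratios, 0)
  expect_setequal(r2$missing, names(paleosnake:::RATIO_DEFS))
})

test_that("ratio rounding is half-up at the requested decimals", {
  v <- vertebra_specimen("X", lengths_mm = c(coW = 12.5, coH = 10))  # 1.25
  expect_equal(unname(compute_ratio_suite(v, 1)$ratios["coW/coH"]), 1.3)
  expect_equal(unname(compute_ratio_suite(v, 2)$ratios["coW/coH"]), 1.25)
})

test_that("ratio suite is scale invariant", {
  base <- c(cL = 50, prW = 90, coW = 12, coH = 10, nsH = 20, tvH = 80)
  r1 <- compute_ratio_suite(vertebra_specimen("a", lengths_mm = base), 3)
  for (c0 in c(0.1, 2, 17.3)) {
    rc <- compute_ratio_suite(vertebra_specimen("a", lengths_mm = base * c0), 3)
    expect_equal(rc$ratios, r1$ratios)
  }
})

test_that("non-positive measurements are rejected naming the field", {
  expect_error(vertebra_specimen("bad", lengths_mm = c(coW = -1, coH = 10)),
               "coW")
  expect_error(vertebra_specimen("bad", lengths_mm = c(cL = 0)), "cL")
  expect_error(vertebra_specimen("bad", angles_deg = c(alpha_syn = 190)),
               "alpha_syn")
})

test_that("trunk classification follows flags first, then the width/cL rule", {
  # diagnosis extremes: prW/cL = 111.4/62.7 > 1
  big <- vertebra_specimen("big", lengths_mm = c(prW = 111.4, cL = 62.7))
  expect_equal(classify_trunk_position(big), "MTV")
  # hypapophysis wins regardless of proportions
  expect_equal(classify_trunk_position(fixture_atv(prW = 200, cL = 50)), "ATV")
  # ratio exactly 1 is not anterior-of-posterior
  eq <- vertebra_specimen("eq", lengths_mm = c(prW = 50, cL = 50))
  expect_equal(classify_trunk_position(eq), "POSTERIOR_TRUNK")
  # nothing to go on
  expect_equal(classify_trunk_position(vertebra_specimen("na")), "UNKNOWN")
  # idempotent / independent of call order
  expect_equal(classify_trunk_position(big), classify_trunk_position(big))
  # poW switch
  pow <- vertebra_specimen("pow", lengths_mm = c(poW = 80, cL = 50))
  expect_equal(classify_trunk_position(pow, "poW"), "MTV")
  expect_equal(classify_trunk_position(pow, "prW"), "UNKNOWN")
})

test_that("size-estimation selection filters to MTV, sorts by width, breaks ties by id", {
  s1 <- fixture_mtv("m-big", prW = 111.4)
  s2 <- fixture_mtv("m-mid", prW = 90)
  s3 <- fixture_atv("a-1", prW = 70)
  sel <- select_size_estimation_specimens(list(s3, s2, s1))
  expect_equal(vapply(sel, `[[`, "", "specimen_id"), c("m-big", "m-mid"))

  expect_length(select_size_estimation_specimens(list(s3, fixture_atv("a-2"))), 0)

  t1 <- fixture_mtv("zzz", prW = 90); t2 <- fixture_mtv("aaa", prW = 90)
  sel2 <- select_size_estimation_specimens(list(t1, t2))
  expect_equal(vapply(sel2, `[[`, "", "specimen_id"), c("aaa", "zzz"))

  # sublist of input; stable under re-application
  again <- select_size_estimation_specimens(sel)
  expect_equal(vapply(again, `[[`, "", "specimen_id"),
               vapply(sel, `[[`, "", "specimen_id"))
})

test_that("measurement CSV and ratio reports round-trip", {
  ser <- sim_vertebral_series(n_vertebrae = 6, seed = 11)
  csv <- tempfile(fileext = ".csv")
  write_measurements_csv(ser, csv)
  back <- read_measurements_csv(csv)
  expect_length(back, 6)
  expect_equal(back[[3]]$lengths_mm["prW"], ser[[3]]$lengths_mm["prW"],
               tolerance = 1e-9)
  expect_equal(vapply(back, classify_trunk_position, ""),
               vapply(ser, classify_trunk_position, ""))

  reports <- lapply(ser, compute_ratio_suite, decimals = 2)
  p_csv <- tempfile(fileext = ".csv"); p_json <- tempfile(fileext = ".json")
  write_ratio_reports(reports, p_csv)
  write_ratio_reports(reports, p_json)
  from_csv <- utils::read.csv(p_csv, check.names = FALSE)
  from_json <- jsonlite::fromJSON(p_json)
  expect_equal(from_csv$`coW/coH`, from_json$`coW/coH`, tolerance = 1e-12)
  expect_equal(from_csv$specimen_id, from_json$specimen_id)
})
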