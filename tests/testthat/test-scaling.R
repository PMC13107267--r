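test_that("standardization rescales each study-consumer group to 100%", {
  recs <- quant_rows(resources = c("GOOSE", "SEAL", "PLANT"),
                     raw = c(30, 30, 60),
                     layer = c("Pr", "Sc", "He"))
  out <- standardize_shares(validate_records(recs, tiny_nodes()))
  expect_equal(out$share, c(25, 25, 50))

  single <- quant_rows(resources = "GOOSE", raw = 100)
  expect_equal(standardize_shares(validate_records(single, tiny_nodes()))$share,
               100)
})

test_that("standardization rejects degenerate and incommensurable groups", {
  zeros <- validate_records(quant_rows(raw = c(0, 0)), tiny_nodes())
  expect_error(standardize_shares(zeros), "all-zero raw values")

  mixed <- quant_rows(raw = c(60, 40))
  mixed$metric_type <- c("freq_occurrence", "relative_biomass")
  mixed <- validate_records(mixed, tiny_nodes())
  expect_error(standardize_shares(mixed), "mixed metric_type")
})

test_that("shares map onto the log2 ordinal scale with upper-inclusive bins", {
  expect_equal(scale_share(c(0, 3, 10, 50, 80)), c(0L, 1L, 2L, 4L, 8L))
  # boundaries are upper-inclusive; the keystone class starts above 67
  expect_equal(scale_share(c(5, 20, 67)), c(1L, 2L, 4L))
  expect_equal(scale_share(c(67 + 1e-9, 100)), c(8L, 8L))
  expect_error(scale_share(101), "outside")
  expect_error(scale_share(-0.1), "outside")
})

test_that("the ordinal map is monotone with range exactly {0,1,2,4,8}", {
  set.seed(7)
  x <- sort(c(0, 5, 20, 67, 100, runif(500, 0, 100)))
  sc <- scale_share(x)
  expect_true(all(diff(sc) >= 0))
  expect_setequal(unique(sc), c(0L, 1L, 2L, 4L, 8L))
})

test_that("per-study scores average with equal weight and half-up rounding", {
  expect_equal(average_scores(c(4, 2)), 3.0)
  expect_equal(average_scores(8), 8.0)
  expect_equal(average_scores(c(4, 4, 1)), 3.0)
  expect_equal(average_scores(c(1, 2)), 1.5)
  expect_equal(average_scores(c(1, 1, 2)), 1.3)
  # half away from zero, not banker's rounding
  expect_equal(average_scores(c(0, 1)), 0.5)
  expect_equal(average_scores(c(1, 2, 2, 2)), 1.8)
  expect_error(average_scores(numeric(0)), "no scores")
})

test_that("rounding to one decimal is idempotent and keeps [0, 8]", {
  set.seed(21)
  for (i in 1:50) {
    sc <- sample(c(0, 1, 2, 4, 8), sample(1:6, 1), replace = TRUE)
    s <- average_scores(sc)
    expect_gte(s, 0); expect_lte(s, 8)
    expect_identical(average_scores(s), s)
  }
})

test_that("case-study-only links get the constant 0.1 floor", {
  nodes <- tiny_nodes()
  one_case <- data.frame(
    study_id = "C1", pub_year = 2010L, consumer = "FOX", resource = "SEAL",
    layer = "Sc", metric_type = "anecdotal", raw_value = NA,
    study_months = "Jul", study_type = "case_study",
    excluded_review = FALSE, stringsAsFactors = FALSE)
  links <- scale_strengths(validate_records(one_case, nodes))
  expect_equal(links$strength, 0.1)
  expect_equal(links$provenance, "case_only")
  expect_equal(links$season, "summer")

  # the floor is a constant, not a sum over reports
  two_cases <- rbind(one_case, transform(one_case, study_id = "C2"))
  links2 <- scale_strengths(validate_records(two_cases, nodes))
  expect_equal(links2$strength, 0.1)
  expect_equal(links2$n_studies, 2L)

  # measured data dominate: case records are ignored for that link-season
  quant <- quant_rows(resources = "SEAL", raw = 100, layer = "Sc",
                      months = "Jul")
  mixprov <- rbind(quant, one_case)
  links3 <- scale_strengths(validate_records(mixprov, nodes))
  expect_equal(nrow(links3), 1L)
  expect_equal(links3$strength, 8.0)
  expect_equal(links3$provenance, "measured")
})

test_that("season-agnostic case reports floor both seasons", {
  nodes <- tiny_nodes()
  no_months <- data.frame(
    study_id = "C1", pub_year = 2010L, consumer = "FOX", resource = "SEAL",
    layer = "Sc", metric_type = "anecdotal", raw_value = NA,
    study_months = "", study_type = "case_study",
    excluded_review = FALSE, stringsAsFactors = FALSE)
  links <- scale_strengths(validate_records(no_months, nodes))
  expect_setequal(links$season, c("summer", "winter"))
  expect_true(all(links$strength == 0.1))
})

test_that("winter extrapolation is opt-in, copies summer, refuses overwrite", {
  nodes <- tiny_nodes()
  summer <- quant_rows(resources = c("GOOSE", "SEAL"), raw = c(30, 70),
                       layer = c("Pr", "Sc"), months = "Jun;Jul")
  recs <- validate_records(summer, nodes)
  listed <- data.frame(consumer = "FOX", resource = "SEAL", layer = "Sc",
                       stringsAsFactors = FALSE)

  links <- scale_strengths(recs, extrapolate = listed)
  wi <- links[links$season == "winter", ]
  expect_equal(nrow(wi), 1L)
  expect_equal(wi$resource, "SEAL")
  expect_equal(wi$strength, 8)  # copied from summer (70% -> 8)
  expect_equal(wi$provenance, "extrapolated")
  expect_equal(wi$n_studies, 0L)

  # not listed -> no winter link
  links0 <- scale_strengths(recs)
  expect_false("winter" %in% links0$season)

  # measured winter data already present -> refuse
  winter <- quant_rows(study = "W1", resources = "SEAL", raw = 100,
                       layer = "Sc", months = "Dec;Jan")
  both <- validate_records(rbind(summer, winter), nodes)
  expect_error(scale_strengths(both, extrapolate = listed),
               "measured winter strength already present")

  # a case-only winter floor is replaced by the extrapolated value
  case_w <- data.frame(
    study_id = "C1", pub_year = 2010L, consumer = "FOX", resource = "SEAL",
    layer = "Sc", metric_type = "anecdotal", raw_value = NA,
    study_months = "Dec", study_type = "case_study",
    excluded_review = FALSE, stringsAsFactors = FALSE)
  mix <- validate_records(rbind(summer, case_w), nodes)
  links2 <- scale_strengths(mix, extrapolate = listed)
  wi2 <- links2[links2$season == "winter" & links2$resource == "SEAL", ]
  expect_equal(wi2$provenance, "extrapolated")
  expect_equal(wi2$strength, 8)
})

test_that("unclassifiable quantitative studies are dropped with a warning", {
  nodes <- tiny_nodes()
  recs <- quant_rows(months = "Apr")
  expect_warning(links <- scale_strengths(validate_records(recs, nodes)),
                 "unclassifiable season")
  expect_equal(nrow(links), 0L)
})

test_that("records from excluded reviews never reach the scaled links", {
  nodes <- tiny_nodes()
  recs <- quant_rows(resources = c("GOOSE", "SEAL"), raw = c(50, 50))
  recs$excluded_review <- TRUE
  links <- scale_strengths(validate_records(recs, nodes))
  expect_equal(nrow(links), 0L)
})

test_that("group shares always sum to 100 on random study tables", {
  set.seed(101)
  for (i in 1:40) {
    sim <- simulate_records(synth_config(seed = i, n_nodes = 10L,
                                         n_studies = 15L, noise = 0.5))
    quant <- sim$records[sim$records$study_type == "quantitative", ]
    if (!nrow(quant)) next
    std <- standardize_shares(quant)
    sums <- tapply(std$share, paste(std$study_id, std$consumer), sum)
    expect_true(all(abs(sums - 100) < 1e-9))
  }
})

test_that("the vectorized scaling stage matches the brute-force reference", {
  for (seed in 1:25) {
    sim <- simulate_records(synth_config(seed = seed, n_nodes = 8L,
                                         n_studies = 12L, noise = 0.4,
                                         case_study_fraction = 0.4))
    got <- suppressWarnings(scale_strengths(sim$records))
    want <- oracle_scale_strengths(sim$records)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})
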