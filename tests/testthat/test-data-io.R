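test_that("a toy CSV round-trips through read_survey_csv", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "clus,house,pid,bt,aw,cp,age",
    "C1,H1,p1,0,1,1,30",
    "C1,H1,p2,1,1,0,41",
    "C1,H1,p3,0,0,0,22",
    "C2,H2,p4,0,1,1,35",
    "C2,H2,p5,0,1,1,28",
    "C2,H2,p6,1,1,1,55"), path)
  schema <- list(cluster = "clus", household = "house", person = "pid",
                 outcomes = c("bt", "aw", "cp"),
                 covariates = list(age = "continuous"))
  ds <- read_survey_csv(path, schema)
  expect_s3_class(ds, "survey_dataset")
  expect_equal(nrow(ds$df), 6)
  expect_equal(length(unique(ds$df$cluster_id)), 2)
  expect_equal(ds$covariate_names, "age")
  expect_true(all(ds$complete))

  out <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(ds, out)
  schema2 <- list(cluster = "cluster_id", household = "household_id",
                  person = "person_id", outcomes = c("y1", "y2", "y3"),
                  covariates = list(age = "continuous"))
  ds2 <- read_survey_csv(out, schema2)
  expect_equal(ds2$df[, c("y1", "y2", "y3", "age")],
               ds$df[, c("y1", "y2", "y3", "age")])
  expect_equal(ds2$X, ds$X)
})

test_that("nesting and domain violations are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("clus,house,y1,y2,y3",
               "C1,H1,0,1,1",
               "C2,H1,1,1,0"), path)
  schema <- list(cluster = "clus", household = "house",
                 outcomes = c("y1", "y2", "y3"))
  expect_error(read_survey_csv(path, schema), "more than one cluster")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("clus,house,y1,y2,y3",
               "C1,H1,0,don't know,1",
               "C1,H2,1,1,0"), path2)
  expect_error(read_survey_csv(path2, schema), "non-numeric")
  # same file parses once the code is declared missing
  schema$missing_codes <- "don't know"
  ds <- read_survey_csv(path2, schema)
  expect_equal(sum(ds$complete), 1)
  # a 2 is a domain error even though it is numeric
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("clus,house,y1,y2,y3", "C1,H1,0,2,1"), path3)
  expect_error(read_survey_csv(path3, schema), "outside")
  # unknown column in the schema
  schema$covariates <- list(not_there = "continuous")
  expect_error(read_survey_csv(path2, schema), "absent")
})

test_that("pattern tabulation reproduces the published survey table", {
  pt <- pattern_table(survey_pattern_counts)
  expect_equal(pt$total, 9311)
  # zero-count patterns are retained
  expect_equal(unname(pt$counts[c("001", "101")]), c(0, 0))
  expect_equal(unname(pt$percentages["000"]), 20.51)
  expect_equal(unname(pt$percentages["011"]), 46.62)
  expect_equal(sum(pt$percentages), 100, tolerance = 0.05)

  expect_equal(unname(marginal_counts(pt, 1)), c(1246, 13.4))
  expect_equal(unname(marginal_counts(pt, 2)), c(7191, 77.2))
  expect_equal(unname(marginal_counts(pt, 3)), c(5110, 54.9))
})

test_that("tabulate_patterns counts complete records and excludes missing", {
  df <- data.frame(cluster_id = "C1", household_id = "H1",
                   person_id = c("a", "b"),
                   y1 = c(1L, NA), y2 = c(1L, 1L), y3 = c(1L, 0L))
  ds <- survey_dataset(df)
  pt <- tabulate_patterns(ds)
  expect_equal(unname(pt$counts["111"]), 1)
  expect_equal(pt$total, 1)
  expect_equal(attr(pt, "n_missing"), 1)
  expect_equal(pt$total + attr(pt, "n_missing"), nrow(ds$df))

  # all-missing dataset cannot be tabulated
  df$y1 <- NA_integer_
  expect_error(tabulate_patterns(survey_dataset(df)), "no complete")
})

test_that("independent outcomes at expit(0) put 1/8 mass on each pattern", {
  cfg <- intercept_only_config(100, households = 10, persons = 8, seed = 31)
  pt <- tabulate_patterns(simulate_survey(cfg)$dataset)
  n <- pt$total
  se <- sqrt(0.125 * 0.875 / n)
  for (k in names(pt$counts))
    expect_lt(abs(pt$counts[[k]] / n - 0.125), 3 * se)
})

test_that("marginal counts are invariant to how patterns are supplied", {
  shuffled <- survey_pattern_counts[c(3, 1, 6, 2, 5, 4)]
  expect_equal(marginal_counts(pattern_table(shuffled), 2),
               marginal_counts(pattern_table(survey_pattern_counts), 2))
})

test_that("dataset invariants are enforced at construction", {
  base <- data.frame(cluster_id = "C1", household_id = "H1",
                     person_id = "p1", y1 = 1L, y2 = 0L, y3 = 1L)
  bad <- base
  bad$y2 <- 3L
  expect_error(survey_dataset(bad), "outside \\{0, 1, NA\\}")
  expect_error(survey_dataset(base[, -1]), "missing required")
})
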