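test_that("write/read round-trips datasets exactly", {
  # empty dataset -> header-only file -> empty dataset
  empty <- trial_dataset(data.frame(individual_id = character(),
                                    group = character(), sex = character(),
                                    trial_index = integer(),
                                    emerged = logical(),
                                    latency_s = numeric()))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials(empty, f)
  expect_identical(nrow(read_trials(f)), 0L)

  # single record maps emerged=1, latency=150 onto the schema
  one <- trial_dataset(data.frame(individual_id = "x", group = "infected",
                                  sex = "female", trial_index = 1L,
                                  emerged = TRUE, latency_s = 150))
  write_trials(one, f)
  back <- read_trials(f)
  expect_equal(nrow(back), 1L)
  expect_true(back$emerged)
  expect_equal(back$latency_s, 150)

  # full synthetic study: 87 individuals, full-precision latencies
  ds <- simulate_emergence(seed = 5)$dataset
  expect_equal(length(unique(ds$individual_id)), 87L)
  write_trials(ds, f)
  back <- read_trials(f)
  expect_equal(as.data.frame(back), as.data.frame(ds))
})

test_that("reader honours the table dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id;status;sx;day;out;secs",
               "c1;ctrl;M;1;yes;200",
               "c1;ctrl;M;2;no;"), f)
  dia <- trial_dialect(
    columns = list(individual_id = "id", group = "status", sex = "sx",
                   trial_index = "day", emerged = "out", latency_s = "secs"),
    group_labels = c(ctrl = "virus_free", inf = "infected"),
    sex_labels = c(M = "male", F = "female"),
    sep = ";")
  ds <- read_trials(f, dia)
  expect_equal(as.character(ds$group), rep("virus_free", 2))
  expect_equal(as.character(ds$sex), rep("male", 2))
  expect_equal(ds$emerged, c(TRUE, FALSE))
  expect_equal(ds$latency_s, c(200, NA))

  # dialect round-trips through YAML config
  cfgf <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(columns = list(individual_id = "id",
                                       group = "status", sex = "sx",
                                       trial_index = "day", emerged = "out",
                                       latency_s = "secs"),
                        group_labels = list(ctrl = "virus_free"),
                        sex_labels = list(M = "male"),
                        sep = ";"), cfgf)
  ds2 <- read_trials(f, read_dialect(cfgf))
  expect_equal(as.data.frame(ds2), as.data.frame(ds))
})

test_that("reader errors name the offending column or row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,group,sex,trial_index,emerged",
               "a,virus_free,male,1,1"), f)
  expect_error(read_trials(f), "latency_s")

  writeLines(c("individual_id,group,sex,trial_index,emerged,latency_s",
               "a,virus_free,male,1,1,100",
               "a,virus_free,male,oops,1,100"), f)
  expect_error(read_trials(f), "row 2")

  writeLines(c("individual_id,group,sex,trial_index,emerged,latency_s",
               "a,plague,male,1,1,100"), f)
  expect_error(read_trials(f), "group")
  expect_error(read_trials(withr::local_tempfile()), "not found")
})

test_that("every validation rule has a violating fixture that is flagged", {
  base <- function() data.frame(
    individual_id = c("a", "a", "b"), group = c("virus_free", "virus_free",
                                                "infected"),
    sex = c("male", "male", "female"), trial_index = c(1L, 2L, 1L),
    emerged = c(TRUE, FALSE, TRUE), latency_s = c(100, NA, 50),
    stringsAsFactors = FALSE)

  cases <- list(
    latency_bounds = function(d) { d$latency_s[3] <- 650; d },
    latency_missing = function(d) { d$latency_s[1] <- NA; d },
    latency_spurious = function(d) { d$latency_s[2] <- 30; d },
    trial_index_positive = function(d) { d$trial_index[3] <- 0L; d },
    trial_index_duplicate = function(d) { d$trial_index[2] <- 1L; d },
    inconsistent_group = function(d) { d$group[2] <- "infected"; d },
    inconsistent_sex = function(d) { d$sex[2] <- "female"; d },
    missing_field = function(d) { d$emerged[3] <- NA; d })
  for (rule in names(cases)) {
    ds <- trial_dataset(cases[[rule]](base()))
    rep <- validate_dataset(ds)
    expect_true(rule %in% rep$rule, label = paste("rule flagged:", rule))
  }
  expect_equal(nrow(validate_dataset(trial_dataset(base()))), 0L)

  # all violations reported, not just the first
  d <- base()
  d$latency_s[3] <- 700
  d$latency_s[2] <- 5
  rep <- validate_dataset(trial_dataset(d))
  expect_setequal(rep$rule, c("latency_bounds", "latency_spurious"))
})

test_that("default synthetic datasets validate cleanly", {
  for (seed in 1:3) {
    ds <- simulate_emergence(seed = seed)$dataset
    expect_equal(nrow(validate_dataset(ds)), 0L)
  }
})

test_that("constructor requires the full schema", {
  expect_error(trial_dataset(data.frame(individual_id = "a")),
               "missing required column")
})

test_that("the shipped example file reads through its dialect config", {
  csv <- system.file("extdata", "example_trials.csv",
                     package = "crickemerge")
  dia <- read_dialect(system.file("extdata", "example_dialect.yaml",
                                  package = "crickemerge"))
  ds <- read_trials(csv, dia)
  expect_equal(nrow(ds), 16L)
  expect_equal(nrow(validate_dataset(ds)), 0L)
  expect_equal(sort(unique(as.character(ds$group))),
               c("infected", "virus_free"))
})
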