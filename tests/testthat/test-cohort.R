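write_toy_table <- function(df, ext = "csv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = if (ext == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  path
}

toy_table <- function() {
  catL <- catalog_subset(feature_catalog(), "L")
  df <- data.frame(subject_id = c("a", "b", "c"))
  for (key in catL$key)
    df[[key]] <- if (key == "r11_heart_rate") c(40, 75, 120) else
      c("Y", "N", "Y")
  df
}

test_that("load_cohort decodes yes/no cells and preserves row order", {
  catL <- catalog_subset(feature_catalog(), "L")
  path <- write_toy_table(toy_table())
  cohort <- load_cohort(path, catL)
  expect_identical(rownames(cohort$values), c("a", "b", "c"))
  expect_equal(unname(cohort$values[, "r04_syncope"]), c(1, 0, 1))
  expect_equal(unname(cohort$values[, "r11_heart_rate"]), c(40, 75, 120))
})

test_that("load_cohort rejects schema and cell defects loudly", {
  catL <- catalog_subset(feature_catalog(), "L")
  df <- toy_table()
  df$r11_heart_rate <- NULL
  expect_error(load_cohort(write_toy_table(df), catL), "missing feature")

  df <- toy_table()
  df$not_a_feature <- "Y"
  expect_error(load_cohort(write_toy_table(df), catL), "unknown feature")

  df <- toy_table()
  df$r04_syncope[2] <- "maybe"
  expect_error(load_cohort(write_toy_table(df), catL),
               "unparseable binary cell 'maybe' at row 2")
})

test_that("missing values are rejected by default, imputed on request", {
  catL <- catalog_subset(feature_catalog(), "L")
  df <- toy_table()
  df$r04_syncope[1] <- NA
  df$r11_heart_rate[3] <- NA
  path <- write_toy_table(df)
  expect_error(load_cohort(path, catL), "missing value")
  cohort <- suppressMessages(load_cohort(path, catL, impute_missing = TRUE))
  expect_equal(unname(cohort$values[1, "r04_syncope"]), 0)   # binary -> 0
  expect_equal(unname(cohort$values[3, "r11_heart_rate"]),
               stats::median(c(40, 75)))                     # cont -> median
})

test_that("select_subset restricts columns and validates coverage", {
  cat45 <- feature_catalog()
  set.seed(1)
  values <- matrix(rbinom(5 * 45, 1, 0.3), 5, 45,
                   dimnames = list(paste0("s", 1:5), cat45$key))
  values[, "r08_bmi_numeric"] <- runif(5, 18, 30)
  values[, "r11_heart_rate"] <- runif(5, 50, 100)
  full <- cohort_matrix(values, cat45)
  sub <- select_subset(full, "L")
  expect_equal(ncol(sub$values), 8L)
  expect_identical(rownames(sub$values), rownames(values))
  expect_identical(select_subset(full, "LE")$values, full$values)
  expect_error(select_subset(sub, "LE"), "schema error")
})

test_that("min-max normalization maps extremes to 0/1 and is idempotent", {
  bin <- matrix(rep(c(0, 1), each = 7), 2, 7, byrow = TRUE)
  cohort <- toy_cohort(rbind(bin, matrix(0, 1, 7)), hr = c(40, 120, 75))
  norm <- minmax_normalize(cohort)
  hr <- unname(norm$values[, "r11_heart_rate"])
  expect_equal(hr, c(0, 1, 0.4375))                 # (75-40)/(120-40)
  bin_keys <- setdiff(colnames(norm$values), "r11_heart_rate")
  expect_identical(norm$values[, bin_keys], cohort$values[, bin_keys])
  expect_identical(minmax_normalize(norm)$values, norm$values)
  expect_equal(norm$normalization$x_min[norm$normalization$key ==
                                          "r11_heart_rate"], 40)
  # monotone: ordering within the feature is preserved
  expect_identical(order(hr), order(c(40, 120, 75)))
})

test_that("constant continuous feature normalizes to 0 with a warning", {
  cohort <- toy_cohort(matrix(0, 3, 7), hr = c(70, 70, 70))
  expect_warning(norm <- minmax_normalize(cohort), "constant")
  expect_equal(unname(norm$values[, "r11_heart_rate"]), c(0, 0, 0))
})

test_that("stored normalization maps new subjects, allowing out-of-range", {
  cohort <- toy_cohort(matrix(0, 3, 7), hr = c(40, 120, 75))
  norm <- minmax_normalize(cohort)
  new <- toy_cohort(matrix(0, 1, 7), hr = 160, ids = "n1")
  expect_message(out <- apply_normalization(new, norm$normalization),
                 "outside the training range")
  expect_equal(unname(out$values[, "r11_heart_rate"]), 1.5)
  expect_error(apply_normalization(new, NULL), "no stored normalization")
})

test_that("write/load round-trip reproduces identical values", {
  catL <- catalog_subset(feature_catalog(), "L")
  set.seed(7)
  cohort <- toy_cohort(matrix(rbinom(5 * 7, 1, 0.4), 5, 7),
                       hr = runif(5, 40, 170))
  path <- withr::local_tempfile(fileext = ".csv")
  side <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(minmax_normalize(cohort), path, normalization_path = side)
  back <- load_cohort(path, catL)
  expect_identical(back$values, minmax_normalize(cohort)$values)
  rec <- read_normalization(side)
  expect_equal(rec$key, "r11_heart_rate")
})
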