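test_that("registry reading types columns, maps missing codes, reports schema errors", {
  rows <- make_registry(list(registry_row(), registry_row(apgar5 = 7),
                             registry_row(apgar5 = 99)))
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  reg <- read_registry(f, missing_codes = list(apgar5 = 99))
  expect_equal(nrow(reg), 3)
  expect_equal(reg$apgar5, c(9, 7, NA))
  expect_s3_class(reg$birth_date, "Date")
  expect_equal(unname(attr(reg, "missingness")["apgar5"]), 1L)
  # required column absent -> error naming it
  rows2 <- rows[, setdiff(names(rows), "gest_weeks")]
  write.csv(rows2, f, row.names = FALSE)
  expect_error(read_registry(f), "gest_weeks")
  unlink(f)
})

test_that("malformed registry rows are dropped below the threshold, fatal above", {
  rows <- make_registry(c(replicate(20, registry_row(), simplify = FALSE),
                          list(registry_row(birthweight_g = "heavy"))))
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  expect_message(reg <- read_registry(f), "malformed")
  expect_equal(nrow(reg), 20)
  expect_error(read_registry(f, max_bad_frac = 0.01), "malformed")
  unlink(f)
})

test_that("the low-risk cascade retains boundaries and counts each record once", {
  # boundary values 2500 g, 4000 g, 37 w, 41 w are retained
  recs <- make_registry(list(
    registry_row(birthweight_g = 2500), registry_row(birthweight_g = 4000),
    registry_row(gest_weeks = 37), registry_row(gest_weeks = 41)))
  out <- apply_lowrisk_filters(recs)
  expect_equal(nrow(out$records), 4)
  expect_true(all(out$flowchart$n_excluded == 0))
  # 42 weeks is excluded at the gestational-age step
  recs2 <- make_registry(list(registry_row(gest_weeks = 42)))
  out2 <- apply_lowrisk_filters(recs2)
  expect_equal(out2$flowchart$n_excluded[out2$flowchart$label ==
                                           "gestational age <37 or >41 w"], 1)
})

test_that("an engineered cascade hits every exclusion step exactly once", {
  recs <- make_registry(list(
    registry_row(plurality = "multiple"),
    registry_row(municipality_id = "OUT"),
    registry_row(apgar5 = NA),
    registry_row(birthweight_g = 2400),
    registry_row(gest_weeks = 42),
    registry_row(anomaly = "yes"),
    registry_row(presentation = "other"),
    registry_row(birthweight_g = NA),
    registry_row(), registry_row(apgar5 = 5),
    registry_row(apgar5 = 7), registry_row(birthweight_g = 3999)))
  out <- apply_lowrisk_filters(recs, state_municipalities = "M01")
  expect_equal(out$flowchart$n_excluded, rep(1L, 8))
  expect_equal(attr(out$flowchart, "final"), 4)
  # conservation: initial - sum(excluded) = final
  expect_equal(attr(out$flowchart, "initial") - sum(out$flowchart$n_excluded),
               attr(out$flowchart, "final"))
  # idempotence: refiltering the output excludes nothing
  again <- apply_lowrisk_filters(out$records, state_municipalities = "M01")
  expect_equal(sum(again$flowchart$n_excluded), 0)
})

test_that("flowchart conservation holds on simulated registries", {
  study <- simulate_births(small_config(seed = 5, frac_nonlowrisk = 0.05,
                                        frac_missing_apgar = 0.002))
  out <- apply_lowrisk_filters(study$births)
  expect_equal(attr(out$flowchart, "initial") - sum(out$flowchart$n_excluded),
               attr(out$flowchart, "final"))
  expect_true(sum(out$flowchart$n_excluded) > 0) # the generator plants violations
})

test_that("outcome classification splits low scores into the reported subcategories", {
  out <- classify_outcome(c(7, 8, 2, 0, 5, 6, 10, 3))
  expect_equal(as.character(out$category),
               c("6-7", "normal", "0-2", "0-2", "3-5", "6-7", "normal", "3-5"))
  expect_equal(out$low, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_error(classify_outcome(c(5, NA)), "missing")
  expect_error(classify_outcome(11), "0, 10")
})

test_that("Pearson chi-square is uncorrected, symmetric, and rejects empty margins", {
  tab <- rbind(a = c(12, 30, 9), b = c(40, 22, 17))
  colnames(tab) <- c("x", "y", "z")
  res <- pearson_chi_square(tab)
  expect_equal(res$df, 2)
  # transposition and permutation invariance
  expect_equal(pearson_chi_square(t(tab))$statistic, res$statistic)
  expect_equal(pearson_chi_square(tab[, c(3, 1, 2)])$statistic, res$statistic)
  # proportional rows -> exactly independent
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(pearson_chi_square(prop)$statistic, 0)
  # no Yates correction on a 2x2 (continuity-corrected value would differ)
  t22 <- rbind(c(8, 12), c(15, 5))
  expect_equal(pearson_chi_square(t22)$statistic,
               unname(chisq.test(t22, correct = FALSE)$statistic))
  # dropping a level that holds all of one column's counts empties that margin
  sparse <- rbind(a = c(10, 5), b = c(8, 0), c = c(7, 0))
  colnames(sparse) <- c("x", "y")
  expect_error(pearson_chi_square(sparse, drop_levels = "a"), "margin",
               ignore.case = TRUE)
})

test_that("share_of_initial rounds half-up to two decimals", {
  expect_equal(share_of_initial(499493, 4166174), 11.99)
  expect_equal(share_of_initial(4575, 4166174), 0.11)
  expect_equal(share_of_initial(0, 1000), 0)
  expect_equal(share_of_initial(125, 100000), 0.13) # 0.125 rounds up
  expect_error(share_of_initial(1, 0), "positive")
})

test_that("the descriptive fixture tables have the published margins", {
  t1 <- table1_fixture()
  expect_equal(sum(t1$maternal_age["low", ]), 34980)
  expect_equal(sum(t1$maternal_age["normal", ]), 3133287) # 6 missing excluded
  expect_equal(sum(t1$education["low", ]), 34881) # 99 missing excluded
  expect_equal(unname(attr(t1$sex, "missing")), c(0, 0))
  totals <- attr(t1, "totals")
  for (nm in names(t1)) {
    miss <- attr(t1[[nm]], "missing")
    expect_equal(unname(rowSums(t1[[nm]]) + miss), unname(totals),
                 label = paste("margins of", nm))
  }
})
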