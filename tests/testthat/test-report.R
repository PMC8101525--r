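test_that("the published cross-tabs reproduce the study's exact rates", {
  d <- gastric_cohort_counts("sex")
  cs <- cohort_summary(d)
  expect_equal(cs$n_total, 339)
  expect_equal(cs$n_events, 195)
  expect_equal(cs$event_rate, 195 / 339)
  expect_equal(round(100 * cs$event_rate, 1), 57.5)
  expect_equal(round(100 * cs$censored_rate, 1), 42.5)
  expect_equal(cs$crosstabs$sex["male", "died"], 121)
  expect_equal(cs$crosstabs$sex["female", "censored"], 49)
  # every variable's counts sum to the cohort totals
  tab <- gastric_table1()
  died <- tapply(tab$died, tab$variable, sum)
  cens <- tapply(tab$censored, tab$variable, sum)
  expect_true(all(died == 195))
  expect_true(all(cens == 144))
  one <- cohort_summary(data.frame(time = 3, event = 1))
  expect_equal(one$event_rate, 1)
})

test_that("odds ratio summaries transform coefficients exactly", {
  fake <- structure(list(
    estimate = c("cure_(Intercept)" = 0, cure_g = log(2)),
    se = c("cure_(Intercept)" = 0.1, cure_g = (log(3) - log(1.5)) / (2 * qnorm(0.975))),
    vcov = diag(c(0.01, 0.05)), frame = list(inc_names = "g"),
    converged = TRUE), class = "curefrail")
  dimnames(fake$vcov) <- list(names(fake$estimate), names(fake$estimate))
  fake$se["cure_g"] <- (log(3) - log(2)) / qnorm(0.975)
  or <- odds_ratio_summary(fake, "g")
  expect_equal(unname(or["estimate"]), 2, tolerance = 1e-10)
  expect_equal(unname(or["upper"]), 3, tolerance = 1e-10)
  expect_equal(unname(or["lower"]), 2 * 2 / 3, tolerance = 1e-10)
  # reciprocal direction: OR 0.39 reads as about 2.56 for the reference level
  fake$estimate["cure_g"] <- log(0.39)
  rec <- odds_ratio_summary(fake, "g", direction = "ref-vs-level")
  expect_equal(unname(rec["estimate"]), 1 / 0.39, tolerance = 1e-10)
  expect_equal(round(unname(rec["estimate"]), 2), 2.56)
  expect_error(odds_ratio_summary(fake, "nope"), "unknown")
})

test_that("cure probability summaries respect the link and the profile", {
  fake <- structure(list(
    estimate = c("cure_(Intercept)" = 0, cure_g = 1),
    se = c(0.2, 0.2), vcov = diag(c(0.04, 0.04)),
    frame = list(inc_names = "g")), class = "curefrail")
  dimnames(fake$vcov) <- list(names(fake$estimate), names(fake$estimate))
  p0 <- cure_probability_summary(fake, NULL)
  expect_equal(unname(p0["estimate"]), 0.5)
  # a constant chain at b0 = logit(0.73) gives a degenerate 0.73 summary
  bchain <- structure(list(
    draws = matrix(c(qlogis(0.73), 0), 200, 2, byrow = TRUE,
                   dimnames = list(NULL, c("cure_(Intercept)", "cure_g"))),
    frame = list(inc_names = "g")),
    class = c("curefrail_bayes", "curefrail"))
  ps <- cure_probability_summary(bchain, NULL)
  expect_equal(unname(ps["estimate"]), 0.73, tolerance = 1e-12)
  expect_equal(unname(ps["lower"]), unname(ps["upper"]))
  # monotone in b0 draws
  bchain$draws[, 1] <- seq(-2, 2, length.out = 200)
  lo <- cure_probability_summary(bchain, NULL)
  bchain$draws[, 1] <- bchain$draws[, 1] + 1
  hi <- cure_probability_summary(bchain, NULL)
  expect_gt(hi[["estimate"]], lo[["estimate"]])
  expect_error(cure_probability_summary(fake, c(zz = 1)), "profile")
})

test_that("report tables have the declared schema and round-trip via CSV", {
  d <- simulate_cohort(gastric_scenario(n = 600), seed = 51)
  fit <- curefrail(gastric_formula, data = d,
                   control = curefrail_control(seed = 1, n_starts = 2))
  lt <- long_term_table(fit)
  expect_equal(names(lt), c("variable", "or", "or_lower", "or_upper",
                            "cure_prob", "cure_lower", "cure_upper"))
  # one level row plus one reference row per incidence dummy
  expect_equal(nrow(lt), 2 * length(fit$frame$inc_names))
  ref <- grepl("reference", lt$variable)
  expect_true(all(lt$or[ref] == 1))
  expect_true(all(lt$cure_prob >= 0 & lt$cure_prob <= 1))

  st <- short_term_table(classical = fit)
  expect_setequal(st$parameter,
                  c("scale", "theta", "shape", "cure_(Intercept)",
                    paste0("surv_", fit$frame$lat_names)))
  dir <- file.path(tempdir(), "reports")
  write_report_tables(dir, cohort = cohort_summary(d), short = st, long = lt)
  back <- read.csv(file.path(dir, "table2_short_term.csv"))
  expect_equal(back$classical_est, st$classical_est)
  expect_equal(back$parameter, st$parameter)
})
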