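test_that("normative OLS matches the closed-form toy fit", {
  # 4 NC subjects, ages 60/70/80/90, feature = 10 - 0.1*age +/- 0.05 pattern:
  # hand OLS gives beta = (10.15, -0.102), sigma = sqrt(0.008 / 2)
  rec <- subject_records(sprintf("s%d", 1:4), "V01", "NC",
                         age = c(60, 70, 80, 90), sex = "M", icv = 1.5e6,
                         field_strength = "3T")
  y <- 10 - 0.1 * c(60, 70, 80, 90) + c(0.05, -0.05, 0.05, -0.05)
  sets <- list(feature_set_spec("volume", 500, 1))
  tab <- feature_table(rec[, c("subject_id", "visit_id")],
                       matrix(y, 4, 1), sets)
  m <- fit_normative(tab, rec, covariates = "age")
  expect_equal(unname(m$beta[, 1]), c(10.15, -0.102), tolerance = 1e-12)
  expect_equal(unname(m$sigma[1]), sqrt(0.008 / 2), tolerance = 1e-10)

  # independent oracle: stats::lm on a random multi-covariate design
  rec2 <- toy_records(40, seed = 8)
  X2 <- matrix(rnorm(40 * 3), 40, 3)
  tab2 <- feature_table(rec2[, c("subject_id", "visit_id")], X2,
                        list(feature_set_spec("volume", 500, 3)))
  m2 <- fit_normative(tab2, rec2,
                      covariates = c("age", "sex", "icv", "field_strength"))
  fit <- lm(X2[, 2] ~ age + I(sex == "M") + icv + I(field_strength == "3T"),
            data = rec2)
  expect_equal(unname(m2$beta[, 2]), unname(coef(fit)), tolerance = 1e-8)
  expect_equal(unname(m2$sigma[2]), summary(fit)$sigma, tolerance = 1e-8)
})

test_that("normative fit rejects degenerate designs", {
  rec <- toy_records(20, seed = 2)
  rec$site <- rec$field_strength                   # collinear with fs dummies
  tab <- feature_table(rec[, c("subject_id", "visit_id")],
                       matrix(rnorm(20), 20, 1),
                       list(feature_set_spec("volume", 500, 1)))
  expect_error(fit_normative(tab, rec,
                             covariates = c("age", "field_strength", "site")),
               "collinear")
  tab3 <- feature_table(rec[1:3, c("subject_id", "visit_id")],
                        tab$X[1:3, , drop = FALSE],
                        list(feature_set_spec("volume", 500, 1)))
  expect_error(fit_normative(tab3, rec[1:3, ],
                             covariates = c("age", "sex", "icv", "field_strength")),
               "NC rows")
})

test_that("w-scores are centered/scaled on training NC and remove covariates", {
  sets <- test_sets(24)
  co <- generate_cohort(cohort_spec(
    n_per_group = c(NC = 1000, AD = 100, FTD = 100), sets = sets,
    effect_size = 1, sparsity = 0.1, subject_sd_frac = 0, seed = 31))
  rec <- co$records
  nc_idx <- which(rec$diagnosis == "NC")
  train <- nc_idx[1:500]; held <- nc_idx[501:1000]
  ftrain <- feature_table(co$table$ids[train, ], co$table$X[train, ],
                          sets, "raw")
  m <- fit_normative(ftrain, rec[train, ],
                     covariates = c("age", "sex", "icv", "field_strength"))
  w <- compute_wscore(m, co$table, rec)
  expect_identical(w$kind, "wscore")
  # training NC: mean 0 to 1e-10, SD ~ 1 (exact up to (n-1)/(n-p) factor)
  wm <- colMeans(w$X[train, ])
  expect_lt(max(abs(wm)), 1e-10)
  wsd <- apply(w$X[train, ], 2, sd)
  expect_true(all(abs(wsd - 1) < 0.05))
  # held-out NC: near-standard and decorrelated from age despite the
  # injected age slope
  expect_lt(max(abs(colMeans(w$X[held, ]))), 0.15)
  cors <- abs(cor(w$X[held, ], rec$age[held]))
  # per-feature sampling noise at n = 500 is ~0.045, so the extreme over many
  # features exceeds 0.1 under the null; the bound applies to the typical
  # feature, with a generous cap on the extreme
  expect_lt(mean(cors), 0.1)
  expect_lt(max(cors), 0.25)
  # observed == prediction -> w = 0
  pred_row <- m$beta["intercept", ] + m$beta["age", ] * 70 +
    m$beta["icv", ] * 1.5e6
  rec0 <- subject_records("z", "V01", "NC", 70, "F", 1.5e6, "1.5T")
  tab0 <- feature_table(rec0[, c("subject_id", "visit_id")],
                        matrix(pred_row, 1), sets)
  w0 <- compute_wscore(m, tab0, rec0)
  expect_lt(max(abs(w0$X)), 1e-10)
})

test_that("w-scores are invariant to positive rescaling of a raw feature", {
  rec <- toy_records(60, seed = 12)
  X <- matrix(rnorm(60 * 2), 60, 2)
  sets <- list(feature_set_spec("volume", 500, 2))
  tab <- feature_table(rec[, c("subject_id", "visit_id")], X, sets)
  Xs <- X; Xs[, 2] <- X[, 2] * 37.5
  tabs <- feature_table(rec[, c("subject_id", "visit_id")], Xs, sets)
  cov4 <- c("age", "sex", "icv", "field_strength")
  w1 <- compute_wscore(fit_normative(tab, rec, cov4), tab, rec)
  w2 <- compute_wscore(fit_normative(tabs, rec, cov4), tabs, rec)
  expect_equal(w1$X, w2$X, tolerance = 1e-10)
})

test_that("unseen categorical levels are rejected at scoring time", {
  rec <- toy_records(30, seed = 3)
  rec$field_strength <- "3T"
  X <- matrix(rnorm(30), 30, 1)
  sets <- list(feature_set_spec("volume", 500, 1))
  tab <- feature_table(rec[, c("subject_id", "visit_id")], X, sets)
  m <- fit_normative(tab, rec, covariates = c("age", "field_strength"))
  rec2 <- rec; rec2$field_strength[1] <- "1.5T"
  expect_error(compute_wscore(m, tab, rec2), "unseen")
})

test_that("normative model CSV round-trips", {
  rec <- toy_records(25, seed = 5)
  X <- matrix(rnorm(75), 25, 3)
  tab <- feature_table(rec[, c("subject_id", "visit_id")], X,
                       list(feature_set_spec("thickness", 1000, 3)))
  m <- fit_normative(tab, rec, covariates = c("age", "sex"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_normative_model(m, f)
  back <- read_normative_model(f)
  expect_equal(unname(back$beta), unname(m$beta))
  expect_equal(unname(back$sigma), unname(m$sigma))
})

test_that("groupwise Welch tests match t.test and control the null", {
  sets <- test_sets(12)
  co <- generate_cohort(cohort_spec(
    n_per_group = c(NC = 40, AD = 40, FTD = 0), sets = sets,
    effect_size = 0, sparsity = 0, subject_sd_frac = 0, seed = 17))
  w <- feature_table(co$table$ids, scale(co$table$X), sets, "wscore")
  res <- groupwise_feature_tests(w, co$records, "NC", "AD")
  g <- co$records$diagnosis
  or <- t.test(w$X[g == "NC", 7], w$X[g == "AD", 7])   # Welch by default
  expect_equal(res$t[7], unname(or$statistic), tolerance = 1e-10)
  expect_equal(res$p[7], or$p.value, tolerance = 1e-10)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))

  # identical groups: all t = 0, nothing discovered
  ids2 <- data.frame(subject_id = sprintf("d%d", 1:8),
                     visit_id = "V01")
  rec2 <- subject_records(ids2$subject_id, "V01",
                          rep(c("NC", "AD"), each = 4),
                          70, "M", 1.5e6, "3T")
  Xd <- rbind(w$X[1:4, ], w$X[1:4, ])
  wd <- feature_table(ids2, Xd, sets, "wscore")
  rd <- groupwise_feature_tests(wd, rec2, "NC", "AD")
  expect_true(all(rd$t == 0))
  expect_false(any(rd$significant))

  # a 2-SD shifted feature at n = 200/group is discovered
  co2 <- generate_cohort(cohort_spec(
    n_per_group = c(NC = 200, AD = 200, FTD = 0), sets = sets,
    effect_size = 2, sparsity = 0.05, subject_sd_frac = 0, seed = 19))
  z <- feature_table(co2$table$ids, scale(co2$table$X), sets, "wscore")
  res2 <- groupwise_feature_tests(z, co2$records, "NC", "AD")
  aff <- ground_truth(cohort_spec(
    n_per_group = c(NC = 200, AD = 200, FTD = 0), sets = sets,
    effect_size = 2, sparsity = 0.05, seed = 19))$affected$AD
  expect_true(all(res2$significant[aff]))
})
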