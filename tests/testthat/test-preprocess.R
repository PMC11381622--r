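test_that("validity rules mask out-of-range cells and convert units", {
  ct <- toy_cohort()
  ct$values$hr[1] <- -5
  rules <- list(list(variable = "hr", valid_range = c(0, 300)),
                list(variable = "sbp", factor = 2.54, unit = "cm"))
  out <- apply_validity_and_units(ct, rules)
  expect_true(is.na(out$values$hr[1]))
  expect_equal(sum(is.na(out$values$hr)), 1)
  # unit conversion verified against per-cell hand multiplication
  expect_equal(out$values$sbp, ct$values$sbp * 2.54)
  expect_equal(out$meta$unit[out$meta$name == "sbp"], "cm")
  # untouched column and cells unchanged
  expect_equal(out$values$glucose, ct$values$glucose)
  expect_equal(out$values$hr[-1], ct$values$hr[-1])

  expect_identical(apply_validity_and_units(ct, list())$values, ct$values)
  expect_error(apply_validity_and_units(ct, list(list(variable = "nope"))),
               "nope")
})

test_that("missingness filter drops variables then subjects at strict thresholds", {
  # variable missing in 26 of 100 -> dropped; exactly 25 -> retained
  vals <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  vals$a[1:26] <- NA
  vals$b[1:25] <- NA
  meta <- data.frame(name = c("a", "b", "c"), role = "modelling",
                     vtype = "continuous")
  res <- filter_missingness(cohort_table(vals, meta))
  expect_equal(res$report$dropped_variables, "a")
  expect_true(all(c("b", "c") %in% colnames(res$table$values)))

  # engineered 10 x 4 toy, per-variable missing fractions {0.1,0.1,0.3,0.5};
  # one subject misses both surviving variables
  vals2 <- as.data.frame(matrix(rnorm(40), 10, 4))
  colnames(vals2) <- c("v1", "v2", "v3", "v4")
  vals2$v1[1] <- NA
  vals2$v2[1] <- NA
  vals2$v3[3:5] <- NA
  vals2$v4[3:7] <- NA
  meta2 <- data.frame(name = colnames(vals2), role = "modelling",
                      vtype = "continuous")
  ct2 <- cohort_table(vals2, meta2)
  res2 <- filter_missingness(ct2)
  # brute-force recount
  frac <- colMeans(is.na(vals2))
  expect_equal(sort(res2$report$dropped_variables),
               sort(names(frac)[frac > 0.25]))
  surv <- names(frac)[frac <= 0.25]
  subj_frac <- rowMeans(is.na(vals2[, surv]))
  expect_equal(res2$report$dropped_subjects,
               ct2$subject_ids[subj_frac > 0.30])
  expect_equal(length(res2$report$dropped_variables), 2L)
  expect_equal(length(res2$report$dropped_subjects), 1L)

  # idempotence: filtering its own output changes nothing
  res3 <- filter_missingness(res2$table)
  expect_equal(res3$table$values, res2$table$values)
  expect_length(res3$report$dropped_variables, 0)
  expect_length(res3$report$dropped_subjects, 0)

  all_na <- cohort_table(data.frame(a = rep(NA_real_, 5)),
                         data.frame(name = "a", role = "modelling",
                                    vtype = "continuous"))
  expect_error(filter_missingness(all_na), "empty after filtering")
})

test_that("skew transform hits only skewed nonnegative modelling variables", {
  set.seed(7)
  n <- 500
  vals <- data.frame(sym = rnorm(n), expo = rexp(n, 1), neg = rexp(n, 1))
  vals$neg[1] <- -0.5  # skewed but contains a negative value
  meta <- data.frame(name = c("sym", "expo", "neg"), role = "modelling",
                     vtype = "continuous")
  ct <- cohort_table(vals, meta)
  before <- phenomap:::sample_skewness(vals$expo)
  expect_gt(before, 1.5)  # exponential draws are strongly right-skewed
  res <- transform_skewed(ct, 1.0)
  expect_equal(res$transformed, "expo")
  expect_equal(res$skipped, "neg")
  expect_equal(res$table$values$sym, vals$sym)
  expect_equal(res$table$values$neg, vals$neg)
  expect_equal(res$table$values$expo, log1p(vals$expo))
  # skewness strictly reduced, ranks preserved (monotone transform)
  after <- phenomap:::sample_skewness(res$table$values$expo)
  expect_lt(after, before)
  expect_equal(rank(res$table$values$expo), rank(vals$expo))
})

test_that("iterative imputation is exact on collinear data and deterministic", {
  ct <- toy_cohort()
  out <- impute_cohort(ct)
  expect_identical(out$table$values, ct$values)  # complete table untouched
  expect_equal(out$imputed_cell_count, 0L)

  # two perfectly collinear columns y = 2x, one missing y-cell
  set.seed(3)
  x <- rnorm(50)
  vals <- data.frame(x = x, y = 2 * x)
  vals$y[10] <- NA
  meta <- data.frame(name = c("x", "y"), role = "modelling",
                     vtype = "continuous")
  ct2 <- cohort_table(vals, meta)
  imp <- impute_cohort(ct2)
  expect_equal(imp$table$values$y[10], 2 * x[10], tolerance = 1e-6)
  expect_equal(imp$imputed_cell_count, 1L)
  # observed cells bit-identical
  expect_identical(imp$table$values$y[-10], vals$y[-10])
  expect_identical(imp$table$values$x, vals$x)
  # determinism: bitwise-identical on a rerun
  imp2 <- impute_cohort(ct2)
  expect_identical(imp2$table$values, imp$table$values)

  all_na <- ct2
  all_na$values$y <- NA_real_
  expect_error(impute_cohort(all_na), "no observed values")
})

test_that("standardisation is exact and invertible", {
  ct <- toy_cohort()
  res <- standardize_cohort(ct)
  for (v in c("hr", "sbp", "glucose")) {
    expect_lt(abs(mean(res$table$values[[v]])), 1e-10)
    expect_equal(sd(res$table$values[[v]]), 1, tolerance = 1e-10)
  }
  # investigative column untouched
  expect_identical(res$table$values$age, ct$values$age)
  back <- inverse_standardize(res$table, res$scaler)
  expect_equal(as.matrix(back$values[c("hr", "sbp", "glucose")]),
               as.matrix(ct$values[c("hr", "sbp", "glucose")]),
               tolerance = 1e-9)

  const <- cohort_table(data.frame(a = rep(2, 5), b = rnorm(5)),
                        data.frame(name = c("a", "b"), role = "modelling",
                                   vtype = "continuous"))
  expect_error(standardize_cohort(const), "a")
})

test_that("ordinal one-hot encoding produces indicator columns", {
  vals <- data.frame(grade = c("a", "a", "b", "c", "c"), num = 1:5,
                     stringsAsFactors = FALSE)
  meta <- data.frame(name = c("grade", "num"),
                     role = c("investigative", "modelling"),
                     vtype = c("ordinal", "continuous"))
  ct <- cohort_table(vals, meta)
  out <- encode_ordinals(ct, "grade")
  ind <- as.matrix(out$values[c("grade.a", "grade.b", "grade.c")])
  expect_equal(unname(colSums(ind)), c(2, 1, 2))   # hand count
  expect_equal(unname(rowSums(ind)), rep(1, 5))
  expect_equal(out$meta$vtype[out$meta$name == "grade.a"], "categorical")

  single <- cohort_table(data.frame(g = rep("x", 4)),
                         data.frame(name = "g", role = "investigative",
                                    vtype = "ordinal"))
  enc <- encode_ordinals(single, "g")
  expect_equal(enc$values$g.x, rep(1, 4))

  expect_error(encode_ordinals(ct, "num"), "not ordinal")
})

test_that("full preprocessing chain composes and reports", {
  set.seed(11)
  spec <- cohort_spec(n_subjects = 120, n_dims = 6, n_clusters = 2,
                      cluster_separation = 6, skewed_fraction = 0.3,
                      missing_rate_cell = 0.05, seed = 11)
  co <- generate_cohort(spec)
  tab <- inject_missingness(co$table, spec)
  res <- preprocess(tab)
  m <- modelling_matrix(res$table)
  expect_false(anyNA(m))
  expect_true(all(abs(colMeans(m)) < 1e-10))
  expect_gt(res$report$imputed_cell_count, 0)
})
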