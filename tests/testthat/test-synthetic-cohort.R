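test_that("generation is deterministic given the seed", {
  cfg <- generator_config(300, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(cohort_data(a), cohort_data(b))
  c2 <- generate_cohort(generator_config(300, seed = 12))
  expect_false(identical(cohort_data(a), cohort_data(c2)))
})

test_that("marginal death rate matches the configured prevalence", {
  coh <- generate_cohort(generator_config(10000, prevalence = 0.105, seed = 1))
  frac <- mean(cohort_data(coh)$outcome == "dead")
  expect_lt(abs(frac - 0.105), 0.01)
  se <- sqrt(0.105 * 0.895 / 10000)
  expect_lt(abs(frac - 0.105), 3 * se)
})

test_that("degenerate subgroup mixture yields a single subgroup", {
  coh <- generate_cohort(generator_config(
    100, subgroup_mix = c(clear_alive = 1, clear_dead = 0, ambiguous = 0),
    seed = 3))
  expect_true(all(cohort_data(coh)$true_subgroup == "clear_alive"))
})

test_that("config validation rejects bad inputs", {
  expect_error(generator_config(0), "positive")
  expect_error(generator_config(10, subgroup_mix = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(generator_config(10, prevalence = 1.2), "prevalence")
})

test_that("worst-value draws are bimodal at zero loading", {
  spec <- feature_spec("hr", "continuous", reference_value = 75,
                       low_mode = 45, high_mode = 130, severity_loading = 0.8)
  draws <- withr::with_seed(5, sample_worst_value(spec, rep(0, 1e5)))
  h <- hist(draws, breaks = 80, plot = FALSE)
  dens <- h$density
  # local maxima of the binned density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  peak_locs <- h$mids[peaks[order(dens[peaks], decreasing = TRUE)][1:2]]
  expect_lt(min(abs(peak_locs - 45)), 6)
  expect_lt(min(abs(peak_locs - 130)), 6)
})

test_that("coincident modes give unimodal draws at the reference", {
  spec <- feature_spec("x", "continuous", reference_value = 10,
                       low_mode = 10, high_mode = 10)
  draws <- withr::with_seed(6, sample_worst_value(spec, rep(0, 1e4)))
  expect_lt(abs(mean(draws) - 10), 0.05)
  expect_lt(sd(draws), 1)
})

test_that("severity pushes draws toward the extreme mode", {
  spec <- feature_spec("bun", "continuous", reference_value = 12,
                       low_mode = 12, high_mode = 70, severity_loading = 1)
  d0 <- withr::with_seed(7, sample_worst_value(spec, rep(0, 1e4)))
  d3 <- withr::with_seed(8, sample_worst_value(spec, rep(3, 1e4)))
  expect_gt(mean(abs(d3 - 12)), mean(abs(d0 - 12)))
})

test_that("sample_worst_value rejects non-continuous specs", {
  expect_error(
    sample_worst_value(feature_spec("b", "binary", base_rate = 0.5), 0),
    "continuous")
})

test_that("missingness hits the schema rate when uninformative", {
  schema <- list(feature_spec("fio2", "continuous", reference_value = 0.21,
                              low_mode = 0.21, high_mode = 0.9,
                              missing_rate = 0.732))
  dat <- tibble::tibble(patient_id = sprintf("p%05d", 1:10000),
                        fio2 = runif(10000), aps = rnorm(10000, 40, 10))
  coh <- new_cohort(dat, schema)
  out <- inject_missingness(coh, informative_strength = 0, seed = 9)
  expect_lt(abs(mean(is.na(cohort_data(out)$fio2)) - 0.732), 0.01)
  expect_false(anyNA(cohort_data(coh)$fio2))  # input untouched
})

test_that("zero missing rates leave no missing cells", {
  coh <- toy_cohort()
  coh$schema[[1]]$missing_rate <- 0
  out <- inject_missingness(coh, 1, seed = 2)
  expect_false(anyNA(cohort_data(out)$f1))
})

test_that("informative missingness gives dead patients fewer missing values", {
  coh <- generate_cohort(generator_config(10000, seed = 4))
  d <- cohort_data(coh)
  feats <- vapply(cohort_schema(coh), `[[`, "", "name")
  miss <- rowSums(is.na(d[, feats]))
  expect_lt(mean(miss[d$outcome == "dead"]), mean(miss[d$outcome == "alive"]))
})

test_that("discharge offsets are ordered and probabilities valid", {
  d <- cohort_data(generate_cohort(generator_config(3000, seed = 5)))
  expect_true(all(d$hospital_discharge_offset >= d$unit_discharge_offset))
  expect_true(all(d$reference_probability >= 0 & d$reference_probability <= 1))
  expect_true(all(d$aps >= 0))
  expect_false(anyDuplicated(d$patient_id) > 0)
})

test_that("planted ambiguous patients are genuinely ambiguous to a logistic model", {
  coh <- fixture_cohort(seed = 1, n_raw = 6000)
  imp <- fit_imputer(coh)
  cohi <- apply_imputer(imp, coh)
  enc <- encode_onehot(cohort_schema(cohi), cohort_data(cohi))
  y <- as.integer(cohort_data(cohi)$outcome == "dead")
  df <- data.frame(enc$matrix, y = y)
  g <- suppressWarnings(stats::glm(y ~ ., data = df, family = binomial()))
  sc <- stats::predict(g, type = "response")
  sg <- cohort_data(cohi)$true_subgroup
  amb <- sg == "ambiguous"
  expect_lt(auroc(sc[amb], y[amb]), 0.65)
  expect_gt(auroc(sc[!amb], y[!amb]), 0.9)
})

test_that("cohort CSV round-trips with its schema sidecar", {
  coh <- generate_cohort(generator_config(150, seed = 10))
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(vapply(cohort_schema(back), `[[`, "", "name"),
               vapply(cohort_schema(coh), `[[`, "", "name"))
  expect_equal(cohort_data(back)$outcome, cohort_data(coh)$outcome)
  expect_equal(cohort_data(back)$bun, cohort_data(coh)$bun, tolerance = 1e-8)
  unlink(c(path, paste0(path, ".schema.json")))
})
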