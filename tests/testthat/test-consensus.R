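test_that("fusion reproduces the worked examples", {
  # 92% alive votes, agreement threshold 90, dead at discharge: false negative
  r <- fuse(92, 8, "dead", 90)
  expect_equal(r$final_prediction, "Alive")
  expect_equal(r$group, "FN")
  # unanimous alive fuses to Alive at any valid threshold
  for (th in c(55, 75, 90, 100)) {
    expect_equal(fuse(30, 0, "alive", th)$group, "TN")
  }
  # 70/30 split is MIXED at threshold 90
  expect_equal(fuse(70, 30, "alive", 90)$group, "MIXED")
  expect_equal(fuse(70, 30, "dead", 90)$group, "MIXED")
})

test_that("agreement comparison is inclusive by default, strict on request", {
  expect_equal(fuse(9, 1, "alive", 90)$final_prediction, "Alive")
  expect_equal(fuse(9, 1, "alive", 90, strict = TRUE)$final_prediction,
               "MIXED")
  # strict comparison makes the 100% threshold unattainable
  expect_equal(fuse(10, 0, "alive", 100, strict = TRUE)$final_prediction,
               "MIXED")
  expect_equal(fuse(10, 0, "alive", 100)$final_prediction, "Alive")
})

test_that("fusion validates its domain", {
  expect_error(fuse(1, 1, "alive", 50), "50")
  expect_error(fuse(0, 0, "alive", 90), "unassessed")
})

test_that("fused groups partition assessed patients and match the oracle", {
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(5:80, 1)
      led <- tibble::tibble(
        patient_id = sprintf("p%03d", seq_len(n)),
        n_appearances = sample(0:20, n, replace = TRUE),
        outcome = sample(c("alive", "dead"), n, replace = TRUE)
      )
      votes <- led$n_appearances * 4
      led$votes_alive <- vapply(votes, function(v) {
        if (v == 0) 0L else sample(0:v, 1)
      }, 0L)
      led$votes_dead <- votes - led$votes_alive
      th <- sample(seq(55, 100, 5), 1)
      asg <- fuse_ledger(led, th)
      assessed <- led$n_appearances > 0
      expect_equal(nrow(asg), sum(assessed))
      expect_setequal(attr(asg, "unassessed"), led$patient_id[!assessed])
      oracle <- fuse_oracle(led$votes_alive[assessed],
                            led$votes_dead[assessed],
                            led$outcome[assessed], th)
      expect_identical(asg$group, oracle$group)
      expect_identical(asg$final_prediction, oracle$final)
      expect_equal(asg$fraction_alive + asg$fraction_dead, rep(100, nrow(asg)))
    }
  })
})

test_that("threshold sweep shares sum to 100 and are monotone", {
  withr::with_seed(12, {
    n <- 400
    led <- tibble::tibble(
      patient_id = sprintf("p%04d", seq_len(n)),
      n_appearances = sample(1:30, n, replace = TRUE),
      outcome = sample(c("alive", "dead"), n, replace = TRUE,
                       prob = c(0.9, 0.1))
    )
    votes <- led$n_appearances * 4
    led$votes_alive <- vapply(votes, function(v) sample(0:v, 1), 0L)
    led$votes_dead <- votes - led$votes_alive
    sw <- sweep_thresholds(led, seq(55, 100, 5))
    expect_equal(sw$tn + sw$tp + sw$fn + sw$fp + sw$mixed,
                 rep(100, nrow(sw)))
    expect_true(all(diff(sw$mixed) >= 0))
    for (col in c("tn", "tp", "fn", "fp")) {
      expect_true(all(diff(sw[[col]]) <= 0))
    }
  })
})

test_that("a single unanimously-alive patient is TN at every threshold", {
  led <- tibble::tibble(patient_id = "p1", n_appearances = 10,
                        votes_alive = 40L, votes_dead = 0L,
                        outcome = "alive")
  sw <- sweep_thresholds(led, c(55, 70, 90, 100))
  expect_true(all(sw$tn == 100))
})

test_that("raising the threshold only ever moves patients into MIXED", {
  withr::with_seed(13, {
    n <- 300
    va <- sample(0:40, n, replace = TRUE)
    led <- tibble::tibble(patient_id = sprintf("p%03d", 1:n),
                          n_appearances = 10,
                          votes_alive = va, votes_dead = 40L - va,
                          outcome = sample(c("alive", "dead"), n, TRUE))
    prev <- fuse_ledger(led, 55)$final_prediction
    for (th in seq(60, 100, 5)) {
      cur <- fuse_ledger(led, th)$final_prediction
      moved <- prev != cur
      expect_true(all(cur[moved] == "MIXED"))
      prev <- cur
    }
  })
})

test_that("occurrence statistics are exact order statistics and mean", {
  led <- tibble::tibble(patient_id = c("a", "b", "c"),
                        n_appearances = c(8, 25, 46),
                        votes_alive = 0, votes_dead = 0,
                        outcome = "alive")
  oc <- occurrence_stats(led)
  expect_equal(oc$min, 8)
  expect_equal(oc$max, 46)
  expect_equal(oc$mean, mean(c(8, 25, 46)))
  led$n_appearances <- rep(7, 3)
  expect_equal(unlist(occurrence_stats(led)), c(min = 7, mean = 7, max = 7))
})

test_that("a one-round, one-model experiment gives one vote per test patient", {
  coh <- toy_cohort(n = 60, f1 = rnorm(60),
                    outcome = rep(c("alive", "alive", "alive", "dead"), 15))
  cfg <- experiment_config(
    n_rounds = 1,
    model_specs = list(reference = model_spec("reference")),
    base_seed = 5, keep_attributions = FALSE)
  ex <- run_experiment(coh, cfg)
  led <- ex$ledger
  assessed <- led$n_appearances > 0
  expect_equal(sum(assessed), 15)
  expect_true(all(led$votes_alive[assessed] + led$votes_dead[assessed] == 1))
  expect_true(all(led$votes_alive[!assessed] + led$votes_dead[!assessed] == 0))
})

test_that("experiments are reproducible from the base seed", {
  coh <- toy_cohort(n = 80, f1 = rnorm(80),
                    outcome = rep(c("alive", "alive", "alive", "dead"), 20))
  cfg <- experiment_config(
    n_rounds = 3,
    model_specs = list(reference = model_spec("reference")),
    base_seed = 17, keep_attributions = FALSE)
  ex1 <- run_experiment(coh, cfg)
  ex2 <- run_experiment(coh, cfg)
  expect_identical(ex1$ledger, ex2$ledger)
  expect_identical(ex1$rounds$threshold, ex2$rounds$threshold)
})

test_that("vote totals equal appearances times the number of voters", {
  coh <- fixture_cohort(seed = 2, n_raw = 1200)
  ms <- fixture_model_specs()
  ex <- run_experiment(coh, experiment_config(
    n_rounds = 2, model_specs = ms, base_seed = 3,
    keep_attributions = FALSE))
  led <- ex$ledger
  expect_true(all(led$votes_alive + led$votes_dead ==
                    led$n_appearances * length(ms)))
})
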