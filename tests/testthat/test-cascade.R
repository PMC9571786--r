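test_that("sampler weights invert class frequencies", {
  w <- weighted_sampler_weights(rep(c("a", "b"), each = 10))
  expect_equal(w, rep(1 / 20, 20))
  w2 <- weighted_sampler_weights(c(rep("min", 10), rep("maj", 90)))
  expect_equal(w2[1] / w2[11], 9)
  expect_equal(sum(w2), 1)
  expect_error(weighted_sampler_weights(character()),
               class = "ramangrade_validation")
})

test_that("weighted sampling balances a 1:4 imbalanced set", {
  labels <- c(rep("min", 20), rep("maj", 80))
  w <- weighted_sampler_weights(labels)
  set.seed(99)
  draws <- sample(labels, 1e5, replace = TRUE, prob = w)
  expect_equal(mean(draws == "min"), 0.5, tolerance = 0.02)
})

test_that("per-class accuracy matches hand counts at printed precision", {
  # 13 of 31 correct -> 41.9%; 20 of 24 -> 83.3%
  true <- c(rep("E", 31), rep("G1", 24))
  pred <- c(rep("E", 13), rep("G1", 18), rep("G1", 20), rep("E", 4))
  acc <- per_class_accuracy(pred, true, c("E", "G1"))
  expect_equal(round(acc[["E"]], 1), 41.9)
  expect_equal(round(acc[["G1"]], 1), 83.3)
  expect_equal(per_class_accuracy(true, true, c("E", "G1")),
               c(E = 100, G1 = 100))
  expect_error(per_class_accuracy(pred, true, c("E", "G1", "G2G3")),
               class = "ramangrade_validation")
  expect_error(per_class_accuracy(pred[1:3], true),
               class = "ramangrade_validation")
})

test_that("the aggregation identities hold and the mean is a convex combination", {
  all100 <- aggregate_final_accuracy(100, 100, 100, 100, 31, 24, 99)
  expect_equal(all100$acc_final, 100)
  set.seed(5)
  for (i in 1:20) {
    accs <- round(stats::runif(4, 0, 100), 1)
    r <- aggregate_final_accuracy(accs[1], accs[2], accs[3], accs[4],
                                  31, 24, 99)
    expect_equal(r$acc_G2G3_final, r$acc_G2G3_stage1)
    expect_equal(r$acc_E_final, r$acc_E_stage2 * r$acc_EG1_stage1 / 100)
    expect_equal(r$acc_G1_final, r$acc_G1_stage2 * r$acc_EG1_stage1 / 100)
    finals <- c(r$acc_E_final, r$acc_G1_final, r$acc_G2G3_final)
    expect_gte(r$acc_final, min(finals) - 1e-9)
    expect_lte(r$acc_final, max(finals) + 1e-9)
  }
  expect_error(aggregate_final_accuracy(101, 50, 50, 50, 1, 1, 1),
               class = "ramangrade_validation")
  expect_error(aggregate_final_accuracy(50, 50, 50, 50, 0, 1, 1),
               class = "ramangrade_validation")
})

test_that("a simulated cascade's empirical accuracies match the products", {
  # independent oracle: simulate per-sample routing and stage-2 calls with
  # class-independent stage error rates, then compare the empirical final
  # per-class accuracies with the multiplicative identities
  set.seed(77)
  n <- 10000L
  truth <- sample(c("E", "G1", "G2G3"), n, replace = TRUE,
                  prob = c(0.3, 0.2, 0.5))
  p_route_eg1 <- 0.92   # P(stage1 says EG1 | true EG1)
  p_route_g2g3 <- 0.88  # P(stage1 says G2G3 | true G2G3)
  p_e2 <- 0.85; p_g12 <- 0.75
  is_eg1 <- truth %in% c("E", "G1")
  routed <- ifelse(is_eg1, stats::runif(n) < p_route_eg1,
                   stats::runif(n) >= p_route_g2g3)
  pred <- rep("G2G3", n)
  stage2_correct <- ifelse(truth == "E", stats::runif(n) < p_e2,
                           stats::runif(n) < p_g12)
  pred[routed & truth == "E"] <- ifelse(stage2_correct[routed & truth == "E"],
                                        "E", "G1")
  pred[routed & truth == "G1"] <- ifelse(stage2_correct[routed & truth == "G1"],
                                         "G1", "E")
  pred[routed & truth == "G2G3"] <- sample(c("E", "G1"),
                                           sum(routed & truth == "G2G3"),
                                           replace = TRUE)
  emp <- per_class_accuracy(pred, truth, c("E", "G1", "G2G3"))
  expect_equal(emp[["E"]], 100 * p_e2 * p_route_eg1, tolerance = 0.015)
  expect_equal(emp[["G1"]], 100 * p_g12 * p_route_eg1, tolerance = 0.02)
  expect_equal(emp[["G2G3"]], 100 * p_route_g2g3, tolerance = 0.015)
})

test_that("fraction-count aggregation reconstructs printed-table arithmetic", {
  # 92.73% of 55 as a printed mean corresponds to 51/55 correct
  r <- aggregate_final_accuracy(100, 100, 100, 83.3, 31, 24, 99)
  expect_equal(r$acc_G1_stage2, 100 * 20 / 24)
  # printed_products multiplies percentages directly
  r2 <- aggregate_final_accuracy(60, 100, 50, 10, 31, 24, 99,
                                 rounding = "printed_products")
  expect_equal(r2$acc_E_final, 30)
  expect_equal(r2$acc_G1_final, 6)
})

test_that("run_cascade composes oracle stages and degenerate routers", {
  coh <- generate_cohort(small_cohort_config(), seed = 55)
  te <- normalize_spectra(cohort_split(coh)$test)
  oracle1 <- function(sp) {
    ifelse(collapse_grades(sp$meta$grade) %in% c("E", "G1"),
           "positive", "negative")
  }
  oracle2 <- function(sp) collapse_grades(sp$meta$grade)
  casc <- run_cascade(te, oracle1, oracle2)
  expect_equal(per_class_accuracy(casc$pred, casc$true, c("E", "G1", "G2G3")),
               c(E = 100, G1 = 100, G2G3 = 100))
  # stage 1 labels everything G2G3: E and G1 terminate incorrectly
  all_neg <- function(sp) rep("negative", length(sp))
  casc2 <- run_cascade(te, all_neg, oracle2)
  acc2 <- per_class_accuracy(casc2$pred, casc2$true, c("E", "G1", "G2G3"))
  expect_equal(unname(acc2), c(0, 0, 100))
  # untrained models are refused
  expect_error(run_cascade(te, build_cnn1d(length(te$wavenumbers)), oracle2),
               class = "ramangrade_validation")
  expect_error(run_cascade(te, oracle1, build_transfer_model(base_width = 4L)),
               class = "ramangrade_validation")
})

test_that("reports tidy, glance and print consistently", {
  r <- aggregate_final_accuracy(90, 95, 85, 80, 31, 24, 99)
  td <- tidy(r)
  expect_equal(nrow(td), 8L)
  expect_equal(td$accuracy[td$quantity == "acc_final"], r$acc_final)
  gl <- glance(r)
  expect_equal(gl$n, 154L)
  expect_output(print(r), "mean")
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
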