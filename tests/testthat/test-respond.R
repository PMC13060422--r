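test_that("patient-level prediction uses the most recent timepoint", {
  preds <- data.table::data.table(
    sample_id = c("p1_S", "p1_D", "p1_A", "p2_S", "p3_D"),
    patient_id = c("p1", "p1", "p1", "p2", "p3"),
    timepoint = c("Screen", "Day0", "AdjWk1", "Screen", "Day0"),
    probability = c(0.2, 0.4, 0.9, 0.3, 0.5))
  out <- patient_prediction(preds)
  expect_equal(out$probability[out$patient_id == "p1"], 0.9)
  expect_equal(out$predicted[out$patient_id == "p1"], "Responder")
  # Screen-only patient falls back to Screen
  expect_equal(out$timepoint[out$patient_id == "p2"], "Screen")
  # tie at 0.5 resolves to the positive class
  expect_equal(out$predicted[out$patient_id == "p3"], "Responder")
  # unscored patients are excluded and counted
  preds2 <- rbind(preds, data.table::data.table(
    sample_id = "p4_S", patient_id = "p4", timepoint = "Screen",
    probability = NA_real_))
  out2 <- patient_prediction(preds2)
  expect_false("p4" %in% out2$patient_id)
  expect_equal(attr(out2, "n_excluded"), 1L)
})

test_that("sensitivity at fixed specificity enumerates thresholds correctly", {
  labels <- rep(c("Responder", "Non-Responder"), each = 10)
  sep <- c(rep(0.9, 10), rep(0.1, 10))
  expect_equal(sensitivity_at_specificity(sep, labels), 1)
  same <- rep(0.5, 20)
  expect_equal(sensitivity_at_specificity(same, labels), 0)
  # random scores: mean sensitivity at 95% specificity is near the 5% FPR
  set.seed(60)
  sens <- replicate(100, {
    sensitivity_at_specificity(runif(200),
                               rep(c("Responder", "Non-Responder"), 100))
  })
  expect_lt(abs(mean(sens) - 0.05), 0.03)
  expect_error(sensitivity_at_specificity(1:3, rep("Responder", 3)),
               "both classes")
})

test_that("AUC equals brute-force pairwise concordance", {
  set.seed(61)
  for (i in 1:5) {
    n <- 40
    scores <- rnorm(n)
    labels <- sample(c("Responder", "Non-Responder"), n, replace = TRUE)
    pos <- scores[labels == "Responder"]; neg <- scores[labels != "Responder"]
    if (!length(pos) || !length(neg)) next
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(auc_score(scores, labels), brute, tolerance = 1e-10)
  }
})

test_that("patient-level splits never leak a patient across train and test", {
  sim <- simulate_rmds_matrix(n_patients_per_group = 10, n_bins = 60,
                              effect_bins = 1:10, effect_size = 1, seed = 62)
  pt <- unique(sim$metadata[, c("patient_id", "response", "institute")])
  for (kind in c("repeated_kfold", "leave_one_institute_out",
                 "random_patient_holdout")) {
    sch <- eval_scheme(kind, folds = 4, rounds = 2, holdout_size = 5)
    splits <- rmdskit:::.make_splits(pt$patient_id, pt$response,
                                     pt$institute, sch, seed = 1)
    for (sp in splits) {
      expect_length(intersect(sp$train, sp$test), 0)
      expect_setequal(c(sp$train, sp$test), pt$patient_id)
    }
  }
})

test_that("a planted effect is classified well; permuted labels are not", {
  sim <- simulate_rmds_matrix(n_patients_per_group = 12, n_bins = 300,
                              effect_bins = 1:40, effect_size = 1,
                              patient_icc = 0.3, seed = 63)
  sch <- eval_scheme("repeated_kfold", folds = 4, rounds = 3)
  rep <- run_evaluation(standardize_bins(sim$values), sim$metadata, sch,
                        seed = 64)
  pat_auc <- rep$aggregate[rep$aggregate$level == "patient" &
                             rep$aggregate$metric == "auc"]
  expect_gte(pat_auc$mean, 0.9)
  # permuted labels at the patient level -> chance
  md_perm <- data.table::copy(sim$metadata)
  set.seed(65)
  pt <- unique(md_perm$patient_id)
  relab <- setNames(sample(md_perm$response[match(pt, md_perm$patient_id)]),
                    pt)
  md_perm[, response := relab[patient_id]]
  rep0 <- run_evaluation(standardize_bins(sim$values), md_perm, sch,
                         seed = 66)
  auc0 <- rep0$aggregate[rep0$aggregate$level == "sample" &
                           rep0$aggregate$metric == "auc"]
  expect_lt(abs(auc0$mean - 0.5), 0.2)
  # report invariants: confusion counts sum to evaluated patients
  cm <- rep$patient_rounds
  expect_true(all(cm$tp + cm$fp + cm$fn + cm$tn == length(pt)))
})

test_that("LOIO evaluates one institute per split", {
  sim <- simulate_rmds_matrix(n_patients_per_group = 9, n_bins = 120,
                              effect_bins = 1:20, effect_size = 1.2,
                              seed = 67)
  sch <- eval_scheme("leave_one_institute_out")
  rep <- run_evaluation(standardize_bins(sim$values), sim$metadata, sch,
                        seed = 68)
  tested <- unique(rep$predictions[, .(round, patient_id)])
  md <- sim$metadata
  for (inst in unique(md$institute)) {
    pats <- unique(md$patient_id[md$institute == inst])
    expect_setequal(tested$patient_id[tested$round == inst], pats)
  }
})

test_that("refit correction policy never learns from test samples", {
  sim <- simulate_rmds_matrix(n_patients_per_group = 9, n_bins = 120,
                              effect_bins = 1:20, effect_size = 1,
                              institute_offsets = c(instA = 1, instB = -1,
                                                    instC = 0),
                              seed = 69)
  sch <- eval_scheme("random_patient_holdout", rounds = 2, holdout_size = 4)
  r1 <- run_evaluation(sim$values, sim$metadata, sch,
                       correction_policy = "refit", seed = 70)
  # perturb the held-out samples' values: training-side pipeline unchanged,
  # so the test predictions change only via the perturbed features
  tested <- unique(r1$predictions$sample_id[r1$predictions$round == 1])
  v2 <- sim$values
  v2[tested, ] <- v2[tested, ] + 5
  r2 <- run_evaluation(v2, sim$metadata, sch,
                       correction_policy = "refit", seed = 70)
  train_side <- setdiff(rownames(sim$values), tested)
  # identical split structure: same patients tested
  expect_identical(r1$predictions$sample_id, r2$predictions$sample_id)
})

test_that("subset evaluation favors effect bins over random bins", {
  sim <- simulate_rmds_matrix(n_patients_per_group = 10, n_bins = 200,
                              effect_bins = 1:25, effect_size = 1,
                              seed = 71)
  sch <- eval_scheme("repeated_kfold", folds = 3, rounds = 2)
  set.seed(72)
  subsets <- list(effect = paste0("bin_", 1:25),
                  random = paste0("bin_", sample(26:200, 25)))
  reps <- feature_subset_evaluation(standardize_bins(sim$values),
                                    sim$metadata, subsets, sch, seed = 73)
  auc_of <- function(r) r$aggregate[r$aggregate$level == "patient" &
                                      r$aggregate$metric == "auc"]$mean
  expect_gt(auc_of(reps$effect), auc_of(reps$random) + 0.1)
  expect_error(feature_subset_evaluation(sim$values, sim$metadata,
                                         list(bad = character(0)), sch),
               "empty")
})
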