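test_that("the positivity rule dichotomizes at BI-RADS 4", {
  expect_equal(classify_positive(c(1, 2, 3, 4, 5)),
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # agrees with thresholding the ordinal score at 4
  br <- sample(1:5, 50, replace = TRUE)
  expect_equal(classify_positive(br), birads_score(br) >= 4)
})

test_that("sensitivity and specificity pool counts over readers", {
  # 4 cancers rated (5, 4, 3, 2) by one reader -> sensitivity 0.5
  truth <- data.frame(
    case_id = sprintf("C%d", 1:8),
    patient_id = rep(sprintf("P%d", 1:4), each = 2),
    side = rep(c("left", "right"), 4),
    truth = c(rep("malignant", 4), rep("normal_negative", 4)),
    density = rep(c("dense", "non_dense"), each = 4),
    finding_type = c(rep("mass", 4), rep("none", 4)),
    lesion_size_mm = c(10, 12, 14, 16, NA, NA, NA, NA),
    histology = NA_character_, stringsAsFactors = FALSE)
  ratings <- data.frame(
    case_id = truth$case_id, reader_id = "R1", mode = "DM", session = 1L,
    bi_rads = c(5L, 4L, 3L, 2L, 1L, 1L, 4L, 1L),
    pom = c(90L, 70L, 30L, NA, NA, NA, 80L, NA),
    stringsAsFactors = FALSE)
  ds <- mrmc_study(truth, ratings)
  bp <- binary_perf(ds, "DM", "overall")
  expect_equal(bp$sensitivity, 0.5)
  expect_equal(c(bp$tp, bp$fn), c(2, 2))
  expect_equal(bp$specificity, 0.75)
  expect_equal(c(bp$tn, bp$fp), c(3, 1))
})

test_that("stratum denominators follow the declared conventions", {
  ds <- tiny_manual_study()
  # soft-tissue stratum: cases C1 (mal mass), C4 (benign mass), C8 (mal mass)
  st <- binary_perf(ds, "DM", "soft_tissue")
  expect_equal(st$tp + st$fn, 2 * 2)  # 2 malignant soft-tissue x 2 readers
  expect_equal(st$tn + st$fp, 1 * 2)  # benign lesions only, not normals
  # calcification stratum: C3 (mal), C7 (benign)
  ca <- binary_perf(ds, "DM", "calcification")
  expect_equal(ca$tp + ca$fn, 2)
  expect_equal(ca$tn + ca$fp, 2)
  # density strata use all non-malignant breasts of that density
  dn <- binary_perf(ds, "DM", "dense")
  expect_equal(dn$tp + dn$fn, 1 * 2)   # C1 is the only dense malignant
  expect_equal(dn$tn + dn$fp, 3 * 2)   # C2, C5, C6
})

test_that("an empty denominator is flagged, not silently NaN", {
  ds <- tiny_manual_study()
  # distortion stratum has no cases in the fixture
  bp <- binary_perf(ds, "DM", "distortion")
  expect_false(bp$sensitivity_defined)
  expect_false(bp$specificity_defined)
  expect_true(is.na(bp$sensitivity))
  expect_true(is.na(bp$specificity))
})

test_that("stratum counts partition the reference composition", {
  ds <- simulate_study(sim_config(), seed = 21)
  tr <- ds$truth
  expect_equal(sum(tr$density == "non_dense") + sum(tr$density == "dense"),
               388)
  mal <- tr$truth == "malignant"
  ben <- tr$truth == "benign_biopsy"
  soft <- tr$finding_type %in% c("mass", "mass_calc", "focal_asymmetry")
  calc <- tr$finding_type == "calcification"
  dist <- tr$finding_type == "distortion"
  expect_equal(sum(soft), 104)
  expect_equal(sum(calc), 53)
  expect_equal(sum(mal & soft) + sum(mal & calc) + sum(mal & dist), 84)
  expect_equal(sum(ben & soft) + sum(ben & calc) + sum(ben & dist), 83)
  # pooled sensitivity denominator: 84 malignant x 4 readers
  bp <- binary_perf(ds, "DM", "overall")
  expect_equal(bp$tp + bp$fn, 84 * 4)
})

test_that("a perfect reader panel attains sensitivity and specificity 1", {
  ds <- tiny_sim_study(seed = 22)
  rt <- ds$ratings
  lab <- ds$truth$truth[match(rt$case_id, ds$truth$case_id)] == "malignant"
  rt$bi_rads <- ifelse(lab, 5L, 1L)
  rt$pom <- ifelse(lab, 100L, NA_integer_)
  perfect <- mrmc_study(ds$truth, rt)
  for (s in c("overall", "non_dense", "dense", "soft_tissue",
              "calcification")) {
    bp <- binary_perf(perfect, "DM", s)
    if (bp$sensitivity_defined) expect_equal(bp$sensitivity, 1)
    if (bp$specificity_defined) expect_equal(bp$specificity, 1)
  }
})

test_that("binary comparisons reuse the paired bootstrap", {
  ds <- clone_mode(tiny_sim_study(seed = 23), "DM", "AICAD_SM")
  cmp <- compare_binary(ds, "DM", "AICAD_SM", "sensitivity",
                        spec = boot_spec(25, 4, seed = 1))
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
  # determinism
  ds2 <- tiny_sim_study(seed = 24)
  a <- compare_binary(ds2, "DM", "AICAD_SM", "sensitivity",
                      spec = boot_spec(25, 4, seed = 7))
  b <- compare_binary(ds2, "DM", "AICAD_SM", "sensitivity",
                      spec = boot_spec(25, 4, seed = 7))
  expect_identical(a, b)
  expect_equal(a$statistic, "sensitivity")
})

test_that("a built-in sensitivity gap is recovered by the estimator", {
  # raise the AICAD_SM malignant shift so its sensitivity exceeds DM's;
  # the mean estimated gap over replicates matches the latent-model gap
  cfg <- sim_config_small(mu = c(DM = 2.2, AICAD_SM = 2.64,
                                 DM_DBT = 2.2, AICAD_SM_DBT = 2.64),
                          n_patients = 60L,
                          composition = c(malignant = 30L,
                                          benign_biopsy = 30L,
                                          normal_negative = 60L),
                          density = c(non_dense = 60L, dense = 60L),
                          finding_margins = {
                            m <- rbind(mass = c(15, 15), mass_calc = c(5, 5),
                                       focal_asymmetry = c(4, 4),
                                       distortion = c(3, 3),
                                       calcification = c(3, 3))
                            colnames(m) <- c("malignant", "benign_biopsy")
                            m
                          })
  # population sensitivity gap at the BI-RADS >= 4 cutpoint (latent 2.6):
  # reader-effect-averaged P(x > t3) difference between the two mu values
  v <- sqrt(cfg$sigma2_case + cfg$sigma2_interaction + cfg$sigma2_residual +
              cfg$sigma2_reader)
  true_gap <- pnorm((2.64 - 2.6) / v) - pnorm((2.2 - 2.6) / v)
  gaps <- vapply(1:100, function(i) {
    ds <- simulate_study(cfg, seed = 3000 + i)
    binary_perf(ds, "AICAD_SM")$sensitivity -
      binary_perf(ds, "DM")$sensitivity
  }, numeric(1))
  mc_se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - true_gap), 3 * mc_se + 0.005)
})
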