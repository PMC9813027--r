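test_that("generated truth matches the configured margins exactly", {
  cfg <- sim_config_small()
  set.seed(1)
  tr <- generate_truth(cfg)
  expect_equal(nrow(tr), 40)
  expect_equal(unname(table(tr$truth)[c("malignant", "benign_biopsy",
                                        "normal_negative")]),
               c(8L, 8L, 24L), ignore_attr = TRUE)
  expect_equal(sum(tr$density == "non_dense"), 20)
  # density is a patient attribute
  by_pat <- tapply(tr$density, tr$patient_id,
                   function(d) length(unique(d)))
  expect_true(all(by_pat == 1))
  # finding margins exact within each class
  mal_f <- table(factor(tr$finding_type[tr$truth == "malignant"],
                        levels = rownames(cfg$finding_margins)))
  expect_equal(unname(c(mal_f)), unname(cfg$finding_margins[, "malignant"]))
  # structural invariants
  expect_true(all(tr$finding_type[tr$truth == "normal_negative"] == "none"))
  expect_true(all(is.na(tr$lesion_size_mm[tr$finding_type == "none"])))
  expect_true(all(!is.na(tr$lesion_size_mm[tr$finding_type != "none"])))
  expect_true(all(table(tr$patient_id) == 2))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_patients = 10,
                          composition = c(malignant = 84, benign_biopsy = 83,
                                          normal_negative = 221)),
               "sum to 2 \\* n_patients")
  expect_error(sim_config_small(density = c(non_dense = 19, dense = 21)),
               "even")
  expect_error(sim_config_small(birads_cutpoints = c(2, 1, 3, 4)),
               "strictly increasing")
  expect_error(sim_config_small(rho_patient = 1), "rho")
  expect_error(calibrate_mu(0.4), "0.5")
  expect_error(calibrate_mu(1), "0.5")
})

test_that("rating generation is complete and protocol-faithful", {
  cfg <- sim_config_small()
  ds <- simulate_study(cfg, seed = 9)
  expect_equal(nrow(ds$ratings), 40 * 4 * 4)
  expect_true(validate_completeness(ds)$complete)
  expect_true(all(ds$ratings$bi_rads %in% 1:5))
  expect_true(all(is.na(ds$ratings$pom[ds$ratings$bi_rads <= 2])))
  expect_true(all(!is.na(ds$ratings$pom[ds$ratings$bi_rads >= 3])))
  pom <- ds$ratings$pom[!is.na(ds$ratings$pom)]
  expect_true(all(pom == round(pom) & pom >= 0 & pom <= 100))
  # POM order agrees with BI-RADS order within reader x mode (both are
  # monotone maps of the same latent score): every POM in a lower
  # category is <= every POM in a higher one
  by <- split(ds$ratings, paste(ds$ratings$reader_id, ds$ratings$mode))
  for (g in by) {
    g <- g[!is.na(g$pom), ]
    cats <- sort(unique(g$bi_rads))
    if (length(cats) < 2) next
    hi <- tapply(g$pom, g$bi_rads, max)[as.character(cats)]
    lo <- tapply(g$pom, g$bi_rads, min)[as.character(cats)]
    expect_true(all(utils::head(hi, -1) <= utils::tail(lo, -1)))
  }
})

test_that("same seed reproduces the dataset; different seed varies it", {
  cfg <- sim_config_small()
  a <- simulate_study(cfg, seed = 123)
  b <- simulate_study(cfg, seed = 123)
  expect_identical(a$truth, b$truth)
  expect_identical(a$ratings, b$ratings)
  c <- simulate_study(cfg, seed = 124)
  expect_false(identical(a$ratings$bi_rads, c$ratings$bi_rads))
})

test_that("vanishing noise with a large shift saturates every AUC at 1", {
  cfg <- sim_config_small(
    mu = c(DM = 60, AICAD_SM = 60, DM_DBT = 60, AICAD_SM_DBT = 60),
    sigma2_reader = 0, sigma2_case = 1e-6, sigma2_interaction = 0,
    sigma2_residual = 1e-6, benign_shift = 0)
  ds <- simulate_study(cfg, seed = 5)
  for (m in cfg$modes) {
    tab <- reader_auc_table(ds, m, "pom")
    expect_equal(unname(tab$auc), rep(1, 4))
    tabb <- reader_auc_table(ds, m, "birads")
    expect_equal(tabb$mean, 1)
  }
})

test_that("latent-scale calibration has the closed binormal form", {
  expect_equal(calibrate_mu(0.5, scale = "latent"), 0)
  # unit total case-varying variance: AUC = Phi(mu / sqrt(2))
  expect_equal(calibrate_mu(0.76, sigma2_case = 1, sigma2_interaction = 0,
                            sigma2_residual = 0, scale = "latent"),
               sqrt(2) * qnorm(0.76))
  # inverse consistency at the default variances
  mu <- calibrate_mu(0.871, scale = "latent")
  expect_equal(binormal_auc(mu), 0.871, tolerance = 1e-8)
})

test_that("observed-scale calibration accounts for the BI-RADS 1-2 collapse", {
  mu_lat <- calibrate_mu(0.87, benign_shift = 0.8, prop_benign = 0.3,
                         scale = "latent")
  mu_obs <- calibrate_mu(0.87, benign_shift = 0.8, prop_benign = 0.3,
                         scale = "observed")
  # collapsing the low categories loses discrimination, so the observed
  # scale needs a larger shift
  expect_gt(mu_obs, mu_lat)
  # and the population POM-scale AUC at mu_obs equals the target
  expect_equal(pom_auc_population(mu_obs, benign_shift = 0.8,
                                  prop_benign = 0.3), 0.87,
               tolerance = 1e-6)
})

test_that("calibrated generator recovers the target AUC in simulation", {
  # moderately large scaled study; mean reader-averaged POM AUC over
  # replicates should sit on the calibrated target within MC error
  cfg <- sim_config(n_patients = 194L, target_auc = c(
    DM = 0.87, AICAD_SM = 0.87, DM_DBT = 0.87, AICAD_SM_DBT = 0.87),
    modes = c("DM", "AICAD_SM", "DM_DBT", "AICAD_SM_DBT"))
  aucs <- vapply(1:40, function(i) {
    ds <- simulate_study(cfg, seed = 500 + i)
    reader_auc_table(ds, "DM", "pom")$mean
  }, numeric(1))
  mc_se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.87), 3 * mc_se + 0.002)
})

test_that("simulation configs round-trip through JSON and YAML", {
  cfg <- sim_config_small(seed = 77)
  fj <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, fj)
  back <- read_sim_config(fj)
  expect_equal(back$composition, cfg$composition)
  expect_equal(back$mu, cfg$mu)
  expect_equal(back$finding_margins, cfg$finding_margins)
  expect_equal(back$seed, cfg$seed)
  expect_identical(simulate_study(back, seed = 1)$ratings,
                   simulate_study(cfg, seed = 1)$ratings)
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, fy)
  backy <- read_sim_config(fy)
  expect_equal(backy$mu, cfg$mu)
})

test_that("per-finding mode adjustments shift only the targeted lesions", {
  adj <- matrix(-3, nrow = 1, ncol = 1,
                dimnames = list("calcification", "AICAD_SM"))
  cfg <- sim_config_small(mode_finding_adjust = adj,
                          mu = c(DM = 4, AICAD_SM = 4, DM_DBT = 4,
                                 AICAD_SM_DBT = 4))
  ds <- simulate_study(cfg, seed = 31)
  calc_mal <- ds$truth$case_id[ds$truth$finding_type == "calcification" &
                                 ds$truth$truth == "malignant"]
  rt <- ds$ratings
  dm_calc <- rt$bi_rads[rt$mode == "DM" & rt$case_id %in% calc_mal]
  sm_calc <- rt$bi_rads[rt$mode == "AICAD_SM" & rt$case_id %in% calc_mal]
  expect_gt(mean(dm_calc), mean(sm_calc))
})
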