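# Shared fixtures and independent oracles.

# O(n^2) pair-counting AUC oracle: wins + half ties over all pos-neg pairs.
# Deliberately independent of the package's sweep/trapezoid implementation.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A deterministic hand-built 2-case-per-patient study: 4 patients
# (8 breasts), 2 readers, 2 modes. Rating rows are written explicitly so
# tests can reason about every count.
tiny_manual_study <- function() {
  truth <- data.frame(
    case_id = sprintf("C%d", 1:8),
    patient_id = rep(sprintf("P%d", 1:4), each = 2),
    side = rep(c("left", "right"), 4),
    truth = c("malignant", "normal_negative", "malignant", "benign_biopsy",
              "normal_negative", "normal_negative", "benign_biopsy",
              "malignant"),
    density = c("dense", "dense", "non_dense", "non_dense",
                "dense", "dense", "non_dense", "non_dense"),
    finding_type = c("mass", "none", "calcification", "mass",
                     "none", "none", "calcification", "mass"),
    lesion_size_mm = c(15, NA, 8, 22, NA, NA, 12, 30),
    histology = c("idc", NA, "dcis", NA, NA, NA, NA, "idc"),
    stringsAsFactors = FALSE)
  grid <- expand.grid(case_id = truth$case_id,
                      reader_id = c("R1", "R2"),
                      mode = c("DM", "AICAD_SM"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # malignant cases score high, benign intermediate, normals low
  base <- c(C1 = 5L, C2 = 1L, C3 = 4L, C4 = 3L, C5 = 2L, C6 = 1L,
            C7 = 3L, C8 = 5L)
  grid$bi_rads <- unname(base[grid$case_id])
  # reader 2 is one category more conservative on C3 under DM
  sel <- grid$case_id == "C3" & grid$reader_id == "R2" & grid$mode == "DM"
  grid$bi_rads[sel] <- 3L
  grid$session <- ifelse(grid$mode %in% c("DM", "DM_DBT"), 1L, 2L)
  pom_map <- c("3" = 30L, "4" = 70L, "5" = 95L)
  grid$pom <- ifelse(grid$bi_rads >= 3,
                     pom_map[as.character(grid$bi_rads)], NA_integer_)
  mrmc_study(truth, grid)
}

# Small simulated study shared across tests (fixed latent shifts, no
# calibration cost).
tiny_sim_study <- function(seed = 1, ...) {
  simulate_study(sim_config_small(...), seed = seed)
}

# Copy one mode's ratings onto another so both modes are identical
# (paired-difference null fixture).
clone_mode <- function(ds, from, to) {
  rt <- ds$ratings
  src <- rt[rt$mode == from, ]
  src$mode <- to
  src$session <- unname(c(DM = 1L, DM_DBT = 1L, AICAD_SM = 2L,
                          AICAD_SM_DBT = 2L)[to])
  rt <- rbind(rt[!(rt$mode %in% to), ], src)
  mrmc_study(ds$truth, rt, provenance = "synthetic",
             seed = ds$metadata$seed)
}

random_score_instance <- function(n, tie_prob = 0.5) {
  # mixed continuous/tied scores with guaranteed class mix
  labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
  scores <- if (runif(1) < tie_prob)
    sample(1:4, n, replace = TRUE) + labels * runif(1, 0, 2)
  else
    rnorm(n) + labels * runif(1, 0, 2)
  list(scores = scores, labels = labels)
}
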