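## Synthetic reader-study generator.
##
## Latent-score variance-components model in the Roe-Metz tradition: for
## breast k (patient p), reader j and reading mode m,
##
##   x_{jkm} = mu_m 1[malignant_k] + delta_b 1[benign_k]
##             + r_j + c_k + rc_{jk} + eps_{jkm}
##
## with r_j ~ N(0, s2_reader), c_k = s_case (sqrt(rho) u_p + sqrt(1-rho) w_k)
## (within-patient correlation rho between the two breasts), interaction
## rc_{jk} ~ N(0, s2_interaction) shared across modes, and residual
## eps ~ N(0, s2_residual) independent per mode. Forced BI-RADS categories
## come from four ordered cutpoints on the latent scale; a POM (0-100) is
## emitted only when BI-RADS >= 3, via a deterministic monotone probit
## squash of the latent score (so POM order agrees with latent order).

.default_finding_margins <- function() {
  m <- rbind(mass            = c(49, 34),
             mass_calc       = c(15, 1),
             focal_asymmetry = c(2, 3),
             distortion      = c(4, 6),
             calcification   = c(14, 39))
  colnames(m) <- c("malignant", "benign_biopsy")
  m
}

.sim_mode_targets <- c(DM = 0.871, AICAD_SM = 0.902,
                       DM_DBT = 0.895, AICAD_SM_DBT = 0.909)

#' Binormal latent-scale AUC of the simulator
#'
#' Population AUC of a single reader's continuous latent score for the
#' malignant class against the mixed non-diseased class (a fraction
#' `prop_benign` of negatives is shifted by `benign_shift`):
#' `AUC = (1 - p_b) Phi(mu / sqrt(2 v)) + p_b Phi((mu - delta_b) / sqrt(2 v))`
#' with `v = s2_case + s2_interaction + s2_residual` (reader effects cancel
#' within reader).
#'
#' @param mu malignant latent shift.
#' @param sigma2_case,sigma2_interaction,sigma2_residual variance
#'   components of the case-varying latent terms.
#' @param benign_shift latent shift of biopsy-proven benign cases.
#' @param prop_benign fraction of the non-diseased class that is benign.
#' @return The population AUC.
#' @export
binormal_auc <- function(mu, sigma2_case = 1, sigma2_interaction = 0.1,
                         sigma2_residual = 1, benign_shift = 0,
                         prop_benign = 0) {
  v2 <- 2 * (sigma2_case + sigma2_interaction + sigma2_residual)
  (1 - prop_benign) * stats::pnorm(mu / sqrt(v2)) +
    prop_benign * stats::pnorm((mu - benign_shift) / sqrt(v2))
}

## Observed-scale population AUC of the POM score: the latent AUC minus
## the tie-group correction from collapsing BI-RADS 1 and 2 (which carry
## no POM) to single score values. For a reader with effect r the
## categories live at cutpoints t - r on the case-varying latent scale;
## the correction is averaged over the reader-effect distribution by a
## dense trapezoidal grid. Integer rounding of the POM itself is ignored
## (its tie mass is negligible at 101 levels).
pom_auc_population <- function(mu, sigma2_case = 1, sigma2_interaction = 0.1,
                               sigma2_residual = 1, sigma2_reader = 0.05,
                               benign_shift = 0, prop_benign = 0,
                               cutpoints = c(0.5, 1.5, 2.6, 3.5)) {
  s <- sqrt(sigma2_case + sigma2_interaction + sigma2_residual)
  cont <- binormal_auc(mu, sigma2_case, sigma2_interaction, sigma2_residual,
                       benign_shift, prop_benign)
  neg_w <- c(1 - prop_benign, prop_benign)
  neg_mean <- c(0, benign_shift)
  keep <- neg_w > 0
  t1 <- cutpoints[1]; t2 <- cutpoints[2]

  corr_at <- function(r) {
    bounds <- list(c(-Inf, t1 - r), c(t1 - r, t2 - r))
    corr <- 0
    for (bd in bounds) {
      a <- bd[1]; b <- bd[2]
      p_pos <- stats::pnorm(b, mu, s) - stats::pnorm(a, mu, s)
      if (p_pos < 1e-14) next
      for (k in which(keep)) {
        dk <- neg_mean[k]
        p_neg <- stats::pnorm(b, dk, s) - stats::pnorm(a, dk, s)
        if (p_neg < 1e-14) next
        Fa <- stats::pnorm(a, dk, s)
        both_gt <- stats::integrate(function(x)
          stats::dnorm(x, mu, s) * (stats::pnorm(x, dk, s) - Fa),
          lower = a, upper = b, rel.tol = 1e-9)$value
        corr <- corr + neg_w[k] * (both_gt - 0.5 * p_pos * p_neg)
      }
    }
    corr
  }

  if (sigma2_reader <= 0) return(cont - corr_at(0))
  sr <- sqrt(sigma2_reader)
  grid <- seq(-4.5 * sr, 4.5 * sr, length.out = 41)
  w <- stats::dnorm(grid, 0, sr)
  w <- w / sum(w)
  cont - sum(w * vapply(grid, corr_at, numeric(1)))
}

#' Calibrate the malignant latent shift for a target AUC
#'
#' Inverts the simulator's population AUC so that a reading mode attains a
#' requested discriminability. `scale = "latent"` inverts the binormal
#' identity of the continuous latent score ([binormal_auc()]); with no
#' benign shift this is the closed form `mu = sqrt(2 v) * qnorm(target)`.
#' `scale = "observed"` (the generator's default) inverts the population
#' AUC of the POM score actually analysed, which is slightly lower than
#' the latent AUC because BI-RADS 1-2 cases carry no POM and collapse to
#' two tie groups.
#'
#' @param target_auc requested AUC in `[0.5, 1)`.
#' @inheritParams pom_auc_population
#' @param scale `"observed"` or `"latent"`.
#' @return The latent shift `mu`.
#' @export
#' @examples
#' calibrate_mu(0.76, sigma2_case = 1, sigma2_interaction = 0,
#'              sigma2_residual = 0, scale = "latent")  # sqrt(2)*qnorm(0.76)
calibrate_mu <- function(target_auc, sigma2_case = 1,
                         sigma2_interaction = 0.1, sigma2_residual = 1,
                         sigma2_reader = 0.05, benign_shift = 0,
                         prop_benign = 0,
                         cutpoints = c(0.5, 1.5, 2.6, 3.5),
                         scale = c("observed", "latent")) {
  scale <- match.arg(scale)
  if (target_auc < 0.5 || target_auc >= 1)
    stop("target_auc must be in [0.5, 1)")
  if (scale == "latent" && prop_benign == 0) {
    v2 <- 2 * (sigma2_case + sigma2_interaction + sigma2_residual)
    return(sqrt(v2) * stats::qnorm(target_auc))
  }
  f <- if (scale == "latent") {
    function(m) binormal_auc(m, sigma2_case, sigma2_interaction,
                             sigma2_residual, benign_shift, prop_benign) -
      target_auc
  } else {
    function(m) pom_auc_population(m, sigma2_case, sigma2_interaction,
                                   sigma2_residual, sigma2_reader,
                                   benign_shift, prop_benign, cutpoints) -
      target_auc
  }
  stats::uniroot(f, interval = c(-2, 25), tol = 1e-8)$root
}

#' Simulation configuration
#'
#' Defines a synthetic reader study: case composition, reader count,
#' reading modes, latent-model variance components and per-mode target
#' AUCs. The defaults reproduce the reference study design: 388 breasts in
#' 194 patients (two per patient, MLO view), 84 malignant / 83
#' biopsy-proven benign / 221 normal-negative, density split 206 non-dense
#' / 182 dense (assigned per patient), lesion-type margins mass 49/34,
#' mass+calcification 15/1, focal asymmetry 2/3, distortion 4/6,
#' calcification 14/39 (malignant/benign), 4 readers, 4 sequential modes,
#' and per-mode POM AUC targets 0.871 / 0.902 / 0.895 / 0.909.
#'
#' @param n_patients number of patients; every patient contributes both
#'   breasts.
#' @param composition named counts `malignant`, `benign_biopsy`,
#'   `normal_negative`; must sum to `2 * n_patients`.
#' @param density named counts `non_dense`, `dense`; density is a patient
#'   attribute, so each count must be even and they must sum to
#'   `2 * n_patients`.
#' @param finding_margins 5 x 2 matrix (rows `mass`, `mass_calc`,
#'   `focal_asymmetry`, `distortion`, `calcification`; columns
#'   `malignant`, `benign_biopsy`) whose column sums match `composition`.
#' @param n_readers number of readers.
#' @param modes reading modes to generate.
#' @param target_auc named per-mode POM AUC targets in `[0.5, 1)`; used to
#'   calibrate `mu` when `mu` is `NULL`.
#' @param mu optional named per-mode malignant latent shifts; bypasses
#'   calibration.
#' @param sigma2_reader,sigma2_case,sigma2_interaction,sigma2_residual
#'   latent variance components.
#' @param rho_patient within-patient correlation of the case effect,
#'   `0 <= rho < 1`.
#' @param benign_shift latent shift of biopsy-proven benign cases (they
#'   drew suspicion in reality, so they sit between normal and malignant).
#' @param birads_cutpoints four strictly increasing latent cutpoints for
#'   the forced BI-RADS categories; the defaults put the BI-RADS >= 4
#'   operating point of a 0.871-AUC mode at roughly 94% specificity.
#' @param pom_scale latent width of the probit POM map.
#' @param mode_finding_adjust optional findings x modes matrix added to
#'   the malignant latent shift per finding type (e.g. to make a mode
#'   weaker on calcifications); `NULL` for none.
#' @param calibrate_scale `"observed"` or `"latent"`; see
#'   [calibrate_mu()].
#' @param seed default generator seed.
#' @return An object of class `mrmc_sim_config` (with `mu` filled in).
#' @seealso [simulate_study()], [sim_config_small()]
#' @export
sim_config <- function(n_patients = 194L,
                       composition = c(malignant = 84L,
                                       benign_biopsy = 83L,
                                       normal_negative = 221L),
                       density = c(non_dense = 206L, dense = 182L),
                       finding_margins = .default_finding_margins(),
                       n_readers = 4L,
                       modes = .modes,
                       target_auc = .sim_mode_targets[modes],
                       mu = NULL,
                       sigma2_reader = 0.05,
                       sigma2_case = 1,
                       sigma2_interaction = 0.1,
                       sigma2_residual = 1,
                       rho_patient = 0.5,
                       benign_shift = 0.8,
                       birads_cutpoints = c(0.5, 1.5, 2.6, 3.5),
                       pom_scale = 1.5,
                       mode_finding_adjust = NULL,
                       calibrate_scale = c("observed", "latent"),
                       seed = 1L) {
  calibrate_scale <- match.arg(calibrate_scale)
  n_breasts <- 2L * as.integer(n_patients)
  composition <- composition[.truth_levels]
  if (anyNA(composition))
    stop("composition must name counts for ",
         paste(.truth_levels, collapse = ", "))
  if (sum(composition) != n_breasts)
    stop("composition counts must sum to 2 * n_patients = ", n_breasts)
  density <- density[.density_levels]
  if (anyNA(density) || sum(density) != n_breasts)
    stop("density counts must name non_dense and dense and sum to ",
         n_breasts)
  if (any(density %% 2L != 0L))
    stop("density is a patient attribute: each density count must be even")
  fm <- as.matrix(finding_margins)
  lesion_findings <- setdiff(.finding_levels, "none")
  if (!identical(rownames(fm), lesion_findings) ||
      !identical(colnames(fm), c("malignant", "benign_biopsy")))
    stop("finding_margins must have rows ",
         paste(lesion_findings, collapse = ", "),
         " and columns malignant, benign_biopsy")
  if (sum(fm[, "malignant"]) != composition[["malignant"]] ||
      sum(fm[, "benign_biopsy"]) != composition[["benign_biopsy"]])
    stop("finding_margins column sums must match the composition counts")
  if (length(birads_cutpoints) != 4L || any(diff(birads_cutpoints) <= 0))
    stop("birads_cutpoints must be 4 strictly increasing values")
  if (rho_patient < 0 || rho_patient >= 1)
    stop("rho_patient must satisfy 0 <= rho < 1")
  stopifnot(sigma2_reader >= 0, sigma2_case > 0, sigma2_interaction >= 0,
            sigma2_residual > 0, pom_scale > 0, n_readers >= 1)
  prop_benign <- composition[["benign_biopsy"]] /
    (composition[["benign_biopsy"]] + composition[["normal_negative"]])
  if (is.null(mu)) {
    target_auc <- target_auc[modes]
    if (anyNA(target_auc))
      stop("target_auc must name every mode in 'modes'")
    ## calibrate each distinct target once
    uniq <- unique(target_auc)
    mu_u <- vapply(uniq, function(t)
      calibrate_mu(t, sigma2_case, sigma2_interaction, sigma2_residual,
                   sigma2_reader, benign_shift, prop_benign,
                   birads_cutpoints, calibrate_scale),
      numeric(1))
    mu <- stats::setNames(mu_u[match(target_auc, uniq)], modes)
  } else {
    mu <- mu[modes]
    if (anyNA(mu)) stop("mu must name every mode in 'modes'")
    target_auc <- NULL
  }
  if (!is.null(mode_finding_adjust)) {
    mfa <- as.matrix(mode_finding_adjust)
    if (!all(rownames(mfa) %in% lesion_findings) ||
        !all(colnames(mfa) %in% modes))
      stop("mode_finding_adjust rows must be finding types and columns modes")
  }
  structure(list(n_patients = as.integer(n_patients),
                 composition = composition, density = density,
                 finding_margins = fm, n_readers = as.integer(n_readers),
                 modes = modes, target_auc = target_auc, mu = mu,
                 sigma2_reader = sigma2_reader, sigma2_case = sigma2_case,
                 sigma2_interaction = sigma2_interaction,
                 sigma2_residual = sigma2_residual,
                 rho_patient = rho_patient, benign_shift = benign_shift,
                 birads_cutpoints = birads_cutpoints,
                 pom_scale = pom_scale,
                 mode_finding_adjust = mode_finding_adjust,
                 prop_benign = prop_benign,
                 seed = as.integer(seed)),
            class = "mrmc_sim_config")
}

#' @export
print.mrmc_sim_config <- function(x, ...) {
  cat("Synthetic reader-study configuration\n")
  cat(sprintf("  %d patients (%d breasts): %s\n", x$n_patients,
              2L * x$n_patients,
              paste(sprintf("%d %s", x$composition, names(x$composition)),
                    collapse = ", ")))
  cat(sprintf("  density: %d non-dense / %d dense (per patient)\n",
              x$density[["non_dense"]], x$density[["dense"]]))
  cat(sprintf("  %d readers x modes %s\n", x$n_readers,
              paste(x$modes, collapse = ", ")))
  cat(sprintf("  mu: %s\n",
              paste(sprintf("%s=%.3f", names(x$mu), x$mu), collapse = ", ")))
  cat(sprintf("  variances: reader %.3g, case %.3g, interaction %.3g, residual %.3g; rho_patient %.2f; benign shift %.2f\n",
              x$sigma2_reader, x$sigma2_case, x$sigma2_interaction,
              x$sigma2_residual, x$rho_patient, x$benign_shift))
  cat(sprintf("  BI-RADS cutpoints: %s; seed %d\n",
              paste(x$birads_cutpoints, collapse = ", "), x$seed))
  invisible(x)
}

#' Small example configuration
#'
#' A 20-patient (40-breast) scaled-down configuration with fixed latent
#' shifts (no calibration step), intended for examples and quick tests.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return An `mrmc_sim_config`.
#' @export
sim_config_small <- function(...) {
  args <- list(
    n_patients = 20L,
    composition = c(malignant = 8L, benign_biopsy = 8L,
                    normal_negative = 24L),
    density = c(non_dense = 20L, dense = 20L),
    finding_margins = {
      m <- rbind(mass = c(4, 4), mass_calc = c(1, 1),
                 focal_asymmetry = c(1, 1), distortion = c(1, 1),
                 calcification = c(1, 1))
      colnames(m) <- c("malignant", "benign_biopsy")
      m
    },
    mu = c(DM = 1.7, AICAD_SM = 2.0, DM_DBT = 1.9, AICAD_SM_DBT = 2.1))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Generate a case-truth table
#'
#' Draws the per-breast reference standard with *exact* configured
#' margins: truth classes, finding types within class, and per-patient
#' density all match the configured counts, not merely in expectation.
#' Uses the current RNG state; [simulate_study()] seeds it.
#'
#' @param cfg an [sim_config()] object.
#' @return A data frame of case-truth rows (see [read_truth()]).
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "mrmc_sim_config"))
  np <- cfg$n_patients
  n <- 2L * np
  patient_id <- rep(sprintf("P%04d", seq_len(np)), each = 2L)
  side <- rep(c("left", "right"), np)
  case_id <- paste0(patient_id, "_", substr(side, 1, 1))

  truth <- sample(rep(names(cfg$composition), cfg$composition))
  finding <- rep("none", n)
  fm <- cfg$finding_margins
  finding[truth == "malignant"] <-
    sample(rep(rownames(fm), fm[, "malignant"]))
  finding[truth == "benign_biopsy"] <-
    sample(rep(rownames(fm), fm[, "benign_biopsy"]))

  dens_pat <- sample(rep(.density_levels, cfg$density / 2L))
  density <- dens_pat[rep(seq_len(np), each = 2L)]

  lesion <- finding != "none"
  size <- rep(NA_real_, n)
  ## malignant masses in the reference design: 6-42 mm, median ~19
  size[lesion] <- pmin(60, pmax(4, round(stats::rlnorm(sum(lesion),
                                                       log(18), 0.4))))
  histology <- rep(NA_character_, n)
  mal <- truth == "malignant"
  histology[mal] <- sample(
    c("invasive_ductal_carcinoma", "dcis", "invasive_lobular_carcinoma",
      "tubular_carcinoma", "invasive_micropapillary_carcinoma"),
    sum(mal), replace = TRUE, prob = c(71, 8, 3, 1, 1))

  data.frame(case_id = case_id, patient_id = patient_id, side = side,
             truth = truth, density = density, finding_type = finding,
             lesion_size_mm = size, histology = histology,
             stringsAsFactors = FALSE)
}

#' Generate a complete rating table for a truth table
#'
#' Draws the latent variance-components model (see the package vignette)
#' and emits one rating per breast x reader x mode: forced BI-RADS from
#' the latent cutpoints, POM (integer 0-100) only when BI-RADS >= 3 via a
#' deterministic monotone probit map of the latent score, so POM order
#' agrees with latent order within every reader x mode. Uses the current
#' RNG state; [simulate_study()] seeds it.
#'
#' @param truth a truth table from [generate_truth()].
#' @param cfg the [sim_config()] used to generate it.
#' @return A data frame of rating rows (see [read_ratings()]).
#' @export
generate_ratings <- function(truth, cfg) {
  stopifnot(inherits(cfg, "mrmc_sim_config"))
  n <- nrow(truth)
  R <- cfg$n_readers
  pats <- unique(truth$patient_id)
  pidx <- match(truth$patient_id, pats)

  r_eff <- stats::rnorm(R, 0, sqrt(cfg$sigma2_reader))
  u_pat <- stats::rnorm(length(pats))
  w_breast <- stats::rnorm(n)
  c_eff <- sqrt(cfg$sigma2_case) *
    (sqrt(cfg$rho_patient) * u_pat[pidx] +
       sqrt(1 - cfg$rho_patient) * w_breast)
  rc <- matrix(stats::rnorm(n * R, 0, sqrt(cfg$sigma2_interaction)), n, R)

  mal <- truth$truth == "malignant"
  ben <- truth$truth == "benign_biopsy"
  tcuts <- cfg$birads_cutpoints
  out <- vector("list", length(cfg$modes) * R)
  i <- 0L
  for (m in cfg$modes) {
    shift <- numeric(n)
    shift[mal] <- cfg$mu[[m]]
    shift[ben] <- cfg$benign_shift
    if (!is.null(cfg$mode_finding_adjust) &&
        m %in% colnames(cfg$mode_finding_adjust)) {
      adj <- cfg$mode_finding_adjust[, m, drop = FALSE]
      hit <- mal & truth$finding_type %in% rownames(adj)
      shift[hit] <- shift[hit] + adj[truth$finding_type[hit], 1]
    }
    for (j in seq_len(R)) {
      x <- shift + r_eff[j] + c_eff + rc[, j] +
        stats::rnorm(n, 0, sqrt(cfg$sigma2_residual))
      bi <- findInterval(x, tcuts) + 1L
      pom <- ifelse(bi >= 3L,
                    as.integer(pmin(100, pmax(0, round(
                      100 * stats::pnorm((x - tcuts[3]) / cfg$pom_scale))))),
                    NA_integer_)
      i <- i + 1L
      out[[i]] <- data.frame(case_id = truth$case_id,
                             reader_id = sprintf("R%d", j),
                             mode = m,
                             session = unname(.mode_session[[m]]),
                             bi_rads = bi, pom = pom,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a complete synthetic reader study
#'
#' Seeds the RNG once from `seed`, draws the truth table and the full
#' rating table, and returns them as an [mrmc_study()] tagged as
#' synthetic. Identical configuration and seed reproduce the dataset
#' exactly.
#'
#' @param cfg an [sim_config()] object.
#' @param seed RNG seed; defaults to the configuration's seed.
#' @return An [mrmc_study()] object.
#' @export
#' @examples
#' ds <- simulate_study(sim_config_small(), seed = 42)
#' validate_completeness(ds)$complete
simulate_study <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "mrmc_sim_config"))
  set.seed(seed)
  truth <- generate_truth(cfg)
  ratings <- generate_ratings(truth, cfg)
  mrmc_study(truth, ratings, provenance = "synthetic", seed = seed)
}

#' Write / read a simulation configuration
#'
#' Round-trips an [sim_config()] through a JSON (or, with the `yaml`
#' package, YAML) file. The calibrated `mu` values are stored, so reading
#' a configuration back does not repeat the calibration.
#'
#' @param cfg an `mrmc_sim_config`.
#' @param path output path; extension `.json`, `.yaml` or `.yml`.
#' @return `write_sim_config`: invisibly, `path`. `read_sim_config`: the
#'   reconstructed `mrmc_sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mrmc_sim_config"))
  fm <- cfg$finding_margins
  lst <- unclass(cfg)
  lst$finding_margins <- list(finding = rownames(fm),
                              malignant = unname(fm[, "malignant"]),
                              benign_biopsy = unname(fm[, "benign_biopsy"]))
  lst$composition <- as.list(cfg$composition)
  lst$density <- as.list(cfg$density)
  lst$mu <- as.list(cfg$mu)
  lst$target_auc <- if (is.null(cfg$target_auc)) NULL else
    as.list(cfg$target_auc)
  lst$mode_finding_adjust <- NULL  # not serialized in v1
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::write_yaml(lst, path)
  } else {
    writeLines(jsonlite::toJSON(lst, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"), path)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  fm <- NULL
  if (!is.null(lst$finding_margins)) {
    fm <- cbind(malignant = as.numeric(lst$finding_margins$malignant),
                benign_biopsy = as.numeric(lst$finding_margins$benign_biopsy))
    rownames(fm) <- lst$finding_margins$finding
  }
  args <- list(
    n_patients = lst$n_patients,
    composition = unlist(lst$composition),
    density = unlist(lst$density),
    n_readers = lst$n_readers,
    modes = unlist(lst$modes),
    mu = unlist(lst$mu),
    sigma2_reader = lst$sigma2_reader,
    sigma2_case = lst$sigma2_case,
    sigma2_interaction = lst$sigma2_interaction,
    sigma2_residual = lst$sigma2_residual,
    rho_patient = lst$rho_patient,
    benign_shift = lst$benign_shift,
    birads_cutpoints = unlist(lst$birads_cutpoints),
    pom_scale = lst$pom_scale,
    seed = lst$seed)
  if (!is.null(fm)) args$finding_margins <- fm
  do.call(sim_config, args)
}
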