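#' Synthetic cohorts and boundary traces
#'
#' A seedable forward model of the study data: a cohort of eyes whose
#' demographics and biometry follow the published summary distributions, whose
#' sector ppCT values carry programmed effects of axial length, PMP angle and
#' disc tilt, and whose circumpapillary boundary traces realize those sector
#' values as a smooth angular profile riding on a sinusoidal RPE trajectory.
#' Every analysis stage can therefore be tested end to end without external
#' data.
#'
#' @name synthetic_data
NULL

#' Cohort generator configuration
#'
#' Defaults encode the study conditions: axial length 25.46 +/- 1.43 mm
#' truncated to the observed range, PMP 5.43 +/- 3.47 degrees, disc tilt
#' 53.08 +/- 23.93 px with a weak positive coupling to axial length, and
#' per-sector baseline ppCT means/SDs equal to the published sector summary.
#' Effect sizes are expressed as *target marginal Pearson correlations* per
#' sector (axial length negative everywhere, PMP positive everywhere, tilt
#' negative in T and IT only); the generator solves the implied regression
#' coefficients from the predictor covariance so that at cohort scale the
#' sampled Spearman correlations fall in the published ranges. A share
#' `sector_shared_frac` of each sector's residual variance is a common
#' within-eye component, reflecting the strong correlation of choroidal
#' thickness across sectors of one eye.
#'
#' @param n_eyes Number of eyes.
#' @param seed Optional integer seed stored in the config.
#' @param axial_length List: `mean`, `sd`, `bounds` (truncation, mm).
#' @param pmp List: `mean`, `sd` (degrees).
#' @param tilt List: `mean`, `sd` (px), `al_coupling` (px per mm of axial
#'   length).
#' @param age List: `mean`, `sd`, `bounds` (years).
#' @param refractive List: `mean`, `sd` (diopters), `al_slope` (D per mm).
#' @param sector_mean,sector_sd Named per-sector baseline ppCT mean and SD
#'   (microns), TSNIT order.
#' @param target_r_al,target_r_pmp,target_r_tilt Named per-sector target
#'   marginal correlations of sector ppCT with each predictor.
#' @param sector_shared_frac Fraction of residual sector variance shared
#'   across sectors within an eye, in `[0, 1)`.
#' @param ppa List: `prevalence` and `al_slope` (logit slope per mm) for the
#'   parapapillary atrophy flag.
#' @param sex_ratio_male Fraction of male participants.
#' @param ineligible_fraction Fraction of records carrying a programmed
#'   exclusion flag.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(
    n_eyes = 114,
    seed = NULL,
    axial_length = list(mean = 25.46, sd = 1.43, bounds = c(22.38, 30.42)),
    pmp = list(mean = 5.43, sd = 3.47),
    tilt = list(mean = 53.08, sd = 23.93, al_coupling = 1.5),
    age = list(mean = 25.8, sd = 3.9, bounds = c(20, 40)),
    refractive = list(mean = -4.79, sd = 3.31, al_slope = -2.08),
    sector_mean = c(T = 166.87, ST = 183.41, S = 191.59, SN = 190.50,
                    N = 190.62, IN = 173.21, I = 151.49, IT = 153.09),
    sector_sd = c(T = 62.45, ST = 57.19, S = 50.44, SN = 49.59,
                  N = 47.66, IN = 45.58, I = 44.58, IT = 51.10),
    target_r_al = c(T = -0.43, ST = -0.35, S = -0.30, SN = -0.28,
                    N = -0.24, IN = -0.26, I = -0.33, IT = -0.40),
    target_r_pmp = c(T = 0.37, ST = 0.33, S = 0.28, SN = 0.26,
                     N = 0.23, IN = 0.24, I = 0.26, IT = 0.30),
    target_r_tilt = c(T = -0.32, ST = 0, S = 0, SN = 0,
                      N = 0, IN = 0, I = 0, IT = -0.32),
    sector_shared_frac = 0.7,
    ppa = list(prevalence = 0.69, al_slope = 0.8),
    sex_ratio_male = 0.693,
    ineligible_fraction = 0) {
  sn <- sector_names()
  stopifnot(n_eyes >= 1,
            axial_length$sd > 0, pmp$sd > 0, tilt$sd > 0,
            axial_length$bounds[1] < axial_length$bounds[2],
            identical(names(sector_mean), sn),
            identical(names(sector_sd), sn),
            all(sector_sd > 0),
            identical(names(target_r_al), sn),
            identical(names(target_r_pmp), sn),
            identical(names(target_r_tilt), sn),
            sector_shared_frac >= 0, sector_shared_frac < 1,
            ppa$prevalence > 0, ppa$prevalence < 1,
            sex_ratio_male >= 0, sex_ratio_male <= 1,
            ineligible_fraction >= 0, ineligible_fraction < 1)
  structure(as.list(environment()), class = "cohort_config")
}

# Mean and variance of N(mean, sd^2) truncated to [lo, hi].
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = m, var = v)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Solve per-sector regression coefficients and residual SDs from the target
# marginal correlations and the predictor covariance. Sectors with a zero
# tilt target get a structurally zero tilt coefficient (their observed tilt
# correlation is then whatever the tilt-AL coupling induces).
calibrate_effects <- function(config) {
  al <- config$axial_length
  tm <- truncnorm_moments(al$mean, al$sd, al$bounds[1], al$bounds[2])
  v_al <- tm$var
  v_pmp <- config$pmp$sd^2
  v_tilt <- config$tilt$sd^2
  c_al_tilt <- config$tilt$al_coupling * v_al
  if (config$tilt$al_coupling^2 * v_al >= v_tilt) {
    stop("tilt al_coupling too strong for the stated tilt SD", call. = FALSE)
  }
  Sigma <- matrix(c(v_al,      0,     c_al_tilt,
                    0,         v_pmp, 0,
                    c_al_tilt, 0,     v_tilt),
                  3, 3, dimnames = list(c("al", "pmp", "tilt"),
                                        c("al", "pmp", "tilt")))
  sds <- sqrt(diag(Sigma))
  sn <- sector_names()
  beta <- matrix(0, nrow = 8, ncol = 3,
                 dimnames = list(sn, c("al", "pmp", "tilt")))
  resid_sd <- stats::setNames(numeric(8), sn)
  for (s in sn) {
    r <- c(config$target_r_al[[s]], config$target_r_pmp[[s]],
           config$target_r_tilt[[s]])
    sd_s <- config$sector_sd[[s]]
    if (r[3] == 0) {
      b <- c(r[1] * sd_s / sds[1], r[2] * sd_s / sds[2], 0)
    } else {
      b <- solve(Sigma, r * sd_s * sds)
    }
    rv <- sd_s^2 - drop(t(b) %*% Sigma %*% b)
    if (rv <= 0) {
      stop(sprintf("sector %s: target correlations leave no residual variance",
                   s), call. = FALSE)
    }
    beta[s, ] <- b
    resid_sd[s] <- sqrt(rv)
  }
  list(beta = beta, resid_sd = resid_sd,
       pred_mean = c(al = tm$mean,
                     pmp = config$pmp$mean,
                     tilt = config$tilt$mean +
                       config$tilt$al_coupling * (tm$mean - al$mean)),
       pred_cov = Sigma)
}

#' Generate a synthetic cohort
#'
#' Draws `n_eyes` records: axial length truncated-normal; PMP normal; tilt
#' linear in axial length plus noise, clipped at zero; sector ppCT equal to
#' its baseline plus the calibrated linear effects of the centered predictors
#' plus a within-eye shared residual and a sector-specific residual, clipped
#' at 1 micron; PPA flag Bernoulli with probability increasing in axial
#' length; demographics and eligibility fields to match the study's entry
#' criteria (plus a programmed fraction of exclusion flags).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to the seed stored in the config).
#' @return Tibble with one row per eye: identifiers, demographics, biometry,
#'   `pmp`, `tilt`, `ppct_*` sector columns, `ppa`, eligibility fields and
#'   `exclusion_flag`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_eyes
  al_cfg <- config$axial_length
  cal <- calibrate_effects(config)

  al <- rtruncnorm(n, al_cfg$mean, al_cfg$sd, al_cfg$bounds[1], al_cfg$bounds[2])
  pmp <- stats::rnorm(n, config$pmp$mean, config$pmp$sd)
  tilt_resid_sd <- sqrt(config$tilt$sd^2 -
                          config$tilt$al_coupling^2 * cal$pred_cov["al", "al"])
  tilt <- pmax(0, config$tilt$mean +
                 config$tilt$al_coupling * (al - al_cfg$mean) +
                 stats::rnorm(n, 0, tilt_resid_sd))

  P <- cbind(al = al - cal$pred_mean[["al"]],
             pmp = pmp - cal$pred_mean[["pmp"]],
             tilt = tilt - cal$pred_mean[["tilt"]])
  shared <- stats::rnorm(n)
  rho <- config$sector_shared_frac
  sn <- sector_names()
  ppct <- matrix(NA_real_, nrow = n, ncol = 8,
                 dimnames = list(NULL, paste0("ppct_", sn)))
  for (s in sn) {
    mu <- config$sector_mean[[s]] + drop(P %*% cal$beta[s, ])
    res <- cal$resid_sd[[s]] *
      (sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n))
    ppct[, paste0("ppct_", s)] <- pmax(1, mu + res)
  }

  age <- rtruncnorm(n, config$age$mean, config$age$sd,
                    config$age$bounds[1], config$age$bounds[2])
  refr_resid <- sqrt(max(config$refractive$sd^2 -
                           config$refractive$al_slope^2 *
                           cal$pred_cov["al", "al"], 0.01))
  refr <- config$refractive$mean +
    config$refractive$al_slope * (al - cal$pred_mean[["al"]]) +
    stats::rnorm(n, 0, refr_resid)
  ppa_p <- stats::plogis(stats::qlogis(config$ppa$prevalence) +
                           config$ppa$al_slope * (al - cal$pred_mean[["al"]]))
  tibble::tibble(
    eye_id = sprintf("eye%04d", seq_len(n)),
    laterality = "right",
    age = round(age, 1),
    sex = ifelse(stats::runif(n) < config$sex_ratio_male, "M", "F"),
    refractive_error = refr,
    axial_length = al,
    pmp = pmp,
    tilt = tilt,
    !!!tibble::as_tibble(ppct),
    ppa = stats::runif(n) < ppa_p,
    bcva_logmar = pmin(0.1, stats::rnorm(n, 0, 0.04)),
    iop = pmin(21, pmax(8, stats::rnorm(n, 14.5, 2.2))),
    exclusion_flag = stats::runif(n) < config$ineligible_fraction
  )
}

#' Trace generator configuration
#'
#' @param n_ascans A-scans per circle (>= 64; 1024 for the 3.4 mm protocol).
#' @param axial_scale Microns per axial pixel.
#' @param rpe_noise_sd Per-A-scan RPE depth noise SD (px).
#' @param marking_noise_sd Manual-marking noise SD on the sampled RPE points
#'   (px).
#' @param n_marked_points Number of manually marked RPE points per eye.
#' @param rpe_phase True phase of the sinusoidal RPE trajectory (rad).
#' @param depth_offset_px Constant depth offset of the RPE in the B-scan.
#' @return List of class `trace_config`.
#' @export
trace_config <- function(n_ascans = 1024, axial_scale = 2.6,
                         rpe_noise_sd = 2, marking_noise_sd = 2,
                         n_marked_points = 64, rpe_phase = pi / 2,
                         depth_offset_px = 300) {
  stopifnot(n_ascans >= 64, axial_scale > 0,
            rpe_noise_sd >= 0, marking_noise_sd >= 0,
            n_marked_points >= 6, n_marked_points <= n_ascans)
  structure(as.list(environment()), class = "trace_config")
}

#' Synthesize fundus landmarks for a given PMP angle
#'
#' Places the disc at the origin and the fovea 4 mm away in the temporal
#' direction for the given laterality, displaced vertically so the PMP angle
#' equals `pmp_deg` (positive = fovea inferior, y-down frame).
#'
#' @param pmp_deg PMP angle in degrees, `(-90, 90)`.
#' @param laterality `"right"` or `"left"`.
#' @param distance_um Horizontal disc-fovea distance (microns).
#' @return A [fundus_landmarks()] object.
#' @export
landmarks_from_pmp <- function(pmp_deg, laterality = "right",
                               distance_um = 4000) {
  stopifnot(abs(pmp_deg) < 90, distance_um > 0)
  sx <- if (laterality == "right") -1 else 1
  fundus_landmarks(0, 0, sx * distance_um,
                   distance_um * tan(pmp_deg * pi / 180), laterality)
}

#' Generate a circumpapillary boundary trace for one eye
#'
#' Forward model of the unwrapped circle scan: the RPE depth is a one-period
#' sinusoid whose amplitude equals the eye's tilt (px) plus per-A-scan noise;
#' the sclerochoroidal interface lies below it by the eye's angular thickness
#' profile, obtained by periodic cubic interpolation through its 8 sector ppCT
#' values (converted to pixels) anchored at the eye's sector-map angles.
#' Marked RPE points are `n_marked_points` samples of the noisy RPE with
#' additional marking noise.
#'
#' @param eye One-row cohort record (as from [generate_cohort()]) with `pmp`,
#'   `tilt` and `ppct_*` columns.
#' @param tconfig A [trace_config()].
#' @param seed Optional integer seed.
#' @return List with `trace` ([circumpapillary_trace()]), `marked`
#'   ([marked_rpe_points()]) and `sectors` (the eye's `sector_map`).
#' @export
generate_trace <- function(eye, tconfig = trace_config(), seed = NULL) {
  stopifnot(inherits(tconfig, "trace_config"))
  eye <- as.list(eye)
  if (!is.null(seed)) set.seed(seed)
  n <- tconfig$n_ascans
  sectors <- build_sector_map(landmarks_from_pmp(eye$pmp,
                                                 eye$laterality %||% "right"))
  theta <- 2 * pi * (0:(n - 1)) / n
  z_rpe <- tconfig$depth_offset_px +
    eye$tilt * sin(theta - tconfig$rpe_phase) +
    stats::rnorm(n, 0, tconfig$rpe_noise_sd)

  vals <- vapply(sector_names(), function(s) eye[[paste0("ppct_", s)]],
                 numeric(1))
  thick_um <- periodic_profile(as.numeric(sectors), vals,
                               trace_index_to_angle(0:(n - 1), n))
  thick_px <- pmax(thick_um, 0) / tconfig$axial_scale
  trace <- circumpapillary_trace(z_rpe, z_rpe + thick_px,
                                 axial_scale = tconfig$axial_scale)

  # exactly periodic subsampling, so the sampled sinusoid has zero mean and
  # the intercept-free model applies after recentering
  np <- tconfig$n_marked_points
  idx <- floor(n * (0:(np - 1)) / np) + 1
  marked <- marked_rpe_points(
    x = idx - 1,
    y = z_rpe[idx] + stats::rnorm(length(idx), 0, tconfig$marking_noise_sd),
    scan_width_px = n
  )
  list(trace = trace, marked = marked, sectors = sectors)
}

# Periodic cubic interpolation through (anchor_deg, value) pairs, evaluated at
# angles out_deg (all in degrees on the circle).
periodic_profile <- function(anchor_deg, value, out_deg) {
  ord <- order(anchor_deg)
  xa <- anchor_deg[ord]
  ya <- value[ord]
  # shift the evaluation angles into [xa[1], xa[1] + 360)
  xo <- ((out_deg - xa[1]) %% 360) + xa[1]
  sp <- stats::spline(x = c(xa, xa[1] + 360), y = c(ya, ya[1]),
                      method = "periodic", xout = xo)
  sp$y
}
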