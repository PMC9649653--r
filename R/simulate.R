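# Seeded synthetic-data generators emulating the assays each analysis stage
# consumes: progress curves under competitive inhibition with peptide
# depletion, dose-response curves, HDX centroid series / mass envelopes and
# exponential survival cohorts.

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Kinetics simulation scenario
#'
#' Bundles the true kinetic parameters of a simulated TKD preparation.
#' Defaults follow the published parameters of the ΔL747-A750InsP variant
#' (k_cat 1.26 s^-1 per active enzyme, K_M,ATP 23 uM, K_M,pept 15 uM,
#' erlotinib K_I 5.3 nM) at 100 nM nominal TKD with 72% active fraction
#' (2 x 36 nM afatinib IC50 / 100 nM).
#'
#' @param kcat Turnover number per active enzyme (s^-1).
#' @param km_atp_uM,km_pept_uM Michaelis constants (uM).
#' @param ki_nM Named vector of competitive inhibition constants (nM).
#' @param tkd_conc_nM Nominal TKD concentration (nM).
#' @param active_fraction Fraction of enzyme that is catalytically active.
#' @param noise_cv Multiplicative Gaussian noise CV on fluorescence.
#' @param calibration_slope Counts per uM phosphopeptide of the simulated
#'   plate reader.
#' @param seed Integer seed.
#' @return List of class `kinetics_scenario`.
#' @export
kinetics_scenario <- function(kcat = 1.26, km_atp_uM = 23, km_pept_uM = 15,
                              ki_nM = c(erlotinib = 5.3),
                              tkd_conc_nM = 100, active_fraction = 0.72,
                              noise_cv = 0.02, calibration_slope = 100,
                              seed = 1L) {
  stopifnot(kcat > 0, km_atp_uM > 0, km_pept_uM > 0, all(ki_nM > 0),
            tkd_conc_nM > 0, active_fraction > 0, active_fraction <= 1,
            noise_cv >= 0)
  structure(list(kcat = kcat, km_atp_uM = km_atp_uM, km_pept_uM = km_pept_uM,
                 ki_nM = ki_nM, tkd_conc_nM = tkd_conc_nM,
                 active_fraction = active_fraction, noise_cv = noise_cv,
                 calibration_slope = calibration_slope,
                 seed = as.integer(seed)),
            class = "kinetics_scenario")
}

#' Simulate progress curves under competitive inhibition
#'
#' Integrates peptide-substrate depletion under the two-substrate
#' steady-state rate law with ATP-competitive inhibition,
#' dP/dt = k_cat E_act x ATP / (K_M,ATP (1 + I/K_I) + ATP)
#'                    x (S0 - P) / (K_M,pept + S0 - P),
#' by explicit small-step integration (ATP held constant, in large excess
#' over product). Multiplicative Gaussian noise is applied to the
#' fluorescence signal obtained through the scenario's calibration slope.
#'
#' @param scenario A [kinetics_scenario()].
#' @param conditions Data frame with one row per curve: columns `atp_uM`,
#'   `pept_uM`, optional `inhibitor`, `inhibitor_nM` (default none).
#' @param t_end,dt Curve duration and sampling interval (s).
#' @param n_substeps Integration substeps per sampling interval.
#' @return List of curves; each has `time_s`, `product_uM` (noise-free
#'   truth), `counts` (noisy fluorescence), `v0_true` (analytic t = 0
#'   rate, uM/s), `conditions`.
#' @export
gen_progress_curves <- function(scenario, conditions, t_end = 600, dt = 10,
                                n_substeps = 20L) {
  stopifnot(inherits(scenario, "kinetics_scenario"))
  if (!"inhibitor_nM" %in% names(conditions)) conditions$inhibitor_nM <- 0
  if (!"inhibitor" %in% names(conditions)) conditions$inhibitor <- NA_character_
  e_act_uM <- scenario$tkd_conc_nM * scenario$active_fraction / 1000
  .with_seed(scenario$seed, {
    lapply(seq_len(nrow(conditions)), function(i) {
      cd <- conditions[i, ]
      ki <- if (is.na(cd$inhibitor) || cd$inhibitor_nM == 0) Inf else {
        k <- scenario$ki_nM[[cd$inhibitor]]
        if (is.null(k)) stop("no K_I in scenario for inhibitor ", cd$inhibitor)
        k
      }
      atp_term <- cd$atp_uM /
        (scenario$km_atp_uM * (1 + cd$inhibitor_nM / ki) + cd$atp_uM)
      rate <- function(p) {
        s <- max(cd$pept_uM - p, 0)
        scenario$kcat * e_act_uM * atp_term * s / (scenario$km_pept_uM + s)
      }
      times <- seq(0, t_end, by = dt)
      p <- numeric(length(times)); h <- dt / n_substeps
      for (j in seq_along(times)[-1]) {
        x <- p[j - 1]
        for (k in seq_len(n_substeps)) x <- min(x + h * rate(x), cd$pept_uM)
        p[j] <- x
      }
      counts <- p * scenario$calibration_slope
      if (scenario$noise_cv > 0) {
        counts <- counts * (1 + stats::rnorm(length(counts), 0, scenario$noise_cv))
      }
      list(time_s = times, product_uM = p, counts = counts,
           v0_true = rate(0),
           conditions = as.list(cd))
    })
  })
}

#' Simulate a normalised dose-response table
#'
#' Rates follow rate = 100 / (1 + dose/IC50) with multiplicative Gaussian
#' noise; deterministic under the seed.
#'
#' @param ic50_nM True IC50 (nM).
#' @param doses_nM Inhibitor doses (nM).
#' @param noise_cv Noise CV (0 for noiseless).
#' @param seed Integer seed.
#' @return Data frame with columns `inhibitor_nM`, `rate_pct`.
#' @export
gen_dose_response <- function(ic50_nM, doses_nM, noise_cv = 0.04, seed = 1L) {
  stopifnot(ic50_nM > 0, all(doses_nM >= 0))
  .with_seed(seed, {
    rate <- 100 / (1 + doses_nM / ic50_nM)
    if (noise_cv > 0) rate <- rate * (1 + stats::rnorm(length(rate), 0, noise_cv))
    data.frame(inhibitor_nM = doses_nM, rate_pct = rate)
  })
}

#' HDX simulation scenario
#'
#' @param sequence Peptide amino-acid sequence.
#' @param start_res,end_res Residue bounds (precursor numbering).
#' @param charge Charge state.
#' @param m0 Undeuterated peptide mass (Da, MH+ scale for charge 1).
#' @param k_ex Intrinsic per-amide exchange rate (s^-1) in the EX2 limit.
#' @param k_open Opening rate (s^-1) of the EX1 two-state process, or `NULL`
#'   for pure EX2 behaviour.
#' @param envelope_width Gaussian peak width (Da) of the smoothed envelope.
#' @param timepoints Labelling times (s); default 10/60/180/600.
#' @param max_d_fraction Deuterium content of the labelling buffer.
#' @param noise_sd Additive intensity noise SD (fraction of max intensity).
#' @param seed Integer seed.
#' @return List of class `hdx_scenario`.
#' @export
hdx_scenario <- function(sequence, start_res, end_res, charge = 2L,
                         m0 = 1500, k_ex = 0.01, k_open = NULL,
                         envelope_width = 0.8,
                         timepoints = c(10, 60, 180, 600),
                         max_d_fraction = 0.95,
                         noise_sd = 0.01, seed = 1L) {
  stopifnot(k_ex >= 0, is.null(k_open) || k_open >= 0, envelope_width > 0)
  if (nchar(sequence) != end_res - start_res + 1) {
    stop("sequence length must match the residue span")
  }
  structure(list(sequence = sequence, start_res = start_res,
                 end_res = end_res, charge = as.integer(charge), m0 = m0,
                 k_ex = k_ex, k_open = k_open,
                 envelope_width = envelope_width, timepoints = timepoints,
                 max_d_fraction = max_d_fraction, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "hdx_scenario")
}

#' Simulate HDX centroid series and mass envelopes
#'
#' In the EX2 limit each exchangeable amide incorporates deuterium
#' independently with probability (1 - exp(-k_ex t)) x max_d_fraction,
#' giving a binomial isotope comb at 1.00628/charge m/z spacing that is
#' emitted as a Gaussian-smoothed envelope whose centroid drifts upward.
#' With an EX1 opening rate, the envelope is a two-population mixture: a
#' folded (undeuterated-like) component with weight exp(-k_open t) and a
#' fully-shifted unfolded component. Centroids are computed from the
#' emitted envelopes, and the generator truth (regime, folded fractions,
#' noise-free centroids) is recorded.
#'
#' @param scenario An [hdx_scenario()].
#' @return List with `envelopes` (per timepoint: `mz`, `intensity`,
#'   `timepoint`, `charge`), `centroids` (mass-scale centroid per
#'   timepoint, from the noise-free envelope), `m0_mz`, `mf_mz`, `m0`,
#'   `mf` (mass scale), and `truth` (list: `regime`, `folded_fraction` per
#'   timepoint).
#' @export
gen_hdx_series <- function(scenario) {
  stopifnot(inherits(scenario, "hdx_scenario"))
  z <- scenario$charge
  n_am <- exchangeable_amides(scenario$sequence)
  d_mass <- 1.00628
  mf <- scenario$m0 + scenario$max_d_fraction * n_am * d_mass
  mz0 <- scenario$m0 / z
  # m/z grid spanning the full exchange range with margins
  grid <- seq(mz0 - 3 * scenario$envelope_width / z,
              (mf + 3 * scenario$envelope_width) / z,
              length.out = 600L)
  env_for <- function(weights_d) {
    # weights over deuterium counts 0..n_am -> smoothed comb on the grid
    masses <- (scenario$m0 + (0:n_am) * d_mass) / z
    sd_mz <- scenario$envelope_width / z
    rowSums(vapply(seq_along(masses), function(i) {
      weights_d[i] * exp(-(grid - masses[i])^2 / (2 * sd_mz^2))
    }, numeric(length(grid))))
  }
  ex1 <- !is.null(scenario$k_open) && scenario$k_open > 0
  .with_seed(scenario$seed, {
    envelopes <- list(); centroids <- numeric(0); folded <- numeric(0)
    for (t in scenario$timepoints) {
      if (ex1) {
        f <- exp(-scenario$k_open * t)
        w_folded <- stats::dbinom(0:n_am, n_am, 0)      # undeuterated-like
        w_unf <- stats::dbinom(0:n_am, n_am, scenario$max_d_fraction)
        w <- f * w_folded + (1 - f) * w_unf
      } else {
        f <- NA_real_
        p <- (1 - exp(-scenario$k_ex * t)) * scenario$max_d_fraction
        w <- stats::dbinom(0:n_am, n_am, p)
      }
      intens <- env_for(w)
      centroid_mz <- sum(grid * intens) / sum(intens)
      noisy <- intens + stats::rnorm(length(intens), 0,
                                     scenario$noise_sd * max(intens))
      noisy[noisy < 0] <- 0
      envelopes[[length(envelopes) + 1L]] <-
        list(mz = grid, intensity = noisy, timepoint = t, charge = z)
      centroids <- c(centroids, centroid_mz * z)
      folded <- c(folded, f)
    }
    list(envelopes = envelopes,
         centroids = centroids,
         m0 = scenario$m0, mf = mf,
         m0_mz = mz0, mf_mz = mf / z,
         truth = list(regime = if (ex1) "EX1" else "EX2",
                      folded_fraction = folded),
         scenario = scenario)
  })
}

#' Survival cohort simulation scenario
#'
#' Defaults emulate an erlotinib-treated institutional NSCLC cohort:
#' 6 profile 1 and 70 profile 2 patients, median progression-free survival
#' of 2.3 and 8.5 months respectively, 20% censoring, with variant
#' descriptors drawn from the published cohort composition.
#'
#' @param n_profile1,n_profile2 Patients per profile.
#' @param median1_months,median2_months True median PFS per profile.
#' @param censor_fraction Expected fraction of censored records (in
#'   \[0, 1)).
#' @param descriptor_table Data frame `descriptor`/`n`/`profile` giving the
#'   descriptor frequencies (default [cohort_variant_counts()]).
#' @param seed Integer seed.
#' @return List of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_profile1 = 6L, n_profile2 = 70L,
                            median1_months = 2.3, median2_months = 8.5,
                            censor_fraction = 0.2,
                            descriptor_table = cohort_variant_counts("registry"),
                            seed = 1L) {
  stopifnot(n_profile1 >= 1, n_profile2 >= 1,
            median1_months > 0, median2_months > 0,
            censor_fraction >= 0, censor_fraction < 1)
  structure(list(n_profile1 = as.integer(n_profile1),
                 n_profile2 = as.integer(n_profile2),
                 median1_months = median1_months,
                 median2_months = median2_months,
                 censor_fraction = censor_fraction,
                 descriptor_table = descriptor_table,
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

# upper bound b of U(0, b) censoring giving the target censored fraction
# for exponential event times with rate lambda
.censor_bound <- function(lambda, target) {
  f <- function(b) (1 - exp(-lambda * b)) / (lambda * b) - target
  stats::uniroot(f, lower = 1e-8, upper = 1e6 / lambda, tol = 1e-10)$root
}

#' Simulate a profile-stratified survival cohort
#'
#' Event times are exponential with rate ln(2)/median per profile;
#' censoring times are independent uniform with the upper bound chosen so
#' the requested censored fraction holds in expectation. Each record
#' carries a variant descriptor sampled from the scenario's frequency
#' table for its profile, so descriptor classification round-trips to the
#' generating profile.
#'
#' @param scenario A [cohort_scenario()].
#' @return Data frame with columns `id`, `variant_descriptor`, `profile`,
#'   `time_months`, `event`.
#' @export
gen_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  .with_seed(scenario$seed, {
    sim_group <- function(n, med, profile) {
      lambda <- log(2) / med
      t_event <- stats::rexp(n, lambda)
      if (scenario$censor_fraction > 0) {
        b <- .censor_bound(lambda, scenario$censor_fraction)
        t_cens <- stats::runif(n, 0, b)
      } else {
        t_cens <- rep(Inf, n)
      }
      tab <- scenario$descriptor_table
      tab <- tab[tab$profile == profile, , drop = FALSE]
      desc <- if (nrow(tab)) {
        sample(tab$descriptor, n, replace = TRUE, prob = tab$n)
      } else rep(NA_character_, n)
      data.frame(variant_descriptor = desc,
                 profile = profile,
                 time_months = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 stringsAsFactors = FALSE)
    }
    out <- rbind(sim_group(scenario$n_profile1, scenario$median1_months, 1L),
                 sim_group(scenario$n_profile2, scenario$median2_months, 2L))
    out$id <- seq_len(nrow(out))
    out[, c("id", "variant_descriptor", "profile", "time_months", "event")]
  })
}
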