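# Published steady-state parameter summaries and cohort composition tables.
# These are printed summary inputs (means +/- SD over protein preparations),
# used as worked-example inputs and as generator presets.

#' Published steady-state parameters for EGFR TKD variants
#'
#' Summary table of biochemical properties of purified EGFR tyrosine kinase
#' domains: IC50 values (nM, at 1 mM ATP) for erlotinib, afatinib and
#' osimertinib, the erlotinib inhibition constant K_I (nM), Michaelis
#' constants for ATP and peptide substrate (uM), and apparent/corrected
#' turnover numbers (s^-1). Values are means with SDs over independent
#' protein preparations where available.
#'
#' IC50 assays were run at 100 nM TKD for all variants except ΔL747-E749,
#' which required 1 uM TKD; its printed IC50 values have been divided by 10
#' for comparability, recorded here in `ic50_report_divisor` (assay-scale
#' IC50 = printed value x divisor). `tkd_ic50_nM` is the TKD concentration
#' of the IC50 assay, which is also the concentration at which the
#' active-site correction of the apparent k_cat applies (see
#' [correct_kcat()]). The osimertinib IC50 for ΔL747-E749 is a lower bound
#' (`osi_censored`).
#'
#' @return Data frame with one row per variant, columns
#'   `variant`, `group` ("wild type", "profile 1", "profile 2", "other"),
#'   `ic50_erl_nM`, `ic50_erl_sd`, `ic50_afa_nM`, `ic50_afa_sd`,
#'   `ic50_osi_nM`, `ic50_osi_sd`, `osi_censored`, `ki_erl_nM`, `ki_erl_sd`,
#'   `km_atp_uM`, `km_atp_sd`, `km_pept_uM`, `kcat_app`, `kcat_corr`,
#'   `tkd_ic50_nM`, `ic50_report_divisor`.
#' @export
egfr_kinetic_table <- function() {
  tbl <- data.frame(
    variant = c("WT", "ΔL747-A750InsP", "L747P", "ΔL747-E749",
                "ΔE746-A750", "ΔE746-T751InsA", "ΔL747-T751InsP",
                "ΔL747-P753InsS", "ΔS752-I759", "L858R", "L858R/T790M"),
    group = c("wild type", "profile 1", "profile 1", "profile 1",
              "profile 2", "profile 2", "profile 2", "profile 2",
              "profile 2", "other", "other"),
    ic50_erl_nM = c(NA, 232, 141, 108, 31, 20, 14, 37, 25, 75, 10000),
    ic50_erl_sd = c(NA, 48, 17, 17, 8, 3, 5, 10, 5, 12, NA),
    ic50_afa_nM = c(NA, 36, 37, 42, 27, 8, 6, 23, 20, 23, 92),
    ic50_afa_sd = c(NA, 15, 4, 4, 9, 1, 2, 3, 7, 2, 23),
    ic50_osi_nM = c(NA, 65, 159, 1000, 37, 11, 7, 26, 22, 52, 101),
    ic50_osi_sd = c(NA, 21, 89, NA, 17, 2, 2, 16, 7, 2, 24),
    osi_censored = c(NA, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE),
    ki_erl_nM = c(NA, 5.3, 6.2, NA, NA, NA, NA, 4.2, NA, 4.7, 41),
    ki_erl_sd = c(NA, 1.5, 4.0, NA, NA, NA, NA, 1.7, NA, 2.3, 14),
    km_atp_uM = c(12, 23, 21, 13, 158, 240, 164, 101, 91, 74, 45),
    km_atp_sd = c(3, 6, 6, 8, 24, 59, 48, 22, 25, 14, 6),
    km_pept_uM = c(406, 15, 52, NA, 261, 156, 38, 292, 80, 218, 99),
    kcat_app = c(0.042, 0.91, 0.84, 0.044, 0.60, 0.12, 0.16, 0.49,
                 1.2, 1.4, 6.6),
    kcat_corr = c(0.042, 1.26, 1.14, 0.052, 1.11, 0.75, 1.33, 1.07,
                  3.0, 3.04, NA),
    tkd_ic50_nM = c(NA, 100, 100, 1000, 100, 100, 100, 100, 100, 100, 100),
    ic50_report_divisor = c(NA, 1, 1, 10, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  tbl
}

#' Exon 19 variant composition of published erlotinib-treated cohorts
#'
#' Patient counts per variant descriptor for two erlotinib-treated NSCLC
#' cohorts (a public consortium registry and a single-institution cohort),
#' used as the default descriptor frequency tables of the survival-cohort
#' simulator.
#'
#' @param cohort `"registry"` (n = 5 profile 1, 62 profile 2) or
#'   `"institutional"` (n = 6 profile 1, 70 profile 2).
#' @return Data frame with columns `descriptor`, `n`, `profile`.
#' @export
cohort_variant_counts <- function(cohort = c("registry", "institutional")) {
  cohort <- match.arg(cohort)
  if (cohort == "registry") {
    tbl <- data.frame(
      descriptor = c("ΔL747-A750InsP", "ΔE746-L747InsIP",
                     "ΔE746-A750", "ΔL747-P753InsS", "ΔL747-T751",
                     "ΔE746-S752InsV", "ΔS752-I759", "ΔL747-S752",
                     "ΔE746-S752InsI", "ΔE746-T751InsA", "ΔL747-T751InsP",
                     "ΔE746-T751InsIP"),
      n = c(4L, 1L, 43L, 5L, 3L, 3L, 2L, 2L, 1L, 1L, 1L, 1L),
      profile = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
      stringsAsFactors = FALSE
    )
  } else {
    tbl <- data.frame(
      descriptor = c("ΔL747-A750InsP",
                     "ΔE746-A750", "ΔL747-P753InsS", "ΔL747-T751",
                     "ΔL747-T751InsP", "ΔE746-S752InsV", "ΔL747-T751InsA",
                     "ΔL747-S752", "ΔE746-T751InsVP", "ΔT751-I759InsN"),
      n = c(6L, 55L, 5L, 3L, 2L, 1L, 1L, 1L, 1L, 1L),
      profile = c(1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
      stringsAsFactors = FALSE
    )
  }
  tbl
}
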