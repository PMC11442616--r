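#' Synthetic cohort specification
#'
#' Describes a simulated patient/control cohort with the statistical
#' structure of the brain-tumor study: paired ipsi/contralateral ALPS
#' indices with positive within-subject correlation, healthy-control
#' right/left indices, uniform ages and a fixed sex ratio. Defaults are the
#' study's group parameters (ipsi 1.26 +/- 0.24, contra 1.43 +/- 0.28,
#' n = 24 patients; HC 1.27 +/- 0.22, n = 12; ages 24-73; 14/24 male).
#'
#' @param n_patients,n_controls cohort sizes (>= 1)
#' @param ipsi_mean,contra_mean,hc_mean group means of the ALPS index
#' @param ipsi_sd,contra_sd,hc_sd group standard deviations (>= 0)
#' @param pair_correlation within-subject correlation of the two
#'   hemisphere indices (default 0.8; paired designs with near-zero
#'   correlation would understate the study's paired-test power)
#' @param age_range integer years, uniform
#' @param male_fraction probability of male sex
#' @param seed integer; the whole table is reproducible under it
#' @return a `cohort_sim_spec`
#' @export
cohort_sim_spec <- function(n_patients = 24, n_controls = 12,
                            ipsi_mean = 1.26, contra_mean = 1.43,
                            hc_mean = 1.27,
                            ipsi_sd = 0.24, contra_sd = 0.28, hc_sd = 0.22,
                            pair_correlation = 0.8,
                            age_range = c(24, 73), male_fraction = 14 / 24,
                            seed = 1L) {
  if (n_patients < 1 || n_controls < 0) abort("cohort sizes must be >= 1 patient.")
  if (any(c(ipsi_sd, contra_sd, hc_sd) < 0)) abort("sds must be >= 0.")
  if (abs(pair_correlation) > 1) abort("`pair_correlation` must lie in [-1, 1].")
  structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls),
         ipsi_mean = ipsi_mean, contra_mean = contra_mean, hc_mean = hc_mean,
         ipsi_sd = ipsi_sd, contra_sd = contra_sd, hc_sd = hc_sd,
         pair_correlation = pair_correlation,
         age_range = age_range, male_fraction = male_fraction,
         seed = as.integer(seed)),
    class = "cohort_sim_spec"
  )
}

#' Generate a synthetic cohort table
#'
#' Draws paired hemisphere indices from a bivariate normal with the
#' configured means/sds and correlation, ages uniform over the range, sexes
#' Bernoulli by ratio, and plausible tumor attributes (17/24 primary rate,
#' tumor ADC ~ N(1618, 665) truncated at 50). Output mirrors the packaged
#' fixture schema so the study driver runs on it unchanged.
#'
#' @param spec a [cohort_sim_spec()]
#' @return list of two tibbles, `patients` and `controls`
#' @export
generate_cohort_table <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_patients
    z1 <- rnorm(n)
    z2 <- spec$pair_correlation * z1 +
      sqrt(1 - spec$pair_correlation^2) * rnorm(n)
    adc <- pmax(50, rnorm(n, 1618, 665))
    patients <- tibble(
      id = seq_len(n),
      age = sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE),
      sex = ifelse(runif(n) < spec$male_fraction, "male", "female"),
      alps_ipsi = spec$ipsi_mean + spec$ipsi_sd * z1,
      alps_contra = spec$contra_mean + spec$contra_sd * z2,
      tumor_adc = adc,
      event = sample(c("first_diagnosis", "local_recurrence",
                       "distance_recurrence"), n, replace = TRUE),
      tumor_type = ifelse(runif(n) < 17 / 24, "primary", "metastasis"),
      details = "synthetic",
      tumor_location = "synthetic",
      tumor_side = sample(c("left", "right"), n, replace = TRUE,
                          prob = c(0.8, 0.2)),
      ptbe = ifelse(runif(n) < 19 / 24, "yes", "no"),
      roi_in_ptbe = runif(n) < 5 / 24,
      included = TRUE
    )
    m <- spec$n_controls
    controls <- if (m > 0) {
      w1 <- rnorm(m)
      w2 <- spec$pair_correlation * w1 +
        sqrt(1 - spec$pair_correlation^2) * rnorm(m)
      tibble(
        id = seq_len(m),
        sex = ifelse(runif(m) < spec$male_fraction, "male", "female"),
        age = sample(seq(spec$age_range[1], spec$age_range[2]), m,
                     replace = TRUE),
        alps_right = spec$hc_mean + spec$hc_sd * w1,
        alps_left = spec$hc_mean + spec$hc_sd * w2,
        matched_patients = NA_character_
      )
    } else {
      tibble(id = integer(), sex = character(), age = numeric(),
             alps_right = numeric(), alps_left = numeric(),
             matched_patients = character())
    }
    list(patients = patients, controls = controls)
  })
}
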