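#' Specification for a synthetic stroke cohort
#'
#' The generator realises the third-variable mechanism thought to underlie
#' the negative association between reaching extent and the StartReact
#' effect: a single latent "damage" severity u ~ U(0, 1) per subject
#' (notionally, corticospinal damage) maps linearly into every measure plus
#' independent Gaussian noise. IoEE decreases with damage while StartReact
#' increases, so their population rank correlation is negative by
#' construction; the default noise SDs are calibrated so that population
#' Spearman rho(IoEE, StartReact) is approximately -0.70, the strength of
#' association the measure battery is designed around.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param ioee_intercept,ioee_slope IoEE at u = 0 and its change per unit
#'   damage (slope < 0 for impairment); generated IoEE is clipped to
#'   \[0, 1\].
#' @param startreact_intercept,startreact_slope StartReact (ms) at u = 0 and
#'   per unit damage (slope > 0 for compensatory recruitment).
#' @param ioee_sd,startreact_sd,rt_sd,mas_sd,grip_sd Noise SDs (all >= 0) for
#'   IoEE (dimensionless), StartReact (ms), the per-condition reaction-time
#'   means (ms), the spasticity score (ordinal units) and grip strength (kg).
#' @param arat_sd Noise SD for ARAT subscores, in points, applied per
#'   subscale proportionally to the subscale maximum.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_subjects = 15,
                        ioee_intercept = 0.88, ioee_slope = -0.45,
                        startreact_intercept = 15, startreact_slope = 75,
                        ioee_sd = 0.06, startreact_sd = 18.8,
                        rt_sd = 20, arat_sd = 1.5, mas_sd = 0.7,
                        grip_sd = 2, seed = 1L) {
  if (n_subjects < 3) {
    stop_reach("n_subjects must be >= 3.", "reachstart_error_invalid_spec")
  }
  for (nm in c("ioee_sd", "startreact_sd", "rt_sd", "arat_sd", "mas_sd",
               "grip_sd")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < 0) {
      stop_reach(sprintf("`%s` must be a single non-negative number.", nm),
                 "reachstart_error_invalid_spec")
    }
  }
  check_number(c(ioee_intercept, ioee_slope, startreact_intercept,
                 startreact_slope), "mapping coefficients",
               class = "reachstart_error_invalid_spec")
  structure(
    list(n_subjects = as.integer(n_subjects),
         ioee_intercept = ioee_intercept, ioee_slope = ioee_slope,
         startreact_intercept = startreact_intercept,
         startreact_slope = startreact_slope,
         ioee_sd = ioee_sd, startreact_sd = startreact_sd, rt_sd = rt_sd,
         arat_sd = arat_sd, mas_sd = mas_sd, grip_sd = grip_sd,
         seed = seed),
    class = "cohort_spec"
  )
}

arat_maxima <- c(grasp = 18, grip = 12, pinch = 18, gross = 9)

#' Simulate a cohort table with known latent ground truth
#'
#' One row per subject, linking the kinematic measure (IoEE), the
#' reaction-time measures (VRT/VART/VSRT means and the StartReact effect)
#' and the clinical scores (ARAT total and four subscores, spasticity MAS,
#' grip strengths) — the table a correlation battery runs on. All measures
#' derive from one latent damage severity per subject (see [cohort_spec()]);
#' the latent value is kept in column `latent_damage` so recovery of the
#' built-in associations can be checked against ground truth.
#'
#' Structural invariants hold by construction: `arat_total` is the sum of
#' the four subscores, each within its published maximum (18/12/18/9);
#' `startreact = vart_mean - vsrt_mean` exactly; IoEE lies in \[0, 1\].
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer overriding `spec$seed`.
#' @return A tibble of class `cohort_table`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 15, seed = 7))
#' correlation_table(coh)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!inherits(spec, "cohort_spec")) {
    stop_reach("`spec` must be a cohort_spec().",
               "reachstart_error_invalid_spec")
  }
  seed <- seed %||% spec$seed
  n <- spec$n_subjects
  with_seed_or_not(seed, {
    u <- runif(n)
    ioee <- clip(spec$ioee_intercept + spec$ioee_slope * u +
                   rnorm(n, 0, spec$ioee_sd), 0, 1)
    startreact <- spec$startreact_intercept + spec$startreact_slope * u +
      rnorm(n, 0, spec$startreact_sd)
    vsrt <- 190 + 70 * u + rnorm(n, 0, spec$rt_sd)
    vart <- vsrt + startreact
    vrt <- vart + 50 + abs(rnorm(n, 0, spec$rt_sd))

    ability <- 1 - u
    sub <- purrr::imap(arat_maxima, function(mx, nm) {
      raw <- mx * ability + rnorm(n, 0, spec$arat_sd * mx / 18)
      as.integer(clip(round(raw), 0, mx))
    })
    mas <- as.integer(clip(round(4 * u + rnorm(n, 0, spec$mas_sd)), 0, 4))
    grip_less <- clip(rnorm(n, 26.5, 8.8), 5, Inf)
    grip_aff <- grip_less * clip(0.85 * ability + rnorm(n, 0,
                                                        spec$grip_sd / 26.5),
                                 0, 1)
    structure(
      tibble(
        subject_id = sprintf("S%02d", seq_len(n)),
        latent_damage = u,
        ioee = ioee,
        vrt_mean = vrt, vart_mean = vart, vsrt_mean = vsrt,
        startreact = startreact,
        arat_grasp = sub$grasp, arat_grip = sub$grip,
        arat_pinch = sub$pinch, arat_gross = sub$gross,
        arat_total = sub$grasp + sub$grip + sub$pinch + sub$gross,
        mas = mas,
        grip_affected = grip_aff, grip_less_affected = grip_less,
        grip_normalized = normalized_grip(grip_aff, grip_less)
      ),
      class = c("cohort_table", class(tibble()))
    )
  })
}
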