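## Synthetic cohort tables: one row per patient with clinical covariates and
## perfusion parameters drawn with known multiplicative group effects, so the
## univariate statistical machinery can be validated against configured
## truth.

#' Configuration for a simulated patient cohort
#'
#' Perfusion parameters are drawn lognormally around cohort-scale centers
#' (whole-flap ingress 127 APU, whole-flap ingress rate 9.4 APU/s, zone-I
#' ingress 65 APU, zone-I ingress rate 3.4 APU/s) with log-scale spreads
#' matched to typical clinical interquartile ranges, then multiplied by the
#' configured covariate effects. A shared patient-level factor (\code{rho})
#' correlates the four parameters within a patient.
#'
#' @param n number of patients (>= 2); default 40.
#' @param prevalences named list of covariate prevalences in [0, 1]
#'   (\code{overweight}, \code{hypertension}, \code{dyslipidemia},
#'   \code{diabetes}, \code{former_smoker}, \code{radiotherapy},
#'   \code{chemotherapy}) plus \code{hormone_therapy}, a probability vector
#'   over \code{none} / \code{tamoxifen} / \code{aromatase_inhibitor}.
#' @param effects named list: for each covariate, a named numeric vector of
#'   multiplicative effects (> 0) on any of the outcome columns
#'   \code{ingress_whole_apu}, \code{ingress_rate_whole_apu_s},
#'   \code{ingress_zone1_apu}, \code{ingress_rate_zone1_apu_s}. Covariate
#'   names may be any binary column of the table plus the derived flags
#'   \code{tamoxifen} and \code{age_over_60}. Defaults encode impaired
#'   perfusion under diabetes and tamoxifen and better zone-I perfusion over
#'   age 60, with magnitudes on the scale seen in clinical series.
#' @param centers named numeric vector of lognormal medians for the four
#'   outcome columns (APU / APU/s).
#' @param sdlog named numeric vector of lognormal log-scale sds.
#' @param rho within-patient correlation of the log outcomes, in [0, 1).
#' @param ageMean,ageSd mean and sd of the (truncated, rounded) age draw.
#' @param patternProbs probability vector over pattern labels 1..3.
#' @param seed integer seed; same config + seed reproduces the table exactly.
#' @return A list of class \code{CohortEffectConfig}.
#' @export
cohortEffectConfig <- function(n = 40L,
        prevalences = list(overweight = 0.525, hypertension = 0.15,
                           dyslipidemia = 0.10, diabetes = 0.05,
                           former_smoker = 0.125,
                           radiotherapy = 0.675, chemotherapy = 0.675,
                           hormone_therapy = c(none = 0.40,
                                               tamoxifen = 0.475,
                                               aromatase_inhibitor = 0.125)),
        effects = list(
            diabetes = c(ingress_whole_apu = 0.34,
                         ingress_rate_whole_apu_s = 0.20,
                         ingress_zone1_apu = 0.43,
                         ingress_rate_zone1_apu_s = 0.71),
            tamoxifen = c(ingress_whole_apu = 0.81,
                          ingress_rate_whole_apu_s = 0.77,
                          ingress_zone1_apu = 0.73,
                          ingress_rate_zone1_apu_s = 0.42),
            age_over_60 = c(ingress_whole_apu = 1.42,
                            ingress_rate_whole_apu_s = 1.77,
                            ingress_zone1_apu = 1.89,
                            ingress_rate_zone1_apu_s = 3.66)),
        centers = c(ingress_whole_apu = 127,
                    ingress_rate_whole_apu_s = 9.4,
                    ingress_zone1_apu = 65,
                    ingress_rate_zone1_apu_s = 3.4),
        sdlog = c(ingress_whole_apu = 0.49,
                  ingress_rate_whole_apu_s = 0.83,
                  ingress_zone1_apu = 0.73,
                  ingress_rate_zone1_apu_s = 0.98),
        rho = 0.6, ageMean = 51, ageSd = 9.5,
        patternProbs = c(14, 16, 10) / 40, seed = NULL) {
    if (n < 2L)
        stop("'n' must be at least 2")
    binPrev <- unlist(prevalences[setdiff(names(prevalences),
                                          "hormone_therapy")])
    if (any(binPrev < 0 | binPrev > 1))
        stop("prevalences must lie in [0, 1]")
    ht <- prevalences$hormone_therapy
    if (is.null(ht) || abs(sum(ht) - 1) > 1e-6 || any(ht < 0))
        stop("'hormone_therapy' prevalences must be a probability vector")
    for (ef in effects)
        if (any(ef <= 0))
            stop("covariate effects must be positive multipliers")
    if (rho < 0 || rho >= 1)
        stop("'rho' must lie in [0, 1)")
    structure(list(n = as.integer(n), prevalences = prevalences,
                   effects = effects, centers = centers, sdlog = sdlog,
                   rho = rho, ageMean = ageMean, ageSd = ageSd,
                   patternProbs = patternProbs, seed = seed),
              class = "CohortEffectConfig")
}

#' Simulate a per-patient cohort table
#'
#' @param config a [cohortEffectConfig()].
#' @return A data frame with one row per patient: \code{patient_id},
#'   \code{age_years}, \code{age_over_60}, \code{bmi}, binary clinical flags,
#'   \code{hormone_therapy} (none / tamoxifen / aromatase_inhibitor),
#'   \code{tamoxifen}, \code{radiotherapy}, \code{chemotherapy},
#'   \code{pattern} and the four perfusion columns
#'   \code{ingress_whole_apu}, \code{ingress_rate_whole_apu_s},
#'   \code{ingress_zone1_apu}, \code{ingress_rate_zone1_apu_s}.
#' @examples
#' tab <- simulateCohort(cohortEffectConfig(n = 10, seed = 1))
#' dim(tab)
#' @export
simulateCohort <- function(config = cohortEffectConfig()) {
    stopifnot(inherits(config, "CohortEffectConfig"))
    withSeed(config$seed, {
        n <- config$n
        pv <- config$prevalences
        age <- round(pmin(pmax(stats::rnorm(n, config$ageMean, config$ageSd),
                               30), 75))
        bmi <- round(pmin(pmax(stats::rnorm(n, 25.5, 3.2), 17), 38), 1)
        tab <- data.frame(
            patient_id = seq_len(n),
            age_years = age,
            age_over_60 = age > 60,
            bmi = bmi,
            overweight = stats::runif(n) < pv$overweight,
            hypertension = stats::runif(n) < pv$hypertension,
            dyslipidemia = stats::runif(n) < pv$dyslipidemia,
            diabetes = stats::runif(n) < pv$diabetes,
            former_smoker = stats::runif(n) < pv$former_smoker,
            hormone_therapy = sample(names(pv$hormone_therapy), n,
                                     replace = TRUE,
                                     prob = pv$hormone_therapy),
            radiotherapy = stats::runif(n) < pv$radiotherapy,
            chemotherapy = stats::runif(n) < pv$chemotherapy,
            pattern = sample(1:3, n, replace = TRUE,
                             prob = config$patternProbs),
            stringsAsFactors = FALSE)
        tab$tamoxifen <- tab$hormone_therapy == "tamoxifen"

        shared <- stats::rnorm(n)
        rho <- config$rho
        for (outcome in names(config$centers)) {
            z <- rho * shared + sqrt(1 - rho^2) * stats::rnorm(n)
            logval <- log(config$centers[[outcome]]) +
                config$sdlog[[outcome]] * z
            for (cov in names(config$effects)) {
                ef <- config$effects[[cov]]
                if (!outcome %in% names(ef))
                    next
                if (!cov %in% names(tab))
                    stop("effect refers to unknown covariate: ", cov)
                logval <- logval + log(ef[[outcome]]) * as.numeric(tab[[cov]])
            }
            tab[[outcome]] <- exp(logval)
        }
        tab
    })
}
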