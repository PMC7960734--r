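#' Covariate names used for demographics and medication intake
#'
#' Two demographic indicators (marital and employment status) and eight
#' prescribed-medication indicators (last 30 days): sleep, anxiety,
#' headaches, birth control, depression, energy, steroids, other.
#'
#' @return Character vector of 10 covariate names.
#' @export
covariate_names <- function() {
  c("married", "employed",
    paste0("med_", c("sleep", "anxiety", "headaches", "birth_control",
                     "depression", "energy", "steroids", "other")))
}

#' Simulate demographic and medication covariates
#'
#' Draws each binary covariate conditionally on the outcome label: the
#' continued-AUD group uses the base rate and the remitted group the rate
#' implied by the covariate's log-odds of remission, so the expected
#' odds ratio between groups equals `exp(log_odds)` exactly. Ages at the
#' baseline visit come from one shared truncated normal for both groups
#' (default mean 30.7, sd 9.4, truncated at 18), so groups are age-comparable
#' by construction. Sex and self-reported ancestry are drawn independently of
#' the label.
#'
#' @param subjects Tibble with `subject_id` and `label`.
#' @param covariate_effects Named numeric vector/list mapping covariate names
#'   (see [covariate_names()]) to log-odds of remission; unnamed covariates
#'   get 0 (no effect).
#' @param seed Integer seed.
#' @param base_rates Named base rates (continued group) per covariate;
#'   defaults: married 0.5, employed 0.6, each medication 0.15.
#' @param age_mean,age_sd,age_min Age distribution parameters (years).
#' @param p_male,p_ea Marginal probabilities of male sex and European
#'   (vs African) self-reported ancestry.
#' @return Tibble of subject records: `subject_id`, `label`, `sex`,
#'   `ancestry`, `age`, and one 0/1 column per covariate.
#' @export
simulate_demographics <- function(subjects, covariate_effects = NULL, seed = 1,
                                  base_rates = NULL,
                                  age_mean = 30.7, age_sd = 9.4, age_min = 18,
                                  p_male = 0.6, p_ea = 0.65) {
  covs <- covariate_names()
  eff <- setNames(rep(0, length(covs)), covs)
  if (!is.null(covariate_effects)) {
    covariate_effects <- unlist(covariate_effects)
    unknown <- setdiff(names(covariate_effects), covs)
    assert_that(length(unknown) == 0,
                paste("unknown covariate(s):", paste(unknown, collapse = ", ")))
    eff[names(covariate_effects)] <- covariate_effects
  }
  rates <- setNames(c(0.5, 0.6, rep(0.15, 8)), covs)
  if (!is.null(base_rates)) rates[names(base_rates)] <- unlist(base_rates)
  p_rem <- plogis(qlogis(rates) + eff)
  assert_that(all(p_rem > 0 & p_rem < 1) && all(rates > 0 & rates < 1),
              "implied covariate probabilities must lie in (0, 1)")

  n <- nrow(subjects)
  is_rem <- subjects$label == "remitted"
  with_seed(substream_seed(seed, "demographics"), {
    out <- tibble::tibble(subject_id = subjects$subject_id,
                          label = subjects$label,
                          sex = sample(c("male", "female"), n, TRUE,
                                       prob = c(p_male, 1 - p_male)),
                          ancestry = sample(c("EA", "AA"), n, TRUE,
                                            prob = c(p_ea, 1 - p_ea)),
                          age = rtruncnorm(n, age_mean, age_sd, age_min))
    for (cv in covs) {
      p <- ifelse(is_rem, p_rem[cv], rates[cv])
      out[[cv]] <- rbinom(n, 1L, p)
    }
    out
  })
}

# Normal truncated below at `lo`, by resampling (fast at mild truncation).
rtruncnorm <- function(n, mean, sd, lo) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}
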