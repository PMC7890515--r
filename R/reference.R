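#' Published reference estimates for the snake identification challenge
#'
#' Posterior medians reported by the original hierarchical graded-response
#' analysis of a week-long global online snake identification challenge
#' (250 analysed participants, roughly 1000 photos of 100 core species in 9
#' families and 6 global regions). Useful as plug-in values for predicted
#' probabilities, as generator defaults, and as a scale reference for
#' simulated cohorts. Reference levels: family Boidae, region Africa.
#'
#' @return List with components `tau` (3 ordered thresholds),
#'   `discrimination` (log-scale intercept), `beta` (named fixed-effect
#'   medians: 8 families, 5 regions, home region, taxa repeat, 5 region-home
#'   interactions) and `sd` (named group-level standard deviations and
#'   correlations; participant ability sd is fixed at 1).
#' @examples
#' ref <- reference_grm_estimates()
#' # species-level probability for the first photo of a North American
#' # colubrid seen by an average participant from elsewhere:
#' eta <- ref$beta[["Colubridae"]] + ref$beta[["NorthAmerica"]]
#' category_probs(eta, exp(ref$discrimination), ref$tau)[, "3"]
#' @export
reference_grm_estimates <- function() {
  list(
    tau = c(-2.36, -1.17, -0.53),
    discrimination = 0.15,
    beta = c(
      Colubridae = -1.97, Cylindrophiidae = -2.80, Elapidae = -1.25,
      Lamprophiidae = -2.46, Leptotyphlopidae = -1.58, Pythonidae = -0.15,
      Typhlopidae = -0.81, Viperidae = -1.09,
      Asia = -0.09, Australasia = -0.26, Europe = -0.04,
      NorthAmerica = -0.00, SouthAmerica = 0.30,
      `home_region = T` = 3.14, taxa_repeat = 0.08,
      `Asia: home_region = T` = -2.17,
      `Australasia: home_region = T` = -0.51,
      `Europe: home_region = T` = -2.32,
      `NorthAmerica: home_region = T` = -1.73,
      `SouthAmerica: home_region = T` = -1.63),
    sd = c(participant = 1.00,
           photo_difficulty = 0.65, photo_discrimination = 0.21,
           cor_photo = 0.70,
           species_difficulty = 0.62, species_discrimination = 0.31,
           cor_species = 0.34)
  )
}
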