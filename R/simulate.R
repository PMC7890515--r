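#' Configuration for a simulated identification challenge
#'
#' Defaults reproduce the structure and the estimated latent scale of a large
#' global online snake-identification challenge: 250 participants, 100
#' photographed species in 9 families and 6 global regions with 10 photos
#' each, ordered thresholds (-2.36, -1.17, -0.53), a strong home-region
#' advantage (3.14 on the logit scale) with negative region interactions, a
#' small within-challenge learning effect per prior exposure (0.08),
#' log-scale discrimination intercept 0.15, correlated photo and species
#' difficulty/discrimination pairs, and participant ability standard
#' deviation fixed at 1.
#'
#' @param n_participants,n_species,photos_per_species Challenge size.
#' @param photos_per_participant Photos each participant answers (a random
#'   subset; capped at the number of photos).
#' @param families Named integer vector allocating species to families; the
#'   first name is the reference family. Must sum to `n_species`.
#' @param regions Named integer vector allocating species to regions; the
#'   first name is the reference region. Must sum to `n_species`.
#' @param home_region_dist Named probabilities for participants' home
#'   regions.
#' @param tau Strictly increasing threshold 3-vector.
#' @param beta_family Named effects for non-reference families.
#' @param beta_region Named effects for non-reference regions.
#' @param beta_home Home-region main effect.
#' @param beta_home_x_region Named home-by-region interaction effects for
#'   non-reference regions.
#' @param beta_repeat Effect per prior photo of the same species.
#' @param beta_quality Effect of a low-quality photo (0 by default: photo
#'   quality had no support in the top model).
#' @param delta0 Discrimination intercept on the log scale.
#' @param sd_photo_b,sd_photo_d,rho_photo Photo difficulty/discrimination
#'   standard deviations and their correlation.
#' @param sd_species_b,sd_species_d,rho_species Species-level counterparts.
#' @param sd_participant Participant ability standard deviation (the model
#'   fixes this scale at 1).
#' @param prop_low_quality Fraction of photos per species rated low quality.
#' @param quality_order `"random"` (default) or `"high_first"`, the schedule
#'   in which a participant encounters photo qualities.
#' @param skip_prob Among incorrect (score 0) answers, the probability the
#'   emitted free-text answer is a skip rather than an extra-familial
#'   species. Only affects [attach_answer_strings()]; the ordinal scale pools
#'   skips with wrong answers.
#' @param n_distractors Single-photo distractor species shown but excluded
#'   from analysis; only enters [max_identifications()].
#' @param seed Root seed for [simulate_challenge()]; every draw flows from
#'   this one generator.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 250,
                       n_species = 100,
                       photos_per_species = 10,
                       photos_per_participant = 400,
                       families = c(Boidae = 5, Colubridae = 40,
                                    Cylindrophiidae = 2, Elapidae = 15,
                                    Lamprophiidae = 8, Leptotyphlopidae = 2,
                                    Pythonidae = 5, Typhlopidae = 3,
                                    Viperidae = 20),
                       regions = c(Africa = 17, Asia = 17, Australasia = 16,
                                   Europe = 16, NorthAmerica = 17,
                                   SouthAmerica = 17),
                       home_region_dist = c(Africa = 0.10, Asia = 0.10,
                                            Australasia = 0.04,
                                            Europe = 0.22,
                                            NorthAmerica = 0.50,
                                            SouthAmerica = 0.04),
                       tau = c(-2.36, -1.17, -0.53),
                       beta_family = c(Colubridae = -1.97,
                                       Cylindrophiidae = -2.80,
                                       Elapidae = -1.25,
                                       Lamprophiidae = -2.46,
                                       Leptotyphlopidae = -1.58,
                                       Pythonidae = -0.15,
                                       Typhlopidae = -0.81,
                                       Viperidae = -1.09),
                       beta_region = c(Asia = -0.09, Australasia = -0.26,
                                       Europe = -0.04, NorthAmerica = 0.00,
                                       SouthAmerica = 0.30),
                       beta_home = 3.14,
                       beta_home_x_region = c(Asia = -2.17,
                                              Australasia = -0.51,
                                              Europe = -2.32,
                                              NorthAmerica = -1.73,
                                              SouthAmerica = -1.63),
                       beta_repeat = 0.08,
                       beta_quality = 0,
                       delta0 = 0.15,
                       sd_photo_b = 0.65, sd_photo_d = 0.21, rho_photo = 0.70,
                       sd_species_b = 0.62, sd_species_d = 0.31,
                       rho_species = 0.34,
                       sd_participant = 1,
                       prop_low_quality = 0.5,
                       quality_order = c("random", "high_first"),
                       skip_prob = 0.3,
                       n_distractors = 100,
                       seed = NULL) {
  cfg <- list(n_participants = n_participants, n_species = n_species,
              photos_per_species = photos_per_species,
              photos_per_participant = photos_per_participant,
              families = families, regions = regions,
              home_region_dist = home_region_dist, tau = tau,
              beta_family = beta_family, beta_region = beta_region,
              beta_home = beta_home, beta_home_x_region = beta_home_x_region,
              beta_repeat = beta_repeat, beta_quality = beta_quality,
              delta0 = delta0,
              sd_photo_b = sd_photo_b, sd_photo_d = sd_photo_d,
              rho_photo = rho_photo,
              sd_species_b = sd_species_b, sd_species_d = sd_species_d,
              rho_species = rho_species,
              sd_participant = sd_participant,
              prop_low_quality = prop_low_quality,
              quality_order = match.arg(quality_order),
              skip_prob = skip_prob, n_distractors = n_distractors,
              seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) stop("invalid sim_config field '", field, "': ", why)
  for (f in c("n_participants", "n_species", "photos_per_species",
              "photos_per_participant", "n_distractors")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      fail(f, "must be a single non-negative integer")
  }
  if (cfg$n_participants < 1) fail("n_participants", "must be positive")
  if (length(cfg$tau) != 3 || any(diff(cfg$tau) <= 0))
    fail("tau", "must be 3 strictly increasing thresholds")
  if (sum(cfg$families) != cfg$n_species)
    fail("families", "allocation must sum to n_species")
  if (sum(cfg$regions) != cfg$n_species)
    fail("regions", "allocation must sum to n_species")
  bad <- setdiff(names(cfg$regions), snake_regions())
  if (length(bad)) fail("regions", paste("unknown region", bad[1]))
  if (!setequal(names(cfg$beta_family), names(cfg$families)[-1]))
    fail("beta_family", "names must be the non-reference families")
  if (!setequal(names(cfg$beta_region), names(cfg$regions)[-1]))
    fail("beta_region", "names must be the non-reference regions")
  if (!setequal(names(cfg$beta_home_x_region), names(cfg$regions)[-1]))
    fail("beta_home_x_region", "names must be the non-reference regions")
  if (abs(sum(cfg$home_region_dist) - 1) > 1e-8)
    fail("home_region_dist", "probabilities must sum to 1")
  if (length(bad <- setdiff(names(cfg$home_region_dist), snake_regions())))
    fail("home_region_dist", paste("unknown region", bad[1]))
  for (f in c("sd_photo_b", "sd_photo_d", "sd_species_b", "sd_species_d",
              "sd_participant"))
    if (cfg[[f]] < 0) fail(f, "standard deviation must be >= 0")
  for (f in c("rho_photo", "rho_species"))
    if (abs(cfg[[f]]) > 1) fail(f, "correlation must be in [-1, 1]")
  if (cfg$prop_low_quality < 0 || cfg$prop_low_quality > 1)
    fail("prop_low_quality", "must be in [0, 1]")
  if (cfg$skip_prob < 0 || cfg$skip_prob > 1)
    fail("skip_prob", "must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Maximum identifications a participant could submit
#'
#' Photographed species times photos per species, plus one photo for each
#' single-photo distractor species.
#'
#' @param config A [sim_config()].
#' @return Integer count.
#' @export
max_identifications <- function(config) {
  as.integer(config$n_species * config$photos_per_species +
               config$n_distractors)
}

# Deterministic pseudo-Latin binomials drawn from the active RNG stream.
make_latin_names <- function(n, suffix) {
  syll <- c("ba", "ce", "do", "fe", "ga", "he", "ka", "lo", "mi", "na",
            "pe", "ra", "sa", "te", "vu", "xe", "zo", "chi", "phy", "the")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(2:4, 1)
    nm <- paste0(paste(sample(syll, k, replace = TRUE), collapse = ""), suffix)
    out <- unique(c(out, nm))
  }
  out[seq_len(n)]
}

# Synthetic taxonomy sized to the challenge. Challenge species are padded
# with extra drop-down-only species so every genus has >= 2 species and every
# family >= 2 genera: then congener and confamilial wrong answers exist for
# every photographed species.
make_sim_taxonomy <- function(cfg) {
  fam_of_species <- rep(names(cfg$families), cfg$families)
  region_pool <- sample(rep(names(cfg$regions), cfg$regions))
  rows <- list()
  genus_pool <- make_latin_names(4 * sum(pmax(2, ceiling(cfg$families / 2))),
                                 "us")
  gi <- 0
  challenge <- character(0)
  for (fam in names(cfg$families)) {
    size <- cfg$families[[fam]]
    n_gen <- max(2, ceiling(size / 3))
    sizes <- rep(size %/% n_gen, n_gen)
    extra <- size - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    for (g in seq_len(n_gen)) {
      gi <- gi + 1
      genus <- paste0(toupper(substr(genus_pool[gi], 1, 1)),
                      substr(genus_pool[gi], 2, nchar(genus_pool[gi])))
      n_real <- sizes[g]
      n_total <- max(n_real + 1, 2)  # always one padding congener
      epithets <- make_latin_names(n_total, "a")
      for (s in seq_len(n_total)) {
        binomen <- paste(genus, epithets[s])
        in_challenge <- s <= n_real
        region <- if (in_challenge) {
          r <- region_pool[length(challenge) + 1]
          challenge <- c(challenge, binomen)
          r
        } else names(cfg$regions)[1]
        rows[[length(rows) + 1]] <- data.frame(
          binomen = binomen, genus = genus, family = fam,
          synonyms = if (in_challenge && stats::runif(1) < 0.2)
            paste("Palaeo", tolower(genus), " ", epithets[s], sep = "") else "",
          common_names = if (in_challenge)
            paste(epithets[s], tolower(genus)) else "",
          is_mivs = NA, regions = region,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  # MIVS at genus level, concentrated in the families where venomous snakes sit
  mivs_prob <- c(Viperidae = 1, Elapidae = 1, Lamprophiidae = 0.3,
                 Colubridae = 0.15)
  for (g in unique(tab$genus)) {
    fam <- tab$family[match(g, tab$genus)]
    p <- if (fam %in% names(mivs_prob)) mivs_prob[[fam]] else
      if (all(names(cfg$families) %in% c(names(mivs_prob), "Boidae",
                                         "Pythonidae", "Cylindrophiidae",
                                         "Typhlopidae", "Leptotyphlopidae")))
        0 else 0.25
    tab$is_mivs[tab$genus == g] <- stats::runif(1) < p
  }
  list(taxonomy = taxonomy(tab), challenge_species = challenge)
}

draw_bivariate <- function(n, sd1, sd2, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(b = sd1 * z1, d = sd2 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Forward-simulate an identification challenge
#'
#' Generates a response table with ordinal scores from exactly the latent
#' structure the graded response model assumes: participant abilities
#' `N(0, sd_participant)`, bivariate-normal photo and species
#' difficulty/discrimination pairs, the configured fixed effects on the
#' cumulative-logit scale, and log-link discrimination. The taxa-repeat
#' covariate emerges from the simulated presentation order. All randomness
#' flows from the single root seed, so identical seeds give identical
#' output.
#'
#' @param config A [sim_config()].
#' @param seed Root seed; defaults to `config$seed`. Required.
#' @return An object of class `sim_challenge`: list with `responses` (one
#'   row per participant-photo event, ordinal `score`, `answer_raw` unset
#'   until [attach_answer_strings()]), `taxonomy`, `truth` (a `sim_truth`:
#'   participant abilities, photo and species effect pairs, and the config)
#'   and `config`.
#' @export
simulate_challenge <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("simulate_challenge requires a seed")
  set.seed(seed)
  cfg <- config

  taxgen <- make_sim_taxonomy(cfg)
  species <- data.frame(binomen = taxgen$challenge_species,
                        stringsAsFactors = FALSE)
  ti <- match(species$binomen, taxgen$taxonomy$binomen)
  species$family <- taxgen$taxonomy$family[ti]
  species$region <- vapply(taxgen$taxonomy$regions[ti], `[`, "", 1)
  sp_eff <- draw_bivariate(nrow(species), cfg$sd_species_b, cfg$sd_species_d,
                           cfg$rho_species)
  species$b <- sp_eff[, "b"]
  species$d <- sp_eff[, "d"]

  n_photos <- cfg$n_species * cfg$photos_per_species
  photos <- data.frame(
    photo_id = sprintf("P%04d", seq_len(n_photos)),
    species_idx = rep(seq_len(cfg$n_species), each = cfg$photos_per_species),
    stringsAsFactors = FALSE)
  n_low <- round(cfg$photos_per_species * cfg$prop_low_quality)
  qual <- c(rep("low", n_low), rep("high", cfg$photos_per_species - n_low))
  photos$quality <- as.vector(replicate(cfg$n_species, sample(qual)))
  ph_eff <- draw_bivariate(n_photos, cfg$sd_photo_b, cfg$sd_photo_d,
                           cfg$rho_photo)
  photos$b <- ph_eff[, "b"]
  photos$d <- ph_eff[, "d"]

  participants <- data.frame(
    participant_id = sprintf("U%04d", seq_len(cfg$n_participants)),
    home_region = sample(names(cfg$home_region_dist), cfg$n_participants,
                         replace = TRUE, prob = cfg$home_region_dist),
    theta = stats::rnorm(cfg$n_participants, 0, cfg$sd_participant),
    stringsAsFactors = FALSE)

  npp <- min(cfg$photos_per_participant, n_photos)
  resp <- vector("list", cfg$n_participants)
  for (j in seq_len(cfg$n_participants)) {
    idx <- sample.int(n_photos, npp)
    if (cfg$quality_order == "high_first")
      idx <- idx[order(photos$quality[idx] == "low", sample.int(npp))]
    resp[[j]] <- data.frame(
      participant_id = participants$participant_id[j],
      photo_idx = idx, order_index = seq_len(npp),
      stringsAsFactors = FALSE)
  }
  resp <- do.call(rbind, resp)
  resp$photo_id <- photos$photo_id[resp$photo_idx]
  sp_idx <- photos$species_idx[resp$photo_idx]
  resp$true_species <- species$binomen[sp_idx]
  resp$photo_region <- species$region[sp_idx]
  resp$quality <- photos$quality[resp$photo_idx]
  pj <- match(resp$participant_id, participants$participant_id)
  resp$home_region <- participants$home_region[pj]
  resp$taxa_repeat <- compute_taxa_repeat(resp)

  fam_beta <- c(stats::setNames(0, names(cfg$families)[1]), cfg$beta_family)
  reg_beta <- c(stats::setNames(0, names(cfg$regions)[1]), cfg$beta_region)
  inter_beta <- c(stats::setNames(0, names(cfg$regions)[1]),
                  cfg$beta_home_x_region)
  home <- resp$photo_region == resp$home_region
  eta <- participants$theta[pj] +
    fam_beta[species$family[sp_idx]] +
    reg_beta[resp$photo_region] +
    home * (cfg$beta_home + inter_beta[resp$photo_region]) +
    cfg$beta_repeat * resp$taxa_repeat +
    cfg$beta_quality * (resp$quality == "low") +
    photos$b[resp$photo_idx] + species$b[sp_idx]
  alpha <- exp(cfg$delta0 + photos$d[resp$photo_idx] + species$d[sp_idx])
  pr <- category_probs(eta, alpha, cfg$tau)
  u <- stats::runif(nrow(resp))
  cum <- pr[, 1]
  score <- integer(nrow(resp))
  for (k in 1:3) {
    score[u >= cum] <- k
    if (k < 3) cum <- cum + pr[, k + 1]
  }
  resp$score <- score
  resp$answer_raw <- NA_character_
  resp <- resp[c("participant_id", "home_region", "photo_id", "true_species",
                 "photo_region", "quality", "order_index", "answer_raw",
                 "score", "taxa_repeat")]
  rownames(resp) <- NULL

  truth <- structure(list(participants = participants,
                          photos = photos[c("photo_id", "species_idx",
                                            "quality", "b", "d")],
                          species = species, config = cfg),
                     class = "sim_truth")
  structure(list(responses = resp, taxonomy = taxgen$taxonomy, truth = truth,
                 config = cfg),
            class = "sim_challenge")
}

#' @export
print.sim_challenge <- function(x, ...) {
  cat("Simulated challenge:", nrow(x$truth$participants), "participants,",
      nrow(x$truth$photos), "photos of", nrow(x$truth$species), "species;",
      nrow(x$responses), "responses\n")
  cat("Score distribution:",
      paste(sprintf("%d: %.2f", 0:3,
                    tabulate(x$responses$score + 1L, 4) / nrow(x$responses)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fill in free-text answers consistent with the simulated scores
#'
#' For every simulated response, emits an answer string that re-scores to
#' exactly the simulated ordinal value: the true binomen (occasionally a
#' listed synonym) for score 3, a random congener for score 2, a confamilial
#' species from another genus for score 1, and for score 0 either a skip
#' (with probability `skip_prob`) or an extra-familial species. This lets the
#' whole scoring pipeline be exercised end-to-end against known truth.
#'
#' @param x A `sim_challenge` or a response data frame with `score` and
#'   `true_species` columns.
#' @param taxonomy Taxonomy to draw wrong answers from; defaults to the
#'   simulation's own. Must offer a congener for every species with a score-2
#'   response and a confamilial other-genus species for every score-1
#'   response, otherwise an error names the species that cannot be realized.
#' @param seed Seed for the answer draws.
#' @param skip_prob Probability a score-0 answer is a skip; defaults to the
#'   simulation config's `skip_prob` (0.3 otherwise).
#' @param synonym_prob Probability a score-3 answer uses a listed synonym
#'   instead of the canonical binomen (default 0.1).
#' @return The input with `answer_raw` filled (same type as `x`).
#' @export
attach_answer_strings <- function(x, taxonomy = NULL, seed = NULL,
                                  skip_prob = NULL, synonym_prob = 0.1) {
  is_sim <- inherits(x, "sim_challenge")
  resp <- if (is_sim) x$responses else x
  if (is.null(taxonomy)) {
    if (!is_sim) stop("taxonomy must be supplied for a plain response table")
    taxonomy <- x$taxonomy
  }
  if (is.null(skip_prob))
    skip_prob <- if (is_sim) x$config$skip_prob else 0.3
  if (!is.null(seed)) set.seed(seed)

  sp <- unique(resp$true_species)
  i <- match(sp, taxonomy$binomen)
  if (anyNA(i))
    stop("true species not in taxonomy: ", paste(sp[is.na(i)], collapse = ", "))
  pools <- lapply(seq_along(sp), function(k) {
    genus <- taxonomy$genus[i[k]]
    fam <- taxonomy$family[i[k]]
    list(
      congener = setdiff(taxonomy$binomen[taxonomy$genus == genus], sp[k]),
      confamilial = taxonomy$binomen[taxonomy$family == fam &
                                       taxonomy$genus != genus],
      other = taxonomy$binomen[taxonomy$family != fam],
      synonyms = taxonomy$synonyms[[i[k]]]
    )
  })
  names(pools) <- sp

  need2 <- sp[vapply(pools, function(p) length(p$congener) == 0, TRUE) &
                sp %in% resp$true_species[resp$score == 2]]
  need1 <- sp[vapply(pools, function(p) length(p$confamilial) == 0, TRUE) &
                sp %in% resp$true_species[resp$score == 1]]
  if (length(need2) || length(need1))
    stop("taxonomy too small to realize requested scores; ",
         if (length(need2)) paste("no congener for:",
                                  paste(need2, collapse = ", ")),
         if (length(need2) && length(need1)) "; ",
         if (length(need1)) paste("no confamilial for:",
                                  paste(need1, collapse = ", ")))

  pick <- function(v) if (length(v) == 1) v else sample(v, 1)
  resp$answer_raw <- vapply(seq_len(nrow(resp)), function(r) {
    p <- pools[[resp$true_species[r]]]
    switch(as.character(resp$score[r]),
           "3" = if (length(p$synonyms) && stats::runif(1) < synonym_prob)
             pick(p$synonyms) else resp$true_species[r],
           "2" = pick(p$congener),
           "1" = pick(p$confamilial),
           "0" = if (stats::runif(1) < skip_prob) "" else pick(p$other))
  }, "")
  if (is_sim) {
    x$responses <- resp
    x
  } else resp
}
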