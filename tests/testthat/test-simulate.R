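test_that("config validation names the offending field", {
  expect_error(sim_config(tau = c(0, -1, 1)), "tau")
  expect_error(sim_config(n_species = 10), "families")
  expect_error(sim_config(sd_photo_b = -1), "sd_photo_b")
  expect_error(sim_config(rho_photo = 1.2), "rho_photo")
  expect_error(sim_config(home_region_dist = c(Africa = 0.5)),
               "home_region_dist")
  expect_error(simulate_challenge(sim_config()), "seed")
})

test_that("the same seed reproduces the challenge exactly", {
  cfg <- small_sim_config(seed = 77)
  a <- simulate_challenge(cfg)
  b <- simulate_challenge(cfg)
  expect_identical(a$responses, b$responses)
  expect_identical(as.data.frame(a$taxonomy), as.data.frame(b$taxonomy))
  expect_identical(a$truth$participants, b$truth$participants)
  c2 <- simulate_challenge(cfg, seed = 78)
  expect_false(identical(a$responses$score, c2$responses$score))
})

test_that("simulated structure matches the configuration", {
  sim <- shared_sim()
  cfg <- sim$config
  expect_equal(nrow(sim$truth$participants), cfg$n_participants)
  expect_equal(nrow(sim$truth$species), cfg$n_species)
  expect_equal(nrow(sim$truth$photos),
               cfg$n_species * cfg$photos_per_species)
  expect_equal(nrow(sim$responses),
               cfg$n_participants * cfg$photos_per_participant)
  # families allocated as configured
  expect_equal(table(sim$truth$species$family)[names(cfg$families)],
               table(rep(names(cfg$families), cfg$families)))
  # every participant sees each photo at most once, orders are permutations
  byp <- split(sim$responses$order_index, sim$responses$participant_id)
  expect_true(all(vapply(byp, function(o)
    identical(sort(o), seq_along(o)), TRUE)))
})

test_that("with no heterogeneity, category frequencies match the closed form", {
  cfg <- sim_config(
    n_participants = 100, n_species = 100, photos_per_species = 5,
    photos_per_participant = 500,
    families = c(FamA = 50, FamB = 50),
    regions = c(Africa = 50, Asia = 50),
    home_region_dist = c(Africa = 0.5, Asia = 0.5),
    tau = c(-1, 0, 1),
    beta_family = c(FamB = 0), beta_region = c(Asia = 0),
    beta_home = 0, beta_home_x_region = c(Asia = 0), beta_repeat = 0,
    delta0 = 0, sd_photo_b = 0, sd_photo_d = 0, sd_species_b = 0,
    sd_species_d = 0, sd_participant = 0, seed = 515)
  sim <- simulate_challenge(cfg)
  expect_equal(nrow(sim$responses), 50000)
  p <- as.vector(category_probs(0, 1, c(-1, 0, 1)))
  obs <- tabulate(sim$responses$score + 1L, 4)
  gof <- stats::chisq.test(obs, p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("raising an effect that increases eta raises scores stochastically", {
  means <- vapply(c(0, 1.5, 3), function(bh) {
    cfg <- small_sim_config(seed = 606, n_participants = 40,
                            photos_per_participant = 36)
    cfg$beta_home <- bh
    mean(simulate_challenge(cfg)$responses$score)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("attached answer strings re-score to the simulated ordinal values", {
  sim <- shared_sim()
  scored <- shared_scored()
  expect_identical(scored$score, sim$responses$score)
  # forced cases
  i3 <- scored$score == 3 & scored$answer_raw == scored$true_species
  expect_gt(mean(i3[scored$score == 3]), 0.5)
  tax <- sim$taxonomy
  g_ans <- tax$genus[match(scored$answer_raw, tax$binomen)]
  g_true <- tax$genus[match(scored$true_species, tax$binomen)]
  expect_true(all(g_ans[scored$score == 2] == g_true[scored$score == 2]))
  # score 0 answers are skips or extra-familial species
  f_ans <- tax$family[match(scored$answer_raw, tax$binomen)]
  f_true <- tax$family[match(scored$true_species, tax$binomen)]
  s0 <- scored$score == 0
  expect_true(all(scored$answer_raw[s0] == "" |
                    f_ans[s0] != f_true[s0]))
  # a taxonomy with no congeners cannot realize a score-2 answer
  lonely <- taxonomy(data.frame(
    binomen = c("Aa bb", "Cc dd"), genus = c("Aa", "Cc"),
    family = c("F1", "F1"), synonyms = "", common_names = "",
    is_mivs = FALSE, regions = "Africa", stringsAsFactors = FALSE))
  df <- data.frame(score = 2L, true_species = "Aa bb",
                   stringsAsFactors = FALSE)
  expect_error(attach_answer_strings(df, lonely, seed = 1),
               "no congener")
})

test_that("the maximum identification count includes distractors", {
  expect_equal(max_identifications(sim_config()), 1100)
  expect_equal(max_identifications(small_sim_config()), 12 * 3 + 100)
})
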