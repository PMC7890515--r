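make_scored <- function(participant_id, score, mivs = TRUE) {
  n <- length(score)
  data.frame(participant_id = participant_id,
             photo_id = paste0("p", seq_len(n)),
             true_species = "X a", score = score, mivs_correct = mivs,
             stringsAsFactors = FALSE)
}

test_that("quintile table partitions participants and averages correctly", {
  set.seed(91)
  # 25 participants x 40 responses with genuinely different abilities
  p_acc <- seq(0.05, 0.85, length.out = 25)
  scored <- do.call(rbind, lapply(seq_len(25), function(j) {
    sc <- stats::rbinom(40, 1, p_acc[j]) * 3
    make_scored(sprintf("u%02d", j), sc, mivs = sc == 3)
  }))
  qt <- quintile_table(scored, min_photos = 40)
  expect_equal(nrow(qt), 6)
  expect_equal(qt$n_participants, c(5, 5, 5, 5, 5, 25))
  # species accuracy decreases down the ranking by construction
  expect_true(all(diff(qt$species_pct[1:5]) < 0))
  # whole community equals the participant-weighted quintile mean
  expect_equal(qt$species_pct[6],
               sum(qt$species_pct[1:5] * qt$n_participants[1:5]) / 25)
  expect_true(all(qt$species_pct >= 0 & qt$species_pct <= 100))
  # eligibility threshold filters, and too-few participants is an error
  expect_error(quintile_table(scored[scored$participant_id %in%
                                       c("u01", "u02"), ], 40), "at least 5")
})

test_that("identical abilities leave quintiles statistically indistinguishable", {
  set.seed(92)
  scored_null <- do.call(rbind, lapply(1:100, function(j)
    make_scored(sprintf("u%03d", j), stats::rbinom(100, 1, 0.4) * 3)))
  qt <- quintile_table(scored_null, min_photos = 100)
  # ranking noise alone: top-bottom gap stays within a few binomial sds
  gap <- (qt$species_pct[1] - qt$species_pct[5]) / 100
  expect_lt(gap, 5 * sqrt(0.4 * 0.6 / 100))
  # whereas a heterogeneous cohort of the same shape shows a larger gap
  p_acc <- stats::runif(100, 0.05, 0.8)
  scored_het <- do.call(rbind, lapply(1:100, function(j)
    make_scored(sprintf("u%03d", j), stats::rbinom(100, 1, p_acc[j]) * 3)))
  qt_het <- quintile_table(scored_het, min_photos = 100)
  expect_gt(qt_het$species_pct[1] - qt_het$species_pct[5], 100 * gap)
})

test_that("genus confusion table matches a hand count", {
  tax <- taxonomy(data.frame(
    binomen = c("Xus a", "Xus b", "Yus a", "Zus a"),
    genus = c("Xus", "Xus", "Yus", "Zus"),
    family = c("F1", "F1", "F1", "F2"),
    synonyms = "", common_names = "",
    is_mivs = c(TRUE, TRUE, FALSE, TRUE),
    regions = "Africa", stringsAsFactors = FALSE))
  # 10 responses to MIVS genus Xus: 5 species-correct, 1 congener (genus
  # correct), 3 answered the harmless genus Yus, 1 skip
  answers <- c(rep("Xus a", 5), "Xus b", rep("Yus a", 3), "")
  resp <- data.frame(participant_id = "u", home_region = "Africa",
                     photo_id = paste0("p", 1:10), true_species = "Xus a",
                     photo_region = "Africa", quality = "high",
                     order_index = 1:10, answer_raw = answers,
                     stringsAsFactors = FALSE)
  scored <- score_responses(resp, tax)
  tab <- genus_confusion(scored, tax)
  x <- tab[tab$genus == "Xus", ]
  expect_equal(x$n_responses, 10)
  expect_equal(x$pct_genus_correct, 60)
  expect_equal(x$pct_species_correct, 50)
  expect_equal(x$pct_non_mivs, 30)           # 3 of 10, skip not counted
  expect_equal(x$pct_non_mivs_nonskip, 100 * 3 / 9)
  expect_equal(x$modal_wrong_non_mivs, "Yus")
  expect_equal(x$modal_wrong_non_mivs_pct, 30)
  # all-correct input: nothing identified as non-MIVS
  all_ok <- score_responses(transform(resp, answer_raw = "Xus a"), tax)
  expect_equal(genus_confusion(all_ok, tax)$pct_non_mivs, 0)
})

test_that("per-photo consensus counts uniqueness and majority outcomes", {
  tax <- toy_taxonomy()
  mk <- function(photo, answers, truth) {
    data.frame(participant_id = paste0("u", seq_along(answers)),
               home_region = "Africa", photo_id = photo,
               true_species = truth, photo_region = "Africa",
               quality = "high", order_index = 1,
               answer_raw = answers, stringsAsFactors = FALSE)
  }
  resp <- rbind(
    mk("p1", rep("Bitis arietans", 4), "Bitis arietans"),
    mk("p2", c("Bitis gabonica", "Bitis gabonica", "Bitis arietans",
               "Naja naja", ""), "Bitis arietans"))
  resp$order_index <- stats::ave(seq_len(nrow(resp)), resp$participant_id,
                                 FUN = seq_along)
  scored <- score_responses(resp, tax)
  pc <- photo_consensus_stats(scored)
  p1 <- pc$photos[pc$photos$photo_id == "p1", ]
  expect_equal(p1$n_unique, 1)
  expect_true(p1$majority_correct)
  expect_equal(p1$pct_species_correct, 100)
  p2 <- pc$photos[pc$photos$photo_id == "p2", ]
  expect_equal(p2$n_unique, 3)  # skips excluded from uniqueness
  expect_false(p2$majority_correct)
  expect_equal(p2$modal_answer, "Bitis gabonica")
  expect_equal(pc$n_majority_correct, 1)
  # heavier confusion on some photos forces a negative uniqueness-accuracy
  # correlation by construction
  set.seed(93)
  conf <- do.call(rbind, lapply(1:30, function(k) {
    n_wrong <- k %/% 3
    answers <- c(rep("Bitis arietans", 12 - n_wrong),
                 sample(c("Naja naja", "Boa constrictor", "Python sebae",
                          "Echis ocellatus"), n_wrong, TRUE))
    mk(sprintf("q%02d", k), answers, "Bitis arietans")
  }))
  conf$order_index <- stats::ave(seq_len(nrow(conf)), conf$participant_id,
                                 FUN = seq_along)
  pc2 <- photo_consensus_stats(score_responses(conf, tax))
  expect_lt(pc2$cor_uniqueness_accuracy, 0)
})

test_that("modal-share arithmetic reproduces the printed consensus example", {
  tax <- toy_taxonomy()
  # 79 responses: 57 modal wrong answers, 9 correct, 13 others
  answers <- c(rep("Bitis gabonica", 57), rep("Bitis arietans", 9),
               rep("Naja naja", 7), rep("Echis ocellatus", 6))
  resp <- data.frame(participant_id = paste0("u", 1:79),
                     home_region = "Africa", photo_id = "crotalus_like",
                     true_species = "Bitis arietans",
                     photo_region = "Africa", quality = "high",
                     order_index = 1, answer_raw = answers,
                     stringsAsFactors = FALSE)
  scored <- score_responses(resp, tax)
  pc <- photo_consensus_stats(scored)
  expect_equal(round(100 * 57 / 79), 72)
  expect_equal(round(pc$photos$pct_species_correct), 11)
  expect_equal(pc$photos$modal_answer, "Bitis gabonica")
  expect_false(pc$photos$majority_correct)
})

test_that("accuracy grids respect event nesting and learning monotonicity", {
  fit <- shared_fit()
  grid <- expand.grid(family = c("Boidae", "Viperidae"),
                      region = "NorthAmerica", home = c(FALSE, TRUE),
                      taxa_repeat = c(0L, 4L, 9L),
                      stringsAsFactors = FALSE)
  pg <- predict_accuracy_grid(fit, grid)
  expect_true(all(pg$estimate >= 0 & pg$estimate <= 1))
  wide <- stats::reshape(pg, direction = "wide", idvar = names(grid),
                         timevar = "level")
  expect_true(all(wide$estimate.family >= wide$estimate.genus - 1e-12))
  expect_true(all(wide$estimate.genus >= wide$estimate.species - 1e-12))
  # taxa-repeat draws are positive in this cohort, so repeats help
  if (stats::median(fit$draws[, , "taxa_repeat"]) > 0) {
    first <- pg[pg$taxa_repeat == 0 & pg$level == "species", "estimate"]
    tenth <- pg[pg$taxa_repeat == 9 & pg$level == "species", "estimate"]
    expect_true(all(tenth > first))
  }
  expect_error(predict_accuracy_grid(fit, transform(grid, family = "Nope")),
               "Nope")
})

test_that("difficulty/discrimination report ranks units and compares scales", {
  fit <- shared_fit()
  rep_tab <- difficulty_discrimination_report(fit)
  expect_equal(nrow(rep_tab$species), length(fit$data$species_levels))
  expect_equal(nrow(rep_tab$photos), length(fit$data$photo_levels))
  expect_true(all(diff(rep_tab$species$effect) >= 0))  # hardest first
  expect_true(all(rep_tab$sd_ratios[, "estimate"] > 0))
  expect_true(all(rownames(rep_tab$correlations) == c("photo", "species")))
  expect_true(all(abs(rep_tab$correlations[, "estimate"]) <= 1))
})

test_that("diversity regression reports OLS slope and adjusted R2", {
  # perfectly linear toy data
  fit_lin <- suppressWarnings(diversity_regression(c(0.2, 0.4, 0.6, 0.8), 1:4))
  expect_equal(fit_lin$slope, 0.2, tolerance = 1e-12)
  expect_gt(fit_lin$adj_r2, 0.999)
  # hand-computed oracle on a 5-point set: slope = cov/var
  x <- c(1, 2, 4, 7, 9); yv <- c(0.9, 0.8, 0.75, 0.5, 0.42)
  got <- diversity_regression(yv, x)
  expect_equal(got$slope, stats::cov(x, yv) / stats::var(x), tolerance = 1e-12)
  expect_equal(got$intercept, mean(yv) - got$slope * mean(x),
               tolerance = 1e-12)
  # richness-independent accuracy at small n: adjusted R2 goes negative
  neg <- diversity_regression(c(0.58, 0.59, 0.53, 0.53, 0.41),
                              c(2, 9, 4, 7, 5))
  expect_lt(neg$adj_r2, 0)
  expect_error(diversity_regression(c(0.1, 0.2), c(1, 2)), "at least 3")
  flat <- diversity_regression(c(0.1, 0.2, 0.3), c(2, 2, 2))
  expect_true(is.na(flat$slope))
})
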