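# Descriptive tables and model-derived summaries of a scored challenge.

participant_accuracy <- function(scored) {
  split_idx <- split(seq_len(nrow(scored)), scored$participant_id)
  out <- data.frame(
    participant_id = names(split_idx),
    n = lengths(split_idx),
    species = vapply(split_idx, function(i) mean(scored$score[i] == 3), 0),
    genus = vapply(split_idx, function(i) mean(scored$score[i] >= 2), 0),
    family = vapply(split_idx, function(i) mean(scored$score[i] >= 1), 0),
    mivs = vapply(split_idx, function(i) mean(scored$mivs_correct[i]), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Participant accuracy by quintile
#'
#' Participants who answered at least `min_photos` photos are ranked by
#' their species-level accuracy (ties broken by response count, then id) and
#' cut into five equal groups, top quintile first. For each quintile and for
#' the whole community, the mean across participants of species-, genus- and
#' family-level accuracy and MIVS accuracy is reported as a percentage with
#' a normal-approximation 95% CI half-width of the across-participant mean.
#'
#' @param scored Scored responses (see [score_responses()]).
#' @param min_photos Eligibility threshold (default 80).
#' @return Data frame: one row per quintile plus a `whole community` row;
#'   columns `quintile`, `n_participants`, and `<level>_pct` / `<level>_ci`
#'   for level in species, genus, family, mivs.
#' @export
quintile_table <- function(scored, min_photos = 80) {
  acc <- participant_accuracy(scored)
  acc <- acc[acc$n >= min_photos, ]
  if (nrow(acc) < 5)
    stop("need at least 5 participants with >= ", min_photos,
         " responses (have ", nrow(acc), ")")
  acc <- acc[order(-acc$species, -acc$n, acc$participant_id), ]
  sizes <- diff(floor(seq(0, nrow(acc), length.out = 6)))
  acc$quintile <- rep(seq_len(5), sizes)
  lab <- c("1st quintile (top 20%)", "2nd quintile", "3rd quintile",
           "4th quintile", "5th quintile (bottom 20%)")
  row_for <- function(sub, name) {
    ci <- function(v) 1.96 * stats::sd(v) / sqrt(length(v))
    data.frame(quintile = name, n_participants = nrow(sub),
               species_pct = 100 * mean(sub$species), species_ci = 100 * ci(sub$species),
               genus_pct = 100 * mean(sub$genus), genus_ci = 100 * ci(sub$genus),
               family_pct = 100 * mean(sub$family), family_ci = 100 * ci(sub$family),
               mivs_pct = 100 * mean(sub$mivs), mivs_ci = 100 * ci(sub$mivs),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(5), function(q)
    row_for(acc[acc$quintile == q, ], lab[q])))
  rbind(out, row_for(acc, "whole community"))
}

# MIVS status of the taxon each resolved answer denotes (NA for skips)
answered_mivs_status <- function(scored, taxonomy) {
  status <- rep(NA, nrow(scored))
  sp <- scored$match_rank == "species"
  status[sp] <- taxonomy$is_mivs[match(scored$answer_binomen[sp],
                                       taxonomy$binomen)]
  genus_mivs <- vapply(split(taxonomy$is_mivs, taxonomy$genus), any, TRUE)
  g <- scored$match_rank == "genus"
  status[g] <- genus_mivs[scored$answer_genus[g]]
  family_mivs <- vapply(split(taxonomy$is_mivs, taxonomy$family), any, TRUE)
  f <- scored$match_rank == "family"
  status[f] <- family_mivs[scored$answer_family[f]]
  status
}

#' Confusion table for medically important venomous genera
#'
#' For each genus containing at least one MIVS species and receiving
#' responses: species and response counts, percentage correct at the genus
#' and species level, the percentage of responses identifying the snake as a
#' non-MIVS taxon (reported against two denominators: all responses, and
#' non-skip responses only), and the most frequently chosen incorrect MIVS
#' and non-MIVS genera with their shares of all responses.
#'
#' @param scored Scored responses.
#' @param taxonomy A [taxonomy()] object.
#' @return Data frame, one row per MIVS genus with responses, ordered by
#'   family then genus.
#' @export
genus_confusion <- function(scored, taxonomy) {
  genus_mivs <- vapply(split(taxonomy$is_mivs, taxonomy$genus), any, TRUE)
  status <- answered_mivs_status(scored, taxonomy)
  true_genus <- taxonomy$genus[match(scored$true_species, taxonomy$binomen)]
  mivs_genera <- names(genus_mivs)[genus_mivs]
  rows <- lapply(intersect(mivs_genera, unique(true_genus)), function(g) {
    sel <- true_genus == g
    n <- sum(sel)
    wrong <- sel & !is.na(scored$answer_genus) & scored$answer_genus != g
    modal <- function(mivs_flag) {
      tab <- table(scored$answer_genus[wrong &
                                         !is.na(status) & status == mivs_flag])
      if (!length(tab)) return(list(genus = NA_character_, pct = 0))
      top <- which.max(tab)
      list(genus = names(tab)[top], pct = 100 * tab[[top]] / n)
    }
    mm <- modal(TRUE); mn <- modal(FALSE)
    data.frame(
      family = taxonomy$family[match(g, taxonomy$genus)],
      genus = g,
      n_species = length(unique(scored$true_species[sel])),
      n_responses = n,
      pct_genus_correct = 100 * mean(scored$score[sel] >= 2),
      pct_species_correct = 100 * mean(scored$score[sel] == 3),
      pct_non_mivs = 100 * sum(!status[sel] %in% c(TRUE, NA)) / n,
      pct_non_mivs_nonskip = 100 * sum(!status[sel] %in% c(TRUE, NA)) /
        max(sum(!is.na(status[sel])), 1),
      modal_wrong_mivs = mm$genus, modal_wrong_mivs_pct = mm$pct,
      modal_wrong_non_mivs = mn$genus, modal_wrong_non_mivs_pct = mn$pct,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(invisible(data.frame()))
  out <- out[order(out$family, out$genus), ]
  rownames(out) <- NULL
  out
}

#' Per-photo consensus statistics
#'
#' For every photo: number of responses, number of distinct resolved answers
#' (skips and unresolvable entries excluded), the modal answer and whether
#' the majority identified the species correctly, and the share of
#' species-correct responses. Modal ties are broken toward the incorrect
#' outcome (conservative consensus). Also returns the global counts of
#' majority-correct photos and photos whose modal answer is an outright
#' incorrect identification (one that scores 0), and the correlation between
#' answer diversity and the correct share.
#'
#' @param scored Scored responses.
#' @return List: `photos` (per-photo data frame), `n_majority_correct`,
#'   `n_majority_incorrect`, `n_photos`, `cor_uniqueness_accuracy`.
#' @export
photo_consensus_stats <- function(scored) {
  canon <- ifelse(scored$match_rank == "species", scored$answer_binomen,
                  ifelse(scored$match_rank == "genus", scored$answer_genus,
                         ifelse(scored$match_rank == "family",
                                scored$answer_family, NA)))
  idx <- split(seq_len(nrow(scored)), scored$photo_id)
  rows <- lapply(names(idx), function(pid) {
    i <- idx[[pid]]
    ans <- canon[i]
    resolved <- !is.na(ans)
    tab <- sort(table(ans[resolved]), decreasing = TRUE)
    truth <- scored$true_species[i][1]
    if (length(tab)) {
      top <- tab[tab == max(tab)]
      # tie -> prefer an incorrect answer as the consensus
      modal <- if (length(top) > 1 && any(names(top) != truth))
        names(top)[names(top) != truth][1] else names(top)[1]
    } else modal <- NA_character_
    modal_score <- if (is.na(modal)) 0L else {
      scores_for_modal <- scored$score[i][!is.na(ans) & ans == modal]
      max(scores_for_modal)
    }
    data.frame(photo_id = pid, true_species = truth, n = length(i),
               n_unique = length(tab), modal_answer = modal,
               majority_correct = !is.na(modal) && modal == truth,
               majority_score0 = modal_score == 0L,
               pct_species_correct = 100 * mean(scored$score[i] == 3),
               stringsAsFactors = FALSE)
  })
  photos <- do.call(rbind, rows)
  rownames(photos) <- NULL
  list(photos = photos,
       n_photos = nrow(photos),
       n_majority_correct = sum(photos$majority_correct),
       n_majority_incorrect = sum(photos$majority_score0),
       cor_uniqueness_accuracy = if (nrow(photos) > 2 &&
                                     stats::sd(photos$n_unique) > 0)
         stats::cor(photos$n_unique, photos$pct_species_correct)
       else NA_real_)
}

#' Model-predicted accuracy over a covariate grid
#'
#' Posterior median and 95% credible interval of the probability of a
#' correct identification at the family level (score >= 1), genus level
#' (score >= 2) and species level (score = 3) for each grid cell, with all
#' group-level deviations at zero (an average participant on an average
#' photo of an average species). Because the events are nested on the
#' ordered scale, family >= genus >= species holds in every draw.
#'
#' @param fit A [grm()] fit.
#' @param grid Data frame with columns `family`, `region`, `home`,
#'   `taxa_repeat` (and `quality` if the model uses it); levels must belong
#'   to the fitted design.
#' @return Long-format data frame: the grid columns plus `level`
#'   (family/genus/species), `estimate`, `l95`, `u95` (probabilities).
#' @export
predict_accuracy_grid <- function(fit, grid) {
  pr <- predict(fit, newdata = grid, type = "probs", re = FALSE,
                summary = FALSE)  # draws x cells x 4
  event <- list(family = 2:4, genus = 3:4, species = 4)
  out <- lapply(names(event), function(lv) {
    p <- apply(pr[, , event[[lv]], drop = FALSE], c(1, 2), sum)
    cbind(grid,
          data.frame(level = lv,
                     estimate = apply(p, 2, stats::median),
                     l95 = apply(p, 2, stats::quantile, 0.025),
                     u95 = apply(p, 2, stats::quantile, 0.975),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Difficulty and discrimination landscape of a fitted model
#'
#' Ranks species and photos by posterior median difficulty (lower latent
#' intercept = harder to identify), compares the fixed participant-ability
#' scale against the species and photo difficulty scales, and summarizes the
#' posterior correlation between difficulty and discrimination at both
#' levels.
#'
#' @param fit A [grm()] fit with photo and species effects.
#' @return List: `species` and `photos` data frames ranked hardest first
#'   (`effect` is the latent intercept deviation; negative = harder),
#'   `sd_ratios` (posterior median and 95% CI of participant:species and
#'   participant:photo difficulty-sd ratios), `correlations` (posterior
#'   summaries of the difficulty-discrimination correlations).
#' @export
difficulty_discrimination_report <- function(fit) {
  stopifnot(fit$include$photo, fit$include$species)
  rank_tab <- function(tag, levels) {
    b <- draw_matrix(fit, paste0("b_", tag, "[", levels, "]"))
    d_names <- paste0("d_", tag, "[", levels, "]")
    has_d <- all(d_names %in% dimnames(fit$draws)[[3]])
    out <- data.frame(
      unit = levels,
      effect = apply(b, 2, stats::median),
      l95 = apply(b, 2, stats::quantile, 0.025),
      u95 = apply(b, 2, stats::quantile, 0.975),
      discrimination = if (has_d)
        apply(draw_matrix(fit, d_names), 2, stats::median) else NA_real_,
      stringsAsFactors = FALSE)
    out <- out[order(out$effect), ]
    rownames(out) <- NULL
    out
  }
  ratio_tab <- function(sd_name) {
    r <- fit$sd_participant / draw_matrix(fit, sd_name)[, 1]
    c(estimate = stats::median(r), l95 = unname(stats::quantile(r, 0.025)),
      u95 = unname(stats::quantile(r, 0.975)))
  }
  cor_tab <- function(nm) {
    if (!nm %in% dimnames(fit$draws)[[3]]) return(NULL)
    r <- draw_matrix(fit, nm)[, 1]
    c(estimate = stats::median(r), l95 = unname(stats::quantile(r, 0.025)),
      u95 = unname(stats::quantile(r, 0.975)))
  }
  list(
    species = rank_tab("species", fit$data$species_levels),
    photos = rank_tab("photo", fit$data$photo_levels),
    sd_ratios = rbind(
      participant_vs_species = ratio_tab("sd_species_difficulty"),
      participant_vs_photo = ratio_tab("sd_photo_difficulty")),
    correlations = do.call(rbind, Filter(Negate(is.null), list(
      photo = cor_tab("cor_photo"), species = cor_tab("cor_species"))))
  )
}

#' Does taxonomic diversity predict identification accuracy?
#'
#' Ordinary least squares of per-taxon accuracy on species richness,
#' reporting the slope and the adjusted R-squared (which can be negative
#' when richness explains less than a random regressor would).
#'
#' @param accuracy Numeric accuracy per taxon (genus or family).
#' @param richness Species richness of each taxon.
#' @return List with `slope`, `intercept`, `adj_r2`, `n`. With fewer than 3
#'   taxa an error; with constant richness the slope is undefined (`NA`).
#' @export
diversity_regression <- function(accuracy, richness) {
  stopifnot(length(accuracy) == length(richness))
  if (length(accuracy) < 3) stop("need at least 3 taxa")
  if (stats::sd(richness) == 0)
    return(list(slope = NA_real_, intercept = mean(accuracy),
                adj_r2 = NA_real_, n = length(accuracy)))
  fit <- stats::lm(accuracy ~ richness)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r2 = summary(fit)$adj.r.squared,
       n = length(accuracy))
}
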