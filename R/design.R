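#' Candidate model specifications
#'
#' Every candidate contains photo region, snake family and the taxa-repeat
#' covariate. The six members of the grid add combinations of photo quality
#' and home region, plus a home-region-by-region interaction variant (which
#' always includes the home-region main effect).
#'
#' @param name One of `grm_model_names()`.
#' @return A list of class `grm_model` with logical fields `home`,
#'   `home_x_region`, `quality`.
#' @export
grm_model <- function(name = grm_model_names()) {
  name <- match.arg(name)
  spec <- switch(name,
    base = list(home = FALSE, home_x_region = FALSE, quality = FALSE),
    quality = list(home = FALSE, home_x_region = FALSE, quality = TRUE),
    home = list(home = TRUE, home_x_region = FALSE, quality = FALSE),
    home_quality = list(home = TRUE, home_x_region = FALSE, quality = TRUE),
    home_x_region = list(home = TRUE, home_x_region = TRUE, quality = FALSE),
    home_x_region_quality = list(home = TRUE, home_x_region = TRUE,
                                 quality = TRUE))
  structure(c(list(name = name), spec), class = "grm_model")
}

#' @rdname grm_model
#' @export
grm_model_names <- function() {
  c("base", "quality", "home", "home_quality", "home_x_region",
    "home_x_region_quality")
}

#' @rdname grm_model
#' @return `grm_model_grid()`: named list of all six candidate specs.
#' @export
grm_model_grid <- function() {
  stats::setNames(lapply(grm_model_names(), grm_model), grm_model_names())
}

#' Assemble the model frame for the graded response model
#'
#' Joins scored responses with the taxonomy to recover each photo's snake
#' family, derives the home-region indicator (photo region equals the
#' participant's home region), and ensures the taxa-repeat covariate is
#' present. Factor reference levels follow the original parameterization:
#' family Boidae and region Africa (falling back to the alphabetically first
#' observed level if those are absent).
#'
#' @param responses Scored response table (see [score_responses()]); must
#'   contain `score` unless it still carries simulated scores.
#' @param taxonomy A [taxonomy()] object.
#' @param ref_family,ref_region Reference levels.
#' @return A data frame of class `grm_frame` with columns `score`, `family`,
#'   `region`, `home`, `taxa_repeat`, `quality`, `participant_id`,
#'   `photo_id`, `true_species`.
#' @export
grm_frame <- function(responses, taxonomy, ref_family = "Boidae",
                      ref_region = "Africa") {
  if (!"score" %in% names(responses))
    stop("responses must be scored first (see score_responses)")
  i <- match(responses$true_species, taxonomy$binomen)
  if (anyNA(i))
    stop("true species not in taxonomy: ",
         paste(unique(responses$true_species[is.na(i)]), collapse = ", "))
  fams <- sort(unique(taxonomy$family))
  if (ref_family %in% fams) fams <- c(ref_family, setdiff(fams, ref_family))
  regs <- snake_regions()
  if (ref_region %in% regs) regs <- c(ref_region, setdiff(regs, ref_region))
  if (!"taxa_repeat" %in% names(responses))
    responses$taxa_repeat <- compute_taxa_repeat(responses)
  out <- data.frame(
    score = as.integer(responses$score),
    family = factor(taxonomy$family[i], levels = fams),
    region = factor(responses$photo_region, levels = regs),
    home = responses$photo_region == responses$home_region,
    taxa_repeat = as.integer(responses$taxa_repeat),
    quality = factor(as.character(responses$quality), levels = c("high", "low")),
    participant_id = as.character(responses$participant_id),
    photo_id = as.character(responses$photo_id),
    true_species = as.character(responses$true_species),
    stringsAsFactors = FALSE)
  if (any(out$score < 0 | out$score > 3))
    stop("scores must lie in 0..3")
  class(out) <- c("grm_frame", "data.frame")
  out
}

#' Build the fixed-effect design matrix
#'
#' Dummy coding with the stated reference levels: a reference-cell response
#' (reference family, reference region, outside the home region, first
#' exposure, high quality) has an all-zero row. Column names follow the
#' original reporting convention: family and region levels appear plainly,
#' the home indicator as `home_region = T`, interactions as
#' `<Region>: home_region = T`, photo quality as `quality = low`, and the
#' learning covariate as `taxa_repeat`. The full interaction model over 9
#' families and 6 regions has 20 columns.
#'
#' @param frame A [grm_frame()] (or compatible data frame with `family`,
#'   `region`, `home`, `taxa_repeat`, `quality` columns; factor levels of
#'   the data must be within the frame's levels).
#' @param model A [grm_model()] or its name.
#' @return Numeric design matrix, one row per response.
#' @export
build_design <- function(frame, model = "home_x_region") {
  if (is.character(model)) model <- grm_model(model)
  for (col in c("family", "region")) {
    vals <- frame[[col]]
    if (!is.factor(vals)) stop(col, " must be a factor with reference level first")
    if (anyNA(vals))
      stop("level not in design for '", col, "': ",
           paste(unique(as.character(frame[[col]])[is.na(vals)]), collapse = ", "))
  }
  fams <- levels(frame$family)
  regs <- levels(frame$region)
  cols <- list()
  for (f in fams[-1]) cols[[f]] <- as.numeric(frame$family == f)
  for (r in regs[-1]) cols[[r]] <- as.numeric(frame$region == r)
  if (model$home) cols[["home_region = T"]] <- as.numeric(frame$home)
  cols[["taxa_repeat"]] <- as.numeric(frame$taxa_repeat)
  if (model$home_x_region) {
    for (r in regs[-1])
      cols[[paste0(r, ": home_region = T")]] <-
        as.numeric(frame$region == r & frame$home)
  }
  if (model$quality) {
    if (anyNA(frame$quality)) stop("quality has missing values")
    cols[["quality = low"]] <- as.numeric(frame$quality == "low")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}
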