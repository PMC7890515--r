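#' Build a validated taxonomy
#'
#' A taxonomy is the lookup table against which free-text identifications are
#' resolved. One row per species, with its genus, family, any alternative
#' binomina (synonyms), common names, whether it is a medically important
#' venomous snake (MIVS, WHO Category 1/2), and the global region(s) where it
#' occurs.
#'
#' @param x A data frame with columns `binomen`, `genus`, `family`,
#'   `synonyms`, `common_names`, `is_mivs`, `regions`. The list-valued
#'   columns (`synonyms`, `common_names`, `regions`) may be character vectors
#'   with entries separated by `|`, or list columns of character vectors.
#' @return An object of class `taxonomy`: the validated data frame with a
#'   precomputed name-resolution index attached.
#' @examples
#' tax <- taxonomy(data.frame(
#'   binomen = c("Bitis arietans", "Bitis gabonica", "Echis ocellatus"),
#'   genus = c("Bitis", "Bitis", "Echis"),
#'   family = "Viperidae",
#'   synonyms = "",
#'   common_names = c("puff adder", "Gaboon viper", "West African carpet viper"),
#'   is_mivs = TRUE,
#'   regions = "Africa"
#' ))
#' resolve_name("puff adder", tax)
#' @export
taxonomy <- function(x) {
  required <- c("binomen", "genus", "family", "synonyms", "common_names",
                "is_mivs", "regions")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("taxonomy table is missing column(s): ", paste(missing, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("synonyms", "common_names", "regions")) {
    if (!is.list(x[[col]])) x[[col]] <- strsplit(as.character(x[[col]]), "|", fixed = TRUE)
    x[[col]] <- lapply(x[[col]], function(v) {
      v <- trimws(v)
      v[nzchar(v)]
    })
  }
  x$is_mivs <- as.logical(x$is_mivs)
  if (anyNA(x$is_mivs)) stop("is_mivs must be TRUE/FALSE for every species")
  if (anyDuplicated(x$binomen))
    stop("duplicated binomen: ",
         paste(unique(x$binomen[duplicated(x$binomen)]), collapse = ", "))
  bad_genus <- x$binomen[!startsWith(x$binomen, paste0(x$genus, " "))]
  if (length(bad_genus))
    stop("binomen does not begin with its genus: ", paste(bad_genus, collapse = ", "))
  if (any(!nzchar(x$family))) stop("family must be non-empty for every species")
  bad_region <- setdiff(unlist(x$regions), snake_regions())
  if (length(bad_region))
    stop("unknown region(s) in taxonomy: ", paste(bad_region, collapse = ", "),
         " (expected ", paste(snake_regions(), collapse = ", "), ")")
  syn <- unlist(x$synonyms)
  clash <- intersect(norm_name(syn), norm_name(x$binomen))
  if (length(clash))
    stop("synonym collides with a binomen: ", paste(clash, collapse = ", "))
  if (anyDuplicated(norm_name(syn)))
    stop("synonym listed under more than one species: ",
         paste(unique(syn[duplicated(norm_name(syn))]), collapse = ", "))
  attr(x, "index") <- build_name_index(x)
  class(x) <- c("taxonomy", "data.frame")
  x
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy:", nrow(x), "species,", length(unique(x$genus)), "genera,",
      length(unique(x$family)), "families;",
      sum(x$is_mivs), "flagged MIVS\n")
  invisible(x)
}

#' The six global regions of the challenge
#'
#' @return Character vector of the canonical region labels.
#' @export
snake_regions <- function() {
  c("Africa", "Asia", "Australasia", "Europe", "NorthAmerica", "SouthAmerica")
}

# lower-case, trim, collapse runs of whitespace
norm_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Three environments keyed by normalized name. Species-level names (binomina,
# synonyms, common names) map to the canonical binomen; genus and family names
# map to themselves. Lookup proceeds most-specific-first in resolve_name().
build_name_index <- function(x) {
  species <- new.env(parent = emptyenv())
  genus <- new.env(parent = emptyenv())
  family <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(x))) {
    for (nm in norm_name(c(x$binomen[i], x$synonyms[[i]], x$common_names[[i]])))
      assign(nm, x$binomen[i], envir = species)
  }
  for (g in unique(x$genus)) assign(norm_name(g), g, envir = genus)
  for (f in unique(x$family)) assign(norm_name(f), f, envir = family)
  list(species = species, genus = genus, family = family)
}

tax_row <- function(taxonomy, binomen) {
  i <- match(binomen, taxonomy$binomen)
  if (is.na(i)) stop("species not in taxonomy: ", binomen)
  taxonomy[i, , drop = FALSE]
}

#' Resolve a free-text identification against a taxonomy
#'
#' Matching is case-insensitive, trims and collapses whitespace, and resolves
#' synonyms and common names to the canonical binomen. The returned rank is
#' the most specific level the entered name denotes: a binomen, synonym or
#' common name resolves to species; a bare genus name to genus; a family name
#' to family. Anything else (including a skip, coded as `NA` or the empty
#' string) resolves to rank `"none"` — unresolvable input is a valid outcome,
#' not an error. No fuzzy matching is attempted: the challenge interface used
#' a drop-down, so entries are expected verbatim.
#'
#' @param raw A single free-text answer, or `NA`/`""` for a skip.
#' @param taxonomy A [taxonomy()] object.
#' @return A list of class `name_match` with elements `rank` (one of
#'   `"species"`, `"genus"`, `"family"`, `"none"`), `binomen`, `genus`,
#'   `family` (canonical names, `NA` where not implied by the rank).
#' @export
resolve_name <- function(raw, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy"), length(raw) == 1L)
  idx <- attr(taxonomy, "index")
  none <- structure(list(rank = "none", binomen = NA_character_,
                         genus = NA_character_, family = NA_character_),
                    class = "name_match")
  if (is.na(raw) || !nzchar(trimws(raw))) return(none)
  key <- norm_name(raw)
  hit <- get0(key, envir = idx$species, inherits = FALSE)
  if (!is.null(hit)) {
    row <- tax_row(taxonomy, hit)
    return(structure(list(rank = "species", binomen = hit,
                          genus = row$genus, family = row$family),
                     class = "name_match"))
  }
  hit <- get0(key, envir = idx$genus, inherits = FALSE)
  if (!is.null(hit))
    return(structure(list(rank = "genus", binomen = NA_character_, genus = hit,
                          family = taxonomy$family[match(hit, taxonomy$genus)]),
                     class = "name_match"))
  hit <- get0(key, envir = idx$family, inherits = FALSE)
  if (!is.null(hit))
    return(structure(list(rank = "family", binomen = NA_character_,
                          genus = NA_character_, family = hit),
                     class = "name_match"))
  none
}

#' @export
print.name_match <- function(x, ...) {
  cat("<name_match> rank:", x$rank)
  if (x$rank != "none")
    cat(" [", paste(stats::na.omit(c(x$binomen, x$genus, x$family)),
                    collapse = " / "), "]")
  cat("\n")
  invisible(x)
}

#' Ordinal accuracy score of a resolved identification
#'
#' Identifications are scored on a four-point ordinal scale: 0 = incorrect or
#' skipped, 1 = family correct (but not genus), 2 = genus correct (but not
#' species), 3 = species binomen correct. A bare genus answer can score at
#' most 2 and a bare family answer at most 1, even for monotypic taxa: the
#' scale keys on the rank actually entered.
#'
#' @param match A `name_match` from [resolve_name()], or a raw string/`NA`
#'   which is resolved first.
#' @param true_species Canonical binomen of the depicted species; must exist
#'   in `taxonomy`.
#' @param taxonomy A [taxonomy()] object.
#' @return Integer score in `0:3`.
#' @examples
#' tax <- example_taxonomy()
#' score_response("Bitis gabonica", "Bitis arietans", tax)  # congener -> 2
#' score_response("Echis ocellatus", "Bitis arietans", tax) # confamilial -> 1
#' score_response(NA, "Bitis arietans", tax)                # skip -> 0
#' @export
score_response <- function(match, true_species, taxonomy) {
  if (!inherits(match, "name_match")) match <- resolve_name(match, taxonomy)
  truth <- tax_row(taxonomy, true_species)
  if (match$rank == "none") return(0L)
  if (match$rank == "species" && match$binomen == truth$binomen) return(3L)
  if (match$rank %in% c("species", "genus") &&
      !is.na(match$genus) && match$genus == truth$genus) return(2L)
  if (!is.na(match$family) && match$family == truth$family) return(1L)
  0L
}

# MIVS status of the taxon an answer denotes. A genus- or family-level answer
# is treated as venomous iff that taxon contains at least one MIVS species.
mivs_status <- function(match, taxonomy) {
  switch(match$rank,
         species = taxonomy$is_mivs[match(match$binomen, taxonomy$binomen)],
         genus = any(taxonomy$is_mivs[taxonomy$genus == match$genus]),
         family = any(taxonomy$is_mivs[taxonomy$family == match$family]),
         none = NA)
}

#' Medical-importance (MIVS) correctness of an identification
#'
#' `TRUE` iff the MIVS status of the answered taxon equals the MIVS status of
#' the true species. Genus- and family-level answers carry the status of that
#' higher taxon (venomous iff it contains at least one MIVS species). Skips
#' and unresolvable answers count as incorrect, mirroring the pooling of
#' skips with wrong answers on the ordinal scale.
#'
#' @inheritParams score_response
#' @return Logical.
#' @export
score_mivs <- function(match, true_species, taxonomy) {
  if (!inherits(match, "name_match")) match <- resolve_name(match, taxonomy)
  if (match$rank == "none") return(FALSE)
  status <- mivs_status(match, taxonomy)
  isTRUE(status == taxonomy$is_mivs[match(true_species, taxonomy$binomen)])
}

#' Taxa-repeat covariate: prior exposures to the same species
#'
#' For each response, the number of earlier photos of the same true species
#' the participant had already seen within the challenge (first exposure =
#' 0). "Earlier" is defined by the per-participant presentation order.
#'
#' @param responses Data frame with columns `participant_id`, `photo_id`,
#'   `true_species`, `order_index`.
#' @return Integer vector aligned with the rows of `responses`.
#' @export
compute_taxa_repeat <- function(responses) {
  need <- c("participant_id", "photo_id", "true_species", "order_index")
  missing <- setdiff(need, names(responses))
  if (length(missing))
    stop("responses are missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(responses$participant_id, responses$photo_id,
               responses$order_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (participant, photo, order) rows at positions: ",
         paste(which(duplicated(key) | duplicated(key, fromLast = TRUE)),
               collapse = ", "))
  ord_key <- paste(responses$participant_id, responses$order_index, sep = "\r")
  if (anyDuplicated(ord_key))
    stop("duplicated presentation order within a participant")
  o <- order(responses$participant_id, responses$order_index)
  grp <- paste(responses$participant_id[o], responses$true_species[o], sep = "\r")
  rep_count <- stats::ave(seq_along(o), grp, FUN = seq_along) - 1L
  out <- integer(nrow(responses))
  out[o] <- as.integer(rep_count)
  out
}

#' Score a full response table
#'
#' Resolves every submitted answer, assigns ordinal and MIVS scores, and
#' appends the taxa-repeat covariate.
#'
#' @param responses Response table as returned by [read_responses()] or
#'   [simulate_challenge()] (after [attach_answer_strings()]): columns
#'   `participant_id`, `home_region`, `photo_id`, `true_species`,
#'   `photo_region`, `quality`, `order_index`, `answer_raw`.
#' @param taxonomy A [taxonomy()] object covering every `true_species`.
#' @return The input with columns `match_rank`, `answer_binomen`,
#'   `answer_genus`, `answer_family`, `score`, `mivs_correct`, `taxa_repeat`
#'   added.
#' @export
score_responses <- function(responses, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  unknown <- setdiff(unique(responses$true_species), taxonomy$binomen)
  if (length(unknown))
    stop("true species not in taxonomy: ", paste(unknown, collapse = ", "))
  matches <- lapply(responses$answer_raw, resolve_name, taxonomy = taxonomy)
  responses$match_rank <- vapply(matches, `[[`, "", "rank")
  responses$answer_binomen <- vapply(matches, `[[`, "", "binomen")
  responses$answer_genus <- vapply(matches, `[[`, "", "genus")
  responses$answer_family <- vapply(matches, `[[`, "", "family")
  responses$score <- vapply(seq_len(nrow(responses)), function(i) {
    score_response(matches[[i]], responses$true_species[i], taxonomy)
  }, integer(1))
  responses$mivs_correct <- vapply(seq_len(nrow(responses)), function(i) {
    score_mivs(matches[[i]], responses$true_species[i], taxonomy)
  }, logical(1))
  responses$taxa_repeat <- compute_taxa_repeat(responses)
  responses
}

#' Small worked-example taxonomy
#'
#' A handful of well-known snakes (puff adder, Gaboon viper, saw-scaled
#' viper, coralsnakes and their mimics, rattlesnakes, a boa and a python)
#' used in examples and documentation. Read from the package's bundled
#' taxonomy file.
#'
#' @return A [taxonomy()] object.
#' @export
example_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "example_taxonomy.csv",
                            package = "snakeid", mustWork = TRUE))
}
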