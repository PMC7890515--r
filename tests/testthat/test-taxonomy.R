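test_that("free-text names resolve at the most specific rank they denote", {
  tax <- example_taxonomy()
  m <- resolve_name("puff adder", tax)
  expect_equal(m$rank, "species")
  expect_equal(m$binomen, "Bitis arietans")
  expect_equal(resolve_name("Viperidae", tax)$rank, "family")
  expect_equal(resolve_name("Bitis", tax)$rank, "genus")
  expect_equal(resolve_name(NA, tax)$rank, "none")
  expect_equal(resolve_name("", tax)$rank, "none")
  expect_equal(resolve_name("not a snake", tax)$rank, "none")
  # case and whitespace insensitivity
  m2 <- resolve_name("  bitis   ARIETANS ", tax)
  expect_equal(m2$rank, "species")
  expect_equal(m2$binomen, "Bitis arietans")
  # synonyms and common names resolve to the canonical binomen
  expect_equal(resolve_name("Constrictor constrictor", tax)$binomen,
               "Boa constrictor")
})

test_that("ordinal scores follow the four-point scale", {
  tax <- toy_taxonomy()
  expect_identical(score_response("Bitis arietans", "Bitis arietans", tax), 3L)
  expect_identical(score_response("Bitis gabonica", "Bitis arietans", tax), 2L)
  expect_identical(score_response("Echis ocellatus", "Bitis arietans", tax), 1L)
  expect_identical(score_response(NA, "Bitis arietans", tax), 0L)
  expect_identical(score_response("Naja naja", "Bitis arietans", tax), 0L)
  # bare genus and family answers cap at 2 and 1
  expect_identical(score_response("Bitis", "Bitis arietans", tax), 2L)
  expect_identical(score_response("Viperidae", "Bitis arietans", tax), 1L)
  # genus answers never reach 3, even for a monotypic genus
  expect_identical(score_response("Boa", "Boa constrictor", tax), 2L)
  expect_error(score_response("Bitis", "Vipera berus", tax), "not in taxonomy")
})

test_that("scores are total on 0..3 and hierarchy-consistent under synonyms", {
  sim <- shared_sim()
  tax <- sim$taxonomy
  scored <- shared_scored()
  expect_true(all(scored$score %in% 0:3))
  # score 3 implies genus and family also correct
  i3 <- which(scored$score == 3)
  expect_true(all(scored$answer_genus[i3] ==
                    tax$genus[match(scored$true_species[i3], tax$binomen)]))
  # synonym invariance: swapping an answer for a listed synonym keeps the score
  with_syn <- which(lengths(tax$synonyms) > 0)
  for (i in with_syn[seq_len(min(5, length(with_syn)))] ) {
    truth <- sample(tax$binomen, 1)
    expect_identical(score_response(tax$binomen[i], truth, tax),
                     score_response(tax$synonyms[[i]][1], truth, tax))
  }
})

test_that("MIVS correctness compares the answered taxon's status to the truth", {
  tax <- example_taxonomy()
  # harmless kingsnake answered for a coralsnake: wrong about medical status
  expect_false(score_mivs("Lampropeltis getula", "Micrurus diastema", tax))
  expect_true(score_mivs("Micrurus fulvius", "Micrurus diastema", tax))
  expect_true(score_mivs("Micrurus diastema", "Micrurus diastema", tax))
  # two MIVS species in different families still agree on status
  expect_true(score_mivs("Naja naja", "Bitis arietans", tax))
  # genus/family answers take the status of the higher taxon
  expect_true(score_mivs("Micrurus", "Micrurus diastema", tax))
  expect_true(score_mivs("Boidae", "Boa constrictor", tax))
  expect_false(score_mivs("Boidae", "Bitis arietans", tax))
  # a family containing MIVS counts as venomous even when genus is harmless
  expect_true(score_mivs("Colubridae", "Dispholidus typus", tax))
  # skips are always incorrect
  expect_false(score_mivs(NA, "Bitis arietans", tax))
  expect_false(score_mivs("", "Boa constrictor", tax))
})

test_that("taxa-repeat counts prior exposures to the same species", {
  r <- data.frame(
    participant_id = "u1",
    photo_id = paste0("p", 1:6),
    true_species = c("A", "A", "B", "A", "B", "A"),
    order_index = 1:6)
  expect_identical(compute_taxa_repeat(r), c(0L, 1L, 0L, 2L, 1L, 3L))
  # order column, not row order, defines "earlier"
  shuffled <- r[c(4, 1, 6, 2, 5, 3), ]
  expect_identical(compute_taxa_repeat(shuffled),
                   c(2L, 0L, 3L, 1L, 1L, 0L))
  expect_error(compute_taxa_repeat(rbind(r, r[1, ])), "duplicated")
})

test_that("taxa-repeat matches a brute-force prefix scan on random sequences", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    r <- data.frame(
      participant_id = sample(c("a", "b", "c"), n, replace = TRUE),
      true_species = sample(LETTERS[1:6], n, replace = TRUE),
      stringsAsFactors = FALSE)
    r$order_index <- stats::ave(seq_len(n), r$participant_id,
                                FUN = sample)
    r$photo_id <- paste0("p", seq_len(n))
    got <- compute_taxa_repeat(r)
    brute <- vapply(seq_len(n), function(i) {
      sum(r$participant_id == r$participant_id[i] &
            r$true_species == r$true_species[i] &
            r$order_index < r$order_index[i])
    }, 0L)
    expect_identical(got, brute)
    # per-participant totals: a species seen k times contributes 0+1+...+(k-1)
    for (p in unique(r$participant_id)) {
      sel <- r$participant_id == p
      k <- table(r$true_species[sel])
      expect_equal(sum(got[sel]), sum(choose(k, 2)))
    }
  }
})

test_that("taxonomy validation rejects malformed tables", {
  base <- data.frame(binomen = "Bitis arietans", genus = "Bitis",
                     family = "Viperidae", synonyms = "", common_names = "",
                     is_mivs = TRUE, regions = "Africa",
                     stringsAsFactors = FALSE)
  bad <- base; bad$binomen <- "Vipera arietans"
  expect_error(taxonomy(bad), "does not begin with its genus")
  bad <- base; bad$family <- ""
  expect_error(taxonomy(bad), "family")
  bad <- base; bad$regions <- "Atlantis"
  expect_error(taxonomy(bad), "unknown region")
  two <- rbind(base, base)
  expect_error(taxonomy(two), "duplicated binomen")
  # synonym colliding with another species' binomen
  other <- base
  other$binomen <- "Bitis gabonica"; other$synonyms <- "Bitis arietans"
  expect_error(taxonomy(rbind(base, other)), "collides")
})
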