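# Shared fixtures, built once per test run. Sizes are kept at desk scale;
# the simulated cohorts reuse the generator's default latent scale unless a
# test needs a specific structure.

.fixtures <- new.env()

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# a compact three-family challenge with all model ingredients present
small_sim_config <- function(seed = 101, n_participants = 20,
                             photos_per_participant = 30) {
  sim_config(
    n_participants = n_participants, n_species = 12, photos_per_species = 3,
    photos_per_participant = photos_per_participant,
    families = c(Boidae = 4, Colubridae = 4, Viperidae = 4),
    regions = c(Africa = 4, Asia = 4, NorthAmerica = 4),
    home_region_dist = c(Africa = 0.3, Asia = 0.3, NorthAmerica = 0.4),
    beta_family = c(Colubridae = -1.97, Viperidae = -1.09),
    beta_region = c(Asia = -0.09, NorthAmerica = 0.00),
    beta_home_x_region = c(Asia = -2.17, NorthAmerica = -1.73),
    seed = seed)
}

shared_sim <- function() memo("sim", {
  attach_answer_strings(simulate_challenge(small_sim_config()), seed = 202)
})

shared_scored <- function() memo("scored", {
  sim <- shared_sim()
  score_responses(sim$responses, sim$taxonomy)
})

shared_split <- function() memo("split", {
  split_train_test(shared_scored(), 0.8, seed = 303)
})

# one moderate hierarchical fit reused across method, selection and summary
# tests
shared_fit <- function() memo("fit", {
  sim <- shared_sim()
  grm(shared_split()$train, sim$taxonomy, model = "home_x_region",
      chains = 2, iter = 250, warmup = 300, seed = 404)
})

# a tiny taxonomy handy for hand-computed scoring examples
toy_taxonomy <- function() {
  taxonomy(data.frame(
    binomen = c("Bitis arietans", "Bitis gabonica", "Echis ocellatus",
                "Naja naja", "Boa constrictor", "Python sebae"),
    genus = c("Bitis", "Bitis", "Echis", "Naja", "Boa", "Python"),
    family = c("Viperidae", "Viperidae", "Viperidae", "Elapidae",
               "Boidae", "Pythonidae"),
    synonyms = c("", "", "", "", "Constrictor constrictor", ""),
    common_names = c("puff adder", "Gaboon viper", "", "Indian cobra",
                     "boa constrictor", ""),
    is_mivs = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    regions = c("Africa", "Africa", "Africa", "Asia", "SouthAmerica",
                "Africa"),
    stringsAsFactors = FALSE))
}
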