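# shared fixtures, built lazily and cached for the whole test run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# ~2-generation pedigree with 96 phenotyped offspring
small_ped <- function() {
  fixture("small_ped", function() {
    simulate_pedigree(n_generations = 2, n_sires = 4, dams_per_sire = 3,
                      offspring_per_dam = 8, seed = 101)
  })
}

small_A <- function() {
  fixture("small_A", function() additive_relationship_matrix(small_ped()))
}

# complete small study (96 phenotyped fish, all assays)
small_study <- function() {
  fixture("small_study", function() {
    simulate_study(ped = small_ped(), A = small_A(), seed = 202,
                   include_all = TRUE)
  })
}
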