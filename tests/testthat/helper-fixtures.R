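# Small in-code fixtures shared across test files.

# Write a census data frame to a temp CSV and return the path.
census_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal valid 3-stem census.
tiny_census <- function() {
  data.frame(tag = c("T1", "T2", "T3"),
             species = c("SP1", "SP1", "SP2"),
             dbh = c(7.5, 22, 41),
             stringsAsFactors = FALSE)
}

tiny_traits <- function() {
  tr <- data.frame(species = c("SP1", "SP2"),
                   genus = c("GenA", "GenB"),
                   family = c("FamA", "FamB"),
                   wsg = c(0.62, 0.48),
                   wsg_source = "field_sample",
                   stringsAsFactors = FALSE)
  tr$dispersal_groups <- list(c("gibbon", "wind"), "smaller_birds")
  tr
}

# Three-species community with a known expectation structure: a
# primate-dispersed and a terrestrial-mammal-dispersed hardwood species over
# a soft wind-dispersed matrix, all stems one diameter.
three_species_community <- function(n_each = 10, dbh = 10) {
  trees <- data.frame(
    tag = sprintf("S%03d", seq_len(4 * n_each)),
    species = rep(c("PRI", "TER", "WIN", "WIN"), each = n_each),
    dbh = dbh, stringsAsFactors = FALSE)
  traits <- data.frame(species = c("PRI", "TER", "WIN"),
                       genus = paste0("G", 1:3),
                       family = paste0("F", 1:3),
                       wsg = c(0.8, 0.75, 0.5),
                       wsg_source = "field_sample",
                       stringsAsFactors = FALSE)
  traits$dispersal_groups <- list("gibbon", "terrestrial_mammals", "wind")
  list(trees = trees, traits = traits)
}

# Random dispersal-group sets for property-style classification tests.
random_group_sets <- function(n, seed = 1) {
  set.seed(seed)
  codes <- dispersal_group_codes()
  lapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)
    sample(codes, k)
  })
}
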