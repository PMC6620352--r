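test_that("read_census accepts valid rows and rejects bad dbh with reasons", {
  path <- census_csv(tiny_census())
  res <- read_census(path)
  expect_equal(res$n_accepted, 3L)
  expect_equal(res$n_rejected, 0L)
  expect_equal(res$trees$tag, c("T1", "T2", "T3"))
  expect_equal(res$trees$dbh, c(7.5, 22, 41))

  bad <- tiny_census()
  bad$dbh <- c("7.5", "NA", "-3")
  res <- read_census(census_csv(bad))
  expect_equal(res$n_accepted, 1L)
  expect_equal(res$n_rejected, 2L)
  expect_setequal(res$rejected$reason, c("non-numeric dbh", "non-positive dbh"))
})

test_that("read_census errors on duplicate tags and missing columns", {
  dup <- tiny_census()
  dup$tag <- c("T1", "T1", "T3")
  expect_error(read_census(census_csv(dup)), "T1")

  nocol <- tiny_census()[, c("tag", "dbh")]
  expect_error(read_census(census_csv(nocol)), "species")

  expect_error(read_census(tempfile()), "not found")
})

test_that("column dialect maps nonstandard headers, including from YAML", {
  df <- tiny_census()
  names(df) <- c("StemTag", "sp_code", "DBH_cm")
  path <- census_csv(df)
  dialect <- list(tag = "StemTag", species = "sp_code", dbh = "DBH_cm")
  res <- read_census(path, dialect = dialect)
  expect_equal(res$trees$dbh, c(7.5, 22, 41))

  ypath <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(columns = dialect), ypath)
  res2 <- read_census(path, dialect = ypath)
  expect_identical(res$trees, res2$trees)
})

test_that("traits parse disperser-group lists and flag unknown codes", {
  tr <- tiny_traits()
  path <- tempfile(fileext = ".csv")
  write_traits(tr, path)
  back <- read_traits(path)
  expect_equal(back$dispersal_groups[[1]], c("gibbon", "wind"))

  txt <- "species,genus,family,wsg,dispersal_groups\nSP1,GenA,FamX,0.62,gibbon|pterodactyl\n"
  bad <- tempfile(fileext = ".csv"); writeLines(txt, bad)
  expect_error(read_traits(bad), "pterodactyl")

  txt2 <- "species,genus,family,wsg,dispersal_groups\nSP1,GenA,FamX,0.62,\n"
  empty <- tempfile(fileext = ".csv"); writeLines(txt2, empty)
  expect_error(read_traits(empty), "empty")
  coerced <- read_traits(empty, empty_groups = "unclassified")
  expect_equal(coerced$dispersal_groups[[1]], "unclassified")
})

test_that("census and trait tables round-trip through write/read", {
  syn <- generate_community(synth_config(n_species = 40, n_stems = 400),
                            seed = 7)
  cpath <- tempfile(fileext = ".csv")
  tpath <- tempfile(fileext = ".csv")
  write_census(syn$trees, cpath)
  write_traits(syn$traits, tpath)
  back_c <- read_census(cpath)
  back_t <- read_traits(tpath)
  expect_equal(back_c$trees$tag, syn$trees$tag)
  expect_equal(back_c$trees$species, syn$trees$species)
  expect_equal(back_c$trees$dbh, syn$trees$dbh, tolerance = 1e-12)
  expect_equal(back_t$species, syn$traits$species)
  expect_equal(back_t$wsg, syn$traits$wsg, tolerance = 1e-12)
  expect_equal(back_t$dispersal_groups, syn$traits$dispersal_groups)
})

test_that("minimum-dbh filter is inclusive, idempotent and monotone", {
  trees <- data.frame(tag = c("a", "b", "c"), species = "SP1",
                      dbh = c(4.9, 5.0, 12.0))
  out <- filter_min_dbh(trees)
  expect_equal(out$dbh, c(5.0, 12.0))
  expect_equal(nrow(filter_min_dbh(trees[0, ])), 0L)
  expect_identical(filter_min_dbh(out), out)

  syn <- generate_community(synth_config(n_species = 20, n_stems = 300),
                            seed = 3)
  expect_equal(nrow(filter_min_dbh(syn$trees, 1)), nrow(syn$trees))
  sizes <- vapply(c(5, 10, 20, 40, 80),
                  function(m) nrow(filter_min_dbh(syn$trees, m)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("unresolved species abort in strict mode, drop-and-log otherwise", {
  trees <- tiny_census()
  traits <- tiny_traits()[1, , drop = FALSE]  # SP2 missing
  expect_error(resolve_species(trees, traits), "SP2")
  out <- resolve_species(trees, traits, strict = FALSE)
  expect_equal(out$species, c("SP1", "SP1"))
  expect_equal(attr(out, "dropped")$species, "SP2")
})
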