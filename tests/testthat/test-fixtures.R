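test_that("the packaged chronogram carries the published clade ages", {
  tr <- magnolia_chronogram()
  expect_equal(ape::Ntip(tr), 39)
  ages <- node_ages(tr)
  expect_equal(max(ages), 92.92)
  mrca_age <- function(tips) unname(ages[ape::getMRCA(tr, tips)])
  # crown Magnolia: everything but the outgroup
  expect_equal(mrca_age(setdiff(tr$tip.label, "Liriodendron_tulipifera")), 44.02)
  talauma <- paste0("Magnolia_", c(
    "allenii", "dodecapetala", "kichuana", "lacandonica", "macrocarpa",
    "mexicana", "ofeliae", "ovata", "pastazaensis", "rimachii", "silvioi",
    "virolinensis", "wetteri", "wolfii", "zamorana", "zoquepopolucae",
    "emarginata", "splendens", "bankardiorum", "coronata", "jaenensis",
    "ptaritepuiana"))
  expect_equal(length(talauma), 22)
  expect_equal(mrca_age(talauma), 35.97)
  expect_equal(mrca_age(c("Magnolia_emarginata", "Magnolia_splendens")), 10.9)
  expect_equal(mrca_age(c("Magnolia_acuminata", "Magnolia_biondii")), 9.7)
  expect_equal(mrca_age(c("Magnolia_sharpii", "Magnolia_panamensis")), 13.83)
  expect_equal(mrca_age(c("Magnolia_grandiflora", "Magnolia_vovidesii")), 6.0)
  # interpolated nodes are strictly younger than their parents
  for (i in seq_len(nrow(tr$edge)))
    expect_lt(ages[tr$edge[i, 2]], ages[tr$edge[i, 1]])
})

test_that("fixture geography codes all 39 taxa into the 10 areas", {
  geo <- magnolia_geography()
  ss <- attr(geo, "space")
  expect_equal(length(geo), 39)
  expect_equal(length(ss$areas), 10)
  expect_equal(ss$n_states, 56)
  expect_true(all(lengths(ss$sets[as.integer(geo)]) <= 2))
  lab <- function(t) ss$labels[geo[[t]]]
  expect_equal(lab("Magnolia_splendens"), "Caribbean")
  expect_equal(lab("Magnolia_grandiflora"), "Nearctic")
  expect_equal(lab("Magnolia_henryi"), "Asia")
  expect_true(grepl("Mesoamerica|Mexican-Transition-Zone",
                    lab("Magnolia_lacandonica")))
  # tips match the chronogram
  expect_setequal(names(geo), magnolia_chronogram()$tip.label)
})

test_that("packaged fixture files match the in-code constructors", {
  ext <- system.file("extdata", package = "decstrat")
  tr_file <- read_chronogram(file.path(ext, "magnolia_chronogram.nwk"))
  tr <- magnolia_chronogram()
  expect_equal(sort(tr_file$tip.label), sort(tr$tip.label))
  expect_lt(max(abs(sort(node_ages(tr_file)) - sort(node_ages(tr)))), 1e-6)
  geo_file <- read_geography(file.path(ext, "magnolia_geography.txt"),
                             magnolia_state_space())
  geo <- magnolia_geography()
  expect_identical(as.integer(geo_file[names(geo)]), as.integer(geo))
  gz <- utils::read.csv(file.path(ext, "magnolia_gazetteer.csv"))
  expect_setequal(gz$taxon, names(geo))
  ss <- magnolia_state_space()
  for (i in seq_len(nrow(gz)))
    expect_equal(range_index(ss, trimws(strsplit(gz$areas[i], ",")[[1]])),
                 geo[[gz$taxon[i]]])
})

test_that("fixture files can be materialized into a working directory", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  expect_true(all(file.exists(paths)))
  sc <- read_scenario(file.path(dir, "scenario_closing_americas.txt"))
  expect_equal(multiplier(sc, "Mesoamerica", "Pacific", 25), 0.01)
})
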