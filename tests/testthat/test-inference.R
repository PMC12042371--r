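test_that("pruning matches exhaustive enumeration on small instances", {
  bf <- brute_force_biogeo(tree4, geo4_2, "DEC", 0, d = 0.2, e = 0.1)
  ll <- biogeo_loglik(tree4, geo4_2, "DEC", d = 0.2, e = 0.1)
  expect_equal(ll, bf$lnL, tolerance = 1e-10)
  anc <- ancestral_ranges(tree4, geo4_2, "DEC", params = c(d = 0.2, e = 0.1))
  expect_lt(max(abs(unname(anc) - bf$marg)), 1e-8)
})

test_that("stratified +J pruning and marginals match enumeration for all bases", {
  conn <- connectivity_spec(c("A", "B", "C"), adjacent = rbind(c("A", "B")))
  sc <- build_scenario("panama", c("A", "B", "C"), conn,
                       strata = make_strata(c(0, 1.2, 10)),
                       gateway = c("A", "C"))
  for (base in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    bf <- brute_force_biogeo(tree4, geo4_3, base, 0.7, d = 0.15, e = 0.05,
                             scenario = sc)
    ll <- biogeo_loglik(tree4, geo4_3, paste0(base, "+J"), scenario = sc,
                        d = 0.15, e = 0.05, j = 0.7)
    expect_equal(ll, bf$lnL, tolerance = 1e-8)
    anc <- ancestral_ranges(tree4, geo4_3, paste0(base, "+J"), scenario = sc,
                            params = c(d = 0.15, e = 0.05, j = 0.7))
    expect_lt(max(abs(unname(anc) - bf$marg)), 1e-8)
  }
})

test_that("survival closed form holds on a single-area cherry", {
  ss1 <- build_state_space("A", 1)
  tr <- read_chronogram("(t1:2,t2:2);")
  geo <- geography(list(t1 = "A", t2 = "A"), ss1)
  # both daughter lineages must avoid extirpation for 2 my each
  ll <- biogeo_loglik(tr, geo, "DEC", d = 0, e = 0.1, root_prior = c(0, 1))
  expect_equal(ll, -2 * 0.1 * 2, tolerance = 1e-10)
})

test_that("a +J model at j = 0 reproduces the base likelihood", {
  ll0 <- biogeo_loglik(tree4, geo4_3, "DEC", d = 0.1, e = 0.05)
  llj <- biogeo_loglik(tree4, geo4_3, "DEC+J", d = 0.1, e = 0.05, j = 0)
  expect_equal(ll0, llj, tolerance = 1e-10)
})

test_that("likelihood is invariant to stratification with identical multipliers", {
  tr <- simulate_yule_tree(15, 0.3, seed = 3)
  ss <- build_state_space(c("A", "B", "C"), 2)
  sim <- simulate_ranges(tr, "DEC", d = 0.2, e = 0.05, space = ss,
                         root_range = "A", seed = 5)
  root_age <- max(node_ages(tr))
  sc1 <- build_scenario("null", ss$areas,
                        strata = make_strata(c(0, root_age + 1)))
  sc5 <- build_scenario("null", ss$areas,
                        strata = make_strata(c(0, root_age / 5 * (1:4), root_age + 1)))
  l1 <- biogeo_loglik(tr, sim$geography, "DEC", scenario = sc1, d = 0.11, e = 0.07)
  l5 <- biogeo_loglik(tr, sim$geography, "DEC", scenario = sc5, d = 0.11, e = 0.07)
  expect_equal(l1, l5, tolerance = 1e-10)
})

test_that("likelihood is invariant to taxon order and child swaps", {
  ll <- biogeo_loglik(tree4, geo4_3, "DIVALIKE", d = 0.2, e = 0.1)
  geo_perm <- geography(as.integer(geo4_3)[c(3, 1, 4, 2)] |>
                          stats::setNames(names(geo4_3)[c(3, 1, 4, 2)]),
                        attr(geo4_3, "space"))
  expect_equal(biogeo_loglik(tree4, geo_perm, "DIVALIKE", d = 0.2, e = 0.1),
               ll, tolerance = 1e-12)
  swapped <- read_chronogram("((t4:0.8,t3:0.8):1.7,(t2:1,t1:1):1.5);")
  expect_equal(biogeo_loglik(swapped, geo4_3, "DIVALIKE", d = 0.2, e = 0.1),
               ll, tolerance = 1e-12)
})

test_that("impossible data yield -Inf rather than an error", {
  ss1 <- build_state_space(c("A", "B"), 1)
  tr <- read_chronogram("(t1:1,t2:1);")
  geo <- geography(list(t1 = "A", t2 = "B"), ss1)
  # d = 0 and max range 1: the two tips can never occupy different areas
  expect_identical(biogeo_loglik(tr, geo, "BAYAREALIKE", d = 0, e = 0.1),
                   -Inf)
})

test_that("AICc and Akaike weights follow the formulas", {
  expect_equal(aicc(-100, 2, 39), 204 + 12 / 36)
  expect_equal(aicc(-100, 3, 39), 206 + 24 / 35)
  df <- data.frame(model = c("m1", "m2"), k = c(2, 2),
                   AICc = c(100, 102))
  w <- model_weights(df)
  expect_equal(w$AICc_wt, c(1 / (1 + exp(-1)), 1 - 1 / (1 + exp(-1))),
               tolerance = 1e-5)
  expect_equal(round(w$AICc_wt, 5), c(0.73106, 0.26894))
  expect_equal(sum(w$AICc_wt), 1, tolerance = 1e-9)
  w1 <- model_weights(df[1, ])
  expect_equal(w1$AICc_wt, 1)
  dfe <- data.frame(model = c("a", "b", "c"), k = 2, AICc = c(50, 50, 50))
  expect_equal(model_weights(dfe)$AICc_wt, rep(1 / 3, 3))
})

test_that("ML fitting recovers the no-change limit and nests +J", {
  ss <- build_state_space(c("A", "B"), 2)
  tr <- simulate_yule_tree(12, 0.25, seed = 21)
  sim <- simulate_ranges(tr, "DEC", d = 0.15, e = 0.03, space = ss,
                         root_range = "A", seed = 31)
  fit <- fit_biogeo(tr, sim$geography, "DEC")
  fitj <- fit_biogeo(tr, sim$geography, "DEC+J")
  expect_gte(fitj$lnL, fit$lnL - 1e-6)
  expect_s3_class(fit, "biogeo_fit")
  expect_equal(fit$k, 2)
  expect_equal(fitj$k, 3)
  expect_equal(fit$AICc, aicc(fit$lnL, 2, 12))
  expect_named(coef(fitj), c("d", "e", "j"))
})

test_that("ancestral marginals are normalized and concentrate when data agree", {
  ss <- build_state_space(c("A", "B"), 2)
  tr <- read_chronogram("((t1:1,t2:1):1,(t3:1,t4:1):1);")
  geo <- geography(list(t1 = "A", t2 = "A", t3 = "A", t4 = "A"), ss)
  anc <- ancestral_ranges(tr, geo, "DEC", params = c(d = 1e-9, e = 1e-9))
  expect_true(all(abs(rowSums(anc) - 1) < 1e-9))
  expect_gt(anc["5", range_index(ss, "A")], 0.999)
})

test_that("the model grid runs all scenario-model combinations", {
  ss <- build_state_space(c("A", "B", "C"), 2)
  tr <- simulate_yule_tree(8, 0.3, seed = 2)
  sim <- simulate_ranges(tr, "DEC", d = 0.1, e = 0.02, space = ss,
                         root_range = "A", seed = 3)
  sc <- list(build_scenario("null", ss$areas,
                            strata = make_strata(c(0, max(node_ages(tr)) + 1))))
  g <- run_model_grid(tr, sim$geography, scenarios = sc,
                      models = c("DEC", "DEC+J", "DIVALIKE"))
  expect_s3_class(g, "biogeo_grid")
  expect_equal(nrow(g), 3)
  expect_equal(sum(g$AICc_wt), 1, tolerance = 1e-9)
  expect_true(all(diff(g$AICc) >= 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(g, f)
  expect_equal(nrow(utils::read.delim(f)), 3)
})
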