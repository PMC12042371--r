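test_that("yule simulation is deterministic and ultrametric", {
  tr <- simulate_yule_tree(2, 0.5, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  tr1 <- simulate_yule_tree(20, 0.2, seed = 99)
  tr2 <- simulate_yule_tree(20, 0.2, seed = 99)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  expect_silent(as_chronogram(tr1, tol = 1e-4))
})

test_that("mean yule root age matches the closed-form expectation", {
  lambda <- 0.2; n <- 20
  ages <- vapply(1:500, function(i)
    max(node_ages(simulate_yule_tree(n, lambda, seed = 1000 + i))), 0)
  expected <- sum(1 / (lambda * (2:n)))
  # variance of a sum of independent Exp(lambda k) epochs
  se <- sqrt(sum(1 / (lambda * (2:n))^2) / 500)
  expect_lt(abs(mean(ages) - expected), 3 * se)
})

test_that("degenerate simulation keeps every lineage in the root range", {
  ss <- build_state_space(c("A", "B"), 2)
  tr <- simulate_yule_tree(10, 0.3, seed = 4)
  sim <- simulate_ranges(tr, "BAYAREALIKE", d = 0, e = 0, space = ss,
                         root_range = "A", seed = 7)
  expect_true(all(as.integer(sim$geography) == range_index(ss, "A")))
  expect_true(all(sim$event_log$kind == "cladogenesis"))
  expect_equal(sim$rejections, 0)
})

test_that("simulations are reproducible and replay to the observed tips", {
  ss <- build_state_space(c("A", "B", "C"), 2)
  tr <- simulate_yule_tree(15, 0.25, seed = 11)
  s1 <- simulate_ranges(tr, "DEC+J", d = 0.15, e = 0.05, j = 0.3, space = ss,
                        root_range = c("A", "B"), seed = 13)
  s2 <- simulate_ranges(tr, "DEC+J", d = 0.15, e = 0.05, j = 0.3, space = ss,
                        root_range = c("A", "B"), seed = 13)
  expect_identical(s1$event_log, s2$event_log)
  expect_identical(as.integer(s1$geography), as.integer(s2$geography))
  for (seed in c(13, 29, 57)) {
    sim <- simulate_ranges(tr, "DEC", d = 0.2, e = 0.08, space = ss,
                           root_range = "A", seed = seed)
    st <- replay_events(sim)
    n <- ape::Ntip(tr)
    expect_identical(st[seq_len(n)][match(names(sim$geography), tr$tip.label)],
                     unname(as.integer(sim$geography)))
    expect_identical(st[(n + 1):(n + tr$Nnode)], unname(sim$node_states))
  }
})

test_that("under the null scenario dispersal counts scale with stratum durations", {
  # time-homogeneous process on a deep cherry: after a burn-in from the
  # deterministic root state, gain events occur at a stationary intensity,
  # so counts in equal-length windows should be binomially split 50:50
  ss <- build_state_space(c("A", "B"), 2)
  tr <- read_chronogram("(t1:10,t2:10);")
  counts <- c(young = 0, old = 0)
  for (i in 1:200) {
    sim <- simulate_ranges(tr, "DEC", d = 0.5, e = 0.25, space = ss,
                           root_range = "A", seed = 3000 + 97L * i)
    ev <- sim$event_log[sim$event_log$kind == "dispersal", ]
    counts["young"] <- counts["young"] + sum(ev$age < 4)
    counts["old"] <- counts["old"] + sum(ev$age >= 4 & ev$age < 8)
  }
  expect_gt(sum(counts), 200)
  expect_gt(stats::chisq.test(counts, p = c(0.5, 0.5))$p.value, 1e-4)
})

test_that("gateway gains track the closing_americas multiplier ratio", {
  # closing_americas structure on a 3-area subsystem so that the gateway
  # source area has high occupancy and the gain counts are informative
  areas <- c("Mesoamerica", "Pacific", "Caribbean")
  conn <- connectivity_spec(areas,
                            adjacent = rbind(c("Mesoamerica", "Pacific")),
                            water = rbind(c("Caribbean", "Mesoamerica"),
                                          c("Caribbean", "Pacific")))
  sc <- build_scenario("closing_americas", areas, conn)
  ss <- build_state_space(areas, 2)
  tr <- read_chronogram("(t1:39,t2:39);")   # spans strata 1-4
  me <- range_index(ss, "Mesoamerica")
  mp <- range_index(ss, c("Mesoamerica", "Pacific"))
  gains_old <- gains_mid <- 0
  time_old <- time_mid <- 0
  for (i in 1:150) {
    sim <- simulate_ranges(tr, "DEC", scenario = sc, d = 0.3, e = 0.05,
                           space = ss, root_range = "Mesoamerica",
                           seed = 5000 + 97L * i)
    ev <- sim$event_log
    g <- ev[ev$kind == "dispersal" & ev$from == me & ev$to == mp, ]
    gains_mid <- gains_mid + sum(g$age >= 3 & g$age < 20)
    gains_old <- gains_old + sum(g$age >= 20)
    time_mid <- time_mid + occupancy_time(sim, me, 3, 20)
    time_old <- time_old + occupancy_time(sim, me, 20, 39)
  }
  # multiplier is 0.5 in 3-20 mya and 0.01 before: per lineage-my spent in
  # the source state, gains in the older strata must be suppressed ~50-fold
  expect_gt(gains_mid, 30)
  expect_lt(gains_old / time_old, 0.2 * gains_mid / time_mid)
})

test_that("recovery experiments tabulate truth and estimates per replicate", {
  ss <- build_state_space(c("A", "B", "C"), 2)
  out <- recovery_experiment(3, n_tips = 25, d = 0.1, e = 0.02,
                             space = ss, root_range = "A", seed = 11)
  expect_equal(nrow(out), 3)
  expect_true(all(is.finite(out$est_d)))
  expect_true(all(out$true_d == 0.1))
  expect_true(is.finite(attr(out, "summary")["median_rel_err_d"]))
})
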