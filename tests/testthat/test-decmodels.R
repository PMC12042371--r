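test_that("rate matrix entries follow the DEC-family generator", {
  Q <- build_rate_matrix(space2, d = 0.1, e = 0.05)
  i <- function(a) range_index(space2, a)
  expect_equal(Q[i("A"), i(c("A", "B"))], 0.1)
  expect_equal(Q[i("A"), 1], 0.05)
  expect_equal(Q[i(c("A", "B")), i("A")], 0.05)
  expect_true(all(abs(rowSums(Q)) < 1e-10))
  expect_true(all(Q[1, ] == 0))                 # null range absorbing

  m <- matrix(1, 2, 2); m[1, 2] <- 0.01
  Qm <- build_rate_matrix(space2, 0.1, 0.05, m)
  expect_equal(Qm[i("A"), i(c("A", "B"))], 0.001)

  # a widespread source sums multiplier contributions over occupied areas
  mm <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.3, 0.2, 0.3, 1), 3, 3)
  ss3w <- build_state_space(c("A", "B", "C"), 3)
  Qw <- build_rate_matrix(ss3w, d = 0.2, e = 0, mm)
  expect_equal(Qw[range_index(ss3w, c("A", "B")), range_index(ss3w, c("A", "B", "C"))],
               0.2 * (mm[1, 3] + mm[2, 3]))
  # no gains beyond max_range_size
  Q3 <- build_rate_matrix(space3, d = 0.2, e = 0)
  expect_true(all(Q3[range_index(space3, c("A", "B")), ] == 0 |
                  seq_len(space3$n_states) %in%
                    c(range_index(space3, "A"), range_index(space3, "B"),
                      range_index(space3, c("A", "B")))))
})

test_that("rate matrix is permutation-equivariant with flat multipliers", {
  ss <- build_state_space(c("A", "B", "C"), 2)
  ssp <- build_state_space(c("C", "A", "B"), 2)
  Q <- build_rate_matrix(ss, 0.13, 0.07)
  Qp <- build_rate_matrix(ssp, 0.13, 0.07)
  perm <- vapply(ss$labels, function(l) {
    as_set <- if (l == "null") character(0) else strsplit(l, "+", fixed = TRUE)[[1]]
    which(vapply(ssp$sets, function(s) setequal(ssp$areas[s], as_set), TRUE))
  }, 0L)
  expect_equal(unname(Q), unname(Qp[perm, perm]))
})

test_that("cladogenesis tables enumerate the documented events", {
  ct <- cladogenesis_table(space2, "DEC", 0)
  a <- range_index(space2, "A")
  expect_equal(sum(ct$anc == a), 1)
  expect_equal(ct$prob[ct$anc == a], 1)
  ab <- range_index(space2, c("A", "B"))
  expect_equal(sum(ct$anc == ab), 6)
  expect_equal(unique(ct$prob[ct$anc == ab]), 1 / 6)

  ctb <- cladogenesis_table(space2, "BAYAREALIKE", 0)
  expect_equal(sum(ctb$anc == ab), 1)
  rows <- which(ctb$anc == ab)
  expect_equal(ctb$left[rows], ab)
  expect_equal(ctb$right[rows], ab)

  ctd <- cladogenesis_table(space3, "DIVALIKE", 1)
  aA <- which(ctd$anc == range_index(space3, "A"))
  expect_equal(length(aA), 5)                   # sympatry + 4 ordered jumps
  expect_equal(unique(ctd$prob[aA]), 0.2)
  # DIVALIKE forbids subset sympatry: any event that keeps the widespread
  # ancestor intact must be a founder jump into the one unoccupied area
  abi <- range_index(space3, c("A", "B"))
  ci <- range_index(space3, "C")
  abd <- which(ctd$anc == abi & ctd$left == abi)
  expect_true(all(ctd$right[abd] == ci))
})

test_that("clado probabilities are proper distributions for all models up to 5 areas", {
  ss5 <- build_state_space(letters[1:5], 5)
  for (base in c("DEC", "DIVALIKE", "BAYAREALIKE")) for (j in c(0, 0.3, 3)) {
    ct <- cladogenesis_table(ss5, base, j)
    sums <- tapply(ct$prob, ct$anc, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_setequal(as.integer(names(sums)), 2:ss5$n_states)
    expect_true(all(ct$left >= 1 & ct$left <= ss5$n_states))
    expect_true(all(ct$right >= 1 & ct$right <= ss5$n_states))
  }
})

test_that("j = 0 in a +J table reproduces the base table exactly", {
  for (base in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    base_tab <- cladogenesis_table(space3, base, 0)
    proto <- decstrat:::clado_proto(space3, base)
    j0 <- decstrat:::clado_with_j(proto, 0)
    expect_identical(base_tab[c("anc", "left", "right", "prob")],
                     j0[c("anc", "left", "right", "prob")])
  }
})

test_that("transition matrices are stochastic and match series expansion", {
  Q <- build_rate_matrix(space3, 0.17, 0.06)
  expect_equal(transition_matrix(Q, 0), diag(space3$n_states))
  P5 <- transition_matrix(Q, 5)
  expect_true(all(abs(rowSums(P5) - 1) < 1e-9))
  expect_true(all(P5 >= 0))

  set.seed(9)
  for (rep in 1:5) {
    A <- matrix(stats::rexp(16, 5), 4, 4)
    diag(A) <- 0; diag(A) <- -rowSums(A)
    t <- stats::runif(1, 0.1, 4)
    expect_lt(max(abs(transition_matrix(A, t) - series_expm(A, t))), 1e-8)
  }
})

test_that("pure-death closed form: P(single area -> null) = 1 - exp(-e t)", {
  ss1 <- build_state_space("A", 1)
  Q <- build_rate_matrix(ss1, d = 0, e = 0.1)
  for (t in c(0.5, 2, 5, 20))
    expect_equal(transition_matrix(Q, t)[2, 1], 1 - exp(-0.1 * t),
                 tolerance = 1e-10)
})

test_that("transition_set agrees with expm for many durations", {
  Q <- build_rate_matrix(build_state_space(letters[1:4], 2), 0.12, 0.05)
  dts <- c(0, 0.3, 1.7, 9)
  Ps <- decstrat:::transition_set(Q, dts)
  for (i in seq_along(dts))
    expect_lt(max(abs(Ps[[i]] - transition_matrix(Q, dts[i]))), 1e-9)
})
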