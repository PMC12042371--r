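# small reusable objects built in code at test time

space2 <- build_state_space(c("A", "B"), 2)
space3 <- build_state_space(c("A", "B", "C"), 2)

tree4 <- read_chronogram("((t1:1,t2:1):1.5,(t3:0.8,t4:0.8):1.7);")
geo4_2 <- geography(list(t1 = "A", t2 = "B", t3 = "B", t4 = c("A", "B")), space2)
geo4_3 <- geography(list(t1 = "A", t2 = "C", t3 = c("A", "B"), t4 = "B"), space3)

occupancy_time <- state_occupancy

make_locus <- function(name, taxa, len, seed) {
  with_seed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
  with_seed(seed, {
    seqs <- vapply(taxa, function(t)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
    alignment(name, seqs)
  })
}
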