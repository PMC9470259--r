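# fabricate a profile from bare records (no VM involved)
fake_profile <- function(viable, phenotype, tkey,
                         tlen = rep(100L, length(viable)),
                         io = rep(3L, length(viable))) {
  records <- data.frame(
    env_id = seq_along(viable) - 1L,
    viable = viable,
    divided = viable,
    truncated = FALSE,
    phenotype = ifelse(viable, phenotype, NA_integer_),
    transcriptome_key = tkey,
    transcriptome_length = tlen,
    io_count = io,
    io_in_repeats = ifelse(viable, 1L, NA_integer_),
    stringsAsFactors = FALSE
  )
  digiplast:::new_profile("fake", records)
}

test_that("classification covers the four quadrants and rejects the undefined case", {
  p <- fake_profile(rep(TRUE, 4), rep(5L, 4), rep("k1", 4))
  expect_equal(classify(p), "non-plastic/robust")
  expect_false(p$plastic); expect_false(p$sensitive)

  p <- fake_profile(rep(TRUE, 4), rep(5L, 4), c("k1", "k2", "k3", "k4"))
  expect_equal(classify(p), "non-plastic/sensitive")

  p <- fake_profile(rep(TRUE, 4), c(1L, 2L, 3L, 1L), rep("k1", 4))
  expect_equal(classify(p), "plastic/robust")

  p <- fake_profile(rep(TRUE, 4), c(1L, 2L, 1L, 2L), c("k1", "k2", "k1", "k2"))
  expect_equal(classify(p), "plastic/sensitive")

  p <- fake_profile(rep(FALSE, 3), rep(NA_integer_, 3), c("a", "b", "c"))
  expect_equal(p$n_phenotypes, 0)
  expect_equal(p$n_transcriptomes, 0)
  expect_error(classify(p), "unclassifiable")
  expect_error(phenotypic_uncertainty(p), "undefined")
})

test_that("counts and uncertainty use viable environments only", {
  p <- fake_profile(c(TRUE, TRUE, FALSE, FALSE),
                    c(5L, 5L, NA, NA),
                    c("k1", "k1", "kX", "kY"))
  expect_equal(p$n_phenotypes, 1)
  expect_equal(p$n_transcriptomes, 1)
  expect_true(p$viability_cost)
  expect_equal(phenotypic_uncertainty(p), 0)
})

test_that("phenotypic uncertainty matches the analytic entropy cases", {
  # identical phenotype everywhere: all p_i in {0,1} -> 0
  p <- fake_profile(rep(TRUE, 8), rep(37L, 8), rep("k", 8))
  expect_equal(phenotypic_uncertainty(p), 0)
  # exactly one operation present in half the environments -> 1/9
  p <- fake_profile(rep(TRUE, 8), rep(c(0L, 1L), 4), rep("k", 8))
  expect_equal(phenotypic_uncertainty(p), 1 / 9)
  # all nine operations each in exactly half the environments -> 1
  p <- fake_profile(rep(TRUE, 8), rep(c(0L, 511L), 4), rep("k", 8))
  expect_equal(phenotypic_uncertainty(p), 1)
})

test_that("tandem repeat detection matches the specification examples", {
  r <- tandem_repeats(c(7, 8, 9, 7, 8, 9, 7, 8, 9, 10))
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 0L)
  expect_equal(r$period, 3L)
  expect_equal(r$count, 3L)
  # strictly increasing positions: no runs
  expect_equal(nrow(tandem_repeats(0:50)), 0)
  # io counting inside runs
  r <- tandem_repeats(c(1, 2, 1, 2, 1, 2, 9),
                      letters = c("v", "y", "v", "y", "v", "y", "x"))
  expect_equal(attr(r, "io_in_repeats"), 3L)
})

test_that("tandem repeat detection equals the brute-force scan", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    x <- sample.int(sample(3:8, 1), n, replace = TRUE)
    expect_equal(as.data.frame(tandem_repeats(x)), oracle_runs(x),
                 label = paste("trace", i))
  }
  # and on a real gestation trace
  g <- make_replicator(loop_payload = "y", seed = 4)
  r <- run_gestation(g, ref_env())
  expect_lte(nrow(r$trace), 200 * 10)  # loop traces stay modest
  expect_equal(as.data.frame(tandem_repeats(r$trace$position)),
               oracle_runs(r$trace$position))
})

test_that("profiles are invariant to environment order and duplication", {
  g <- make_replicator(payload = c("y", "e", "m", "y"), seed = 5,
                       verify = FALSE)
  envs <- test_envs(15)
  p0 <- profile_genome(g, envs)
  # permuted order
  p1 <- profile_genome(g, envs[sample(nrow(envs)), ])
  # duplicated environment
  p2 <- profile_genome(g, envs[c(seq_len(nrow(envs)), 1L), ])
  for (p in list(p1, p2)) {
    expect_equal(p$n_phenotypes, p0$n_phenotypes)
    expect_equal(p$n_transcriptomes, p0$n_transcriptomes)
    expect_equal(p$uncertainty, p0$uncertainty)
    expect_equal(p$viability_cost, p0$viability_cost)
  }
})

test_that("a non-viable environment alongside viable ones implies sensitivity", {
  # a robust transcriptome forces identical viability everywhere, so any
  # genome viable somewhere and non-viable elsewhere must be sensitive
  gs <- sample_genomes(generator_config(
    n_genomes = 25, seed = 33,
    payload_mix = c(io = 1, math = 1, regulatory = 3)))
  envs <- test_envs(30)
  pop <- profile_population(gs, envs)
  seen <- FALSE
  for (p in pop) {
    if (p$viability_cost && p$n_viable > 0) {
      seen <- TRUE
      expect_true(p$sensitive)
    }
  }
  expect_true(seen)  # the regulatory-rich mix does produce viability costs
})

test_that("population summaries are consistent bookkeeping", {
  gs <- sample_genomes(generator_config(n_genomes = 20, seed = 11))
  pop <- profile_population(gs, test_envs(15))
  s <- population_summary(pop)
  expect_equal(sum(s$quadrants), 1)
  expect_equal(sum(s$quadrant_counts), s$n_classifiable)
  expect_equal(sum(s$joint), s$n)
  tbl <- profile_table(pop)
  expect_equal(nrow(tbl), 20)
  # joint table marginals equal the quadrant counts
  np <- tbl$n_phenotypes[!is.na(tbl$quadrant)]
  nt <- tbl$n_transcriptomes[!is.na(tbl$quadrant)]
  expect_equal(sum(s$quadrant_counts[c("plastic/robust", "plastic/sensitive")]),
               sum(np > 1))
  expect_equal(sum(s$quadrant_counts[c("non-plastic/sensitive",
                                       "plastic/sensitive")]),
               sum(nt > 1))
  rec <- record_table(pop)
  expect_equal(nrow(rec), 20 * 15)
})
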