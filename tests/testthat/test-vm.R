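# Instruction semantics are checked through io outputs of hand-simulated
# micro-genomes: pop on an empty stack loads 0 into BX, which makes register
# contents controllable without touching the environment stream.

run_trace <- function(lets, env = ref_env(), max_cycles = 60, start = 0) {
  run_gestation(genome(lets), env, exec_limits(max_cycles = max_cycles),
                start = start)
}

test_that("arithmetic, swap, nand and wraparound follow 32-bit semantics", {
  # pop -> BX=0; dec -> BX=2^32-1 (wraparound); swap -> CX=2^32-1, BX=0;
  # pop -> BX=0; dec -> BX=all-ones; nand -> BX = ~(BX & CX) = 0; output 0
  r <- run_trace("pnrpnuy", max_cycles = 7)
  expect_equal(r$outputs$output[1], 0)

  # inc wraps: pop -> 0, dec -> all-ones, inc -> 0
  r <- run_trace("pnmy", max_cycles = 4)
  expect_equal(r$outputs$output[1], 0)

  # small-number swap/add: BX=3 via incs, swap parks 3 in CX, rebuild BX=2,
  # add -> BX = 2 + 3 = 5; output 5
  r <- run_trace("pmmmrpmmsy", max_cycles = 10)
  expect_equal(r$outputs$output[1], 5)

  # shift-l then shift-r zero-fill: BX=1 -> 2 -> 1; dec, shift-r on all-ones
  r <- run_trace("pmlkyplnky", max_cycles = 10)
  expect_equal(r$outputs$output[1], 1)
  # (0 - 1) >> 1 = 2^31 - 1 with logical shift
  expect_equal(r$outputs$output[2], 2^31 - 1)
})

test_that("initial state pre-loads BX and both buffers from the stream", {
  w <- env_input_words(ref_env(), 5)
  r <- run_trace("yrysy", max_cycles = 5)
  # first io outputs the pre-loaded BX = word 0, checked against words 1, 2
  expect_equal(r$outputs$output[1], w[1])
  expect_equal(r$outputs$input1[1], w[2])
  expect_equal(r$outputs$input2[1], w[3])
  # io then loads word 3 into BX/input-1; swap parks it in CX;
  # second io outputs old CX (0) and loads word 4; add gives w3+w4
  expect_equal(r$outputs$output[2], 0)
  expect_equal(r$outputs$output[3], (w[4] + w[5]) %% 2^32)
})

test_that("jump-head moves the IP by CX then post-advances (hand trace)", {
  # c i h a b: nop; get-head sets CX=1; jump-head (nop-A modifier names the
  # IP) jumps 2 -> 3 then advances to 4; nop at 4; wrap to 0
  r <- run_trace("cihab", max_cycles = 8)
  expect_equal(r$trace$position, c(0, 1, 2, 4, 0, 1, 2, 4))
  expect_equal(r$trace$letter[1:4], c("c", "i", "h", "b"))
})

test_that("if-less executes the next instruction iff BX < CX (signed)", {
  # pop, dec: BX = -1 (signed) < CX = 0 -> execute the io at position 3
  r <- run_trace("pneyqq", max_cycles = 6)
  expect_equal(r$trace$position[1:5], c(0, 1, 2, 3, 4))
  # pop, inc: BX = 1 > CX = 0 -> skip the io
  r <- run_trace("pmeyqq", max_cycles = 6)
  expect_equal(r$trace$position[1:5], c(0, 1, 2, 4, 5))
})

test_that("if-n-equ executes the next instruction iff BX != CX", {
  r <- run_trace("pmdyqq", max_cycles = 6)   # BX=1, CX=0: not equal -> execute
  expect_equal(r$trace$position[1:4], c(0, 1, 2, 3))
  r <- run_trace("ppdyqq", max_cycles = 6)   # BX=0=CX -> skip
  expect_equal(r$trace$position[1:4], c(0, 1, 2, 4))
})

test_that("pop on an empty stack yields 0 and push/pop round-trips", {
  # BX=2 via incs, push, pop into BX after clearing: output 2 then 0 (empty)
  r <- run_trace("pmmoypyqpy", max_cycles = 12)
  # first io outputs BX=2 (after push); stack holds 2
  expect_equal(r$outputs$output[1], 2)
  # pop restores 2, io outputs it; then swap-stk switches to empty stack,
  # pop yields 0, io outputs 0
  expect_equal(r$outputs$output[2], 2)
  expect_equal(r$outputs$output[3], 0)
})

test_that("gestation is deterministic and trace bookkeeping is consistent", {
  g <- make_replicator(payload = c("y", "u", "y"), seed = 8)
  r1 <- run_gestation(g, env_spec(5, 42))
  r2 <- run_gestation(g, env_spec(5, 42))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$outputs, r2$outputs)
  expect_identical(r1$transcriptome_key, r2$transcriptome_key)
  expect_equal(r1$gestation_cycles, nrow(r1$trace))
  expect_equal(sum(r1$trace$letter == "y"), nrow(r1$outputs))
  tr <- transcriptome(r1)
  expect_equal(attr(tr, "length"), r1$gestation_cycles)
  expect_equal(attr(tr, "io_count"), nrow(r1$outputs))
})

test_that("a genome of only nops never divides and is not viable", {
  g <- genome(strrep("a", 100), id = "allnop")
  r <- run_gestation(g, ref_env(), exec_limits(max_cycles = 2000))
  expect_false(r$divided)
  expect_true(r$truncated)
  expect_false(is_viable(g, ref_env(), exec_limits(max_cycles = 2000)))
})

test_that("the default replicator copies itself exactly and is viable", {
  g <- make_replicator(length = 100, seed = 1, verify = FALSE)
  r <- run_gestation(g, env_spec(1, 42))
  expect_true(r$divided)
  expect_false(r$truncated)
  expect_true(r$offspring == g)
  expect_true(is_viable(g, env_spec(1, 42)))
})

test_that("viability requires a self-replicating offspring, not just a divide", {
  # h-copy a few times then divide: offspring is a fragment of nop-Cs and
  # copy machinery that cannot itself divide
  g <- genome(paste0("w", strrep("v", 12), "x", strrep("c", 30)), id = "frag")
  r <- run_gestation(g, ref_env(), exec_limits(max_cycles = 3000,
                                               min_offspring_length = 5))
  if (r$divided) {
    expect_false(is_viable(g, ref_env(),
                           exec_limits(max_cycles = 3000,
                                       min_offspring_length = 5)))
  } else {
    expect_false(is_viable(g, ref_env()))
  }
})

test_that("raising the budget preserves the outcome of a completed gestation", {
  g <- make_replicator(payload = c("y", "e", "m"), seed = 13, verify = FALSE)
  r1 <- run_gestation(g, ref_env(), exec_limits(max_cycles = 2000))
  r2 <- run_gestation(g, ref_env(), exec_limits(max_cycles = 40000))
  expect_true(r1$divided)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$transcriptome_key, r2$transcriptome_key)
})

test_that("execution is translation-equivariant for non-allocating genomes", {
  set.seed(31)
  # no h-alloc (memory extension is appended at absolute positions) and no
  # get-head/set-flow (they move absolute positions through registers, which
  # rotation necessarily relabels)
  pool <- setdiff(letters, c("w", "i", "j"))
  for (i in 1:5) {
    lets <- sample(pool, 40, replace = TRUE)
    g <- genome(lets)
    for (r in c(1, 7)) {
      gr <- rotate_genome(g, r)
      t0 <- run_gestation(g, env_spec(2, 42), exec_limits(max_cycles = 300),
                          start = r)
      t1 <- run_gestation(gr, env_spec(2, 42), exec_limits(max_cycles = 300),
                          start = 0)
      expect_equal(t1$trace$letter, t0$trace$letter)
      expect_equal(t1$trace$position, (t0$trace$position - r) %% 40)
    }
  }
})

test_that("genomes executing no regulatory instruction are robust across environments", {
  # robustness: without if-less/if-n-equ/jump-head/set-flow in the trace,
  # control flow cannot depend on register contents, so every environment
  # executes the identical step sequence with identical viability
  gs <- sample_genomes(generator_config(
    n_genomes = 8, seed = 21,
    payload_mix = c(io = 2, math = 2, regulatory = 0)))
  envs <- environment_set(100, 42)
  for (g in gs) {
    tr <- run_gestation(g, env_spec(0, 42))$trace
    expect_false(any(tr$letter %in% regulatory_letters()))
    p <- profile_genome(g, envs)
    expect_true(all(p$records$viable))
    expect_equal(p$n_transcriptomes, 1)
    expect_false(p$sensitive)
  }
})

test_that("trace export writes the CSV and JSON summaries", {
  g <- make_replicator(payload = "y", seed = 2)
  r <- run_gestation(g, ref_env())
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  export_trace(r, csv = csv, json = json)
  tr <- read.csv(csv)
  expect_equal(nrow(tr), r$gestation_cycles)
  expect_equal(names(tr), c("step", "position", "letter", "name"))
  js <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(js$length, r$gestation_cycles)
  expect_equal(js$canonical_key, r$transcriptome_key)
})
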