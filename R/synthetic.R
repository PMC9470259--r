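# Synthetic self-replicating genomes
#
# The generator emulates the structural properties of a large database of
# viable 100-instruction self-replicators: a working copy scaffold plus
# payload instructions (input-output, math, regulatory) whose composition
# controls the plasticity mechanisms present in the sample.

# Copy scaffold layout (positions in a genome of length L):
#   0: h-alloc            extend memory by L (offspring region)
#   1: h-search c a       find complement label "a b" at the genome end;
#                         flow-head lands at position L (offspring start)
#   4: mov-head c         write-head := flow-head (= L)
#   6 .. L-10-k:          nop-C padding with payload inserted (executed once
#                         on the walk towards the copy loop)
#   L-9-k: h-search       (no label) flow-head := next position (loop start)
#   loop: h-copy, [loop payload], if-label c a, h-divide, mov-head
#   L-2, L-1: a b         copy-termination label (complement of "c a")
.SCAFFOLD_PROLOGUE <- c("w", "z", "c", "a", "g", "c")

scaffold_loop <- function(loop_payload = character(0)) {
  c("z", "v", loop_payload, "f", "c", "a", "x", "g", "a", "b")
}

#' Construct a viable self-replicating genome
#'
#' Builds a genome of the given length containing a working copy scaffold
#' (allocate, label search, h-copy loop with label-terminated exit, divide)
#' with payload instructions and nop-C padding in between. Payload placed in
#' the padding region executes once per gestation (on the walk from the
#' prologue to the copy loop); payload placed inside the copy loop executes
#' once per copied instruction. Viability in the reference environment
#' (`env_id` 0 of `master_seed`) is verified by construction-time execution.
#'
#' @param length Genome length (default 100); must accommodate scaffold and
#'   payload.
#' @param payload Character vector of instruction letters inserted as one
#'   contiguous block at a seeded offset in the padding region (nops are not
#'   allowed as payload; they would act as operand modifiers of neighbouring
#'   instructions).
#' @param loop_payload Letters inserted into the copy loop body.
#' @param seed Integer seed controlling payload placement.
#' @param master_seed Master seed of the reference environment.
#' @param limits An `exec_limits()` object used for verification.
#' @param verify Check viability in the reference environment (default TRUE).
#' @return A `dg_genome`, with attribute `"payload"`.
#' @examples
#' g <- make_replicator(length = 100, payload = c("y", "u"), seed = 7)
#' @export
make_replicator <- function(length = 100, payload = character(0),
                            loop_payload = character(0), seed = 1,
                            master_seed = 42, limits = exec_limits(),
                            verify = TRUE) {
  loop <- scaffold_loop(loop_payload)
  fixed <- base::length(.SCAFFOLD_PROLOGUE) + base::length(loop)
  npad <- length - fixed - base::length(payload)
  if (npad < 1)
    stop("genome length ", length, " cannot accommodate scaffold (",
         fixed, ") plus payload (", base::length(payload), ")")
  if (any(payload %in% c("a", "b", "c")) ||
      any(loop_payload %in% c("a", "b", "c")))
    stop("nop instructions are not valid payload")
  # place payload as one contiguous block at a seeded offset in the padding
  # region: interleaved nops would act as operand modifiers of the payload
  region <- rep("c", npad + base::length(payload))
  if (base::length(payload) > 0) {
    set.seed(seed)
    at <- sample.int(npad + 1, 1)
    k <- base::length(payload)
    region[seq(at, by = 1, length.out = k)] <- payload
    # a nop right after the block would act as an operand modifier of the
    # last payload instruction; guard with the neutral swap-stk
    if (at + k <= base::length(region)) region[at + k] <- "q"
  }
  lets <- c(.SCAFFOLD_PROLOGUE, region, loop)
  g <- genome(lets, id = sprintf("synth_s%d", seed))
  attr(g, "payload") <- payload
  attr(g, "loop_payload") <- loop_payload
  if (verify && !is_viable(g, env_spec(0, master_seed), limits))
    stop("constructed genome is not viable in the reference environment ",
         "(payload derails replication); try another seed or payload")
  g
}

#' Generator configuration
#'
#' @param n_genomes Number of genomes to generate.
#' @param genome_length Genome length (default 100).
#' @param payload_mix Named weights over the payload classes `io`
#'   (input-output), `math` (nand/add/sub/inc/dec/shifts/swap/stack) and
#'   `regulatory` (environment-coupled branch and jump motifs built from
#'   if-less/if-n-equ/jump-head, fed by a fresh input word).
#' @param payload_range Range (min, max) of payload motifs per genome (a
#'   motif is one to three instructions).
#' @param loop_io_prob Probability that a genome also carries an
#'   input-output instruction inside its copy loop (executed every copy
#'   iteration), the main source of repeat-associated io executions.
#' @param seed Integer master seed of the generator.
#' @param master_seed Master seed of the reference environment family.
#' @return A list of class `dg_genconfig`.
#' @export
generator_config <- function(n_genomes = 100, genome_length = 100,
                             payload_mix = c(io = 2, math = 2, regulatory = 1),
                             payload_range = c(2, 10),
                             loop_io_prob = 0.25,
                             seed = 1, master_seed = 42) {
  stopifnot(n_genomes >= 1, genome_length >= 20,
            all(payload_mix >= 0), sum(payload_mix) > 0,
            payload_range[1] >= 0, payload_range[2] >= payload_range[1])
  nm <- names(payload_mix)
  if (!setequal(nm, c("io", "math", "regulatory")))
    stop("payload_mix must have weights named io, math, regulatory")
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = as.integer(genome_length),
                 payload_mix = payload_mix[c("io", "math", "regulatory")],
                 payload_range = as.integer(payload_range),
                 loop_io_prob = loop_io_prob,
                 seed = as.integer(seed),
                 master_seed = master_seed),
            class = "dg_genconfig")
}

# Payload is assembled from motifs, not isolated letters: a regulatory
# instruction acting on constant registers is deterministic, so environmental
# sensitivity requires coupling a fresh input word (y) into the compared or
# jumped-by register first. "y r h" (load, park in CX, jump by it) is the
# strong form: the jump target varies with the environment, which is the main
# source of environment-dependent viability failure.
.PAYLOAD_MOTIFS <- list(
  io = list("y"),
  math = as.list(c("k", "l", "m", "n", "o", "p", "q", "r", "s", "t", "u")),
  regulatory = list("e", "d", c("y", "e"), c("y", "d"), c("y", "r", "h"))
)

#' Sample a set of viable self-replicating genomes
#'
#' Draws payloads per the configured class weights, constructs replicators,
#' and keeps those viable in the reference environment. The fraction of
#' constructions discarded as non-viable is recorded in the result's
#' `"report"` attribute so that empirical quadrant fractions remain
#' interpretable.
#'
#' @param config A [generator_config()].
#' @param limits An `exec_limits()` object.
#' @return List of `dg_genome` objects (class `dg_genome_set`) with
#'   attribute `"report"` (attempted, discarded, achieved). If the retry
#'   budget (10 x n_genomes attempts) is exhausted, the achieved count is
#'   returned with a warning.
#' @export
sample_genomes <- function(config = generator_config(),
                           limits = exec_limits()) {
  stopifnot(inherits(config, "dg_genconfig"))
  w <- config$payload_mix / sum(config$payload_mix)
  out <- vector("list", config$n_genomes)
  got <- 0L
  attempts <- 0L
  budget <- 10L * config$n_genomes
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, budget)
  while (got < config$n_genomes && attempts < budget) {
    attempts <- attempts + 1L
    s <- seeds[attempts]
    set.seed(s)
    k <- sample(config$payload_range[1]:config$payload_range[2], 1)
    classes <- sample(names(w), k, replace = TRUE, prob = w)
    payload <- unlist(lapply(classes, function(cl) {
      pool <- .PAYLOAD_MOTIFS[[cl]]
      pool[[sample.int(base::length(pool), 1)]]
    }))
    loop_payload <- character(0)
    if (w["io"] > 0 && runif(1) < config$loop_io_prob)
      loop_payload <- "y"
    g <- tryCatch(
      make_replicator(config$genome_length, payload, loop_payload,
                      seed = s, master_seed = config$master_seed,
                      limits = limits),
      error = function(e) NULL)
    if (!is.null(g)) {
      got <- got + 1L
      g$id <- sprintf("synth_%04d", got)
      out[[got]] <- g
    }
  }
  if (got < config$n_genomes)
    warning("retry budget exhausted: achieved ", got, " of ",
            config$n_genomes, " genomes")
  out <- out[seq_len(got)]
  attr(out, "report") <- list(attempted = attempts,
                              discarded = attempts - got,
                              achieved = got)
  class(out) <- "dg_genome_set"
  out
}

#' @export
print.dg_genome_set <- function(x, ...) {
  rep <- attr(x, "report")
  cat("<dg_genome_set>", base::length(x), "genomes")
  if (!is.null(rep))
    cat(" (", rep$attempted, "attempted,", rep$discarded, "discarded )")
  cat("\n")
  invisible(x)
}

#' Write a genome set with its manifest
#'
#' Writes one genome file per genome (letters dialect) plus a manifest CSV
#' (id, file, length, payload summary).
#'
#' @param genomes A `dg_genome_set` or list of `dg_genome`s.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_genome_set <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(genomes, function(g) {
    file <- paste0(g$id, ".org")
    write_genome(g, file.path(dir, file))
    pl <- attr(g, "payload")
    data.frame(id = g$id, file = file, length = base::length(g),
               payload = paste(pl, collapse = ""),
               loop_payload = paste(attr(g, "loop_payload"), collapse = ""),
               stringsAsFactors = FALSE)
  }))
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a genome set from a directory with a manifest
#'
#' @param dir Directory written by [write_genome_set()].
#' @return A `dg_genome_set`.
#' @export
read_genome_set <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(man)), function(i)
    read_genome(file.path(dir, man$file[i]), id = man$id[i]))
  class(out) <- "dg_genome_set"
  out
}
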