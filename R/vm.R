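# Gestation execution and transcriptome tracing

#' Execution limits
#'
#' @param max_cycles Execution budget (CPU cycles) for one gestation. The
#'   default, 20000 for 100-instruction genomes, is an order of magnitude
#'   above typical gestation lengths so that truncation only catches genuine
#'   endless loops.
#' @param min_offspring_length Minimum offspring length for a valid divide.
#' @param require_copied_fraction Minimum fraction of offspring positions
#'   that must have been written by `h-copy`.
#' @return An object of class `dg_limits`.
#' @export
exec_limits <- function(max_cycles = 20000L, min_offspring_length = 10L,
                        require_copied_fraction = 0.5) {
  stopifnot(max_cycles >= 1, min_offspring_length >= 1,
            require_copied_fraction >= 0, require_copied_fraction <= 1)
  structure(list(max_cycles = as.integer(max_cycles),
                 min_offspring_length = as.integer(min_offspring_length),
                 require_copied_fraction = require_copied_fraction),
            class = "dg_limits")
}

#' Run one gestation
#'
#' Steps the virtual CPU from a fresh initial state until a successful
#' `h-divide` or budget exhaustion. The initial state has all heads at
#' position `start`, AX = CX = 0, and BX, input-1 and input-2 pre-loaded with
#' the first three words of the environment stream.
#'
#' @param g A `dg_genome`.
#' @param env A `dg_env` environment specification.
#' @param limits An `exec_limits()` object.
#' @param start Start position (all heads); default 0. Non-zero starts
#'   support rotation/isomorphism analyses.
#' @return An object of class `dg_gestation`: a list with `divided`,
#'   `truncated`, `gestation_cycles`, the executed trace (`trace`, a data
#'   frame of step/position/letter), `outputs` (one row per input-output
#'   execution with the two buffer words and the matched-operation bitmask),
#'   `phenotype` (9-bit code over all outputs), `offspring` (a `dg_genome`
#'   or `NULL`) and `transcriptome_key`.
#' @examples
#' g <- make_replicator(length = 50, seed = 1)
#' r <- run_gestation(g, env_spec(0))
#' r$divided
#' @export
run_gestation <- function(g, env, limits = exec_limits(), start = 0L) {
  stopifnot(inherits(g, "dg_genome"))
  env <- as_env(env)
  if (limits$max_cycles < length(g))
    stop("max_cycles must be at least the genome length")
  res <- cpp_run_gestation(letter_to_id(g$instructions), env$master_seed,
                           env$env_id, limits$max_cycles,
                           limits$min_offspring_length,
                           limits$require_copied_fraction,
                           as.integer(start), TRUE)
  trace <- data.frame(step = seq_along(res$trace_pos),
                      position = res$trace_pos,
                      letter = letters[res$trace_inst + 1L],
                      stringsAsFactors = FALSE)
  outputs <- data.frame(output = res$outputs, input1 = res$out_in1,
                        input2 = res$out_in2, op_mask = res$out_mask)
  offspring <- NULL
  if (res$divided && length(res$offspring) > 0)
    offspring <- genome(letters[res$offspring + 1L],
                        id = paste0(g$id, "_offspring"))
  structure(list(
    genome_id = g$id,
    env = env,
    divided = res$divided,
    truncated = res$truncated,
    gestation_cycles = res$cycles,
    trace = trace,
    outputs = outputs,
    phenotype = res$op_mask,
    offspring = offspring,
    transcriptome_key = res$transcriptome_key
  ), class = "dg_gestation")
}

#' @export
print.dg_gestation <- function(x, ...) {
  cat("<dg_gestation> genome", x$genome_id, "in env", x$env$env_id, "\n")
  cat("  divided:", x$divided, " truncated:", x$truncated,
      " cycles:", x$gestation_cycles, "\n")
  cat("  io executions:", nrow(x$outputs),
      " phenotype code:", x$phenotype, "\n")
  invisible(x)
}

#' Transcriptome of a gestation
#'
#' The ordered sequence of (genome position, instruction) pairs actually
#' executed during the gestation, with its length, input-output count and a
#' collision-resistant digest used as identity key.
#'
#' @param gestation A `dg_gestation`.
#' @return A data frame (step, position, letter, name) with attributes
#'   `key`, `length` and `io_count`.
#' @export
transcriptome <- function(gestation) {
  stopifnot(inherits(gestation, "dg_gestation"))
  tr <- gestation$trace
  tr$name <- .INSTRUCTIONS$name[match(tr$letter, .INSTRUCTIONS$letter)]
  attr(tr, "key") <- gestation$transcriptome_key
  attr(tr, "length") <- nrow(tr)
  attr(tr, "io_count") <- sum(tr$letter == "y")
  tr
}

#' Is a genome viable in an environment?
#'
#' Viability requires producing an offspring that can itself self-replicate:
#' the parent's gestation must divide, and the offspring must either be
#' identical to the parent (short-circuit) or divide successfully in one
#' further gestation in the same environment.
#'
#' @inheritParams run_gestation
#' @return Logical.
#' @export
is_viable <- function(g, env, limits = exec_limits()) {
  stopifnot(inherits(g, "dg_genome"))
  env <- as_env(env)
  cpp_is_viable(letter_to_id(g$instructions), env$master_seed, env$env_id,
                limits$max_cycles, limits$min_offspring_length,
                limits$require_copied_fraction)
}

#' Export a trace
#'
#' Writes the per-step trace as CSV (step index, genome position, letter,
#' name) and/or a JSON summary (key, length, io_count, outputs).
#'
#' @param gestation A `dg_gestation`.
#' @param csv,json Output paths (either may be `NULL`).
#' @return Invisibly, a list of the paths written.
#' @export
export_trace <- function(gestation, csv = NULL, json = NULL) {
  tr <- transcriptome(gestation)
  if (!is.null(csv))
    write.csv(as.data.frame(tr), csv, row.names = FALSE)
  if (!is.null(json)) {
    summ <- list(
      genome_id = gestation$genome_id,
      env_id = gestation$env$env_id,
      master_seed = gestation$env$master_seed,
      canonical_key = attr(tr, "key"),
      length = attr(tr, "length"),
      io_count = attr(tr, "io_count"),
      divided = gestation$divided,
      truncated = gestation$truncated,
      phenotype = gestation$phenotype,
      outputs = gestation$outputs
    )
    jsonlite::write_json(summ, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv, json = json))
}
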