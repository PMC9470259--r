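# Plasticity profiling across environment sets

#' Profile a genome across a set of environments
#'
#' Runs one gestation (plus the offspring self-replication check) in every
#' environment and summarises phenotypes, transcriptomes, viability and
#' costs. Counts of distinct phenotypes and transcriptomes are computed over
#' viable environments only.
#'
#' @param g A `dg_genome`.
#' @param envs A `dg_env_set` (or data frame with `env_id`, `master_seed`).
#' @param limits An `exec_limits()` object.
#' @return An object of class `dg_profile`: a list with `genome_id`,
#'   `records` (one row per environment: viable, phenotype, transcriptome
#'   key/length, io counts), `n_phenotypes`, `n_transcriptomes`, `plastic`,
#'   `sensitive`, `viability_cost` and `uncertainty`.
#' @export
profile_genome <- function(g, envs, limits = exec_limits()) {
  stopifnot(inherits(g, "dg_genome"))
  if (nrow(envs) < 1) stop("at least one environment is required")
  ms <- unique(envs$master_seed)
  if (length(ms) != 1)
    stop("all environments in a set must share one master_seed")
  res <- cpp_profile(letter_to_id(g$instructions), ms,
                     as.integer(envs$env_id), limits$max_cycles,
                     limits$min_offspring_length,
                     limits$require_copied_fraction)
  records <- data.frame(
    env_id = res$env_id,
    viable = res$viable,
    divided = res$divided,
    truncated = res$truncated,
    phenotype = res$phenotype,
    transcriptome_key = res$transcriptome_key,
    transcriptome_length = res$transcriptome_length,
    io_count = res$io_count,
    io_in_repeats = res$io_in_repeats,
    stringsAsFactors = FALSE
  )
  new_profile(g$id, records)
}

new_profile <- function(genome_id, records) {
  v <- records$viable
  n_phen <- length(unique(records$phenotype[v]))
  n_tran <- length(unique(records$transcriptome_key[v]))
  unc <- if (any(v)) uncertainty_from_records(records) else NA_real_
  structure(list(
    genome_id = genome_id,
    records = records,
    n_viable = sum(v),
    n_phenotypes = n_phen,
    n_transcriptomes = n_tran,
    plastic = n_phen > 1,
    sensitive = n_tran > 1,
    viability_cost = any(!v),
    uncertainty = unc
  ), class = "dg_profile")
}

#' @export
print.dg_profile <- function(x, ...) {
  cat("<dg_profile>", x$genome_id, "over", nrow(x$records), "environments\n")
  cat("  viable:", x$n_viable, "/", nrow(x$records),
      " phenotypes:", x$n_phenotypes,
      " transcriptomes:", x$n_transcriptomes, "\n")
  lab <- tryCatch(classify(x), error = function(e) "unclassifiable")
  cat("  class:", lab, " uncertainty:",
      formatC(x$uncertainty, digits = 3, format = "f"), "\n")
  invisible(x)
}

#' Classify a profile into the plasticity/sensitivity quadrants
#'
#' `plastic` means the genome encoded more than one distinct phenotype across
#' the environments where it was viable; `sensitive` means it executed more
#' than one distinct transcriptome there. Plastic/robust is the non-genetic
#' mechanism for plasticity (same executed instruction sequence, different
#' input words); plastic/sensitive is the genetic-based mechanism (the
#' environment altered the execution flow).
#'
#' @param profile A `dg_profile`.
#' @return One of `"non-plastic/robust"`, `"non-plastic/sensitive"`,
#'   `"plastic/robust"`, `"plastic/sensitive"`.
#' @export
classify <- function(profile) {
  stopifnot(inherits(profile, "dg_profile"))
  if (profile$n_viable == 0)
    stop("unclassifiable: no viable environment")
  paste0(if (profile$plastic) "plastic" else "non-plastic", "/",
         if (profile$sensitive) "sensitive" else "robust")
}

.QUADRANTS <- c("non-plastic/robust", "non-plastic/sensitive",
                "plastic/robust", "plastic/sensitive")

#' Tandem repeats in an execution trace
#'
#' Finds maximal leftmost-longest periodic runs of the executed-position
#' sequence: at least two full consecutive copies of a period-p block, runs
#' not overlapping (greedy left-to-right), choosing at each start the run
#' with the largest full-period coverage and breaking ties by the smallest
#' period. These runs are the signature of finite execution loops.
#'
#' @param x Integer vector of executed genome positions, or a
#'   `dg_gestation`.
#' @param letters Optional character vector of executed instruction letters
#'   (same length as the position sequence); when supplied (or when `x` is a
#'   gestation), the count of input-output steps inside reported runs is
#'   attached as attribute `io_in_repeats`.
#' @return Data frame with columns `start` (0-based), `period` and `count`.
#' @examples
#' tandem_repeats(c(7, 8, 9, 7, 8, 9, 7, 8, 9, 10))
#' @export
tandem_repeats <- function(x, letters = NULL) {
  if (inherits(x, "dg_gestation")) {
    letters <- x$trace$letter
    x <- x$trace$position
  }
  runs <- cpp_tandem_repeats(as.integer(x))
  out <- data.frame(start = runs$start, period = runs$period,
                    count = runs$count)
  if (!is.null(letters)) {
    stopifnot(length(letters) == length(x))
    n_io <- 0L
    if (nrow(out) > 0) {
      for (j in seq_len(nrow(out))) {
        idx <- (out$start[j] + 1):(out$start[j] + out$period[j] * out$count[j])
        n_io <- n_io + sum(letters[idx] == "y")
      }
    }
    attr(out, "io_in_repeats") <- n_io
  }
  out
}

uncertainty_from_records <- function(records) {
  v <- records$viable
  codes <- records$phenotype[v]
  p <- vapply(0:8, function(b) {
    mean(bitwAnd(codes, 2^b) > 0)
  }, numeric(1))
  mean(binary_entropy(p))
}

binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h
}

#' Phenotypic uncertainty of a profile
#'
#' For each of the nine logic operations, let p_i be the fraction of viable
#' environments in which the operation was performed. The uncertainty is the
#' mean over operations of the binary Shannon entropy (base-2)
#' `-p log2(p) - (1-p) log2(1-p)`, with degenerate terms (p in {0, 1})
#' contributing 0; it is bounded in `[0, 1]`.
#'
#' @param profile A `dg_profile`.
#' @return Numeric in `[0, 1]`.
#' @export
phenotypic_uncertainty <- function(profile) {
  stopifnot(inherits(profile, "dg_profile"))
  if (profile$n_viable == 0)
    stop("undefined: no viable environment")
  uncertainty_from_records(profile$records)
}

#' Profile a population of genomes
#'
#' @param genomes List of `dg_genome` objects.
#' @param envs A `dg_env_set`.
#' @param limits An `exec_limits()` object.
#' @return A list of `dg_profile` objects, class `dg_population`.
#' @export
profile_population <- function(genomes, envs, limits = exec_limits()) {
  stopifnot(length(genomes) >= 1)
  out <- lapply(genomes, profile_genome, envs = envs, limits = limits)
  structure(out, class = "dg_population")
}

#' @export
print.dg_population <- function(x, ...) {
  cat("<dg_population> of", length(x), "profiles\n")
  print(population_summary(x)$quadrants)
  invisible(x)
}

#' Per-genome summary table of a population
#'
#' One row per genome, with the counts, flags and costs consumed by the
#' statistical models.
#'
#' @param population A `dg_population` (list of `dg_profile`s).
#' @return A data frame.
#' @export
profile_table <- function(population) {
  rows <- lapply(population, function(p) {
    v <- p$records$viable
    data.frame(
      genome_id = p$genome_id,
      n_env = nrow(p$records),
      n_viable = p$n_viable,
      n_phenotypes = p$n_phenotypes,
      n_transcriptomes = p$n_transcriptomes,
      plastic = p$plastic,
      sensitive = p$sensitive,
      cost = p$viability_cost,
      viable_all = !p$viability_cost,
      uncertainty = p$uncertainty,
      mean_tlen = if (any(v)) mean(p$records$transcriptome_length[v]) else NA_real_,
      mean_io = if (any(v)) mean(p$records$io_count[v]) else NA_real_,
      mean_io_repeats = if (any(v)) mean(p$records$io_in_repeats[v]) else NA_real_,
      quadrant = if (p$n_viable > 0) classify(p) else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-record (genome x environment) table of a population
#'
#' @param population A `dg_population`.
#' @return A data frame with one row per genome and environment, carrying
#'   the per-genome `plastic`/`sensitive` flags alongside each record.
#' @export
record_table <- function(population) {
  rows <- lapply(population, function(p) {
    r <- p$records
    r$genome_id <- p$genome_id
    r$plastic <- p$plastic
    r$sensitive <- p$sensitive
    r$cost <- p$viability_cost
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("genome_id", "env_id", "viable", "divided", "truncated",
          "phenotype", "transcriptome_key", "transcriptome_length",
          "io_count", "io_in_repeats", "plastic", "sensitive", "cost")]
}

#' Population summary
#'
#' Quadrant proportions, the joint frequency table of (number of phenotypes,
#' number of transcriptomes), and mean transcriptome lengths / input-output
#' counts by quadrant.
#'
#' @param population A `dg_population`.
#' @return An object of class `dg_popsummary`: list with `n`, `quadrants`
#'   (named proportions), `quadrant_counts`, `joint` (table), and
#'   `by_quadrant` (data frame of means).
#' @export
population_summary <- function(population) {
  stopifnot(length(population) >= 1)
  tbl <- profile_table(population)
  cl <- tbl$quadrant[!is.na(tbl$quadrant)]
  counts <- table(factor(cl, levels = .QUADRANTS))
  props <- as.numeric(counts) / max(1L, length(cl))
  names(props) <- .QUADRANTS
  joint <- table(phenotypes = tbl$n_phenotypes,
                 transcriptomes = tbl$n_transcriptomes)
  byq <- do.call(rbind, lapply(.QUADRANTS, function(q) {
    sub <- tbl[!is.na(tbl$quadrant) & tbl$quadrant == q, ]
    data.frame(quadrant = q, n = nrow(sub),
               mean_tlen = if (nrow(sub)) mean(sub$mean_tlen) else NA_real_,
               mean_io = if (nrow(sub)) mean(sub$mean_io) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(n = length(population),
                 n_classifiable = length(cl),
                 quadrants = props,
                 quadrant_counts = counts,
                 joint = joint,
                 by_quadrant = byq,
                 table = tbl),
            class = "dg_popsummary")
}

#' @export
print.dg_popsummary <- function(x, ...) {
  cat("<dg_popsummary>", x$n, "genomes (", x$n_classifiable,
      "classifiable )\n")
  print(round(x$quadrants, 3))
  invisible(x)
}
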