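# Environments as reproducible streams of 32-bit input words

#' Define an environment
#'
#' An environment is a deterministic, restartable stream of uniformly
#' distributed 32-bit words, fully determined by `(master_seed, env_id)`.
#' The stream uses a counter-based keyed construction (splitmix64 mixing of
#' the key with the draw index), so the n-th word is addressable directly and
#' streams are identical across platforms.
#'
#' @param env_id Non-negative integer environment index.
#' @param master_seed Non-negative integer master seed.
#' @return An object of class `dg_env`.
#' @examples
#' e <- env_spec(0, 42)
#' env_input_words(e, 5)
#' @export
env_spec <- function(env_id, master_seed = 42) {
  stopifnot(length(env_id) == 1, length(master_seed) == 1,
            env_id >= 0, master_seed >= 0)
  structure(list(env_id = as.numeric(env_id),
                 master_seed = as.numeric(master_seed)),
            class = "dg_env")
}

#' @export
print.dg_env <- function(x, ...) {
  cat("<dg_env> env_id =", x$env_id, "master_seed =", x$master_seed, "\n")
  invisible(x)
}

#' Words of an environment stream
#'
#' @param env A `dg_env` (or a one-row data frame with `env_id` and
#'   `master_seed`).
#' @param n Number of words.
#' @param from Zero-based index of the first word.
#' @return Numeric vector of words in `[0, 2^32 - 1]`.
#' @export
env_input_words <- function(env, n, from = 0) {
  env <- as_env(env)
  cpp_env_words(env$master_seed, env$env_id, as.integer(n), from)
}

as_env <- function(env) {
  if (inherits(env, "dg_env")) return(env)
  if (is.data.frame(env) && nrow(env) == 1)
    return(env_spec(env$env_id, env$master_seed))
  if (is.list(env) && !is.null(env$env_id))
    return(env_spec(env$env_id, env$master_seed))
  stop("cannot interpret 'env' as an environment specification")
}

#' Create a set of environments
#'
#' @param n Number of environments (>= 1).
#' @param master_seed Master seed shared by the set.
#' @return A data frame with columns `env_id` (0 .. n-1) and `master_seed`,
#'   of class `dg_env_set`.
#' @examples
#' envs <- environment_set(10, master_seed = 42)
#' @export
environment_set <- function(n, master_seed = 42) {
  if (length(n) != 1 || is.na(n) || n < 1)
    stop("'n' must be a single integer >= 1")
  out <- data.frame(env_id = seq_len(n) - 1L,
                    master_seed = as.numeric(master_seed))
  class(out) <- c("dg_env_set", "data.frame")
  out
}

#' Write / read an environment set as CSV
#'
#' @param envs A `dg_env_set` data frame.
#' @param path File path.
#' @return `path` (write) or the environment set (read).
#' @export
write_environment_set <- function(envs, path) {
  write.csv(as.data.frame(envs)[, c("env_id", "master_seed")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_environment_set
#' @export
read_environment_set <- function(path) {
  out <- read.csv(path)
  stopifnot(all(c("env_id", "master_seed") %in% names(out)))
  class(out) <- c("dg_env_set", "data.frame")
  out
}
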