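# Instruction alphabet and genome representation

.INSTRUCTIONS <- data.frame(
  letter = letters,
  name = c("nop-A", "nop-B", "nop-C", "if-n-equ", "if-less", "if-label",
           "mov-head", "jump-head", "get-head", "set-flow", "shift-r",
           "shift-l", "inc", "dec", "push", "pop", "swap-stk", "swap",
           "add", "sub", "nand", "h-copy", "h-alloc", "h-divide",
           "input-output", "h-search"),
  category = c("nop", "nop", "nop", "flow-control", "flow-control",
               "flow-control", "flow-control", "flow-control", "flow-control",
               "flow-control", "math", "math", "math", "math", "math", "math",
               "math", "math", "math", "math", "math", "replication",
               "replication", "replication", "io", "flow-control"),
  stringsAsFactors = FALSE
)

# Instructions whose effect on control flow depends on register contents and
# hence, indirectly, on the environment.
.REGULATORY <- c("if-n-equ", "if-less", "jump-head", "set-flow")

#' The 26-instruction alphabet
#'
#' Each genome position holds one of 26 instructions, written as the letters
#' a-z. Instructions fall into five groups: no-operations (also used as
#' operand/label modifiers), flow control, math (register, stack and bitwise
#' manipulation of 32-bit words), replication (`h-copy`, `h-alloc`,
#' `h-divide`) and input-output. The four *regulatory* instructions
#' (`if-less`, `if-n-equ`, `jump-head`, `set-flow`) are the flow-control
#' instructions whose outcome depends on register contents, and therefore the
#' only route by which the environment can alter which instructions are
#' executed.
#'
#' @return A data frame with columns `letter`, `name`, `category` and the
#'   logical `regulatory`.
#' @examples
#' instruction_set()
#' @export
instruction_set <- function() {
  out <- .INSTRUCTIONS
  out$regulatory <- out$name %in% .REGULATORY
  out
}

#' Regulatory instruction letters
#'
#' @return Character vector of the four regulatory instruction letters.
#' @export
regulatory_letters <- function() {
  .INSTRUCTIONS$letter[.INSTRUCTIONS$name %in% .REGULATORY]
}

letter_to_id <- function(letter) {
  id <- match(letter, letters) - 1L
  if (anyNA(id))
    stop("unknown instruction letter(s): ",
         paste(unique(letter[is.na(id)]), collapse = ", "))
  id
}

name_to_letter <- function(name) {
  i <- match(name, .INSTRUCTIONS$name)
  if (anyNA(i))
    stop("unknown instruction name(s): ",
         paste(unique(name[is.na(i)]), collapse = ", "))
  .INSTRUCTIONS$letter[i]
}

#' Create a genome
#'
#' A genome is a circular, non-empty sequence of instructions, stored as a
#' character vector of single letters with an identifier.
#'
#' @param x A single string of instruction letters (e.g. `"wzcag..."`), a
#'   character vector of letters, or a character vector of canonical
#'   instruction names.
#' @param id Stable identifier; defaults to a short digest of the sequence.
#' @return An object of class `dg_genome`.
#' @examples
#' g <- genome("wzcavxy")
#' length(g)
#' @export
genome <- function(x, id = NULL) {
  if (length(x) == 0 || (length(x) == 1 && !nzchar(x)))
    stop("a genome must be non-empty")
  if (length(x) == 1 && nchar(x) > 1 && !x %in% .INSTRUCTIONS$name)
    x <- strsplit(x, "")[[1]]
  if (all(nchar(x) == 1)) {
    letter_to_id(x)  # validates
    lets <- x
  } else {
    lets <- name_to_letter(x)
  }
  if (length(lets) == 0) stop("a genome must be non-empty")
  if (is.null(id))
    id <- sprintf("g%08x", genome_hash(lets))
  structure(list(instructions = lets, id = id), class = "dg_genome")
}

genome_hash <- function(lets) {
  # small deterministic 31-bit hash for default ids
  h <- 5381
  for (v in utf8ToInt(paste(lets, collapse = ""))) {
    h <- (h * 33 + v) %% 2147483647
  }
  h
}

#' @export
length.dg_genome <- function(x) length(x$instructions)

#' @export
print.dg_genome <- function(x, ...) {
  cat("<dg_genome> ", x$id, " (", length(x), " instructions)\n", sep = "")
  cat(genome_string(x), "\n")
  invisible(x)
}

#' @export
as.character.dg_genome <- function(x, ...) genome_string(x)

#' @export
`==.dg_genome` <- function(e1, e2) {
  identical(e1$instructions, e2$instructions)
}

#' Genome letter string
#'
#' @param g A `dg_genome`.
#' @return Single string of instruction letters.
#' @export
genome_string <- function(g) paste(g$instructions, collapse = "")

#' Rotate a genome
#'
#' Returns the genome whose position 0 is position `r` of `g` (circular
#' shift). Useful for execution-trace isomorphism analyses.
#'
#' @param g A `dg_genome`.
#' @param r Non-negative rotation offset.
#' @return A `dg_genome`.
#' @export
rotate_genome <- function(g, r) {
  n <- length(g)
  r <- r %% n
  if (r == 0) return(g)
  genome(g$instructions[c((r + 1):n, seq_len(r))],
         id = paste0(g$id, "_rot", r))
}

#' Read a genome file
#'
#' Two plain-text dialects are auto-detected: a single line of letters over
#' a-z ("letters"), or one canonical instruction name per line ("names",
#' Avida .org style; blank lines and `#` comments ignored).
#'
#' @param path File path.
#' @param id Identifier; defaults to the file name without extension.
#' @return A `dg_genome`.
#' @export
read_genome <- function(path, id = NULL) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  if (length(ln) == 0) stop("no genome content in ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (length(ln) == 1 && !ln %in% .INSTRUCTIONS$name &&
      grepl("^[a-z]+$", ln)) {
    genome(ln, id = id)
  } else {
    genome(ln, id = id)
  }
}

#' Write a genome file
#'
#' @param g A `dg_genome`.
#' @param path File path.
#' @param dialect `"letters"` (one line of letters) or `"names"` (one
#'   instruction name per line).
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path, dialect = c("letters", "names")) {
  dialect <- match.arg(dialect)
  if (dialect == "letters") {
    writeLines(genome_string(g), path)
  } else {
    writeLines(.INSTRUCTIONS$name[letter_to_id(g$instructions) + 1L], path)
  }
  invisible(path)
}
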