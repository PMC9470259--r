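# Boolean logic operations and phenotype encoding

.LOGIC_OPS <- data.frame(
  name = c("NOT", "NAND", "AND", "OR_N", "OR", "AND_N", "NOR", "XOR", "EQU"),
  arity = c(1L, rep(2L, 8)),
  bit = 0:8,
  stringsAsFactors = FALSE
)

#' The nine Boolean logic operations
#'
#' Each operation is applied bitwise over the full 32-bit width. NOT is
#' unary and is checked against each input buffer individually; the
#' asymmetric operations OR_N (a OR NOT b) and AND_N (a AND NOT b) are
#' accepted in either argument orientation. The phenotype bit order is
#' NOT=0, NAND=1, AND=2, OR_N=3, OR=4, AND_N=5, NOR=6, XOR=7, EQU=8.
#'
#' @return A data frame with columns `name`, `arity` and `bit`.
#' @export
logic_ops <- function() .LOGIC_OPS

#' Which logic operations does an output word represent?
#'
#' Returns every operation whose full-width 32-bit result on
#' `(input1, input2)` — or on each input alone for NOT — equals `output`
#' exactly. The result may be empty, or contain several operations when
#' degenerate inputs make distinct operations coincide.
#'
#' @param output,input1,input2 32-bit words as numerics in `[0, 2^32 - 1]`.
#' @return Character vector of matched operation names.
#' @examples
#' w <- 2^32 - 1
#' check_output(0, w, w)  # all-ones NAND all-ones
#' @export
check_output <- function(output, input1, input2) {
  stopifnot(length(output) == 1, length(input1) == 1, length(input2) == 1)
  mask <- cpp_check_output(output, input1, input2)
  phenotype_ops(mask)
}

#' Encode a set of performed operations as a 9-bit phenotype code
#'
#' @param operations Character vector of operation names (any subset of
#'   `logic_ops()$name`).
#' @return Integer in `[0, 511]`.
#' @examples
#' phenotype_code(c("NOT"))       # 1
#' phenotype_code(.ops <- logic_ops()$name)  # 511
#' @export
phenotype_code <- function(operations) {
  if (length(operations) == 0) return(0L)
  i <- match(operations, .LOGIC_OPS$name)
  if (anyNA(i))
    stop("unknown operation(s): ",
         paste(operations[is.na(i)], collapse = ", "))
  as.integer(sum(2^unique(.LOGIC_OPS$bit[i])))
}

#' Decode a phenotype code into operation names
#'
#' @param code Integer in `[0, 511]` (9-bit phenotype code).
#' @return Character vector of operation names.
#' @export
phenotype_ops <- function(code) {
  stopifnot(length(code) == 1, !is.na(code), code >= 0, code <= 511)
  .LOGIC_OPS$name[bitwAnd(as.integer(code), 2^.LOGIC_OPS$bit) > 0]
}
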