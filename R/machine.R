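# The machine substrate: a concatenative stack language with a bijective
# Goedel numbering (length-then-lexicographic = bijective base-29 numeration)
# and a deterministic step-budgeted interpreter.
#
# A program is a string over a 29-character alphabet.  Every string is
# syntactically valid, which is what makes the numbering a closed-form
# bijection between programs and the non-negative integers.  Tokens on the
# stack are strings; a token of decimal digits doubles as a Goedel number
# wherever an instruction expects a code.

#' The instruction alphabet
#'
#' Character order defines the canonical Goedel numbering
#' (length-then-lexicographic in this collation).  Instructions:
#'
#' * `.` no-op (canonical padding)
#' * `!` flip the polarity suffix of the top token (`:+` <-> `:-`); involution
#' * `:` duplicate the top token
#' * `~` swap the two top tokens
#' * `i` push the current frame's input token
#' * `@` apply: pop a code token and an input token, run the code on the input
#'   in a nested frame and push its output.  A non-numeric code token denotes
#'   itself (assembled phenotypes are self-denoting constants).
#' * `?` pop two tokens; execute the next instruction if they are equal,
#'   otherwise skip it
#' * `H` halt immediately with the top of the stack as output
#' * `S` pop a code token `u`, push the Goedel number of the s-m-n index
#'   `sigma(u, u)` (effective s-m-n at machine level)
#' * `P` pop a code token, push the Goedel number of the same program padded
#'   with one trailing no-op (canonical syntactic padding)
#' * `C` pop code tokens `a` then `b`, push the Goedel number of the effective
#'   composition `a` after `b`
#' * `D` push the Goedel number of the currently executing program (self)
#' * `L` loop forever (one interpreter step per iteration)
#' * `[` ... `]` push the enclosed text as one literal token (an unterminated
#'   `[` quotes to the end of the program; a bare `]` is a no-op)
#' * `+ - t s 0..9` no-ops outside literals; inside literals they spell
#'   phenotype tokens (`t3:+`), state tokens (`s0`) and decimal Goedel numbers
#'
#' @return character vector of the 29 alphabet symbols in canonical order.
#' @export
gtp_alphabet <- function() .ALPHABET

.ALPHABET <- c(".", "!", ":", "~", "i", "@", "?", "H", "S", "P", "C", "D", "L",
               "[", "]", "+", "-", "t", "s",
               "0", "1", "2", "3", "4", "5", "6", "7", "8", "9")
.ALPHA_K <- length(.ALPHABET)
.ALPHA_IDX <- stats::setNames(seq_len(.ALPHA_K), .ALPHABET)

#' Construct a program from instruction text
#'
#' Computes the program's Goedel number: its rank in the canonical
#' length-then-lexicographic enumeration of all programs (closed-form
#' bijective base-29 numeration over [gtp_alphabet()]).  The empty program has
#' Goedel number 0.
#'
#' @param text instruction string over the alphabet.
#' @return a `gtp_program`: list with `gn` (decimal string) and `text`.
#' @examples
#' encode_program("")     # gn 0
#' encode_program("i")    # the identity program
#' encode_program("i!")   # the canonical negator
#' @seealso [decode_program()], [run_program()]
#' @export
encode_program <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% .ALPHABET))
  if (length(bad) > 0L) {
    stop("invalid instruction '", chars[bad[1]], "' at position ", bad[1],
         " (not in the program alphabet)")
  }
  n <- "0"
  for (ch in chars) {
    n <- .big_add_small(.big_mul_small(n, .ALPHA_K), .ALPHA_IDX[[ch]])
  }
  new_gtp_program(n, text)
}

#' Recover a program from its Goedel number
#'
#' Inverse of [encode_program()]: `decode_program(encode_program(p)$gn)$text`
#' is `p` for every program, and `encode_program(decode_program(n)$text)$gn`
#' is `n` for every non-negative integer.
#'
#' @param n Goedel number (number or decimal string).
#' @return a `gtp_program`.
#' @export
decode_program <- function(n) {
  n <- gn(n)
  orig <- n
  chars <- character(0)
  while (n != "0") {
    dm <- .big_divmod_small(n, .ALPHA_K)
    if (dm$r == 0L) {
      chars <- c(chars, .ALPHABET[.ALPHA_K])
      n <- .big_sub(dm$q, "1")
    } else {
      chars <- c(chars, .ALPHABET[dm$r])
      n <- dm$q
    }
  }
  text <- paste(rev(chars), collapse = "")
  new_gtp_program(orig, text)
}

# internal: gn of a text (same loop as encode, no validation)
gn_of_text <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- "0"
  for (ch in chars) n <- .big_add_small(.big_mul_small(n, .ALPHA_K), .ALPHA_IDX[[ch]])
  n
}

new_gtp_program <- function(n, text) {
  structure(list(gn = n, text = text), class = "gtp_program")
}

#' @export
print.gtp_program <- function(x, ...) {
  gnum <- x$gn
  if (nchar(gnum) > 24L) gnum <- paste0(substr(gnum, 1, 10), "...", substr(gnum, nchar(gnum) - 9, nchar(gnum)), " (", nchar(gnum), " digits)")
  cat("<gtp_program> gn ", gnum, "\n  ", deparse(x$text), "\n", sep = "")
  invisible(x)
}

#' @export
format.gtp_program <- function(x, ...) paste0("program(gn=", x$gn, ")")

as_program <- function(x) {
  if (inherits(x, "gtp_program")) return(x)
  if (is.character(x) && grepl("^[0-9]+$", x)) return(decode_program(x))
  if (is.numeric(x)) return(decode_program(x))
  stop("expected a gtp_program or a Goedel number")
}

#' Default step budget
#'
#' "Halts" in this package always means "halts within the configured step
#' budget"; true halting is undecidable, so the sets of halting and
#' forbidden codes are realised operationally.  Every report records the
#' budget in force.
#'
#' @param T maximum interpreter steps (>= 1).
#' @return integer budget.
#' @export
gtp_budget <- function(T = 10000L) {
  T <- as.integer(T)
  stopifnot(length(T) == 1L, !is.na(T), T >= 1L)
  T
}

#' The standard input battery
#'
#' A declared finite battery of state tokens used for operational totality
#' checks and extensional program comparison ("agreement of execution outcomes
#' on the battery at budget T").
#'
#' @param n_states number of state tokens (default 50).
#' @return character vector `s0 ... s<n-1>`.
#' @export
standard_battery <- function(n_states = 50L) paste0("s", seq_len(n_states) - 1L)

## ---- compiled-program cache -------------------------------------------------

.prog_cache <- new.env(parent = emptyenv())

# memo for the effective meta-operations (S, P, C, gn -> text); the same
# tokens recur at every level of self-interpreting runs
.op_cache <- new.env(parent = emptyenv())

.memo <- function(key, thunk) {
  v <- .op_cache[[key]]
  if (is.null(v)) {
    v <- thunk()
    if (length(ls(.op_cache)) < 50000L) .op_cache[[key]] <- v
  }
  v
}

.decode_text <- function(g) .memo(paste0("T", g), function() decode_program(g)$text)

.OP <- c(NOP = 1L, FLIP = 2L, DUP = 3L, SWAP = 4L, INPUT = 5L, APPLY = 6L,
         MATCH = 7L, HALT = 8L, SIGMA = 9L, PAD = 10L, COMPOSE = 11L,
         SELF = 12L, LOOP = 13L, LIT = 14L)

.CHAR_OP <- c("." = 1L, "!" = 2L, ":" = 3L, "~" = 4L, "i" = 5L, "@" = 6L,
              "?" = 7L, "H" = 8L, "S" = 9L, "P" = 10L, "C" = 11L, "D" = 12L,
              "L" = 13L, "]" = 1L, "+" = 1L, "-" = 1L, "t" = 1L, "s" = 1L,
              "0" = 1L, "1" = 1L, "2" = 1L, "3" = 1L, "4" = 1L, "5" = 1L,
              "6" = 1L, "7" = 1L, "8" = 1L, "9" = 1L)

compile_program <- function(text) {
  cached <- .prog_cache[[paste0("k", text)]]
  if (!is.null(cached)) return(cached)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  ops <- integer(0)
  args <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      lit <- if (j > i + 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "") else ""
      ops <- c(ops, .OP[["LIT"]])
      args[[length(ops)]] <- lit
      i <- j + 1L
    } else {
      ops <- c(ops, .CHAR_OP[[ch]])
      args[[length(ops)]] <- NULL
      i <- i + 1L
    }
  }
  out <- list(ops = ops, args = args, n = length(ops), gn = NULL, text = text)
  if (length(ls(.prog_cache)) < 20000L) .prog_cache[[paste0("k", text)]] <- out
  out
}

.flip_token <- function(tok) {
  nc <- nchar(tok)
  if (nc >= 2L) {
    suf <- substr(tok, nc - 1L, nc)
    if (suf == ":+") return(paste0(substr(tok, 1L, nc - 2L), ":-"))
    if (suf == ":-") return(paste0(substr(tok, 1L, nc - 2L), ":+"))
  }
  tok
}

.is_code_token <- function(tok) nchar(tok) > 0L && grepl("^[0-9]+$", tok)

# sigma(u, u) program text; shared by smn_sigma() and the S instruction
.sigma_text <- function(x, y) paste0("[", y, "][", x, "]@i~@")

.compose_text <- function(f_gn, g_gn) paste0("i[", g_gn, "]@[", f_gn, "]@")

#' Run a program on one input under a step budget
#'
#' The interpreter is deterministic: equal `(code, input, budget)` always give
#' identical outcomes, and an outcome that halts at budget `T` is unchanged at
#' any larger budget.  Every interpreter transition costs one step, including
#' the steps of code applied in nested frames, so dovetailed scheduling is
#' fair.  Non-halting within the budget is a status (`BUDGET_EXHAUSTED`), not
#' an error.
#'
#' @param code a `gtp_program` (or a Goedel number accepted by
#'   [decode_program()]).
#' @param input input token: a state token such as `"s0"`, a phenotype token,
#'   or a Goedel number (numbers are converted to their decimal token).
#' @param budget step budget, see [gtp_budget()].
#' @return `gtp_outcome`: list with `status` (`"HALTED"` or
#'   `"BUDGET_EXHAUSTED"`), `output` (token, only when halted), `steps`.
#' @examples
#' run_program(encode_program("i"), "s0")   # identity halts with "s0"
#' run_program(encode_program("L"), "s0")   # loop exhausts the budget
#' @export
run_program <- function(code, input, budget = gtp_budget()) {
  code <- as_program(code)
  if (is.numeric(input)) input <- gn(input)
  stopifnot(is.character(input), length(input) == 1L)
  budget <- gtp_budget(budget)
  .run_text(code$text, input, budget)
}

.run_text <- function(text, input, budget) {
  prog <- compile_program(text)
  # one frame = list(prog, pc, stack, sp, input)
  frames <- vector("list", 8L)
  frames[[1L]] <- new_frame(prog, input)
  depth <- 1L
  steps <- 0L
  stuck <- FALSE
  OPL <- .OP
  repeat {
    fr <- frames[[depth]]
    if (fr$pc > fr$prog$n) {
      out <- if (fr$sp > 0L) fr$stack[[fr$sp]] else ""
      depth <- depth - 1L
      if (depth == 0L) {
        return(new_outcome("HALTED", out, steps, stuck = FALSE))
      }
      pfr <- frames[[depth]]
      pfr$sp <- pfr$sp + 1L
      pfr$stack[[pfr$sp]] <- out
      frames[[depth]] <- pfr
      next
    }
    if (steps >= budget) return(new_outcome("BUDGET_EXHAUSTED", NULL, budget, stuck = stuck))
    op <- fr$prog$ops[fr$pc]
    steps <- steps + 1L
    if (op == 13L) { # LOOP: provably never advances; consume the budget
      return(new_outcome("BUDGET_EXHAUSTED", NULL, budget, stuck = TRUE))
    } else if (op == 14L) { # LIT
      fr$sp <- fr$sp + 1L
      fr$stack[[fr$sp]] <- fr$prog$args[[fr$pc]]
      fr$pc <- fr$pc + 1L
    } else if (op == 5L) { # INPUT
      fr$sp <- fr$sp + 1L
      fr$stack[[fr$sp]] <- fr$input
      fr$pc <- fr$pc + 1L
    } else if (op == 1L) { # NOP
      fr$pc <- fr$pc + 1L
    } else if (op == 2L) { # FLIP
      a <- ""
      if (fr$sp > 0L) { a <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      fr$sp <- fr$sp + 1L
      fr$stack[[fr$sp]] <- .flip_token(a)
      fr$pc <- fr$pc + 1L
    } else if (op == 3L) { # DUP
      a <- ""
      if (fr$sp > 0L) a <- fr$stack[[fr$sp]] else fr$sp <- 0L
      if (fr$sp == 0L) { fr$sp <- 1L; fr$stack[[1L]] <- a }
      fr$sp <- fr$sp + 1L
      fr$stack[[fr$sp]] <- a
      fr$pc <- fr$pc + 1L
    } else if (op == 4L) { # SWAP
      a <- ""; b <- ""
      if (fr$sp > 0L) { a <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      if (fr$sp > 0L) { b <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      fr$sp <- fr$sp + 1L; fr$stack[[fr$sp]] <- a
      fr$sp <- fr$sp + 1L; fr$stack[[fr$sp]] <- b
      fr$pc <- fr$pc + 1L
    } else if (op == 6L) { # APPLY
      a <- ""; b <- ""
      if (fr$sp > 0L) { a <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      if (fr$sp > 0L) { b <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      fr$pc <- fr$pc + 1L
      if (.is_code_token(a)) {
        frames[[depth]] <- fr
        subtext <- .decode_text(a)
        depth <- depth + 1L
        if (depth > length(frames)) frames <- c(frames, vector("list", length(frames)))
        frames[[depth]] <- new_frame(compile_program(subtext), b)
        next
      } else {
        # a non-code token denotes itself: assembled phenotypes are constants
        fr$sp <- fr$sp + 1L
        fr$stack[[fr$sp]] <- a
      }
    } else if (op == 7L) { # MATCH: execute next instruction iff equal
      a <- ""; b <- ""
      if (fr$sp > 0L) { a <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      if (fr$sp > 0L) { b <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      fr$pc <- fr$pc + (if (identical(a, b)) 1L else 2L)
    } else if (op == 8L) { # HALT
      out <- if (fr$sp > 0L) fr$stack[[fr$sp]] else ""
      depth <- depth - 1L
      if (depth == 0L) return(new_outcome("HALTED", out, steps, stuck = FALSE))
      pfr <- frames[[depth]]
      pfr$sp <- pfr$sp + 1L
      pfr$stack[[pfr$sp]] <- out
      frames[[depth]] <- pfr
      next
    } else if (op == 9L) { # SIGMA
      a <- "0"
      if (fr$sp > 0L) { a <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      if (!.is_code_token(a)) a <- "0"
      fr$sp <- fr$sp + 1L
      fr$stack[[fr$sp]] <- .memo(paste0("S", a), function() gn_of_text(.sigma_text(a, a)))
      fr$pc <- fr$pc + 1L
    } else if (op == 10L) { # PAD
      a <- "0"
      if (fr$sp > 0L) { a <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      if (!.is_code_token(a)) a <- "0"
      fr$sp <- fr$sp + 1L
      fr$stack[[fr$sp]] <- .memo(paste0("P", a), function() gn_of_text(paste0(.decode_text(a), ".")))
      fr$pc <- fr$pc + 1L
    } else if (op == 11L) { # COMPOSE
      a <- "0"; b <- "0"
      if (fr$sp > 0L) { a <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      if (fr$sp > 0L) { b <- fr$stack[[fr$sp]]; fr$sp <- fr$sp - 1L }
      if (!.is_code_token(a)) a <- "0"
      if (!.is_code_token(b)) b <- "0"
      fr$sp <- fr$sp + 1L
      fr$stack[[fr$sp]] <- .memo(paste0("C", a, "|", b), function() gn_of_text(.compose_text(a, b)))
      fr$pc <- fr$pc + 1L
    } else if (op == 12L) { # SELF
      if (is.null(fr$prog$gn)) {
        fr$prog$gn <- gn_of_text(fr$prog$text)
        key <- paste0("k", fr$prog$text)
        if (!is.null(.prog_cache[[key]])) .prog_cache[[key]]$gn <- fr$prog$gn
      }
      fr$sp <- fr$sp + 1L
      fr$stack[[fr$sp]] <- fr$prog$gn
      fr$pc <- fr$pc + 1L
    } else {
      stop("internal: unknown opcode ", op)
    }
    frames[[depth]] <- fr
  }
}

new_frame <- function(prog, input) {
  list(prog = prog, pc = 1L, stack = vector("list", 16L), sp = 0L, input = input)
}

new_outcome <- function(status, output, steps, stuck = FALSE) {
  structure(list(status = status, output = output, steps = steps),
            class = "gtp_outcome", stuck = stuck)
}

#' @export
print.gtp_outcome <- function(x, ...) {
  cat("<gtp_outcome> ", x$status,
      if (x$status == "HALTED") paste0(" output=", deparse(x$output)) else "",
      " steps=", x$steps, "\n", sep = "")
  invisible(x)
}

#' Effective composition of programs
#'
#' Returns a program computing `phi_f(phi_g(x))`.  The encoding is canonical
#' and deterministic (it wraps the two Goedel numbers in a fixed template), so
#' `compose(f, g)` has a stable, comparable Goedel number.  In the model this
#' realises `f ∘ g`: in particular a negator antigen `f¬` applied to a gene
#' `g` yields the conflicted code `g¬ = compose(f¬, g)`.
#'
#' @param f,g `gtp_program`s (or Goedel numbers).
#' @return a `gtp_program`.
#' @export
compose <- function(f, g) {
  f <- as_program(f); g <- as_program(g)
  encode_program(.compose_text(f$gn, g$gn))
}

#' Operational totality check on a battery
#'
#' True totality is undecidable (the set of total computable functions is not
#' recursively enumerable); this operational surrogate asks whether the
#' program halts within the budget on every input of a declared finite
#' battery.
#'
#' @param f a `gtp_program` (or Goedel number).
#' @param battery nonempty character vector of input tokens.
#' @param budget step budget.
#' @return `TRUE`/`FALSE`; attribute `"diverging_input"` names the first
#'   non-halting input when `FALSE`.
#' @export
is_total_on_battery <- function(f, battery = standard_battery(), budget = gtp_budget()) {
  f <- as_program(f)
  stopifnot(length(battery) > 0L)
  for (b in battery) {
    if (run_program(f, b, budget)$status != "HALTED") {
      return(structure(FALSE, diverging_input = b))
    }
  }
  TRUE
}

#' Extensional equality on a battery
#'
#' Two programs are extensionally equal (operationally) when their execution
#' outcomes — status and output — agree on every input of the declared battery
#' at the given budget.  All extensional claims in this package are of this
#' bounded form.
#'
#' @param f,g programs (or Goedel numbers).
#' @param battery character vector of input tokens.
#' @param budget step budget.
#' @return `TRUE`/`FALSE`; attribute `"witness"` names the first
#'   distinguishing input when `FALSE`.
#' @export
ext_equal <- function(f, g, battery = standard_battery(), budget = gtp_budget()) {
  f <- as_program(f); g <- as_program(g)
  for (b in battery) {
    rf <- run_program(f, b, budget)
    rg <- run_program(g, b, budget)
    if (!identical(rf$status, rg$status) || !identical(rf$output, rg$output)) {
      return(structure(FALSE, witness = b))
    }
  }
  TRUE
}
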