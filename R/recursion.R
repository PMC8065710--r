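# The recursion-theoretic core: Diag (self-application), the s-m-n sigma
# index (offline meta-representation), the Rogers fixed-point construction,
# bounded dovetailed enumeration of listable sets, and the liar fixed point
# ("Goedel sentence") for a negator antigen acting on a gene code.

#' s-m-n meta-index sigma(x, y)
#'
#' Builds the canonical program whose run on a state token `s` realises the
#' two-stage semantics: evaluate `phi_x(y)`; if that halts with output `e`,
#' evaluate `phi_e(s)`.  The index exists for every pair — including pairs
#' whose first-stage evaluation diverges — which is what lets the thymus run
#' simulation exercises over codes it can never safely execute online.
#'
#' The pair also gets a single composite identifier `pair(x, y)` used for
#' exact (intensional) matching of motifs against the peripheral meta-index.
#'
#' @param x,y Goedel numbers (numbers, decimal strings, or `gtp_program`s).
#' @return a `sigma_index`: list with `left`, `right` (decimal strings),
#'   `code` (`gtp_program`) and `composite_gn` (decimal string).
#' @examples
#' s <- smn_sigma(encode_program("i"), 0)
#' s$composite_gn
#' @export
smn_sigma <- function(x, y) {
  x <- .as_gn(x); y <- .as_gn(y)
  code <- encode_program(.sigma_text(x, y))
  structure(list(left = x, right = y, code = code, composite_gn = pair(x, y)),
            class = "sigma_index")
}

.as_gn <- function(x) {
  if (inherits(x, "gtp_program")) return(x$gn)
  gn(x)
}

#' @export
print.sigma_index <- function(x, ...) {
  cat("<sigma_index> sigma(", .abbrev_gn(x$left), ", ", .abbrev_gn(x$right),
      ") composite ", .abbrev_gn(x$composite_gn), "\n", sep = "")
  invisible(x)
}

.abbrev_gn <- function(g) {
  if (nchar(g) > 18L) paste0(substr(g, 1, 8), "..", substr(g, nchar(g) - 5, nchar(g))) else g
}

#' Self-application Diag(g)
#'
#' Runs program `g` on its own Goedel number — the model of online
#' self-assembly: a gene code instructs the machine to execute itself, and a
#' halting self-application emits the tissue phenotype.
#'
#' @param g a `gtp_program` or Goedel number.
#' @param budget step budget.
#' @return a `gtp_outcome`.
#' @export
self_apply <- function(g, budget = gtp_budget()) {
  g <- as_program(g)
  run_program(g, g$gn, budget)
}

#' Rogers fixed point of a total code transformer
#'
#' For a transformer `f` (a program mapping Goedel-number tokens to
#' Goedel-number tokens, total on the declared battery) constructs `v` with
#' `phi_{f(v)}` extensionally equal to `phi_v`.  The construction is the
#' standard diagonal one expressed with [smn_sigma()] and [self_apply()]:
#' let `p` compute `u -> f(sigma(u, u))`; then `v = sigma(p, p)`, since
#' `phi_v(z) = phi_{phi_p(p)}(z) = phi_{f(sigma(p,p))}(z) = phi_{f(v)}(z)`.
#'
#' @param f transformer program (or Goedel number).
#' @param battery battery of code tokens on which `f` must be total
#'   (default: Goedel numbers 0..24 as tokens).
#' @param budget step budget.
#' @return `fixed_point_result`: list with `v` (`gtp_program`) and
#'   `transformer_gn`.
#' @export
fixed_point <- function(f, battery = as.character(0:24), budget = gtp_budget()) {
  f <- as_program(f)
  tot <- is_total_on_battery(f, battery, budget)
  if (!isTRUE(tot)) {
    stop("transformer is not total on the battery; diverges on input '",
         attr(tot, "diverging_input"), "'")
  }
  p <- encode_program(paste0("iS[", f$gn, "]@"))
  v <- smn_sigma(p$gn, p$gn)$code
  structure(list(v = v, transformer_gn = f$gn), class = "fixed_point_result")
}

#' Apply a code transformer to a program
#'
#' Runs transformer `f` on the Goedel number of `g` and decodes the output
#' token as a program.  Used to evaluate the two legs of the fixed-point law.
#'
#' @param f transformer program; must halt on `g`'s Goedel number.
#' @param g program (or Goedel number).
#' @param budget step budget.
#' @return a `gtp_program`.
#' @export
transform_code <- function(f, g, budget = gtp_budget()) {
  f <- as_program(f); g <- as_program(g)
  r <- run_program(f, g$gn, budget)
  if (r$status != "HALTED") stop("transformer did not halt on ", .abbrev_gn(g$gn))
  if (!.is_code_token(r$output)) stop("transformer output is not a Goedel number")
  decode_program(r$output)
}

#' Bounded dovetailed enumeration of a listable set
#'
#' Enumerates, in deterministic discovery order, inputs on which program `x`
#' halts: the bounded operational surrogate of the recursively enumerable set
#' `W_x`.  Candidates are the integers `0, 1, 2, ...` up to `max_candidates`;
#' in round `r` every candidate seen so far has its step allotment raised by a
#' quantum of 64 steps (capped at `budget`) and is re-examined in index order.
#' A candidate whose run parks on the perpetual-loop instruction is provably
#' non-halting at every budget and is not re-examined.
#'
#' @param x program (or Goedel number) indexing the set.
#' @param bound maximum number of members to return (`N >= 0`).
#' @param budget per-candidate step cap.
#' @param max_candidates size of the scanned candidate space (documented
#'   bound of the surrogate; the unbounded set is not recursively scannable).
#' @return `we_prefix`: list with `index`, `bound`, `members` (numeric vector
#'   in discovery order), `budget`, `max_candidates`.
#' @export
enumerate_we <- function(x, bound, budget = gtp_budget(), max_candidates = 1024L) {
  x <- as_program(x)
  bound <- as.integer(bound)
  stopifnot(bound >= 0L, max_candidates >= 1L)
  members <- numeric(0)
  if (bound > 0L) {
    quantum <- 64L
    allot <- integer(max_candidates)  # steps granted so far; 0 = untried
    state <- integer(max_candidates)  # 0 active, 1 halted, 2 proven non-halting
    r <- 0L
    repeat {
      r <- r + 1L
      active_any <- FALSE
      upto <- min(r, max_candidates)
      for (i in seq_len(upto)) {
        if (state[i] != 0L) next
        if (allot[i] >= budget) next
        allot[i] <- min(allot[i] + quantum, budget)
        active_any <- TRUE
        res <- .run_text(x$text, as.character(i - 1L), allot[i])
        if (res$status == "HALTED") {
          state[i] <- 1L
          members <- c(members, i - 1L)
          if (length(members) >= bound) break
        } else if (isTRUE(attr(res, "stuck"))) {
          state[i] <- 2L
        }
      }
      if (length(members) >= bound) break
      if (!active_any && upto >= max_candidates) break
    }
  }
  structure(list(index = x$gn, bound = bound, members = members,
                 budget = budget, max_candidates = as.integer(max_candidates)),
            class = "we_prefix")
}

#' @export
print.we_prefix <- function(x, ...) {
  cat("<we_prefix> W_", .abbrev_gn(x$index), ": ", length(x$members),
      " member(s) found (bound ", x$bound, ", budget ", x$budget, ")\n", sep = "")
  invisible(x)
}

#' Liar fixed point: the Goedel sentence for an antigen-gene pair
#'
#' Given a total negator `f¬` and a gene code `g`, forms the conflicted code
#' `g¬ = compose(f¬, g)` and its diagonal meta-index `sigma(g¬, g¬)` — the
#' sentence by which the attacked self-code can report the attack.  The
#' sentence's composite Goedel number is the canonical identifier of the
#' antigen–tissue pair.  Direct evaluation of the sentence code exhausts any
#' step budget: self-application of the conflicted code re-enters its own
#' self-check and diverges, so at the fixed point the outcome of the
#' host–parasite game is not predictable.
#'
#' @param negator a total transformer program (the antigen code).
#' @param g gene program or Goedel number.
#' @param battery battery for the totality pre-check of the negator.
#' @param budget step budget.
#' @return list with `g_neg` (decimal-string Goedel number of the conflicted
#'   code) and `sentence` (a `sigma_index`).
#' @export
liar_fixed_point <- function(negator, g, battery = standard_battery(), budget = gtp_budget()) {
  negator <- as_program(negator)
  tot <- is_total_on_battery(negator, battery, budget)
  if (!isTRUE(tot)) {
    stop("negator is not total on the battery; diverges on input '",
         attr(tot, "diverging_input"), "'")
  }
  g <- as_program(g)
  g_neg <- compose(negator, g)
  sentence <- smn_sigma(g_neg$gn, g_neg$gn)
  list(g_neg = g_neg$gn, sentence = sentence)
}
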