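# Shared fixtures and independent oracles.  Oracles re-derive expected
# behaviour without going through the code path under test.

ID <- encode_program("i")
NEG <- encode_program("i!")
LOOP <- encode_program("L")

tiny_genome <- function(n = 2L, seed = 7L) synth_genome(n, seed)

# Independent two-stage oracle for sigma-indexed execution: evaluate
# phi_x(y); if that halts with output e, evaluate e as a code on s using the
# machine's documented token-as-code convention.  Each stage gets its own
# budget; the sigma path is run with a generous combined budget so that the
# comparison is away from the halting boundary.
oracle_two_stage <- function(x, y, s, stage_budget = 2048L) {
  r1 <- run_program(decode_program(x), y, stage_budget)
  if (r1$status != "HALTED") {
    return(list(status = "BUDGET_EXHAUSTED", output = NULL))
  }
  e <- r1$output
  if (grepl("^[0-9]+$", e) && nchar(e) > 0L) {
    r2 <- run_program(decode_program(e), s, stage_budget)
    return(list(status = r2$status,
                output = if (r2$status == "HALTED") r2$output else NULL))
  }
  list(status = "HALTED", output = e)
}

# A pool of programs with varied halting behaviour for property tests.
program_pool <- function(genome) {
  genes <- lapply(genome$gn, decode_program)
  composites <- lapply(genes, function(g) compose(NEG, g))
  c(list(ID, NEG, LOOP, encode_program(""), encode_program("i!."),
         encode_program("i."), encode_program("[t0:+]"), encode_program("iP"),
         encode_program("iS")),
    genes, composites)
}

# Total code transformers for fixed-point tests: identity, no-op padding
# stacks, constants, and compose-with-f wrappers.
transformer_pool <- function(genome, k = 20L) {
  consts <- lapply(genome$gn[seq_len(min(4L, nrow(genome)))],
                   function(g) encode_program(paste0("[", g, "]")))
  pads <- lapply(1:6, function(j) encode_program(paste0("i", strrep("P", j))))
  wraps <- lapply(c(ID$gn, encode_program("i.")$gn), function(f)
    encode_program(paste0("i[", f, "]C")))
  base <- c(list(ID), pads, consts, wraps,
            list(encode_program("iS"), encode_program("iSP"),
                 encode_program("iPS"), encode_program("iPP."),
                 encode_program("i..P"), encode_program("[0]"),
                 encode_program("[5]"), encode_program("iP.P")))
  base[seq_len(min(k, length(base)))]
}
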