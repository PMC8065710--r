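# The machine substrate: numbering bijection, pairing, interpreter
# determinism and budget semantics, effective composition, totality.

test_that("Goedel numbering is a bijection with canonical ordering", {
  # round trip over an integer range
  for (n in c(0:400, 2500, 5000)) {
    expect_identical(encode_program(decode_program(n)$text)$gn, gn(n))
  }
  # canonical first element
  expect_identical(encode_program("")$gn, "0")
  # brute-force oracle: all strings of length <= 2 enumerate exactly 0..K
  alph <- gtp_alphabet()
  strs <- c("", alph, as.vector(outer(alph, alph, paste0)))
  gns <- vapply(strs, function(s) encode_program(s)$gn, character(1))
  K <- length(alph) + length(alph)^2
  expect_setequal(as.numeric(gns), 0:K)
  # ordering is length-then-lexicographic in the alphabet collation
  expect_lt(as.numeric(encode_program(alph[1])$gn),
            as.numeric(encode_program(alph[2])$gn))
  expect_lt(as.numeric(encode_program(alph[length(alph)])$gn),
            as.numeric(encode_program(paste0(alph[1], alph[1]))$gn))
  # round trip for all programs of length <= 3 over a sub-alphabet
  sub <- c(".", "i", "!", "[", "]")
  for (s in c(sub, as.vector(outer(sub, sub, paste0)),
              as.vector(outer(as.vector(outer(sub, sub, paste0)), sub, paste0)))) {
    expect_identical(decode_program(encode_program(s)$gn)$text, s)
  }
})

test_that("syntax errors are rejected naming the offending instruction", {
  expect_error(encode_program("i%"), "'%' at position 2")
  expect_error(encode_program("x"), "'x' at position 1")
})

test_that("Cantor pairing matches the closed form and inverts", {
  expect_identical(pair(0, 0), "0")
  expect_identical(pair(1, 2), "8")  # (1+2)(1+2+1)/2 + 2
  for (x in 0:50) for (y in 0:50) {
    u <- unpair(pair(x, y))
    expect_identical(u$x, gn(x))
    expect_identical(u$y, gn(y))
  }
  # closed form against independent arithmetic on a coarse grid
  for (x in c(0, 3, 17)) for (y in c(0, 5, 40)) {
    expect_identical(pair(x, y), gn((x + y) * (x + y + 1) / 2 + y))
  }
  # works beyond double precision and stays bijective
  big <- paste0("123456789", strrep("0", 30))
  u <- unpair(pair(big, "7"))
  expect_identical(u$x, gn(big))
  expect_identical(u$y, "7")
  expect_error(pair(-1, 0))
})

test_that("the interpreter is deterministic with monotone budget semantics", {
  r <- run_program(ID, "s0")
  expect_identical(r$status, "HALTED")
  expect_identical(r$output, "s0")
  loop <- run_program(LOOP, "s0", 777L)
  expect_identical(loop$status, "BUDGET_EXHAUSTED")
  expect_identical(loop$steps, 777L)
  expect_null(loop$output)
  # determinism: identical outcomes on repeated runs
  g <- tiny_genome(1)
  a <- run_program(decode_program(g$gn[1]), g$gn[1], 500L)
  b <- run_program(decode_program(g$gn[1]), g$gn[1], 500L)
  expect_identical(a[], b[])
  # monotonicity: halting outcomes invariant under budget increase
  for (T2 in c(600L, 5000L, 50000L)) {
    c2 <- run_program(decode_program(g$gn[1]), g$gn[1], T2)
    expect_identical(c2$status, a$status)
    expect_identical(c2$output, a$output)
    expect_identical(c2$steps, a$steps)
  }
})

test_that("composition has extensional two-stage semantics", {
  battery <- c(standard_battery(10), "t0:+", "t0:-")
  # identity law and negation involution
  expect_true(ext_equal(compose(ID, NEG), NEG, battery, 2000L))
  expect_true(ext_equal(compose(NEG, NEG), ID, battery, 2000L))
  # two-stage oracle: compose(NEG, g) equals NEG applied to g's output
  g <- decode_program(tiny_genome(1)$gn[1])
  for (x in c(g$gn, "s0")) {
    lhs <- run_program(compose(NEG, g), x, 4000L)
    r1 <- run_program(g, x, 2000L)
    if (r1$status == "HALTED") {
      rhs <- run_program(NEG, r1$output, 2000L)
      expect_identical(lhs$status, "HALTED")
      expect_identical(lhs$output, rhs$output)
    } else {
      expect_identical(lhs$status, "BUDGET_EXHAUSTED")
    }
  }
  # associativity on evaluated triples from a program pool
  pool <- list(ID, NEG, encode_program("i."), encode_program("i!."))
  for (f in pool) for (gg in pool) for (h in pool) {
    expect_true(ext_equal(compose(f, compose(gg, h)),
                          compose(compose(f, gg), h),
                          standard_battery(5), 2000L))
  }
  # composition has a stable canonical Goedel number
  expect_identical(compose(NEG, ID)$gn, compose(NEG, ID)$gn)
})

test_that("operational totality separates total from diverging programs", {
  expect_true(is_total_on_battery(ID, standard_battery(20), 500L))
  tot <- is_total_on_battery(LOOP, standard_battery(20), 500L)
  expect_false(isTRUE(tot))
  expect_identical(attr(tot, "diverging_input"), "s0")
  # the canonical negator is total on the standard battery
  expect_true(is_total_on_battery(NEG, standard_battery(), 500L))
})
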