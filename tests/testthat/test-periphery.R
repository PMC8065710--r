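# Online attacks, peripheral meta-index updates, rendezvous detection,
# antibody production, the response decision table, and autoimmune patrol.

peri_world <- function(n = 4L, seed = 29L, ifn = TRUE, dropout = character(0)) {
  genome <- synth_genome(n, seed)
  world <- develop(genome)
  records <- self_rep(genome, dropout)
  rep <- thymic_select(genome, records, n = 60L, seed = seed)
  list(genome = genome, world = world, records = records, repertoire = rep,
       state = pmhc_init(world, ifn_gamma = ifn))
}

test_that("online attacks negate the phenotype and obey the idempotence guard", {
  fx <- peri_world()
  target <- fx$genome[2, ]
  ag <- make_negator(target)
  w2 <- online_attack(fx$world, ag, target)
  ti <- match("t1", w2$tissues$tissue)
  expect_identical(w2$tissues$phenotype[ti], "t1:-")
  # observed equals the independent run of the conflicted code on the gene
  direct <- run_program(compose(ag$code, decode_program(target$gn)), target$gn)
  expect_identical(w2$events$observed[1], direct$output)
  # unattacked world remains the benign baseline
  expect_true(all(fx$world$tissues$phenotype == fx$world$tissues$baseline))
  # a second attack on the same tissue is rejected
  expect_error(online_attack(w2, ag, target), "already negated")
})

test_that("the peripheral index updates only under intact interferon-gamma", {
  fx <- peri_world(ifn = TRUE)
  target <- fx$genome[2, ]
  ag <- make_negator(target)
  w2 <- online_attack(fx$world, ag, target)
  ev <- w2$events[1, ]
  st_on <- pmhc_update(fx$state, ev)
  lf <- liar_fixed_point(ag$code, target$gn)
  ti <- match("t1", st_on$tissue)
  expect_identical(st_on$index[ti], lf$sentence$composite_gn)
  # knockout: the index stays at the benign default (blind spot)
  fx_off <- peri_world(ifn = FALSE)
  st_off <- pmhc_update(fx_off$state, ev)
  expect_identical(st_off$index, st_off$default_index)
  # two attacks on different tissues update independently, in either order
  t3 <- fx$genome[4, ]
  ag3 <- make_negator(t3)
  w3 <- online_attack(w2, ag3, t3, time = 2L)
  ev3 <- w3$events[2, ]
  ab <- pmhc_update(pmhc_update(fx$state, ev), ev3)
  ba <- pmhc_update(pmhc_update(fx$state, ev3), ev)
  expect_identical(ab$index, ba$index)
})

test_that("rendezvous detection requires the conflicted index and the motif", {
  fx <- peri_world()
  target <- fx$genome[2, ]
  ag <- make_negator(target)
  lf <- liar_fixed_point(ag$code, target$gn)
  diag_motif <- make_motif(ag$code, target, "DIAGONAL")
  rep_with <- inject_motif(fx$repertoire, diag_motif)
  w2 <- online_attack(fx$world, ag, target)
  st <- pmhc_update(fx$state, w2$events[1, ])
  hit <- detect(rep_with, st)
  expect_false(is.null(hit))
  expect_identical(hit$composite_gn, lf$sentence$composite_gn)
  expect_identical(hit$tissue_matched, "t1")
  # benign default index never fires, even with the motif present
  expect_null(detect(rep_with, fx$state))
  # missing diagonal motif: no rendezvous
  without <- fx$repertoire$released[
    fx$repertoire$released$composite_gn != lf$sentence$composite_gn, ]
  expect_null(detect(without, st))
})

test_that("produced antibodies restore the baseline and avoid the listable sets", {
  fx <- peri_world()
  target <- fx$genome[2, ]
  ag <- make_negator(target)
  reg <- build_registry(list())
  lf <- liar_fixed_point(ag$code, target$gn)
  w2 <- online_attack(fx$world, ag, target)
  ab <- produce_antibody(lf$sentence$composite_gn, ag, target, fx$genome, reg,
                         bound = 200L)
  # neutralisation: involution restores the attacked tissue
  w3 <- apply_antibody(w2, ab, "t1")
  ti <- match("t1", w3$tissues$tissue)
  expect_identical(w3$tissues$phenotype[ti], w3$tissues$baseline[ti])
  # productivity surrogate: outside both enumerated prefixes and both sets
  pg <- enumerate_we(genome_sentinel(fx$genome), 200L, max_candidates = 256L)
  pr <- enumerate_we(set_sentinel(reg$entries$key), 200L, max_candidates = 256L)
  expect_false(ab$gn %in% c(fx$genome$gn, reg$entries$key,
                            as.character(pg$members), as.character(pr$members)))
  # a registry-listed sentence is refused (misrouting signal)
  reg2 <- build_registry(list(list(antigen = ag, gene = target)))
  expect_error(produce_antibody(lf$sentence$composite_gn, ag, target,
                                fx$genome, reg2, bound = 50L),
               "known registry")
})

test_that("the response decision table routes outcomes correctly", {
  # (b) novel antigen, interferon on, motif present -> NOVEL_ANTIBODY
  fx <- peri_world()
  target <- fx$genome[2, ]
  ag <- make_negator(target)
  rep_with <- inject_motif(fx$repertoire, make_motif(ag$code, target, "DIAGONAL"))
  w2 <- online_attack(fx$world, ag, target)
  st <- pmhc_update(fx$state, w2$events[1, ])
  reg <- build_registry(list())
  out <- respond(w2, rep_with, st, reg, fx$genome, bound = 100L, patrol_steps = 5L)
  expect_identical(out$kind, "NOVEL_ANTIBODY")
  expect_false(is.null(out$antibody))
  # phenotype restored, and the sentence is now registered
  expect_true(all(out$world$tissues$phenotype == out$world$tissues$baseline))
  key <- pair(w2$events$g_neg_gn[1], w2$events$g_neg_gn[1])
  expect_true(key %in% out$registry$entries$key)
  # re-attack by the same antigen now takes the known path
  w3 <- online_attack(out$world, ag, target, time = 5L)
  st3 <- pmhc_update(st, w3$events[nrow(w3$events), ])
  out2 <- respond(w3, rep_with, st3, out$registry, fx$genome, bound = 100L,
                  patrol_steps = 5L)
  expect_identical(out2$kind, "KNOWN_ANTIBODY")
  # (a) registry-listed antigen -> KNOWN_ANTIBODY even without rendezvous
  fx2 <- peri_world(ifn = FALSE)
  regk <- build_registry(list(list(antigen = ag, gene = target)))
  w4 <- online_attack(fx2$world, ag, target)
  out3 <- respond(w4, fx2$repertoire, fx2$state, regk, fx2$genome,
                  bound = 100L, patrol_steps = 5L)
  expect_identical(out3$kind, "KNOWN_ANTIBODY")
  # (c) interferon knockout, novel antigen -> CYTOKINE_STORM, unrestored
  w5 <- online_attack(fx2$world, ag, target)
  out4 <- respond(w5, fx2$repertoire, fx2$state, reg, fx2$genome,
                  bound = 100L, patrol_steps = 5L)
  expect_identical(out4$kind, "CYTOKINE_STORM")
  ti <- match("t1", out4$world$tissues$tissue)
  expect_identical(out4$world$tissues$phenotype[ti], "t1:-")
  # (e) attack on a never-developed tissue -> UNDETECTED
  fx3 <- peri_world()
  fx3$world$tissues$developed[3] <- FALSE
  w6 <- online_attack(fx3$world, make_negator(fx3$genome[3, ]), fx3$genome[3, ])
  out5 <- respond(w6, fx3$repertoire, fx3$state, reg, fx3$genome,
                  bound = 100L, patrol_steps = 5L)
  expect_identical(out5$kind, "UNDETECTED")
  # integrity: an updated index without an attack event is an error
  st_bad <- fx$state
  st_bad$index[1] <- pair(1, 1)
  expect_error(respond(fx$world, fx$repertoire, st_bad, reg, fx$genome),
               "integrity")
})

test_that("patrol is safe for selected repertoires and lethal for escapes", {
  fx <- peri_world()
  # a fully selected repertoire never flips a healthy tissue
  pat <- autoimmune_patrol(fx$repertoire, fx$world, steps = 200L)
  expect_identical(nrow(pat$events), 0L)
  expect_identical(pat$world$tissues$phenotype, fx$world$tissues$baseline)
  # forced injection of a program-change motif flips its tissue at step 1
  ag <- make_negator(fx$genome[1, ])
  bad <- make_motif(ag$code, fx$genome[1, ], "PROGRAM_CHANGE")
  rep_bad <- inject_motif(fx$repertoire, bad)
  pat2 <- autoimmune_patrol(rep_bad, fx$world, steps = 10L)
  expect_identical(nrow(pat2$events), 1L)
  expect_identical(pat2$events$time[1], 1L)
  expect_identical(pat2$events$tissue[1], "t0")
  # conservation: other tissues keep their benign phenotype
  others <- pat2$world$tissues$tissue != "t0"
  expect_identical(pat2$world$tissues$phenotype[others],
                   pat2$world$tissues$baseline[others])
  # the no-attack respond branch classifies this as AUTOIMMUNE
  out <- respond(fx$world, rep_bad, fx$state, build_registry(list()),
                 fx$genome, patrol_steps = 10L)
  expect_identical(out$kind, "AUTOIMMUNE")
})
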