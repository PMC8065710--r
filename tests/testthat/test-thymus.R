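# Thymic mirror records, V(D)J motif generation and classification, and the
# positive/negative selection filters.

test_that("self-representation mirrors the genome minus AIRE dropout", {
  genome <- synth_genome(4, seed = 3)
  recs <- self_rep(genome)
  expect_identical(nrow(recs), 4L)
  drop <- self_rep(genome, aire_dropout = "t2")
  expect_identical(nrow(drop), 3L)
  expect_false("t2" %in% drop$tissue)
  # each record's phenotype equals the independent Diag output, and the
  # record's composite index is the diagonal pair
  for (k in seq_len(nrow(recs))) {
    expect_identical(recs$phenotype[k],
                     self_apply(decode_program(recs$gene_gn[k]))$output)
    expect_identical(recs$composite_gn[k], pair(recs$gene_gn[k], recs$gene_gn[k]))
  }
})

test_that("motif generation is seeded, gene-restricted and exhaustive when asked", {
  genome <- synth_genome(2, seed = 11)
  neg <- encode_program("i!")
  # 1 gene x 1 transformer: the exhaustive space has the three change forms
  m1 <- vdj_exhaustive(genome[1, ], list(neg))
  expect_identical(nrow(m1), 3L)
  expect_setequal(m1$nominal_form, c("INPUT_CHANGE", "PROGRAM_CHANGE", "DIAGONAL"))
  # all generated motifs reference a genome gene
  m <- vdj_generate(genome, list(neg), n = 50, seed = 5)
  expect_true(all(m$g_gn %in% genome$gn))
  expect_identical(vdj_generate(genome, list(neg), n = 50, seed = 5)$composite_gn,
                   m$composite_gn)
  # pool of 2 x 2 genes: exhaustive generation covers all 12 combinations
  pool2 <- list(neg, encode_program("i."))
  m12 <- vdj_exhaustive(genome, pool2)
  expect_identical(nrow(m12), 12L)
  combos <- unique(paste(m12$nominal_form, m12$f_gn, m12$g_gn))
  expect_length(combos, 12L)
  expect_error(vdj_generate(genome, list(), n = 5), "nonempty")
})

test_that("extensionally inert transformers collapse motifs to SELF", {
  genome <- synth_genome(2, seed = 11)
  id_pad <- encode_program("i.")
  m <- vdj_exhaustive(genome, list(id_pad))
  expect_true(all(m$form == "SELF"))
  neg <- encode_program("i!")
  mn <- vdj_exhaustive(genome, list(neg))
  expect_false(any(mn$form == "SELF"))
})

test_that("positive selection rejects exactly input-change and self motifs", {
  genome <- synth_genome(2, seed = 13)
  pool <- list(encode_program("i!"), encode_program("i."))
  m <- vdj_exhaustive(genome, pool)
  kept <- positive_select(m)
  # sigma(g, f.g) rejected; sigma(f.g, g) and sigma(f.g, f.g) retained;
  # SELF (inert transformer) rejected
  expect_setequal(unique(kept$form), c("PROGRAM_CHANGE", "DIAGONAL"))
  expect_identical(nrow(kept), 4L)  # 2 forms x 1 effective transformer x 2 genes
  expect_identical(attr(kept, "generated")$composite_gn, m$composite_gn)
  # order preserved
  expect_identical(kept$composite_gn,
                   m$composite_gn[m$form %in% c("PROGRAM_CHANGE", "DIAGONAL")])
})

test_that("negative selection eliminates lethal program-change motifs", {
  genome <- synth_genome(2, seed = 17)
  records <- self_rep(genome)
  neg <- encode_program("i!")
  m <- vdj_exhaustive(genome, list(neg))
  rep <- negative_select(positive_select(m), records)
  # the toy world: 6 generated, 4 post-positive, 2 diagonal released
  expect_identical(unname(rep$counts), c(6L, 4L, 2L))
  expect_true(all(rep$released$form == "DIAGONAL"))
  expect_true(all(rep$post_positive$composite_gn %in% m$composite_gn))
  expect_true(all(rep$released$composite_gn %in% rep$post_positive$composite_gn))
  # the eliminated motifs are exactly the two program-change ones
  gone <- setdiff(rep$post_positive$composite_gn, rep$released$composite_gn)
  expect_setequal(gone, m$composite_gn[m$form == "PROGRAM_CHANGE"])
})

test_that("AIRE dropout lets untestable program-change motifs escape", {
  genome <- synth_genome(3, seed = 19)
  records <- self_rep(genome, aire_dropout = "t2")
  neg <- encode_program("i!")
  m <- vdj_exhaustive(genome, list(neg))
  rep <- negative_select(positive_select(m), records)
  escaped <- rep$released[rep$released$form == "PROGRAM_CHANGE", ]
  expect_identical(nrow(escaped), 1L)
  expect_identical(escaped$tissue, "t2")
  # with escape disabled the motif is eliminated instead
  rep2 <- negative_select(positive_select(m), records,
                          escape_on_missing_record = FALSE)
  expect_false(any(rep2$released$form == "PROGRAM_CHANGE"))
})

test_that("repertoire stages are contained and summarised", {
  genome <- synth_genome(3, seed = 23)
  records <- self_rep(genome)
  rep <- thymic_select(genome, records, n = 60, seed = 2)
  expect_true(rep$counts[["released"]] <= rep$counts[["post_positive"]])
  expect_true(rep$counts[["post_positive"]] <= rep$counts[["generated"]])
  gl <- glance(rep)
  expect_identical(gl$generated, 60L)
  td <- tidy(rep)
  expect_identical(nrow(td), sum(rep$counts))
})
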