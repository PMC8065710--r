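# The offline thymic mirror: self-representation records (thymic MHC),
# V(D)J motif generation in the three change forms, and the two-stage
# positive/negative selection that releases only diagonal motifs.

#' Self-representation of the genome (thymic MHC records)
#'
#' One record per self-repped gene: the diagonal meta-index `sigma(g, g)`
#' together with the recorded healthy phenotype — the mirror of the
#' peripheral self on which receptor training is educated.  Genes whose
#' tissue is in `aire_dropout` fail to be mirrored (AIRE knockout) and are
#' invisible to negative selection.
#'
#' @param genome a `gtp_genome`.
#' @param aire_dropout character vector of tissues removed from the mirror.
#' @param budget step budget.
#' @return tibble with columns `gene_gn`, `tissue`, `phenotype`,
#'   `composite_gn` (of `sigma(g, g)`).
#' @export
self_rep <- function(genome, aire_dropout = character(0), budget = gtp_budget()) {
  keep <- genome$self_repped & !(genome$tissue %in% aire_dropout)
  g <- genome[keep, , drop = FALSE]
  phen <- character(nrow(g))
  comp <- character(nrow(g))
  for (k in seq_len(nrow(g))) {
    r <- self_apply(decode_program(g$gn[k]), budget)
    stopifnot(r$status == "HALTED")
    phen[k] <- r$output
    comp[k] <- pair(g$gn[k], g$gn[k])
  }
  tibble::tibble(gene_gn = g$gn, tissue = g$tissue, phenotype = phen,
                 composite_gn = comp)
}

#' Default transformer pool
#'
#' Total transformers the thymus composes onto gene codes when generating
#' receptor motifs: the canonical polarity negator, a padded negator variant
#' (same action, distinct Goedel number), and a padded identity (extensionally
#' inert — its motifs collapse to self).
#'
#' @return named list of `gtp_program`s.
#' @export
gtp_default_pool <- function() {
  list(neg = encode_program("i!"),
       neg_pad = encode_program("i!."),
       id_pad = encode_program("i."))
}

.motif_cols <- function() {
  tibble::tibble(nominal_form = character(0), form = character(0),
                 f_gn = character(0), g_gn = character(0), tissue = character(0),
                 left = character(0), right = character(0),
                 composite_gn = character(0), injected = logical(0))
}

# build one motif row; fg_cache maps paste(f_gn, g_gn) -> list(fg_gn, degenerate)
.build_motif <- function(f, gene_row, nominal_form, fg_cache, budget) {
  key <- paste0(f$gn, "|", gene_row$gn)
  ent <- fg_cache[[key]]
  if (is.null(ent)) {
    fg <- compose(f, decode_program(gene_row$gn))
    degen <- isTRUE(ext_equal(fg, gene_row$gn,
                              battery = c(gene_row$gn, "s0"), budget = 512L))
    ent <- list(fg_gn = fg$gn, degenerate = degen)
    fg_cache[[key]] <- ent
  }
  g <- gene_row$gn
  lr <- switch(nominal_form,
               INPUT_CHANGE   = c(g, ent$fg_gn),
               PROGRAM_CHANGE = c(ent$fg_gn, g),
               DIAGONAL       = c(ent$fg_gn, ent$fg_gn))
  form <- if (ent$degenerate) "SELF" else nominal_form
  tibble::tibble(nominal_form = nominal_form, form = form,
                 f_gn = f$gn, g_gn = g, tissue = gene_row$tissue,
                 left = lr[1], right = lr[2],
                 composite_gn = pair(lr[1], lr[2]), injected = FALSE)
}

#' Generate V(D)J receptor motifs
#'
#' Samples `n` motifs uniformly over (change form) x (transformer pool) x
#' (genes), reproducibly under the seed.  The three forms are a change of
#' input `sigma(g, f.g)`, a change of program `sigma(f.g, g)`, and a change
#' of both `sigma(f.g, f.g)`.  Transformers are only ever applied to genome
#' genes — motifs over non-biotic codes are ruled out a priori.  A motif
#' whose transformed code is extensionally indistinguishable from the gene
#' itself (checked on the gene's own Goedel number and a state token) offers
#' no diversity from self and is classified `SELF`.
#'
#' @param genome a `gtp_genome`.
#' @param pool nonempty list of total transformer programs.
#' @param n number of motifs (>= 1).
#' @param seed integer seed.
#' @param budget step budget for the pool totality pre-check.
#' @return `gtp_motifs` tibble: `nominal_form`, `form`, `f_gn`, `g_gn`,
#'   `tissue`, `left`, `right`, `composite_gn`, `injected`.
#' @export
vdj_generate <- function(genome, pool = gtp_default_pool(), n, seed = 42L,
                         budget = gtp_budget()) {
  if (length(pool) == 0L) stop("transformer pool must be nonempty")
  n <- as.integer(n)
  stopifnot(n >= 1L)
  pool <- lapply(pool, as_program)
  for (f in pool) {
    tot <- is_total_on_battery(f, standard_battery(), budget)
    if (!isTRUE(tot)) stop("pool transformer ", .abbrev_gn(f$gn),
                           " is not total on the battery")
  }
  forms <- c("INPUT_CHANGE", "PROGRAM_CHANGE", "DIAGONAL")
  draws <- withr::with_seed(seed, {
    tibble::tibble(fi = sample.int(3L, n, replace = TRUE),
                   pi = sample.int(length(pool), n, replace = TRUE),
                   gi = sample.int(nrow(genome), n, replace = TRUE))
  })
  fg_cache <- new.env(parent = emptyenv())
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    rows[[k]] <- .build_motif(pool[[draws$pi[k]]], genome[draws$gi[k], ],
                              forms[draws$fi[k]], fg_cache, budget)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gtp_motifs", class(out))
  out
}

#' Exhaustively enumerate the motif space
#'
#' Deterministic full enumeration of (form) x (pool) x (genes) — the toy-world
#' counterpart of [vdj_generate()] used to study the selection filters without
#' sampling noise.
#'
#' @inheritParams vdj_generate
#' @return `gtp_motifs` tibble.
#' @export
vdj_exhaustive <- function(genome, pool = gtp_default_pool(), budget = gtp_budget()) {
  if (length(pool) == 0L) stop("transformer pool must be nonempty")
  pool <- lapply(pool, as_program)
  fg_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (form in c("INPUT_CHANGE", "PROGRAM_CHANGE", "DIAGONAL")) {
    for (f in pool) {
      for (gi in seq_len(nrow(genome))) {
        rows[[length(rows) + 1L]] <- .build_motif(f, genome[gi, ], form,
                                                  fg_cache, budget)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gtp_motifs", class(out))
  out
}

#' Positive selection of receptor motifs
#'
#' Rejects every input-change motif `sigma(g, f.g)` — an execution
#' `phi_g(f.g)` that is no longer a self-assembly operation and is untenable
#' in the system — and every `SELF` motif, which offers no diversity from
#' self.  Program-change and diagonal motifs are retained, in order.
#'
#' @param motifs a `gtp_motifs` tibble.
#' @return retained motifs (`gtp_motifs`), with the full generated set in
#'   attribute `"generated"`.
#' @export
positive_select <- function(motifs) {
  out <- motifs[motifs$form %in% c("PROGRAM_CHANGE", "DIAGONAL"), , drop = FALSE]
  attr(out, "generated") <- motifs
  out
}

#' Negative selection against the self-representation records
#'
#' Each program-change motif with a mirrored record for its gene is executed
#' in simulation (the motif's sigma code on a state token): if the outcome
#' negates the recorded healthy phenotype the receptor is eliminated — these
#' motifs are exactly the ones that would be lethal in the periphery.
#' Diagonal motifs are retained: their simulated self-application diverges,
#' and divergence does not negate any record.  A program-change motif whose
#' gene has no record (AIRE dropout) cannot be tested; by default it escapes
#' into the released repertoire.
#'
#' @param motifs post-positive-selection motifs.
#' @param records self-representation records from [self_rep()].
#' @param budget step budget for the simulated runs.
#' @param escape_on_missing_record if `TRUE` (default) untestable motifs
#'   escape into the released set; if `FALSE` they are eliminated.
#' @param state state token used in the simulation.
#' @return `gtp_repertoire`: list with `generated`, `post_positive`,
#'   `released` motif tibbles and per-stage `counts`.
#' @export
negative_select <- function(motifs, records, budget = gtp_budget(),
                            escape_on_missing_record = TRUE, state = "s0") {
  generated <- attr(motifs, "generated")
  if (is.null(generated)) generated <- motifs
  keep <- logical(nrow(motifs))
  sim_cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(motifs))) {
    m <- motifs[k, ]
    if (m$form == "DIAGONAL") { keep[k] <- TRUE; next }
    if (m$form != "PROGRAM_CHANGE") { keep[k] <- FALSE; next }
    ri <- match(m$g_gn, records$gene_gn)
    if (is.na(ri)) { keep[k] <- escape_on_missing_record; next }
    ck <- paste0(m$left, "|", m$right)
    sim <- sim_cache[[ck]]
    if (is.null(sim)) {
      sim <- run_program(smn_sigma(m$left, m$right)$code, state, budget)
      sim_cache[[ck]] <- sim
    }
    negates <- sim$status == "HALTED" &&
      identical(sim$output, negate_phenotype(records$phenotype[ri]))
    keep[k] <- !negates
  }
  released <- motifs[keep, , drop = FALSE]
  new_repertoire(generated, motifs, released)
}

new_repertoire <- function(generated, post_positive, released) {
  structure(list(generated = generated, post_positive = post_positive,
                 released = released,
                 counts = c(generated = nrow(generated),
                            post_positive = nrow(post_positive),
                            released = nrow(released))),
            class = "gtp_repertoire")
}

#' One-call thymic training
#'
#' Convenience wrapper: generate motifs, apply positive then negative
#' selection, and return the staged repertoire.
#'
#' @inheritParams vdj_generate
#' @param records self-representation records ([self_rep()]).
#' @param escape_on_missing_record see [negative_select()].
#' @return a `gtp_repertoire`.
#' @export
thymic_select <- function(genome, records, pool = gtp_default_pool(), n = 500L,
                          seed = 42L, budget = gtp_budget(),
                          escape_on_missing_record = TRUE) {
  motifs <- vdj_generate(genome, pool, n, seed, budget)
  negative_select(positive_select(motifs), records, budget,
                  escape_on_missing_record)
}

#' @export
print.gtp_repertoire <- function(x, ...) {
  cat("<gtp_repertoire> generated ", x$counts[["generated"]],
      " -> post-positive ", x$counts[["post_positive"]],
      " -> released ", x$counts[["released"]], "\n", sep = "")
  invisible(x)
}

#' Inject a motif into a released repertoire
#'
#' Appends a motif row (flagged `injected`) to the released set — used by the
#' scenario runner both to rescue the detection-relevant diagonal motif when
#' sampling missed it and to model forced escape of a dangerous
#' program-change receptor.
#'
#' @param repertoire a `gtp_repertoire`.
#' @param motif a one-row motif tibble.
#' @return the updated `gtp_repertoire`.
#' @export
inject_motif <- function(repertoire, motif) {
  motif$injected <- TRUE
  repertoire$released <- dplyr::bind_rows(repertoire$released, motif)
  repertoire$counts[["released"]] <- nrow(repertoire$released)
  repertoire
}

#' Build a single motif for a given transformer, gene and form
#'
#' @param f transformer program.
#' @param gene_row one-row genome slice.
#' @param form one of `"INPUT_CHANGE"`, `"PROGRAM_CHANGE"`, `"DIAGONAL"`.
#' @param budget step budget.
#' @return one-row motif tibble.
#' @export
make_motif <- function(f, gene_row, form, budget = gtp_budget()) {
  form <- match.arg(form, c("INPUT_CHANGE", "PROGRAM_CHANGE", "DIAGONAL"))
  .build_motif(as_program(f), gene_row, form, new.env(parent = emptyenv()), budget)
}
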