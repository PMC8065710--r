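# The online world: antigen attacks, peripheral-MHC meta-index updates gated
# by interferon-gamma, Goedel-sentence rendezvous detection, productive
# novel-antibody construction, and autoimmune patrol.

#' Initialise the peripheral MHC state
#'
#' Each tissue's meta-index starts in the benign default `pair(g, g)` —
#' the record "self unaltered, the other's agency calibrated as self".  The
#' index moves to the conflicted diagonal `pair(g¬, g¬)` only when an attack
#' is recorded while the interferon-gamma circuitry is intact.
#'
#' @param world a `gtp_world`.
#' @param ifn_gamma logical; `FALSE` models the knockout (blind spot).
#' @return `pmhc_state`: tibble with `tissue`, `index`, `default_index`,
#'   plus attribute `ifn_gamma`.
#' @export
pmhc_init <- function(world, ifn_gamma = TRUE) {
  idx <- vapply(world$tissues$gene_gn, function(g) pair(g, g), character(1),
                USE.NAMES = FALSE)
  out <- tibble::tibble(tissue = world$tissues$tissue, index = idx,
                        default_index = idx)
  structure(out, ifn_gamma = isTRUE(ifn_gamma), class = c("pmhc_state", class(out)))
}

#' Online antigen attack on a tissue
#'
#' Runs the conflicted code `g¬ = compose(antigen, gene)` against the gene's
#' Goedel number: the attack succeeds (negates the phenotype) exactly because
#' the halting self-assembly computation is in place to be hijacked.  The
#' world's phenotype for that tissue flips and the event is logged.  A second
#' attack on an already-negated tissue is rejected.
#'
#' @param world a `gtp_world`.
#' @param antigen a `gtp_antigen`.
#' @param gene one-row genome slice (the target).
#' @param time integer time step for the event log.
#' @param budget step budget.
#' @return the updated `gtp_world`.
#' @export
online_attack <- function(world, antigen, gene, time = 1L, budget = gtp_budget()) {
  ti <- match(gene$tissue[1], world$tissues$tissue)
  if (is.na(ti)) stop("gene's tissue not present in the world")
  g_neg <- compose(antigen$code, decode_program(gene$gn[1]))
  if (!isTRUE(world$tissues$developed[ti])) {
    # attack on a never-developed tissue: nothing is in place to hijack,
    # and nothing records the damage
    world$events <- dplyr::bind_rows(world$events, tibble::tibble(
      time = as.integer(time), type = "attack_undeveloped",
      tissue = gene$tissue[1], gene_gn = gene$gn[1],
      antigen_gn = antigen$code$gn, g_neg_gn = g_neg$gn,
      motif_composite = NA_character_, observed = NA_character_))
    return(world)
  }
  if (world$tissues$phenotype[ti] != world$tissues$baseline[ti]) {
    stop("tissue ", gene$tissue[1], " is already negated; attack rejected")
  }
  r <- run_program(g_neg, gene$gn[1], budget)
  stopifnot(r$status == "HALTED")
  observed <- r$output
  stopifnot(identical(observed, negate_phenotype(world$tissues$baseline[ti])))
  world$tissues$phenotype[ti] <- observed
  world$events <- dplyr::bind_rows(world$events, tibble::tibble(
    time = as.integer(time), type = "attack", tissue = gene$tissue[1],
    gene_gn = gene$gn[1], antigen_gn = antigen$code$gn, g_neg_gn = g_neg$gn,
    motif_composite = NA_character_, observed = observed))
  world
}

#' Update the peripheral MHC meta-index after an attack
#'
#' With interferon-gamma intact, the attacked tissue's index is updated from
#' the benign default `pair(g, g)` to the conflicted diagonal
#' `pair(g¬, g¬)` — the experiential leg of the Goedel sentence.  With the
#' knockout, the index is left unchanged: the host keeps a blind spot about
#' the agency of the other.
#'
#' @param state a `pmhc_state`.
#' @param event a one-row attack event (from the world's event log).
#' @return the updated `pmhc_state`.
#' @export
pmhc_update <- function(state, event) {
  if (!isTRUE(attr(state, "ifn_gamma"))) return(state)
  if (!identical(event$type, "attack")) return(state)
  ti <- match(event$tissue, state$tissue)
  stopifnot(!is.na(ti))
  state$index[ti] <- pair(event$g_neg_gn, event$g_neg_gn)
  state
}

#' Goedel-sentence rendezvous detection
#'
#' Returns the first released receptor motif whose composite Goedel number
#' exactly equals some tissue's current peripheral meta-index, provided that
#' index differs from the tissue's benign default (a benign `sigma(g, g)`
#' match never fires).  Matching is intensional — exact integer equality of
#' canonical composite indices, no tolerance.
#'
#' @param released released motif tibble (or a `gtp_repertoire`).
#' @param state a `pmhc_state`.
#' @return a one-row motif tibble with an added `tissue_matched` column, or
#'   `NULL` when no rendezvous occurs.
#' @export
detect <- function(released, state) {
  if (inherits(released, "gtp_repertoire")) released <- released$released
  hot <- state$index != state$default_index
  if (!any(hot) || nrow(released) == 0L) return(NULL)
  hot_idx <- state$index[hot]
  hot_tissue <- state$tissue[hot]
  for (k in seq_len(nrow(released))) {
    m <- match(released$composite_gn[k], hot_idx)
    if (!is.na(m)) {
      out <- released[k, ]
      out$tissue_matched <- hot_tissue[m]
      return(out)
    }
  }
  NULL
}

#' Produce a novel antibody (productive surprise function)
#'
#' Constructs a total code that re-applies the negation to the attacked
#' tissue's output — negation is an involution, so application restores the
#' baseline phenotype — canonically padded with no-ops until its Goedel
#' number avoids the genome code set, the registry key set, and the first-`N`
#' dovetail-enumerated members of both listable-set surrogates.  This is the
#' operational reading of the productive-function requirement that the
#' response index lie outside the known listable sets.
#'
#' @param sentence composite Goedel number of the detected sentence.
#' @param antigen the attacking `gtp_antigen`.
#' @param gene one-row genome slice (the attacked gene).
#' @param genome the `gtp_genome` (its code set is one exclusion set).
#' @param registry a `gtp_registry` (its key set is the other).
#' @param bound `N`: enumeration depth of the exclusion prefixes.
#' @param budget step budget.
#' @param max_candidates candidate-space bound of the dovetailed scan
#'   (see [enumerate_we()]).
#' @return `gtp_antibody`: list with `code`, `gn`, `target_sentence`,
#'   `target_tissue`.
#' @export
produce_antibody <- function(sentence, antigen, gene, genome, registry,
                             bound = 10000L, budget = gtp_budget(),
                             max_candidates = 1024L) {
  if (sentence %in% registry$entries$key) {
    stop("sentence is in the known registry; use the stock antibody path")
  }
  pref_g <- enumerate_we(genome_sentinel(genome), bound, budget, max_candidates)
  pref_r <- enumerate_we(set_sentinel(registry$entries$key), bound, budget,
                         max_candidates)
  excluded <- c(genome$gn, registry$entries$key,
                vapply(pref_g$members, gn, character(1)),
                vapply(pref_r$members, gn, character(1)))
  text <- "i!"
  code <- encode_program(text)
  while (code$gn %in% excluded) {
    text <- paste0(text, ".")
    code <- encode_program(text)
  }
  stopifnot(isTRUE(is_total_on_battery(code, standard_battery(), budget)))
  structure(list(code = code, gn = code$gn, target_sentence = sentence,
                 target_tissue = gene$tissue[1]),
            class = "gtp_antibody")
}

#' @export
print.gtp_antibody <- function(x, ...) {
  cat("<gtp_antibody> gn ", .abbrev_gn(x$gn), " for sentence ",
      .abbrev_gn(x$target_sentence), " (", x$target_tissue, ")\n", sep = "")
  invisible(x)
}

#' Apply an antibody to a tissue
#'
#' Runs the antibody code on the tissue's current phenotype token and writes
#' the result back — for a negated tissue the involution restores the
#' baseline.
#'
#' @param world a `gtp_world`.
#' @param antibody a `gtp_antibody` (or any program).
#' @param tissue tissue label.
#' @param time event-log time.
#' @param budget step budget.
#' @return the updated `gtp_world`.
#' @export
apply_antibody <- function(world, antibody, tissue, time = 2L, budget = gtp_budget()) {
  code <- if (inherits(antibody, "gtp_antibody")) antibody$code else as_program(antibody)
  ti <- match(tissue, world$tissues$tissue)
  stopifnot(!is.na(ti))
  r <- run_program(code, world$tissues$phenotype[ti], budget)
  stopifnot(r$status == "HALTED")
  world$tissues$phenotype[ti] <- r$output
  world$events <- dplyr::bind_rows(world$events, tibble::tibble(
    time = as.integer(time), type = "antibody", tissue = tissue,
    gene_gn = world$tissues$gene_gn[ti], antigen_gn = NA_character_,
    g_neg_gn = NA_character_, motif_composite = NA_character_,
    observed = r$output))
  world
}

#' Autoimmune patrol of released receptors
#'
#' Executes every released motif against the world at each step: a motif
#' whose simulated action halts with the negation of a healthy tissue's
#' current phenotype flips that tissue and is logged as an autoimmune event.
#' Diagonal motifs are harmless on a healthy world — their self-application
#' diverges.  Motif actions are cached per (motif, tissue state): the world
#' dynamics are deterministic, so unchanged states replay identically.
#'
#' @param released released motif tibble (or `gtp_repertoire`).
#' @param world a `gtp_world`.
#' @param steps number of patrol steps.
#' @param budget step budget per simulated run.
#' @param state state token for the simulated runs.
#' @return list with `world` (possibly flipped tissues, events appended) and
#'   `events` (the autoimmune events logged by this patrol).
#' @export
autoimmune_patrol <- function(released, world, steps = 1000L,
                              budget = gtp_budget(), state = "s0") {
  if (inherits(released, "gtp_repertoire")) released <- released$released
  steps <- as.integer(steps)
  events <- empty_events()
  cache <- new.env(parent = emptyenv())
  if (nrow(released) > 0L) {
    for (st in seq_len(steps)) {
      changed <- FALSE
      for (k in seq_len(nrow(released))) {
        mo <- released[k, ]
        ti <- match(mo$tissue, world$tissues$tissue)
        if (is.na(ti)) next
        cur <- world$tissues$phenotype[ti]
        ck <- paste0(mo$composite_gn, "|", cur)
        act <- cache[[ck]]
        if (is.null(act)) {
          sim <- run_program(smn_sigma(mo$left, mo$right)$code, state, budget)
          act <- if (sim$status == "HALTED") sim$output else NA_character_
          cache[[ck]] <- act
        }
        healthy <- cur == world$tissues$baseline[ti]
        if (!is.na(act) && healthy && identical(act, negate_phenotype(cur))) {
          world$tissues$phenotype[ti] <- act
          ev <- tibble::tibble(time = st, type = "autoimmune", tissue = mo$tissue,
                               gene_gn = mo$g_gn, antigen_gn = NA_character_,
                               g_neg_gn = mo$left,
                               motif_composite = mo$composite_gn, observed = act)
          events <- dplyr::bind_rows(events, ev)
          world$events <- dplyr::bind_rows(world$events, ev)
          changed <- TRUE
        }
      }
      # deterministic dynamics: once no motif can act on the current state,
      # further steps are identical
      if (!changed && st > 1L) break
    }
  }
  list(world = world, events = events)
}

#' Immune response decision
#'
#' Applies the outcome decision table to the current world, released
#' repertoire, peripheral state and registry:
#'
#' * attack whose sentence is in the registry: `KNOWN_ANTIBODY` (stock
#'   antibody applied, phenotype restored);
#' * attack + rendezvous match + novel antigen: `NOVEL_ANTIBODY` via
#'   [produce_antibody()] (applied, restored, and the new antibody is added
#'   to the registry under the sentence key);
#' * attack with no rendezvous (interferon-gamma knockout, or the diagonal
#'   motif is missing from the repertoire): `CYTOKINE_STORM` — damage is
#'   sensed but no code-specific response is produced and the phenotype
#'   stays negated;
#' * no attack, but a released program-change motif flips a healthy tissue
#'   during patrol: `AUTOIMMUNE`;
#' * attack on a tissue whose baseline was never developed: `UNDETECTED`;
#' * nothing at all: `NONE` (quiescent benign run).
#'
#' @param world a `gtp_world`.
#' @param released released motifs (or `gtp_repertoire`).
#' @param state a `pmhc_state`.
#' @param registry a `gtp_registry`.
#' @param genome the `gtp_genome`.
#' @param bound enumeration depth for antibody production.
#' @param budget step budget.
#' @param patrol_steps patrol length used on the no-attack branch.
#' @param max_candidates candidate-space bound for the exclusion scans.
#' @return `immune_outcome`: list with `kind`, `antibody` (or `NULL`),
#'   `events`, `world`, `registry`.
#' @export
respond <- function(world, released, state, registry, genome,
                    bound = 10000L, budget = gtp_budget(), patrol_steps = 1000L,
                    max_candidates = 1024L) {
  if (inherits(released, "gtp_repertoire")) released <- released$released
  # integrity: a non-default index must be backed by an attack event
  hot <- which(state$index != state$default_index)
  for (ti in hot) {
    ok <- any(world$events$type == "attack" & world$events$tissue == state$tissue[ti])
    if (!ok) stop("integrity error: peripheral index for ", state$tissue[ti],
                  " updated with no recorded attack event")
  }
  undev <- world$events[world$events$type == "attack_undeveloped", , drop = FALSE]
  if (nrow(undev) > 0L) {
    return(new_outcome_immune("UNDETECTED", NULL, world$events, world, registry))
  }
  attacks <- world$events[world$events$type == "attack", , drop = FALSE]
  unresolved <- attacks[vapply(seq_len(nrow(attacks)), function(k) {
    ti <- match(attacks$tissue[k], world$tissues$tissue)
    world$tissues$phenotype[ti] != world$tissues$baseline[ti]
  }, logical(1)), , drop = FALSE]
  if (nrow(unresolved) > 0L) {
    ev <- unresolved[1, ]
    key <- pair(ev$g_neg_gn, ev$g_neg_gn)
    ri <- match(key, registry$entries$key)
    if (!is.na(ri)) {
      world <- apply_antibody(world, decode_program(registry$entries$antibody_gn[ri]),
                              ev$tissue, time = ev$time + 1L, budget = budget)
      ti <- match(ev$tissue, world$tissues$tissue)
      stopifnot(world$tissues$phenotype[ti] == world$tissues$baseline[ti])
      return(new_outcome_immune("KNOWN_ANTIBODY", NULL, world$events, world, registry))
    }
    hit <- detect(released, state)
    if (!is.null(hit)) {
      gene_row <- genome[genome$tissue == ev$tissue, , drop = FALSE]
      antigen <- structure(list(code = decode_program(ev$antigen_gn),
                                target_tissue = ev$tissue, target_gn = ev$gene_gn,
                                novel = TRUE), class = "gtp_antigen")
      ab <- produce_antibody(key, antigen, gene_row, genome, registry,
                             bound = bound, budget = budget,
                             max_candidates = max_candidates)
      world <- apply_antibody(world, ab, ev$tissue, time = ev$time + 1L,
                              budget = budget)
      ti <- match(ev$tissue, world$tissues$tissue)
      stopifnot(world$tissues$phenotype[ti] == world$tissues$baseline[ti])
      registry$entries <- dplyr::bind_rows(registry$entries, tibble::tibble(
        key = key, antigen_gn = ev$antigen_gn, gene_gn = ev$gene_gn,
        antibody_gn = ab$gn, antibody_text = ab$code$text))
      registry$sentinel_index <- set_sentinel(registry$entries$key)$gn
      return(new_outcome_immune("NOVEL_ANTIBODY", ab, world$events, world, registry))
    }
    # innate fallback: the flip is sensed, no code-specific response
    storm <- tibble::tibble(time = ev$time + 1L, type = "cytokine_storm",
                            tissue = ev$tissue, gene_gn = ev$gene_gn,
                            antigen_gn = ev$antigen_gn, g_neg_gn = ev$g_neg_gn,
                            motif_composite = NA_character_,
                            observed = world$tissues$phenotype[
                              match(ev$tissue, world$tissues$tissue)])
    world$events <- dplyr::bind_rows(world$events, storm)
    return(new_outcome_immune("CYTOKINE_STORM", NULL, world$events, world, registry))
  }
  pat <- autoimmune_patrol(released, world, steps = patrol_steps, budget = budget)
  world <- pat$world
  if (nrow(pat$events) > 0L) {
    return(new_outcome_immune("AUTOIMMUNE", NULL, world$events, world, registry))
  }
  new_outcome_immune("NONE", NULL, world$events, world, registry)
}

new_outcome_immune <- function(kind, antibody, events, world, registry) {
  structure(list(kind = kind, antibody = antibody, events = events,
                 world = world, registry = registry),
            class = "immune_outcome")
}

#' @export
print.immune_outcome <- function(x, ...) {
  cat("<immune_outcome> ", x$kind,
      if (!is.null(x$antibody)) paste0(" (antibody gn ", .abbrev_gn(x$antibody$gn), ")") else "",
      ", ", nrow(x$events), " event(s)\n", sep = "")
  invisible(x)
}
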