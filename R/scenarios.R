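# Scenario runner: reproducible end-to-end experiments tying the genome,
# thymus and periphery together, with JSON/JSONL/TSV reporting.

.SCENARIOS <- c("baseline_novel", "known_antigen", "ifn_knockout",
                "aire_knockout", "forced_escape", "no_attack")

#' Scenario configuration
#'
#' @param scenario one of `baseline_novel` (novel antigen, intact host:
#'   novel antibody), `known_antigen` (registry-listed antigen: stock
#'   antibody), `ifn_knockout` (interferon-gamma off: cytokine storm),
#'   `aire_knockout` (mirror dropout lets a dangerous receptor escape:
#'   autoimmunity), `forced_escape` (a program-change receptor is injected
#'   directly: autoimmunity), `no_attack` (quiescent benign run).
#' @param n_genes genome size (default 8).
#' @param vdj_n number of sampled receptor motifs (default 500).
#' @param seed integer seed (default 42).
#' @param budget step budget `T` (default 10000); recorded in every report.
#' @param bound enumeration bound `N` (default 10000).
#' @param aire_dropout tissues dropped from the thymic mirror; defaults to
#'   `"t2"` for the `aire_knockout` scenario, empty otherwise.
#' @param ifn_gamma interferon-gamma intact? Defaults to `FALSE` only for
#'   `ifn_knockout`.
#' @param rescue guarantee the detection-relevant diagonal motif is present
#'   in the released repertoire (appended and flagged if sampling missed
#'   it), so the scenario tests detection logic rather than sampling luck;
#'   disable to expose the stochastic-miss case.
#' @param attack_gene index (1-based) of the attacked gene (default 2, i.e.
#'   gene index 1 in 0-based tissue labels).
#' @param register_attacker put the attacking antigen in the known registry
#'   (defaults to `TRUE` for `known_antigen`).
#' @param pool transformer pool for receptor generation.
#' @param patrol_steps patrol length on no-attack branches (default 1000).
#' @param max_candidates candidate-space bound for exclusion scans in
#'   antibody production.
#' @return `scenario_config` list.
#' @export
scenario_config <- function(scenario = "baseline_novel", n_genes = 8L,
                            vdj_n = 500L, seed = 42L, budget = 10000L,
                            bound = 10000L, aire_dropout = NULL,
                            ifn_gamma = NULL, rescue = TRUE,
                            attack_gene = 2L, register_attacker = NULL,
                            pool = NULL, patrol_steps = 1000L,
                            max_candidates = 1024L) {
  if (!scenario %in% .SCENARIOS) {
    stop("unknown scenario '", scenario, "'; valid names: ",
         paste(.SCENARIOS, collapse = ", "))
  }
  stopifnot(n_genes >= 1L, vdj_n >= 1L, budget >= 1L, bound >= 0L,
            patrol_steps >= 1L, attack_gene >= 1L, attack_gene <= n_genes)
  if (is.null(aire_dropout)) {
    aire_dropout <- if (scenario == "aire_knockout") "t2" else character(0)
  }
  if (is.null(ifn_gamma)) ifn_gamma <- scenario != "ifn_knockout"
  if (is.null(register_attacker)) register_attacker <- scenario == "known_antigen"
  structure(list(scenario = scenario, n_genes = as.integer(n_genes),
                 vdj_n = as.integer(vdj_n), seed = as.integer(seed),
                 budget = as.integer(budget), bound = as.integer(bound),
                 aire_dropout = aire_dropout, ifn_gamma = isTRUE(ifn_gamma),
                 rescue = isTRUE(rescue), attack_gene = as.integer(attack_gene),
                 register_attacker = isTRUE(register_attacker), pool = pool,
                 patrol_steps = as.integer(patrol_steps),
                 max_candidates = as.integer(max_candidates)),
            class = "scenario_config")
}

#' Run a scenario end to end
#'
#' Deterministic under the configured seed: synthesises the genome, develops
#' the baseline world, mirrors the self-representation (minus any AIRE
#' dropout), trains the receptor repertoire, stages the configured attack or
#' escape, and classifies the immune outcome.  Expected outcomes under
#' default configuration: `baseline_novel -> NOVEL_ANTIBODY`,
#' `known_antigen -> KNOWN_ANTIBODY`, `ifn_knockout -> CYTOKINE_STORM`,
#' `aire_knockout -> AUTOIMMUNE`, `forced_escape -> AUTOIMMUNE`,
#' `no_attack -> NONE` with an empty event list.
#'
#' @param config a `scenario_config` (or a scenario name, with defaults).
#' @param ... passed to [scenario_config()] when `config` is a name.
#' @return `scenario_report`: list with `config`, `outcome` (kind string),
#'   `antibody_gn`, `counts` (per-stage repertoire counts), `events`,
#'   `repertoire`, `rescued`, `budget`.
#' @export
run_scenario <- function(config = "baseline_novel", ...) {
  if (is.character(config)) config <- scenario_config(config, ...)
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  budget <- cfg$budget
  genome <- synth_genome(cfg$n_genes, cfg$seed)
  world <- develop(genome, budget)
  records <- self_rep(genome, cfg$aire_dropout, budget)
  pool <- if (is.null(cfg$pool)) gtp_default_pool() else cfg$pool
  motifs <- vdj_generate(genome, pool, cfg$vdj_n, cfg$seed, budget)
  repertoire <- negative_select(positive_select(motifs), records, budget)

  target <- genome[cfg$attack_gene, , drop = FALSE]
  antigen <- make_negator(target, seed = NULL, budget = budget)
  registry <- if (cfg$register_attacker) {
    build_registry(list(list(antigen = antigen, gene = target)),
                   bound = cfg$bound, budget = budget)
  } else {
    build_registry(list(), bound = cfg$bound, budget = budget)
  }

  state <- pmhc_init(world, ifn_gamma = cfg$ifn_gamma)
  rescued <- FALSE

  if (cfg$scenario %in% c("baseline_novel", "known_antigen", "ifn_knockout")) {
    lf <- liar_fixed_point(antigen$code, target$gn, budget = budget)
    if (cfg$rescue &&
        !(lf$sentence$composite_gn %in% repertoire$released$composite_gn)) {
      repertoire <- inject_motif(repertoire,
                                 make_motif(antigen$code, target, "DIAGONAL", budget))
      rescued <- TRUE
    }
    world <- online_attack(world, antigen, target, time = 1L, budget = budget)
    state <- pmhc_update(state, world$events[nrow(world$events), ])
  } else if (cfg$scenario == "aire_knockout") {
    # ensure the untestable program-change receptor exists to escape
    esc_gene <- genome[genome$tissue %in% cfg$aire_dropout, , drop = FALSE][1, ]
    esc <- make_motif(antigen$code, esc_gene, "PROGRAM_CHANGE", budget)
    if (!(esc$composite_gn %in% repertoire$released$composite_gn)) {
      repertoire <- inject_motif(repertoire, esc)
      rescued <- TRUE
    }
  } else if (cfg$scenario == "forced_escape") {
    esc <- make_motif(antigen$code, genome[1, ], "PROGRAM_CHANGE", budget)
    repertoire <- inject_motif(repertoire, esc)
  }

  outcome <- respond(world, repertoire, state, registry, genome,
                     bound = cfg$bound, budget = budget,
                     patrol_steps = cfg$patrol_steps,
                     max_candidates = cfg$max_candidates)

  structure(list(config = cfg, outcome = outcome$kind,
                 antibody_gn = if (is.null(outcome$antibody)) NA_character_ else outcome$antibody$gn,
                 counts = repertoire$counts, events = outcome$events,
                 repertoire = repertoire, rescued = rescued,
                 budget = budget),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report> ", x$config$scenario, " (seed ", x$config$seed,
      ", T=", x$budget, ")\n  repertoire ", x$counts[["generated"]], " -> ",
      x$counts[["post_positive"]], " -> ", x$counts[["released"]],
      if (x$rescued) " (+1 flagged)" else "",
      "\n  outcome: ", x$outcome, ", ", nrow(x$events), " event(s)\n", sep = "")
  invisible(x)
}

#' Write scenario report files
#'
#' Writes a JSON summary, a JSONL event log (one event per line) and a TSV
#' repertoire table (`stage`, `form`, `f_gn`, `g_gn`, `composite_gn`).  The
#' files are bit-stable across runs with equal seeds: nothing time- or
#' path-dependent is recorded.
#'
#' @param report a `scenario_report`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
report_write <- function(report, dir) {
  stopifnot(inherits(report, "scenario_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary_path <- file.path(dir, "summary.json")
  events_path <- file.path(dir, "events.jsonl")
  rep_path <- file.path(dir, "repertoire.tsv")
  cfg <- report$config
  summary <- list(
    scenario = cfg$scenario,
    config = list(n_genes = cfg$n_genes, vdj_n = cfg$vdj_n, seed = cfg$seed,
                  budget = cfg$budget, bound = cfg$bound,
                  aire_dropout = as.list(cfg$aire_dropout),
                  ifn_gamma = cfg$ifn_gamma, rescue = cfg$rescue,
                  attack_gene = cfg$attack_gene),
    budget = report$budget,
    counts = as.list(report$counts),
    outcome = report$outcome,
    antibody_gn = if (is.na(report$antibody_gn)) NULL else report$antibody_gn,
    rescued = report$rescued,
    n_events = nrow(report$events))
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", digits = NA), summary_path)
  ev <- report$events
  lines <- vapply(seq_len(nrow(ev)), function(k) {
    as.character(jsonlite::toJSON(as.list(ev[k, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA))
  }, character(1))
  writeLines(lines, events_path)
  rep_tbl <- dplyr::bind_rows(
    dplyr::mutate(report$repertoire$generated, stage = "generated"),
    dplyr::mutate(report$repertoire$post_positive, stage = "post_positive"),
    dplyr::mutate(report$repertoire$released, stage = "released"))
  utils::write.table(rep_tbl[, c("stage", "form", "f_gn", "g_gn", "composite_gn")],
                     rep_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(summary = summary_path, events = events_path, repertoire = rep_path))
}

#' Read a scenario configuration from JSON
#'
#' Reads a flat JSON object of [scenario_config()] fields; an example lives
#' at `system.file("extdata", "baseline_scenario.json", package = "gtais")`.
#'
#' @param path path to a JSON file.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(scenario_config))
  raw <- raw[intersect(names(raw), known)]
  do.call(scenario_config, raw)
}
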