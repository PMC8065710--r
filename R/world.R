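# Synthetic-data layer: genomes of halting self-assembly gene codes with
# tissue-labelled phenotypes, negator antigens, and the registry of known
# antigens (the bounded surrogate of the forbidden-code set).

#' Phenotype tokens
#'
#' A phenotype is a tissue label with a polarity: `"t3:+"` is the healthy
#' output of the tissue-3 gene, `"t3:-"` its negation.  Negation flips only
#' the polarity, never the tissue label, and is an involution.
#'
#' @param tissue tissue label (e.g. `"t0"`).
#' @param polarity `"+"` or `"-"`.
#' @return phenotype token string.
#' @export
phenotype <- function(tissue, polarity = "+") {
  stopifnot(polarity %in% c("+", "-"))
  paste0(tissue, ":", polarity)
}

#' @rdname phenotype
#' @param p a phenotype token.
#' @export
negate_phenotype <- function(p) .flip_token(p)

#' Synthesise a genome of halting self-assembly genes
#'
#' Each gene is a program that halts on exactly one input — its own Goedel
#' number — and emits its tissue phenotype with healthy polarity; on any
#' other input it diverges.  Self-application (`Diag`) therefore halts for
#' every gene (the genome is inside the halting self-assembly set by
#' construction), while the conflicted code obtained by composing a negator
#' onto a gene does not halt on itself — the defining property of forbidden
#' codes.  Seed-dependent no-op padding varies the Goedel numbers across
#' seeds and gives receptor generation a non-trivial code space.
#'
#' @param n_genes number of genes (>= 1); tissues are labelled `t0..t(n-1)`.
#' @param seed integer seed; equal seeds give identical genomes.
#' @return `gtp_genome`: a tibble with columns `tissue`, `gn`, `text`,
#'   `self_repped`.
#' @export
synth_genome <- function(n_genes, seed = 42L) {
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 1L)
  pads <- withr::with_seed(seed, sample.int(40L, n_genes, replace = TRUE))
  tissue <- paste0("t", seq_len(n_genes) - 1L)
  text <- paste0("[", tissue, ":+]iD?HL", strrep(".", pads))
  gns <- vapply(text, gn_of_text, character(1), USE.NAMES = FALSE)
  out <- tibble::tibble(tissue = tissue, gn = gns, text = text, self_repped = TRUE)
  class(out) <- c("gtp_genome", class(out))
  out
}

#' Develop the benign baseline world
#'
#' Applies self-assembly (`Diag`) to every gene and records the resulting
#' tissue phenotypes.  All healthy outputs have `+` polarity; the map is the
#' benign baseline against which attacks and autoimmune flips are judged.
#' Developing is idempotent: the genes are deterministic programs.
#'
#' @param genome a `gtp_genome`.
#' @param budget step budget.
#' @return `gtp_world`: list with `tissues` (tibble: `tissue`, `gene_gn`,
#'   `baseline`, `phenotype`, `developed`) and `events` (empty event tibble).
#' @export
develop <- function(genome, budget = gtp_budget()) {
  outs <- character(nrow(genome))
  for (k in seq_len(nrow(genome))) {
    r <- self_apply(decode_program(genome$gn[k]), budget)
    if (r$status != "HALTED" || !identical(r$output, phenotype(genome$tissue[k]))) {
      stop("gene for tissue ", genome$tissue[k],
           " violated the construction invariant (self-assembly did not emit ",
           phenotype(genome$tissue[k]), ")")
    }
    outs[k] <- r$output
  }
  structure(list(
    tissues = tibble::tibble(tissue = genome$tissue, gene_gn = genome$gn,
                             baseline = outs, phenotype = outs, developed = TRUE),
    events = empty_events()
  ), class = "gtp_world")
}

empty_events <- function() {
  tibble::tibble(time = integer(0), type = character(0), tissue = character(0),
                 gene_gn = character(0), antigen_gn = character(0),
                 g_neg_gn = character(0), motif_composite = character(0),
                 observed = character(0))
}

#' @export
print.gtp_world <- function(x, ...) {
  flips <- sum(x$tissues$phenotype != x$tissues$baseline)
  cat("<gtp_world> ", nrow(x$tissues), " tissue(s), ", flips,
      " negated, ", nrow(x$events), " event(s)\n", sep = "")
  invisible(x)
}

#' Construct a negator antigen for a target gene
#'
#' A negator is a total transformer that, composed onto an executed gene
#' code, flips the polarity of the emitted phenotype (and only the polarity:
#' the attack is tissue-specific).  Applying it twice restores the baseline —
#' negation is an involution.  Seeded construction pads the canonical flip
#' code with no-ops so that independently arising antigens carry distinct
#' Goedel numbers (and hence distinct Goedel sentences).
#'
#' @param target a one-row slice of a `gtp_genome` (the attacked gene), or
#'   `NULL` for an untargeted negator.
#' @param seed optional seed controlling the antigen's padding.
#' @param registry optional `gtp_registry`; the antigen is flagged novel iff
#'   its sentence is absent from the registry.
#' @param budget step budget (totality pre-check).
#' @return `gtp_antigen`: list with `code` (`gtp_program`), `target_tissue`,
#'   `target_gn`, `novel`.
#' @export
make_negator <- function(target = NULL, seed = NULL, registry = NULL,
                         budget = gtp_budget()) {
  pad <- if (is.null(seed)) 0L else withr::with_seed(seed, sample.int(30L, 1L))
  code <- encode_program(paste0("i!", strrep(".", pad)))
  stopifnot(isTRUE(is_total_on_battery(code, standard_battery(), budget)))
  target_tissue <- if (is.null(target)) NA_character_ else target$tissue[1]
  target_gn <- if (is.null(target)) NA_character_ else target$gn[1]
  novel <- TRUE
  if (!is.null(registry) && !is.null(target)) {
    key <- liar_fixed_point(code, target_gn, budget = budget)$sentence$composite_gn
    novel <- !(key %in% registry$entries$key)
  }
  structure(list(code = code, target_tissue = target_tissue,
                 target_gn = target_gn, novel = novel),
            class = "gtp_antigen")
}

#' @export
print.gtp_antigen <- function(x, ...) {
  cat("<gtp_antigen> gn ", .abbrev_gn(x$code$gn),
      if (!is.na(x$target_tissue)) paste0(" targeting ", x$target_tissue) else "",
      if (x$novel) " (novel)" else " (known)", "\n", sep = "")
  invisible(x)
}

#' Sentinel program of a finite code set
#'
#' Builds a program that halts exactly on the member tokens of a finite set —
#' the machine-listable presentation used for the genome set and the known
#' (forbidden-code) registry.  Its halting set is then scanned with
#' [enumerate_we()].
#'
#' @param members character vector of tokens (typically decimal Goedel
#'   numbers).
#' @return a `gtp_program` halting iff its input is in `members`.
#' @export
set_sentinel <- function(members) {
  body <- paste0(vapply(members, function(m) paste0("i[", m, "]?H"), character(1)),
                 collapse = "")
  encode_program(paste0(body, "L"))
}

#' Sentinel for the genome set
#'
#' @param genome a `gtp_genome`.
#' @return a `gtp_program` halting exactly on the genome's gene Goedel
#'   numbers.
#' @export
genome_sentinel <- function(genome) set_sentinel(genome$gn)

#' Build the registry of known antigens
#'
#' For each known (antigen, gene) pair the registry derives the pair's
#' Goedel sentence via [liar_fixed_point()] and stores its composite Goedel
#' number together with the stock antibody — the inverse transformer, which
#' for an involutory negator is the polarity-flip code itself.  A known
#' pathogen is then identified trivially and recursively by exact key lookup.
#'
#' @param known list of `list(antigen = <gtp_antigen>, gene = <one-row
#'   genome slice>)` pairs (possibly empty).
#' @param bound maximum registry size.
#' @param budget step budget.
#' @return `gtp_registry`: list with `entries` (tibble: `key`,
#'   `antigen_gn`, `gene_gn`, `antibody_gn`, `antibody_text`),
#'   `sentinel_index`, `bound`.
#' @export
build_registry <- function(known = list(), bound = 10000L, budget = gtp_budget()) {
  rows <- lapply(known, function(kp) {
    lf <- liar_fixed_point(kp$antigen$code, kp$gene$gn[1], budget = budget)
    tibble::tibble(key = lf$sentence$composite_gn,
                   antigen_gn = kp$antigen$code$gn,
                   gene_gn = kp$gene$gn[1],
                   antibody_gn = kp$antigen$code$gn,
                   antibody_text = kp$antigen$code$text)
  })
  entries <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(key = character(0), antigen_gn = character(0),
                   gene_gn = character(0), antibody_gn = character(0),
                   antibody_text = character(0))
  if (anyDuplicated(entries$key)) {
    stop("duplicate registry entry: sentence ",
         .abbrev_gn(entries$key[duplicated(entries$key)][1]), " already present")
  }
  if (nrow(entries) > bound) stop("registry exceeds its bound of ", bound)
  structure(list(entries = entries,
                 sentinel_index = set_sentinel(entries$key)$gn,
                 bound = as.integer(bound)),
            class = "gtp_registry")
}

#' @export
print.gtp_registry <- function(x, ...) {
  cat("<gtp_registry> ", nrow(x$entries), " known antigen(s), bound ",
      x$bound, "\n", sep = "")
  invisible(x)
}

#' Write a genome as a two-column TSV
#'
#' @param genome a `gtp_genome`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome_tsv <- function(genome, path) {
  utils::write.table(genome[, c("tissue", "gn")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
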