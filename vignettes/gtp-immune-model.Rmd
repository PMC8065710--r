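---
title: "A computable model of self, non-self and novelty in the adaptive immune system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A computable model of self, non-self and novelty in the adaptive immune system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtais)
```

## The model

`gtais` treats adaptive immunity as a problem in the theory of computation.
The organism's gene codes are literal programs; the hostile other — a
negator antigen — is a program transformer that inverts what a gene
produces; and detection of a *novel* attacker is a fixed-point construction:
the attacked self-code ends up carrying an index, the Gödel sentence, that
simultaneously names the attacked gene and the code of its attacker.  The
package makes every step of that story executable and testable:

1. **Gene codes and self-assembly.**  A gene `g` is a program whose
   *self-application* `Diag(g) = phi_g(g)` halts and emits a tissue-labelled
   phenotype token such as `"t3:+"`.  Self-application is the model of
   online self-assembly: the code instructs the machine to run the code.
2. **The thymic mirror (Self-Rep).**  The s-m-n index `sigma(g, g)` is a
   program that *simulates* the online execution offline:
   `phi_sigma(g,g)(s) = phi_{phi_g(g)}(s)`.  One record per gene — the
   thymic MHC display — is the system's operational definition of self.
3. **Negator antigens and forbidden codes.**  An antigen `f¬` is a total
   transformer that flips the polarity of an emitted phenotype
   (`q -> q¬`, an involution).  The conflicted code `g¬ = f¬ ∘ g` halts on
   the gene's own index (that is what a successful attack is) but diverges
   on *its own* index: forbidden codes are exactly the codes whose
   self-application does not halt.
4. **V(D)J motifs and thymic selection.**  Receptor motifs are two-place
   sigma indices over a gene and a transformed gene: change of input
   `sigma(g, f∘g)`, change of program `sigma(f∘g, g)`, change of both
   `sigma(f∘g, f∘g)`.  Positive selection rejects input-change and
   self-equivalent motifs; negative selection executes each program-change
   motif against the recorded self and eliminates those whose outcome
   negates a record.  Only diagonal motifs survive.
5. **The Gödel sentence and rendezvous.**  When an attack happens online,
   the peripheral MHC meta-index for that tissue is updated — only if the
   interferon-gamma flag is on — from the benign `pair(g, g)` to the
   conflicted diagonal `pair(g¬, g¬)`.  Detection is an *exact integer
   match* between that index and a released diagonal motif.  Running the
   sentence code itself exhausts any budget: at the fixed point the
   contest between host and parasite is undecidable.
6. **Novel antibodies as a productive function.**  On detection of a novel
   attacker the host constructs a total code that re-applies the negation
   (involution ⇒ restoration), padded so that its Gödel number lies outside
   the genome set, the registry of known antigens, and the bounded
   enumerations of both — the operational reading of "the response index
   lies outside the known listable sets".

## The machine substrate

No concrete machine model is canonical for this kind of model, so the
choice is a design decision of the package.  We use a concatenative stack
language over a 29-symbol alphabet (see `?gtp_alphabet`) in which **every
string is a valid program**.  That makes the Gödel numbering a closed-form
bijection (bijective base-29 numeration, length-then-lexicographic), so
`encode_program()` and `decode_program()` are exact inverses over the whole
integer range with no enumeration or search.

Four contracts shape the design, and each is carried by a primitive:

* effective composition: `compose(f, g)` wraps two Gödel numbers in a fixed
  template, so composites have stable, comparable indices;
* effective s-m-n: the `S` instruction maps a code `u` to the index of
  `sigma(u, u)` — this is what makes the Rogers fixed-point construction
  (`fixed_point()`) expressible *inside* the language;
* self-reference: the `D` instruction pushes the executing program's own
  Gödel number, which is how a gene can halt exactly on its own index
  without circular construction;
* a step-counted interpreter: every transition costs one step, including
  nested applications, so dovetailed scheduling is fair.

Gene programs have the shape `"[t3:+]iD?HL"` plus seed-dependent no-op
padding: *push the phenotype; compare the input with my own index; if they
match, halt and emit; otherwise loop*.  Input-sensitivity is essential, not
decorative.  Three properties must hold at once:

* `sigma(g¬, g)` must *evaluate to* `q¬` — that is what negative selection
  simulates and why the motif is lethal;
* `sigma(g¬, g¬)` must *diverge* — that is the undecidability of the
  sentence;
* `phi_{g¬}(g)` must halt with `q¬` — that is a successful online attack.

With input-ignoring genes the first two coincide and the model collapses.
With self-checking genes all three hold, and divergence of the sentence
arises exactly where it should: self-application of the conflicted code
re-enters the gene's self-check and never halts.

Two further token conventions close the semantics: a non-numeric token
applied as code denotes itself (an assembled phenotype is a self-denoting
constant), and a numeric token applied as code is decoded and run.

## Arbitrary-precision Gödel numbers

Composite indices overflow doubles by construction — a sigma code over two
composed genes has a Gödel number of hundreds of digits.  The package
therefore carries all Gödel numbers as canonical decimal strings with its
own limb arithmetic (add, subtract, multiply, small divmod, integer square
root), which is exactly what Cantor pairing (`pair()`, `unpair()`) and the
numbering need.  Exact string equality of canonical decimals is exact
integer equality, which is what intensional motif matching requires.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `budget` (T) | 10 000 steps | operational halting bound; "halts" always means "halts within T"; every report records it |
| `n_genes` | 8 | genome/tissue count of the study world |
| `vdj_n` | 500 | receptor motifs sampled per scenario |
| `bound` (N) | 10 000 | members requested from bounded enumerations |
| `max_candidates` | 1 024 (4 096 nowhere needed) | candidate space scanned by the dovetailer; an unbounded candidate set cannot be scanned, so the surrogate is explicit |
| battery | 50 state tokens | declared finite battery for totality and extensional checks |
| battery budget | 512 steps | budget for extensional-equality sweeps; all programs in the study worlds either halt well under this or provably loop |
| `seed` | 42 | every stochastic step (genome padding, motif sampling) is seed-derived |

Extensional claims are always of the bounded form "agreement of execution
outcomes on the declared battery at budget T" and are labelled as such.
The test batteries keep halting times far from the budget boundary, so the
bounded comparisons do not sit on knife edges.

## What the generator emulates — and what it does not

`synth_genome()` builds the study conditions: one gene per tissue, each a
halting self-assembly program, with seed-varied padding standing in for
the natural variation of real coding sequence.  The world is code-level by
design: there are no nucleotides, no binding affinities, no clonal
expansion, no population dynamics.  Negative selection simulates motif
*computation* rather than scoring affinity — that substitution of
computation for reactivity is the point of the model, not a shortcut.
Passing tests therefore establish the internal logic of the
self/non-self/novelty machinery; they say nothing quantitative about
biological repertoires.  The released fraction, for example, is whatever
the filters produce for the configured pool and is reported, not targeted.

## Numerical and procedural choices

* **Divergence handling.**  True halting being undecidable, divergence is
  always realised as `BUDGET_EXHAUSTED` at the configured T.  The
  interpreter fast-forwards a program parked on the perpetual-loop
  instruction to the budget — observationally identical, and it makes a
  provable non-halter cheap to re-examine.  The dovetailer uses the same
  fact to stop re-scheduling such candidates.
* **Dovetail schedule.**  Round r admits candidate r−1 and raises every
  active candidate's allotment by a 64-step quantum, scanning in index
  order; discovery order is therefore deterministic and reproducible.
* **Degenerate motifs.**  A transformer that acts as the identity on a
  gene (checked extensionally on the gene's own index plus a state token)
  yields motifs classified `SELF` and removed at positive selection, even
  though its composite index differs syntactically.
* **Diagonal motifs at negative selection.**  Their simulated run diverges
  at budget; divergence does not negate any record, so they are retained.
  This is an interpretive choice: elimination would empty the repertoire
  and make detection impossible.
* **Quiescent outcome.**  A run with no attack and a clean patrol reports
  outcome `NONE`; the five eventful kinds (`NOVEL_ANTIBODY`,
  `KNOWN_ANTIBODY`, `CYTOKINE_STORM`, `AUTOIMMUNE`, `UNDETECTED`) are
  reserved for runs where something happened.
* **Rescue.**  `run_scenario()` guarantees by default that the
  detection-relevant diagonal motif is present in the released repertoire,
  appending and flagging it if sampling missed it, so the named scenarios
  test the detection logic rather than sampling luck; `rescue = FALSE`
  exposes the stochastic-miss path, which ends in a cytokine storm.
* **Registry growth.**  A novel antibody's sentence key is added to the
  registry on production; a re-attack by the same antigen then takes the
  known path.  Registry keys are derived bit-exactly from their
  (antigen, gene) pairs and duplicates are rejected.

## Worked example

```{r example, eval = FALSE}
report <- run_scenario("baseline_novel")
glance(report)
autoplot(report$repertoire)
```

The report's stage counts trace the selection funnel (generated →
post-positive → released), and the outcome field is the decision-table
classification.  `tidy(report)` returns the event log as a tibble.

## Problem sizes

The packaged checks run the toy world (2 genes × 1 transformer,
exhaustively), the default study world (8 genes, 500 motifs, T = 10 000,
N = 10 000), 200 s-m-n oracle triples, 20 transformers × 50-input battery
for the fixed-point law, 1 000-step patrols, and the full 2×2×2 rendezvous
table — sizes chosen so that each property is exercised at the scale the
model's claims are stated at.

## Known limitations

* All halting claims are budget-relative; a program that halts just beyond
  T is operationally a non-halter.
* Enumerations scan a bounded candidate space; the genome and registry
  Gödel numbers lie far outside it, so the enumerated prefixes of those
  sets are empty and the productive-exclusion check leans on the direct
  set exclusions as well.
* The host–parasite contest at the fixed point is classified, not
  resolved: the simulator stops at the outcome kind.
* The mirror-system reading of social cognition (the same construction
  over self-action codes) is structurally identical under relabelling and
  is deliberately not instantiated separately.
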