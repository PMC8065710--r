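# gtais

An executable Gödel–Turing–Post model of the adaptive immune system.

## The problem

How can a decentralised, code-based system know that one of its own codes
has been altered by an attacker it has never seen — and respond with
something genuinely new?  This package takes that question literally, for
readers and researchers at the border of theoretical immunology, artificial
immune systems and computability theory.  Gene codes are programs; the
hostile other is a program transformer; and self/non-self discrimination is
carried by the classical machinery of recursion theory rather than by
affinity scores.

The core constructions, in the field's standard notation:

* **Self-Ref (Diag):** a gene is a program `g` whose self-application
  `Diag(g) = φ_g(g)` halts and emits a tissue phenotype `q` — the model of
  online self-assembly.
* **Self-Rep (s-m-n):** the index `σ(g, g)` with
  `φ_{σ(g,g)}(s) ≅ φ_{φ_g(g)}(s)` is an offline program that simulates the
  online execution — the thymic mirror, one record per gene.
* **Negator antigen:** a total transformer `f¬` with
  `φ_{f¬∘g}(g) = ¬φ_{φ_g(g)}(s) = q¬`; the conflicted code `g¬ = f¬∘g`
  diverges on its own index — forbidden codes are non-halting on
  self-application.
* **V(D)J motifs and selection:** receptor motifs
  `σ(g, f∘g), σ(f∘g, g), σ(f∘g, f∘g)` are generated combinatorially;
  positive selection rejects input-change and self motifs, negative
  selection executes program-change motifs against the mirrored self and
  eliminates those that negate a record.  Only diagonal motifs survive.
* **The Gödel sentence:** after an online attack, interferon-gamma permits
  the peripheral MHC meta-index to update from `pair(g, g)` to
  `pair(g¬, g¬)`; detection is an exact integer match between that index
  and a released diagonal motif `σ(g¬, g¬)`.  The sentence code itself
  diverges: at the fixed point the contest is undecidable.
* **Productive novelty:** the antibody is a total restoring code whose
  Gödel number is constructed to lie outside the genome set, the known
  registry, and bounded enumerations of both.

Knockouts close the loop: without interferon-gamma the index never
updates and the host falls back to an unspecific cytokine storm; an AIRE
dropout removes genes from the mirror and lets lethal program-change
receptors escape into autoimmunity.

## Worked example

```r
library(gtais)
report <- run_scenario("baseline_novel")
print(report)
#> <scenario_report> baseline_novel (seed 42, T=10000)
#>   repertoire 500 -> 216 -> 96
#>   outcome: NOVEL_ANTIBODY, 2 event(s)
tidy(report)[, c("time", "type", "tissue", "observed")]
#> # A tibble: 2 x 4
#>    time type     tissue observed
#>   <int> <chr>    <chr>  <chr>
#> 1     1 attack   t1     t1:-
#> 2     2 antibody t1     t1:+
```

Reading the numbers: 500 receptor motifs were sampled over
(form × transformer × gene); positive selection kept 216 (the
program-change and diagonal motifs of the non-degenerate transformers);
negative selection eliminated the lethal program-change motifs, releasing
96 diagonal receptors.  At step 1 a novel negator antigen flipped tissue
`t1` from `t1:+` to `t1:-`; the peripheral meta-index updated, matched the
released diagonal motif for the conflicted code exactly, and the produced
antibody restored `t1:+` at step 2.  `autoplot(report$repertoire)` draws
the selection funnel; `glance(report)` gives the one-row summary.

The same machinery is exposed piecewise — `synth_genome()`, `develop()`,
`self_rep()`, `vdj_generate()`, `positive_select()`, `negative_select()`,
`online_attack()`, `pmhc_update()`, `detect()`, `produce_antibody()`,
`respond()`, `autoimmune_patrol()` — and at the recursion-theory level:
`encode_program()`, `run_program()`, `compose()`, `smn_sigma()`,
`self_apply()`, `fixed_point()`, `enumerate_we()`, `liar_fixed_point()`.
A thin command-line front end lives at `inst/cli/gtais.R`
(`Rscript inst/cli/gtais.R run --scenario baseline_novel --out DIR`).

See `vignettes/gtp-immune-model.Rmd` for the model, its assumptions, the
machine substrate, and the package's design decisions.

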