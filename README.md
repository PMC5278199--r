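# soupsearch

Forward and backward symbolic search over rule-based models of cellular
signaling.

## The problem

Signaling pathways — the EGF/EGFR axis that drives proliferation is the
canonical example — are naturally described *qualitatively*: the cell is a
**dish** of named locations (extracellular space `XOut`, receptor-complex
container `EgfRC`, membrane faces `CLo`/`CLm`/`CLi`, cytoplasm `CLc`,
nucleus `NUc`), each holding a **soup**: an unordered multiset of proteins,
chemicals, modified proteins (`[EgfR - Yphos]`, tyrosine-phosphorylated
EGFR) and complexes (`[EgfR - Yphos] : Egf`, the ligand-bound receptor;
`Hras : GTP`, the activated GTPase). Reactions are labeled **rewrite
rules** between dish patterns, with modifiers (enzymes, controls) written
unchanged on both sides and sort constraints typing rule variables
(`gab:GabS` — "Gab1 or Gab2").

Two questions matter for such a model:

* **Forward** — from a concrete initial dish, is a state of interest
  reachable, and through which reactions? `soupsearch` answers this with
  breadth-first search over the rewrite relation: matching rule left-hand
  sides modulo associativity–commutativity of soups, deduplicating states
  by canonical form, and reporting each solution with its bindings and the
  rule labels along the path (a state `t` with rule `l ⇒ r` rewrites at a
  match `σ` with `lσ = t`, giving `rσ`).

* **Backward** — which initial states *cause* a given (possibly symbolic)
  state? This is answered by **narrowing**: instead of matching, the engine
  *unifies* the goal with rule right-hand sides (`lσ =_AC t|σ`), so
  variables standing for unknown soup contents get solved for, and the
  search returns the **most general** initial dish patterns, their binding
  substitutions, and the rule path. Because narrowing requires rules to
  apply at the top of the state term, rules are first **topified** —
  extended with fresh soup- and dish-level extension variables — which
  provably (and, here, property-testedly) preserves the transition
  relation.

## Quick start

```r
library(soupsearch)

kb <- egf_fixture()   # EGF ligand/receptor fragment: rules 001, 188, 529
res <- forward_search(kb, "EgfDish",
                      search_goal("{CLi | (Hras : GTP) ?th:Things}",
                                  max_solutions = 1))
print(res$solutions[[1]])
#> Solution at depth 3
#>   path:  001.EgfR.irt.Egf -> 188.Shp2.irt.Egf -> 529.Hras.irt.Egf
#>   final: {CLc | Abl1 Akt1 Araf ArhGap5 Pi3k [Gab1 - Yphos] [Sos1 - Yphos]}
#>          {CLi | (Cdc42 : GDP) (GDP : Kras) (GTP : Hras) Gnai1 Gnai3 Pld1} ...
```

Reading: EGF binds and phosphorylates its receptor (rule 001), Shp2 is
recruited to the receptor complex and phosphorylated (rule 188), and with
the active complex, phosphorylated Gab1/Sos1 and Pi3k present, Hras swaps
its GDP load for GTP (rule 529) — Ras activation in exactly three steps.

Backward, on the vending-machine teaching model (a dollar becomes four
quarters or a chocolate plus a quarter; two quarters become an apple):

```r
vkb <- vending_fixture()
back <- backward_search(vkb, "{VM | apple ?rest:Things}", max_depth = 2)
head(solutions_df(back), 5)
#>   solution depth path                                     state
#> 1        1     0                      {VM | apple ?rest:Things}
#> 2        2     1                {VM | apple dollar ?v.3:Things}
#> 3        3     1             {VM | quarter quarter ?v.9:Things}
#> 4        4     1      {VM | apple quarter quarter ?v.10:Things}
#> 5        5     2        {VM | apple dollar dollar ?v.13:Things}
```

An apple needs nothing (depth 0: the goal itself), two quarters one step
earlier (depth 1), and a dollar two steps earlier — solution 9 is
`{VM | dollar ?v.27:Things}`. Every backward solution can be validated by
forward replay with `ground_check()`.

Knowledge bases are plain JSON (`load_kb()`, `save_kb()`), random test
systems come from `generate_kb(gen_config(seed = ...))`, and a CLI wraps it
all (`inst/cli/soupsearch.R`: `validate-kb`, `forward-search`,
`backward-search`, `show-path`, `gen-kb`, with DOT transition-graph
export).

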