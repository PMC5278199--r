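---
title: "Located-soup rewriting: forward reachability and backward narrowing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Located-soup rewriting: forward reachability and backward narrowing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soupsearch)
```

## The model

A system state is a **dish**: a finite map from location tags to **soups**,
where a soup is a multiset of **terms** — basic entities (`Egf`), modified
entities (`[EgfR - Yphos]`), and **complexes** of two or more bound terms
(`[EgfR - Yphos] : Egf`). Three algebraic commitments define equality:

* Soup union is associative and commutative with the empty soup (`none`)
  as identity. Two soups with the same element counts are equal regardless
  of construction order.
* Complex binding is likewise associative–commutative: complexes are flat
  multisets of components, and nesting flattens to one level. Nucleotide
  loading (`Hras : GDP`) is represented as an ordinary complex; the model
  does not distinguish a separate "load" operator.
* Modification sets have set semantics: attaching `Yphos` twice equals
  attaching it once, because `[EgfR - Yphos]` denotes a *state*, not a
  count.

Every term, soup and dish carries a canonical string computed at
construction (members sorted bytewise), so multiset equality, state
deduplication and matching all reduce to string keys. `parse_dish()`
inverts the canonical form exactly.

Patterns extend ground dishes with three kinds of variables, in disjoint
namespaces: **element variables** (`?prot:BProtein`) standing for one term
and carrying one or more sort constraints; at most one **soup variable**
per soup (`?rest:Things`) standing for an arbitrary sub-soup; and at most
one **dish variable** (`?r:Dish`) standing for further locations. A
modified term's base may itself be a sorted variable — `[?gab:GabS -
Yphos]`, "some Gab-family protein, tyrosine-phosphorylated" — and such a
base variable only ever binds a bare entity, which keeps matching
unambiguous (binding it to an already-modified term would merge
modification sets and create redundant, non-most-general matches).

**Sorts.** A sort hierarchy maps sort names to members (entities or
subsorts); the subsort graph must be acyclic and membership is decided by
transitive closure of entity sets. `Things` is the implicit top sort of
every term, including complexes; all other sorts contain only (possibly
modified) entities, so a complex belongs to no proper sort. Rule and goal
*conditions* — membership tests `(variable, sort)` — are normalised away
at construction by strengthening the variable's sort annotation; a
variable may therefore carry a *conjunction* of sorts and must satisfy all
of them. This representation is also how unification takes sort meets
without inventing new named sorts (see below).

## Forward semantics

A rule `lhs ⇒ rhs` applies to a ground dish wherever `lhs` matches: AC
matching of each mentioned location's soup, with unmentioned locations
passing through unchanged. Matching threads a substitution left-to-right
through locations and elements; ground pattern elements are cancelled by
counter subtraction, variables branch over the distinct remaining element
keys in bytewise order, and the soup variable absorbs the remainder. The
returned match list is duplicate-free and deterministically ordered, which
makes "the first solution" well-defined. Inside a ground complex a
`Things`-sorted variable may absorb a sub-multiset of two or more
components (a flattened sub-complex); sorted variables bind single
components, since complexes belong only to `Things`.

`forward_search()` is breadth-first: FIFO frontier, rules in lexicographic
label order, matches in match order, visited states pruned by canonical
key — without pruning even the vending machine loops forever. Goal
patterns get an implicit dish variable (a goal says "contains"), their
`min_steps` defaults to 1 ("at least one rewrite"), and goal tests happen
when a state is *reached* rather than when it is expanded, so a state
reproduced by a self-loop rewrite still counts as reachable in one step
even though it is never re-expanded; each state contributes solutions at
most once, at its first admissible depth. The first solution's depth is
therefore the true shortest path length, which the tests cross-check
against a no-dedup exhaustive enumerator.

## Backward semantics: narrowing

Backward search answers "which initial dishes cause this goal?". A
backward step takes the current subgoal pattern `g`, a rule `l ⇒ r`
(renamed apart), and every unifier `σ` of `r` with `g`; it emits `lσ` as a
new, more-initial pattern with the composed substitution and the rule
label prepended to the forward path. The depth-0 identity solution — the
goal itself, no rules applied — is always emitted first, and enumeration
is by nondecreasing depth with (label, unifier-index) tie-breaking, so
solution numbering is reproducible.

Narrowing only works when rules apply at the top of the state term, so
rules are **topified** first: each mentioned location gains a fresh soup
extension variable on both sides (if it does not already carry one), and a
fresh dish extension variable covers the unmentioned locations. A
property suite checks that topified rule sets reach exactly the same
states as the originals on random systems.

### The unification fragment

Full AC unification with repeated collection variables is exponential and
unnecessary for pathway-style rules, so the solver is restricted to the
fragment the engines actually produce:

* **Element variables** unify syntactically, with sort meets: two
  variables unify to a shared fresh variable carrying the union of their
  sort conjunctions (failing if the entity closures are disjoint), a
  variable against a ground term checks membership in every listed sort,
  and an occurs check blocks cyclic bindings. Inside complexes, element
  variables pair with exactly one component (no absorption of several),
  per the syntactic reading of the fragment.
* **Soup variables** (at most one per soup per side, enforced by
  construction) are solved by enumerating pairings between the two sides'
  fixed elements; unpaired left elements go to the right's soup variable
  and vice versa, with a *shared fresh tail* variable when both sides have
  one — so `{A | q q ?v}` and `{A | q ?w}` yield exactly the two
  most-general unifiers `v ↦ ?t, w ↦ q ?t` and `v ↦ q ?t, w ↦ q q ?t`.
  Because any common ground instance induces an occurrence bijection that
  restricts to such a pairing, the returned set is complete for the
  fragment, which the tests verify by exhaustive ground enumeration.
* **Dish variables** absorb the other side's surplus locations, again with
  a shared fresh tail when both sides are open.

### Bookkeeping choices

Subgoal patterns are deduplicated up to variable renaming (canonical form
with variables renumbered in first-occurrence order). This cannot lose
minimal-depth completeness: every ground instance of an emitted pattern
replays its rule path in exactly that many steps (extension variables make
extra material inert), so if a pattern recurs at a greater depth, its
instances already reach the goal faster through the retained shallower
occurrence. Sort constraints travel inside variable annotations and are
re-checked at every binding, pruning unsatisfiable branches at
composition time.

Two validators close the loop. `ground_check()` grounds a backward
solution (element variables to the first entity of their sort closure,
collection variables to empty), replays its rule path forward, and
verifies the grounded goal instance is reached in exactly the solution's
depth. `instance_of()` decides syntactic subsumption between patterns by
freezing the more specific side's variables as rigid markers (marker
entities injected into the sort hierarchy; soup/dish markers that only
collection variables may absorb) and matching. The optional `subsume`
filter of `backward_search()` uses it to drop strict instances; it is off
by default because all per-branch most-general solutions are informative
and no canonical policy exists.

## Fixtures

The vending machine (one location, four entities, three rules) is the
smallest system displaying the forward/backward contrast: an apple is
reachable from two quarters in one step and from a dollar in two; backward
from "a soup containing an apple" the engine proposes the goal itself at
depth 0, a two-quarter pattern at depth 1, and a dollar-bearing pattern at
depth 2.

The EGF fixture encodes the three-rule Ras-activation fragment — ligand
binding (001), Shp2 recruitment (188), Hras GDP→GTP exchange (529) — over
the seven-location `EgfDish`. Two closure choices make the printed chain
executable as a self-contained model, and are deliberate:

* Rule 529's requirement for a tyrosine-phosphorylated Gab-family protein
  and Ras activator is met by placing `[Gab1 - Yphos]` and `[Sos1 -
  Yphos]` in the initial cytoplasm: their activating kinases lie outside
  this three-rule fragment, so the dish carries them pre-activated, while
  Shp2 starts unphosphorylated because rule 188 activates it within the
  fragment. The `[Shp2 - Yphos]` modifier of rule 529 sits in `EgfRC`,
  where rule 188 puts it; Pi3k is required in the cytoplasm.
* The "Gab1 or Gab2" disjunction is encoded once, as a sorted variable
  over `GabS = {Gab1, Gab2}`, and the same idiom covers "RasGrp3 or Sos1"
  via `RasActS` — one rule instead of a cross-product of variants.

The full curated EGF knowledge base has hundreds of rules; only this
printed fragment is encoded, so the fixture supports the three-step chain
and its backward inversion but not, for example, a full Erk-activation
query, which would additionally need modification-set variables
(`mod:ModSet`) that the term language deliberately omits.

## The synthetic generator

`generate_kb()` produces seed-reproducible random systems: entities
`E01…`, locations `L1…`, and rules that *conserve the entity multiset by
construction* (left-hand-side terms are redistributed over the rule's
locations) except for a configurable fraction of transform rules that swap
one entity for another, mirroring nucleotide exchange. Optional modifier
terms (identical on both sides) and sorted-variable conditions mirror the
fixture's idioms. The initial dish embeds a ground witness of every rule's
left-hand side, so generated systems always have transitions to exercise,
and default sizes keep reachable state spaces within a few hundred states
at depth 4 so that exhaustive oracles remain affordable.

What the generator does *not* emulate: realistic pathway topology, rule
sparsity, or the heavy sharing of modifiers seen in curated models.
Passing the random-system properties therefore demonstrates algebraic
correctness of the engines (matching, unification, topification,
narrowing), not biological fidelity — the EGF fixture carries that weight.

## Problem sizes and numerical choices

The property suites run at deliberately small scale, chosen once:
match-oracle equivalence on dishes of up to two locations and three terms
per soup; unifier completeness enumerated over soups of size up to four;
topification equivalence on 20–25 random systems to depth 3; narrowing
soundness and completeness on 50 seeded systems with three entities, two
locations, two rules, and initial soups of size up to two, the
completeness check enumerating all ≤ 100 ground initial dishes per system.
Degenerate inputs are pinned by construction: the empty soup prints
`none`, the empty dish `{}`, complexes need two components or more, and a
second soup variable in one soup is a parse/construction error rather
than a solver case.

## Limitations

* No modification-set variables, so "has at least these modifications"
  goals must be written per modification set.
* No nested locations, stoichiometric rates, concentrations, or temporal
  logic — reachability only.
* Inside complexes, unification pairs element variables with single
  components; patterns needing a variable to absorb a sub-complex during
  unification (as opposed to matching) are outside the fragment.
* Backward search explores most-general patterns breadth-first; with many
  overlapping rules the solution list grows quickly, and `max_depth` /
  `max_solutions` (plus the `subsume` filter) are the intended controls.
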