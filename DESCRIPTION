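Package: soupsearch
Title: Forward and Backward Symbolic Search over Located Biomolecular Soups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiset-rewriting engine for rule-based models of cellular
    signaling. System states are dishes: named cellular locations holding
    unordered multisets (soups) of proteins, chemicals, modified proteins and
    complexes. Reactions are labeled rewrite rules over dish patterns.
    Forward analysis is breadth-first reachability search with
    associative-commutative pattern matching and sort-membership conditions;
    backward analysis is a narrowing search that unifies goals with rule
    right-hand sides (after topifying rules with extension variables) and
    returns most-general initial dish patterns that cause a goal state,
    together with the binding substitutions and rule paths. Includes an EGF
    receptor signaling fixture, a vending-machine teaching fixture, a
    seed-reproducible random knowledge-base generator, JSON knowledge-base
    input/output, transition-graph export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
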