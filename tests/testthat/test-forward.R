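# Forward rewriting and breadth-first reachability.

test_that("rule 001 rewrites the minimal ligand/receptor dish exactly as printed", {
  kb <- egf_fixture()
  d <- parse_dish("{XOut | Egf} {EgfRC | EgfR}")
  succ <- apply_rule(kb$rules[["001.EgfR.irt.Egf"]], d, kb$hierarchy)
  expect_length(succ, 1L)
  expect_identical(canonical(succ[[1]]$dish),
                   canonical(parse_dish("{XOut | none} {EgfRC | ([EgfR - Yphos] : Egf)}")))
})

test_that("rule 188 moves Shp2 from the cytoplasm into the receptor complex, phosphorylated", {
  kb <- egf_fixture()
  after001 <- replay_path(kb, "EgfDish", "001.EgfR.irt.Egf")
  expect_length(after001, 1L)
  succ <- apply_rule(kb$rules[["188.Shp2.irt.Egf"]], after001[[1]], kb$hierarchy)
  expect_length(succ, 1L)
  st <- succ[[1]]$dish
  expect_match(canonical(st$locations$EgfRC), "\\[Shp2 - Yphos\\]")
  expect_no_match(canonical(st$locations$CLc), "Shp2")
})

test_that("a rule whose reactant is missing yields no successor", {
  kb <- egf_fixture()
  locs <- kb$dishes$EgfDish$locations
  locs$CLi <- soup(entity("Gnai1"))
  no_hras <- dish(locations = locs)
  expect_length(apply_rule(kb$rules[["529.Hras.irt.Egf"]], no_hras, kb$hierarchy), 0L)
})

test_that("the EGF fixture reaches GTP-loaded Hras in exactly three steps via 001-188-529", {
  kb <- egf_fixture()
  res <- forward_search(kb, "EgfDish",
                        search_goal("{CLi | (Hras : GTP) ?th:Things}", max_solutions = 1))
  expect_length(res$solutions, 1L)
  sol <- res$solutions[[1]]
  expect_identical(sol$depth, 3L)
  expect_identical(path_labels(sol, kb),
                   c("001.EgfR.irt.Egf", "188.Shp2.irt.Egf", "529.Hras.irt.Egf"))
  # the path replays to the final state
  finals <- replay_path(kb, "EgfDish", sol$path)
  expect_true(canonical(sol$final_dish) %in% vapply(finals, canonical, character(1)))
  # intermediate biology: complex formation, then Shp2 recruitment
  s1 <- replay_path(kb, "EgfDish", sol$path[1])[[1]]
  expect_identical(canonical(s1$locations$XOut), "none")
  expect_match(canonical(s1$locations$EgfRC), "\\(Egf : \\[EgfR - Yphos\\]\\)")
  s2 <- replay_path(kb, "EgfDish", sol$path[1:2])[[1]]
  expect_match(canonical(s2$locations$EgfRC), "\\[Shp2 - Yphos\\]")
})

test_that("path_labels rejects solutions from a changed knowledge base", {
  kb <- vending_fixture()
  res <- forward_search(kb, "DollarDish", search_goal("{VM | apple ?m:Things}",
                                                      max_solutions = 1))
  sol <- res$solutions[[1]]
  expect_identical(path_labels(sol, kb), sol$path)
  other <- egf_fixture()
  expect_error(path_labels(sol, other), "stale")
})

test_that("vending reachability: apple at depth 2 from a dollar, depth 1 from two quarters", {
  kb <- vending_fixture()
  goal <- search_goal("{VM | apple ?m:Things}", max_solutions = 1)
  r1 <- forward_search(kb, "DollarDish", goal)
  expect_identical(r1$solutions[[1]]$depth, 2L)
  expect_identical(r1$solutions[[1]]$path, c("dollar.to.quarters", "quarters.to.apple"))
  r2 <- forward_search(kb, "TwoQuarters", goal)
  expect_identical(r2$solutions[[1]]$depth, 1L)
  expect_identical(r2$solutions[[1]]$path, "quarters.to.apple")
})

test_that("min_steps excludes the start state; a ruleless KB reaches nothing", {
  kb <- knowledge_base(entities = c(dollar = "Things"),
                       dishes = list(D = parse_dish("{VM | dollar}")))
  res <- forward_search(kb, "D", search_goal("{VM | dollar ?m:Things}", min_steps = 1))
  expect_length(res$solutions, 0L)
  res0 <- forward_search(kb, "D", search_goal("{VM | dollar ?m:Things}", min_steps = 0))
  expect_length(res0$solutions, 1L)
  expect_identical(res0$solutions[[1]]$depth, 0L)
})

test_that("solutions come out in nondecreasing depth and replay soundly", {
  kb <- vending_fixture()
  res <- forward_search(kb, "DollarDish",
                        search_goal("{VM | ?m:Things}", min_steps = 0, max_depth = 3,
                                    max_solutions = 50))
  depths <- vapply(res$solutions, function(s) s$depth, integer(1))
  expect_true(all(diff(depths) >= 0))
  for (sol in res$solutions) {
    finals <- replay_path(kb, "DollarDish", sol$path)
    expect_true(canonical(sol$final_dish) %in% vapply(finals, canonical, character(1)))
  }
})

test_that("the first solution's depth equals the true shortest path on random systems", {
  set.seed(202)
  for (seed in 1:12) {
    gen <- generate_kb(gen_config(seed = seed, n_entities = 3, n_locations = 2,
                                  n_rules = 2, max_soup_size = 2, max_rule_width = 1))
    ents <- names(gen$kb$entities)
    goalpat <- search_goal(dish(L1 = soup(entity(ents[[1]]), svar = "g1"),
                                dvar = "gd"),
                           min_steps = 1, max_solutions = 1, max_depth = 3)
    res <- forward_search(gen$kb, gen$dish, goalpat)
    want <- oracle_min_depth(gen$kb, gen$dish, goalpat$pattern, max_depth = 3)
    if (length(res$solutions)) {
      expect_identical(res$solutions[[1]]$depth, as.integer(want))
    } else {
      expect_true(is.na(want))
    }
  }
})

test_that("EGF rules conserve the entity multiset except the GDP-to-GTP swap", {
  kb <- egf_fixture()
  state <- kb$dishes$EgfDish
  for (lb in c("001.EgfR.irt.Egf", "188.Shp2.irt.Egf", "529.Hras.irt.Egf")) {
    succ <- apply_rule(kb$rules[[lb]], state, kb$hierarchy)
    expect_length(succ, 1L)
    before <- entity_multiset(state)
    after <- entity_multiset(succ[[1]]$dish)
    if (lb == "529.Hras.irt.Egf") {
      swapped <- before
      swapped[match("GDP", swapped)] <- "GTP"  # exactly one GDP becomes GTP
      expect_identical(sort(swapped, method = "radix"), after)
    } else {
      expect_identical(before, after)
    }
    state <- succ[[1]]$dish
  }
})
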