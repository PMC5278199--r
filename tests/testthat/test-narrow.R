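# Topification and backward narrowing search.

test_that("topification adds extension variables and preserves the transition relation", {
  kb <- egf_fixture()
  t001 <- topify(kb$rules[["001.EgfR.irt.Egf"]], kb)
  # every mentioned location carries a soup variable on both sides, plus a
  # dish-level variable
  for (side in list(t001$lhs, t001$rhs)) {
    expect_false(is.null(side$dvar))
    for (tg in names(side$locations)) expect_false(is.null(side$locations[[tg]]$svar))
  }
  # idempotent up to renaming
  t2 <- topify(t001, kb)
  norm <- soupsearch:::.rename_canonical
  expect_identical(norm(t2$lhs), norm(t001$lhs))
  expect_identical(norm(t2$rhs), norm(t001$rhs))
  # a topified rule rewrites the full seven-location dish identically
  orig <- apply_rule(kb$rules[["001.EgfR.irt.Egf"]], kb$dishes$EgfDish, kb$hierarchy)
  top <- apply_rule(t001, kb$dishes$EgfDish, kb$hierarchy)
  expect_identical(sort(vapply(orig, function(x) canonical(x$dish), character(1))),
                   sort(vapply(top, function(x) canonical(x$dish), character(1))))
})

test_that("topified rule sets reach exactly the original states on random systems", {
  for (seed in 1:20) {
    gen <- generate_kb(gen_config(seed = seed, n_entities = 3, n_locations = 2,
                                  n_rules = 2, max_soup_size = 2))
    kb <- gen$kb
    topped <- lapply(kb$rules, topify, kb = kb)
    expect_identical(
      reachable_keys(kb$rules, kb$hierarchy, gen$dish, max_depth = 3),
      reachable_keys(topped, kb$hierarchy, gen$dish, max_depth = 3)
    )
  }
})

test_that("backward narrowing reproduces the 0/1/2-step vending trace", {
  kb <- vending_fixture()
  res <- backward_search(kb, "{VM | apple ?rest:Things}", max_depth = 2)
  sols <- res$solutions
  # identity solution first: no rules, the goal itself
  expect_identical(sols[[1]]$depth, 0L)
  expect_length(sols[[1]]$rule_path, 0L)
  expect_true(subst_is_empty(sols[[1]]$accumulated_substitution))
  expect_identical(canonical(sols[[1]]$initial_pattern), canonical(res$goal))
  depths <- vapply(sols, function(s) s$depth, integer(1))
  expect_true(all(diff(depths) >= 0))

  has_entity <- function(s, what) {
    counts <- soupsearch:::.soup_counts(s$initial_pattern$locations$VM)
    what %in% names(counts)
  }
  # a two-quarter pattern at depth 1
  d1_quarter <- Filter(function(s) s$depth == 1 && has_entity(s, "quarter"), sols)
  expect_gt(length(d1_quarter), 0L)
  counts <- soupsearch:::.soup_counts(d1_quarter[[1]]$initial_pattern$locations$VM)
  expect_gte(counts[["quarter"]], 2L)
  expect_identical(d1_quarter[[1]]$rule_path, "quarters.to.apple")
  # a dollar-containing pattern at depth 2, via dollar -> quarters -> apple
  d2_dollar <- Filter(function(s) s$depth == 2 && has_entity(s, "dollar"), sols)
  expect_gt(length(d2_dollar), 0L)
  expect_true(any(vapply(d2_dollar, function(s) {
    identical(s$rule_path, c("dollar.to.quarters", "quarters.to.apple"))
  }, logical(1))))
  # no quarter at depth 0
  expect_false(has_entity(sols[[1]], "quarter"))
})

test_that("backward narrowing on the EGF fixture undoes the chain one step at a time", {
  kb <- egf_fixture()
  chain <- c("001.EgfR.irt.Egf", "188.Shp2.irt.Egf", "529.Hras.irt.Egf")
  post <- replay_path(kb, "EgfDish", chain)[[1]]
  res <- backward_search(kb, post, max_depth = 1)
  sols <- res$solutions
  expect_identical(sols[[1]]$depth, 0L)
  expect_identical(canonical(sols[[1]]$initial_pattern), canonical(post))
  expect_identical(sols[[2]]$depth, 1L)
  expect_length(sols[[2]]$rule_path, 1L)
  # among the one-step-back solutions is the true pre-529 state
  pre529 <- replay_path(kb, "EgfDish", chain[1:2])[[1]]
  d1 <- Filter(function(s) s$depth == 1, sols)
  expect_true(any(vapply(d1, function(s) {
    identical(s$rule_path, "529.Hras.irt.Egf") &&
      instance_of(s$initial_pattern, pre529, kb$hierarchy)
  }, logical(1))))
  for (s in sols) expect_true(ground_check(s, kb, res$goal))
})

test_that("a goal no rule can produce yields only the identity solution", {
  kb <- vending_fixture()
  # nothing produces a dollar
  res <- backward_search(kb, "{VM | dollar}", max_depth = 2)
  expect_length(res$solutions, 1L)
  expect_identical(res$solutions[[1]]$depth, 0L)
})

test_that("ground_check accepts sound solutions and rejects corrupted ones", {
  kb <- vending_fixture()
  res <- backward_search(kb, "{VM | apple ?rest:Things}", max_depth = 2)
  dollar_sol <- Filter(function(s) {
    s$depth == 2 && identical(s$rule_path, c("dollar.to.quarters", "quarters.to.apple"))
  }, res$solutions)[[1]]
  expect_true(ground_check(dollar_sol, kb, res$goal))
  # corrupt the accumulated substitution: the replay no longer hits the goal
  bad <- dollar_sol
  bad$accumulated_substitution <- substitution(
    soups = list(rest = soup(entity("chocolate"), entity("chocolate"))))
  expect_false(ground_check(bad, kb, res$goal))
  # corrupt the rule path
  bad2 <- dollar_sol
  bad2$rule_path <- c("dollar.to.chocolate", "quarters.to.apple")
  expect_false(ground_check(bad2, kb, res$goal))
})

test_that("narrowing is sound and desk-scale complete on seeded random systems", {
  soundness_seeds <- 1:50
  for (seed in soundness_seeds) {
    gen <- generate_kb(gen_config(seed = seed, n_entities = 3, n_locations = 2,
                                  n_rules = 2, max_soup_size = 2, max_rule_width = 1))
    kb <- gen$kb
    ents <- names(kb$entities)
    goal <- dish(L1 = soup(entity(ents[[1]]), svar = "g1"), dvar = "gd")
    res <- backward_search(kb, goal, max_depth = 2, max_solutions = 25)
    for (s in res$solutions) {
      expect_true(ground_check(s, kb, res$goal),
                  label = sprintf("seed %d depth %d", seed, s$depth))
    }
  }
})

test_that("every short forward route is an instance of a backward solution of equal depth", {
  for (seed in 1:10) {
    gen <- generate_kb(gen_config(seed = seed, n_entities = 3, n_locations = 2,
                                  n_rules = 2, max_soup_size = 2, max_rule_width = 1))
    kb <- gen$kb
    ents <- names(kb$entities)
    goal <- dish(L1 = soup(entity(ents[[1]]), svar = "g1"), dvar = "gd")
    back <- backward_search(kb, goal, max_depth = 2, max_solutions = Inf)
    grounds <- enum_ground_dishes(c("L1", "L2"), ents, 2L)
    for (g in grounds) {
      fwd <- forward_search(kb, g, search_goal(goal, min_steps = 0, max_depth = 2,
                                               max_solutions = 1))
      if (length(fwd$solutions) == 0L) next
      d <- fwd$solutions[[1]]$depth
      covered <- any(vapply(back$solutions, function(s) {
        s$depth == d && instance_of(s$initial_pattern, g, kb$hierarchy)
      }, logical(1)))
      expect_true(covered, label = sprintf("seed %d state %s depth %d", seed, g$key, d))
    }
  }
})

test_that("the subsumption filter only removes strict instances of retained solutions", {
  kb <- vending_fixture()
  full <- backward_search(kb, "{VM | apple ?rest:Things}", max_depth = 2)
  filtered <- backward_search(kb, "{VM | apple ?rest:Things}", max_depth = 2,
                              subsume = TRUE)
  kept <- vapply(filtered$solutions, function(s) canonical(s$initial_pattern), character(1))
  expect_lte(length(filtered$solutions), length(full$solutions))
  for (s in full$solutions) {
    if (canonical(s$initial_pattern) %in% kept) next
    is_strict_instance <- any(vapply(filtered$solutions, function(kf) {
      instance_of(kf$initial_pattern, s$initial_pattern, kb$hierarchy) &&
        !instance_of(s$initial_pattern, kf$initial_pattern, kb$hierarchy)
    }, logical(1)))
    expect_true(is_strict_instance, label = canonical(s$initial_pattern))
  }
})
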