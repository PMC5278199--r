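# Knowledge bases: sort hierarchy, validation, JSON round-trip, fixtures.

test_that("sort membership follows the fixture hierarchy transitively", {
  kb <- egf_fixture()
  h <- kb$hierarchy
  expect_true(sort_member(entity("Erks"), "ErkS", h))
  expect_true(sort_member(modified("Erks", c("phos(TEY)", "phos(SPS)")), "BProtein", h))
  expect_true(sort_member(entity("Gab1"), "GabS", h))
  expect_true(sort_member(entity("Gab2"), "GabS", h))
  expect_false(sort_member(entity("Egf"), "ErkS", h))
  expect_false(sort_member(entity("GDP"), "BProtein", h))
  # Things is the top sort: everything belongs, including complexes
  cx <- complex_term(entity("Hras"), entity("GTP"))
  expect_true(sort_member(cx, "Things", h))
  expect_false(sort_member(cx, "BProtein", h))
  expect_error(sort_member(entity("Egf"), "NoSuchSort", h), "unknown sort")
  expect_error(sort_hierarchy(list(A = "B", B = "A")), "cyclic")
})

test_that("the EGF fixture matches its printed description", {
  kb <- egf_fixture()
  expect_setequal(names(kb$rules),
                  c("001.EgfR.irt.Egf", "188.Shp2.irt.Egf", "529.Hras.irt.Egf"))
  d <- kb$dishes$EgfDish
  expect_setequal(names(d$locations),
                  c("XOut", "EgfRC", "CLo", "CLm", "CLi", "CLc", "NUc"))
  expect_identical(canonical(d$locations$CLo), "none")
  expect_identical(canonical(d$locations$XOut), "Egf")
  expect_identical(canonical(d$locations$EgfRC), "EgfR")
  # the GTPases are GDP-loaded complexes at the inner membrane
  cli <- canonical(d$locations$CLi)
  for (gtpase in c("Cdc42", "Hras", "Kras")) {
    expect_match(cli, paste0("\\(", gtpase, " : GDP\\)|\\(GDP : ", gtpase, "\\)"))
  }
  expect_true(is_ground(d))
})

test_that("the vending fixture prints the three rules of the machine", {
  kb <- vending_fixture()
  expect_setequal(names(kb$rules),
                  c("dollar.to.quarters", "dollar.to.chocolate", "quarters.to.apple"))
  rhs <- kb$rules[["dollar.to.quarters"]]$rhs
  n_quarters <- sum(vapply(rhs$locations$VM$elements,
                           function(t) identical(t$key, "quarter"), logical(1)))
  expect_identical(n_quarters, 4L)
  lhs_a <- kb$rules[["quarters.to.apple"]]$lhs
  expect_identical(sum(soupsearch:::.soup_counts(lhs_a$locations$VM)["quarter"]), 2L)
})

test_that("KB JSON save/load round-trips canonical forms", {
  for (kb in list(egf_fixture(), vending_fixture(), generate_kb(gen_config(seed = 3))$kb)) {
    path <- withr::local_tempfile(fileext = ".json")
    save_kb(kb, path)
    kb2 <- load_kb(path)
    expect_identical(vapply(kb2$rules, function(r) r$key, character(1)),
                     vapply(kb$rules, function(r) r$key, character(1)))
    expect_identical(vapply(kb2$dishes, canonical, character(1)),
                     vapply(kb$dishes, canonical, character(1)))
    expect_identical(kb_fingerprint(kb2), kb_fingerprint(kb))
    # a second save is byte-identical
    path2 <- withr::local_tempfile(fileext = ".json")
    save_kb(kb2, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("validation rejects each broken mutant of a valid fixture", {
  # right-hand side inventing a variable
  expect_error(
    rw_rule("bad.rhs.var", "{VM | dollar}", "{VM | ?m:Things}"),
    "invents variable"
  )
  # mismatched location sets between the two sides
  expect_error(
    rw_rule("bad.tags", "{VM | dollar}", "{XX | dollar}"),
    "same location tags"
  )
  # condition variable not on the left
  expect_error(
    rw_rule("bad.cond", "{VM | dollar}", "{VM | dollar}",
            conditions = list(list(var = "z", sort = "Coin"))),
    "condition variable"
  )
  # duplicate labels
  r <- rw_rule("dup", "{VM | dollar ?m:Things}", "{VM | ?m:Things}")
  expect_error(
    knowledge_base(rules = list(r, r), entities = c(dollar = "Things")),
    "duplicate rule labels"
  )
  # undeclared entity in a rule
  expect_error(
    knowledge_base(rules = list(rw_rule("u", "{VM | widget ?m:Things}", "{VM | ?m:Things}")),
                   entities = c(dollar = "Things")),
    "undeclared entit"
  )
  # unknown sort on a rule variable
  expect_error(
    knowledge_base(rules = list(rw_rule("s", "{VM | ?x:NoSort ?m:Things}", "{VM | ?x:NoSort ?m:Things}")),
                   entities = c(dollar = "Things")),
    "unknown sort"
  )
  # undeclared entity in a dish
  expect_error(
    knowledge_base(entities = c(dollar = "Things"),
                   dishes = list(D = parse_dish("{VM | widget}"))),
    "undeclared entit"
  )
})

test_that("load_kb reports schema and parse problems", {
  expect_error(load_kb("{\"version\": 99}"), "schema version")
  expect_error(load_kb("{not json"), "parse error")
  expect_error(load_kb(file.path(tempdir(), "nope-missing.json")), "no such file")
})
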