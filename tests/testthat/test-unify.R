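# Restricted AC unification of dish patterns.

test_that("unifying an open location with a ligand-bearing one extends the soup variable", {
  kb <- egf_fixture()
  l <- parse_dish("{XOut | ?xout:Things}")
  r <- parse_dish("{XOut | Egf ?xp:Things}")
  us <- unify_dishes(l, r, kb$hierarchy, rename = FALSE)
  expect_length(us, 1L)
  img <- apply_subst(l, us[[1]])
  # xout must be of the form "Egf plus a fresh remainder"
  expect_match(canonical(img), "^\\{XOut \\| Egf \\?[A-Za-z0-9._']+:Things\\}$")
  expect_identical(canonical(apply_subst(l, us[[1]])), canonical(apply_subst(r, us[[1]])))
})

test_that("identical ground dishes unify with exactly the empty substitution", {
  kb <- egf_fixture()
  us <- unify_dishes(kb$dishes$EgfDish, kb$dishes$EgfDish, kb$hierarchy)
  expect_length(us, 1L)
  expect_true(subst_is_empty(us[[1]]))
  # distinct ground dishes do not unify
  expect_length(unify_dishes("{XOut | Egf}", "{XOut | EgfR}", kb$hierarchy), 0L)
})

test_that("every unifier equates the two sides and the set is duplicate-free", {
  kb <- vending_fixture()
  l <- parse_dish("{VM | quarter quarter ?v:Things}")
  r <- parse_dish("{VM | quarter ?w:Things}")
  us <- unify_dishes(l, r, kb$hierarchy, rename = FALSE)
  expect_length(us, 2L)
  keys <- vapply(us, function(s) s$key, character(1))
  expect_false(anyDuplicated(keys) > 0)
  for (u in us) {
    expect_identical(canonical(apply_subst(l, u)), canonical(apply_subst(r, u)))
  }
})

test_that("the unifier set is complete against ground enumeration", {
  kb <- vending_fixture()
  h <- kb$hierarchy
  probs <- list(
    c("{VM | quarter quarter ?v:Things}", "{VM | quarter ?w:Things}"),
    c("{VM | apple ?v:Things}", "{VM | ?w:Things}"),
    c("{VM | dollar dollar ?v:Things}", "{VM | dollar chocolate ?w:Things}"),
    c("{VM | apple apple}", "{VM | apple ?w:Things}")
  )
  ents <- c("apple", "chocolate", "dollar", "quarter")
  grounds <- enum_ground_dishes("VM", ents, 4L)
  for (pr in probs) {
    l <- parse_dish(pr[[1]]); r <- parse_dish(pr[[2]])
    us <- unify_dishes(l, r, h, rename = FALSE)
    for (g in grounds) {
      common <- length(match_dish(l, g, h)) > 0 && length(match_dish(r, g, h)) > 0
      covered <- any(vapply(us, function(u) {
        length(match_dish(apply_subst(l, u), g, h)) > 0
      }, logical(1)))
      expect_identical(covered, common)
    }
  }
})

test_that("unification is symmetric up to variable renaming", {
  kb <- vending_fixture()
  h <- kb$hierarchy
  rename_norm <- soupsearch:::.rename_canonical
  probs <- list(
    c("{VM | quarter quarter ?v:Things}", "{VM | quarter ?w:Things}"),
    c("{VM | apple ?v:Things}", "{VM | chocolate ?w:Things}"),
    c("{VM | ?v:Things}", "{VM | dollar}")
  )
  for (pr in probs) {
    l <- parse_dish(pr[[1]]); r <- parse_dish(pr[[2]])
    us_lr <- unify_dishes(l, r, h, rename = FALSE)
    us_rl <- unify_dishes(r, l, h, rename = FALSE)
    inst_lr <- sort(vapply(us_lr, function(u) rename_norm(apply_subst(l, u)), character(1)),
                    method = "radix")
    inst_rl <- sort(vapply(us_rl, function(u) rename_norm(apply_subst(r, u)), character(1)),
                    method = "radix")
    expect_identical(inst_lr, inst_rl)
  }
})

test_that("sorted element variables unify by meet and fail on empty intersections", {
  kb <- egf_fixture()
  h <- kb$hierarchy
  # a GabS variable against [Gab1 - Yphos]: the base resolves to Gab1
  us <- unify_dishes("{CLc | [?gab:GabS - Yphos]}", "{CLc | [Gab1 - Yphos]}", h)
  expect_length(us, 1L)
  expect_identical(us[[1]]$terms$gab$key, "Gab1")
  # GabS and RasActS have no common entity: no unifier
  expect_length(
    unify_dishes("{CLc | ?a:GabS}", "{CLc | ?b:RasActS}", h), 0L)
  # GabS and BProtein meet in GabS: variables unify to a shared fresh variable
  us2 <- unify_dishes("{CLc | ?a:GabS}", "{CLc | ?b:BProtein}", h)
  expect_length(us2, 1L)
  expect_identical(us2[[1]]$terms$a$key,
                   us2[[1]]$terms[[setdiff(names(us2[[1]]$terms), "a")]]$key)
  # the occurs check blocks cyclic bindings (an element variable against a
  # complex containing itself)
  v <- term_var("a", "Things")
  cyc <- complex_term(entity("Gab1"), v)
  expect_length(
    soupsearch:::.unify_term(v, cyc, h, substitution(), soupsearch:::.fresh_env("a")),
    0L)
})

test_that("dish variables absorb surplus locations on either side", {
  kb <- egf_fixture()
  us <- unify_dishes("{XOut | Egf} ?d1:Dish", "{XOut | Egf} {NUc | Atf1} ?d2:Dish",
                     kb$hierarchy, rename = FALSE)
  expect_length(us, 1L)
  expect_match(canonical(us[[1]]$dishes$d1), "\\{NUc \\| Atf1\\}")
  # no dish variable on the narrow side: no unifier
  expect_length(unify_dishes("{XOut | Egf}", "{XOut | Egf} {NUc | Atf1}",
                             kb$hierarchy), 0L)
})
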