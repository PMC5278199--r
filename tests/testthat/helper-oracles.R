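# Independent oracles and small random-case generators for property tests.
# The oracles deliberately use guess-and-check enumeration, not the engines'
# recursive algorithms.

.ss <- function(name) get(name, envir = asNamespace("soupsearch"))

# ---- random object generators (driven by the caller's RNG state) -----------

rand_pool <- c("Ea", "Eb", "Ec", "Ed")

rand_ground_term <- function(pool = rand_pool, p_mod = 0.3, p_cx = 0.2) {
  u <- runif(1)
  if (u < p_cx) {
    complex_term(entity(sample(pool, 1)), entity(sample(pool, 1)))
  } else if (u < p_cx + p_mod) {
    modified(sample(pool, 1), sample(c("Yphos", "phos(TEY)"), 1))
  } else {
    entity(sample(pool, 1))
  }
}

rand_ground_soup <- function(n, pool = rand_pool) {
  soup(lapply(seq_len(n), function(i) rand_ground_term(pool)))
}

rand_ground_dish <- function(tags = c("A", "B"), max_n = 3, pool = rand_pool) {
  locs <- lapply(tags, function(tg) rand_ground_soup(sample.int(max_n + 1, 1) - 1L, pool))
  names(locs) <- tags
  dish(locations = locs)
}

# a pattern over the same tags: some ground terms from the dish, some element
# variables, optionally a soup variable per location
rand_pattern_for <- function(d, h, p_var = 0.35, p_svar = 0.7) {
  vi <- 0L
  locs <- lapply(names(d$locations), function(tg) {
    elems <- d$locations[[tg]]$elements
    keep <- if (length(elems)) {
      elems[runif(length(elems)) < 0.6] # drop some elements into the remainder
    } else list()
    keep <- lapply(keep, function(t) {
      if (runif(1) < p_var) {
        vi <<- vi + 1L
        term_var(paste0("pv", vi), sample(c("Things", "SAny"), 1))
      } else t
    })
    soup(keep, svar = if (runif(1) < p_svar) paste0("sv", tg) else NULL)
  })
  names(locs) <- names(d$locations)
  dish(locations = locs)
}

# hierarchy for the random pools: SAny = all pool entities, SOdd = half
rand_hierarchy <- function(pool = rand_pool) {
  sort_hierarchy(list(SAny = pool, SOdd = pool[c(TRUE, FALSE)]), entities = pool)
}

# ---- brute-force matching oracle -------------------------------------------

# every substitution s with apply_subst(p, s) == d, by exhaustive enumeration
# of element-variable bindings over the subterms of d plus leftover check
oracle_match <- function(p, d, h) {
  collect <- .ss(".collect_vars")
  counts <- .ss(".soup_counts")
  vs <- collect(p)
  cands <- list()
  for (sp in d$locations) {
    for (e in sp$elements) {
      cands[[e$key]] <- e
      if (e$kind == "modified") cands[[e$name]] <- entity(e$name)
      if (e$kind == "complex") for (cmp in e$components) cands[[cmp$key]] <- cmp
    }
  }
  cands <- unname(cands)
  combos <- list(substitution())
  for (v in vs$elem) {
    nxt <- list()
    for (s in combos) {
      for (cand in cands) {
        ok <- all(vapply(vs$sorts[[v]], function(srt) sort_member(cand, srt, h),
                         logical(1)))
        if (!ok) next
        nxt[[length(nxt) + 1L]] <-
          compose_subst(s, substitution(terms = stats::setNames(list(cand), v)))
      }
    }
    combos <- nxt
  }
  out <- list()
  for (s in combos) {
    p2 <- tryCatch(apply_subst(p, s), error = function(e) NULL)
    if (is.null(p2)) next
    full <- s
    ok <- TRUE
    for (tg in names(p2$locations)) {
      ps <- p2$locations[[tg]]
      if (!all(vapply(ps$elements, is_ground, logical(1)))) { ok <- FALSE; break }
      pc <- counts(ps)
      gc <- counts(d$locations[[tg]])
      diff <- gc
      for (k in names(pc)) {
        have <- if (k %in% names(diff)) diff[[k]] else 0L
        if (have < pc[[k]]) { ok <- FALSE; break }
        diff[[k]] <- have - pc[[k]]
      }
      if (!ok) break
      diff <- diff[diff > 0L]
      if (is.null(ps$svar)) {
        if (length(diff)) { ok <- FALSE; break }
      } else {
        left <- list()
        gmap <- list()
        for (e in d$locations[[tg]]$elements) gmap[[e$key]] <- e
        for (k in names(diff)) left <- c(left, rep(list(gmap[[k]]), diff[[k]]))
        full <- compose_subst(full, substitution(
          soups = stats::setNames(list(soup(left)), ps$svar)))
      }
    }
    if (ok) out[[length(out) + 1L]] <- full
  }
  keys <- vapply(out, function(s) s$key, character(1))
  out[!duplicated(keys)]
}

# ---- ground enumeration ----------------------------------------------------

# all multisets (as lists of terms) of size <= max_n over an entity vector
enum_multisets <- function(ents, max_n) {
  out <- list(list())
  grow <- function(acc, start) {
    if (length(acc) < max_n) {
      for (i in start:length(ents)) {
        nxt <- c(acc, list(entity(ents[[i]])))
        out[[length(out) + 1L]] <<- nxt
        grow(nxt, i)
      }
    }
  }
  grow(list(), 1L)
  out
}

# all ground dishes over fixed tags with soups of size <= max_n
enum_ground_dishes <- function(tags, ents, max_n) {
  soups <- lapply(enum_multisets(ents, max_n), soup)
  idx <- rep(list(seq_along(soups)), length(tags))
  grid <- do.call(expand.grid, idx)
  lapply(seq_len(nrow(grid)), function(i) {
    locs <- lapply(seq_along(tags), function(j) soups[[grid[i, j]]])
    names(locs) <- tags
    dish(locations = locs)
  })
}

# ---- independent forward enumerator ----------------------------------------

# minimum number of rewrite steps from `start` to a state matching `goalpat`
# (>= min_steps), by plain depth-bounded DFS over all rule applications with
# no visited-state pruning; NA if unreachable within max_depth
oracle_min_depth <- function(kb, start, goalpat, max_depth, min_steps = 1L) {
  best <- NA_integer_
  rec <- function(state, depth) {
    if (!is.na(best) && depth >= best) return(invisible(NULL))
    if (depth >= min_steps && length(match_dish(goalpat, state, kb$hierarchy))) {
      best <<- depth
      return(invisible(NULL))
    }
    if (depth >= max_depth) return(invisible(NULL))
    for (lb in sort(names(kb$rules), method = "radix")) {
      for (succ in apply_rule(kb$rules[[lb]], state, kb$hierarchy)) {
        rec(succ$dish, depth + 1L)
      }
    }
  }
  rec(start, 0L)
  best
}

# multiset of base entity names in a ground dish (complex components and
# modified bases included, with multiplicity)
entity_multiset <- function(d) {
  out <- character(0)
  walk <- function(t) {
    switch(t$kind,
      entity = out <<- c(out, t$name),
      modified = out <<- c(out, t$name),
      complex = for (cmp in t$components) walk(cmp)
    )
    invisible(NULL)
  }
  for (sp in d$locations) for (e in sp$elements) walk(e)
  sort(out, method = "radix")
}

# reachable canonical state keys up to a depth bound (simple BFS on
# apply_rule; used to compare rule sets before/after topification)
reachable_keys <- function(rules, h, start, max_depth) {
  seen <- new.env(parent = emptyenv())
  seen[[start$key]] <- TRUE
  frontier <- list(start)
  depth <- 0L
  while (depth < max_depth && length(frontier)) {
    nxt <- list()
    for (st in frontier) {
      for (lb in sort(names(rules), method = "radix")) {
        for (succ in apply_rule(rules[[lb]], st, h)) {
          if (is.null(seen[[succ$dish$key]])) {
            seen[[succ$dish$key]] <- TRUE
            nxt[[length(nxt) + 1L]] <- succ$dish
          }
        }
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  sort(ls(seen), method = "radix")
}
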