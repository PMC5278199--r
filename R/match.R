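# AC multiset matching: pattern dishes/soups/terms against ground targets.
# Substitutions are threaded left-to-right; all branching is over bytewise-
# sorted keys, so the returned list order is deterministic.

.counts_of <- function(terms) {
  ks <- .term_keys(terms)
  if (length(ks) == 0L) return(list(cnt = integer(0), map = list()))
  ord <- .corder(ks)
  terms <- terms[ord]; ks <- ks[ord]
  map <- list()
  for (i in seq_along(terms)) if (is.null(map[[ks[i]]])) map[[ks[i]]] <- terms[[i]]
  tab <- table(ks)
  cnt <- as.integer(tab); names(cnt) <- names(tab)
  list(cnt = cnt, map = map)
}

# collection-variable markers used by instance_of(): never bindable by an
# element variable
.is_rigid <- function(g, h) {
  !is.null(h$rigid) && g$kind == "entity" && g$name %in% h$rigid
}

.bind_term <- function(s, var, val) {
  compose_subst(s, substitution(terms = stats::setNames(list(val), var)))
}
.bind_soup <- function(s, var, val) {
  compose_subst(s, substitution(soups = stats::setNames(list(val), var)))
}
.bind_dish <- function(s, var, val) {
  compose_subst(s, substitution(dishes = stats::setNames(list(val), var)))
}

# all sub-multisets of a count vector with total size in [lo, hi]
.submultisets <- function(cnt, lo, hi) {
  keys <- names(cnt)
  out <- list()
  rec <- function(i, acc, size) {
    if (size > hi) return(invisible(NULL))
    if (i > length(keys)) {
      if (size >= lo) out[[length(out) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (k in 0:cnt[[i]]) {
      a2 <- acc
      if (k > 0L) a2[[keys[[i]]]] <- k
      rec(i + 1L, a2, size + k)
    }
  }
  rec(1L, integer(0), 0L)
  out
}

# match one pattern term against one ground term under substitution s;
# returns a list of extended substitutions
.match_term <- function(p, g, h, s) {
  p <- apply_subst(p, s)
  if (is_ground(p)) {
    return(if (identical(p$key, g$key)) list(s) else list())
  }
  switch(p$kind,
    var = {
      if (.is_rigid(g, h)) return(list())
      for (srt in p$sorts) if (!sort_member(g, srt, h)) return(list())
      list(.bind_term(s, p$var, g))
    },
    modified = {
      # variable base: g must be a concrete modified entity with the same mods
      if (g$kind != "modified" ||
          !identical(.mod_keys(p$mods), .mod_keys(g$mods))) return(list())
      bv <- p$base_var
      ge <- entity(g$name)
      for (srt in bv$sorts) if (!sort_member(ge, srt, h)) return(list())
      list(.bind_term(s, bv$var, ge))
    },
    complex = {
      if (g$kind != "complex") return(list())
      gc <- .counts_of(g$components)
      res <- .match_elems(p$components, gc$cnt, gc$map, h, s, in_complex = TRUE)
      out <- list()
      for (r in res) if (sum(r$rest) == 0L) out[[length(out) + 1L]] <- r$s
      out
    },
    list()
  )
}

# match a list of pattern elements against a ground multiset (counts);
# returns list(list(s = substitution, rest = leftover counts))
.match_elems <- function(pelems, gcnt, gmap, h, s, in_complex = FALSE) {
  if (length(pelems) == 0L) return(list(list(s = s, rest = gcnt)))
  p1 <- apply_subst(pelems[[1L]], s)
  rest <- pelems[-1L]
  dec <- function(cnt, key) {
    cnt[[key]] <- cnt[[key]] - 1L
    if (cnt[[key]] == 0L) cnt <- cnt[names(cnt) != key]
    cnt
  }
  out <- list()
  if (is_ground(p1)) {
    k <- p1$key
    if (k %in% names(gcnt)) {
      out <- .match_elems(rest, dec(gcnt, k), gmap, h, s, in_complex)
    }
    return(out)
  }
  if (p1$kind == "var") {
    for (k in names(gcnt)) {
      g <- gmap[[k]]
      if (.is_rigid(g, h)) next
      ok <- TRUE
      for (srt in p1$sorts) if (!sort_member(g, srt, h)) { ok <- FALSE; break }
      if (!ok) next
      s2 <- .bind_term(s, p1$var, g)
      out <- c(out, .match_elems(rest, dec(gcnt, k), gmap, h, s2, in_complex))
    }
    if (in_complex && identical(p1$sorts, "Things")) {
      # inside a flattened complex, a Things variable may absorb >=2 components
      for (sub in .submultisets(gcnt, 2L, sum(gcnt))) {
        comps <- list()
        g2 <- gcnt
        for (k in names(sub)) {
          comps <- c(comps, rep(list(gmap[[k]]), sub[[k]]))
          g2[[k]] <- g2[[k]] - sub[[k]]
        }
        g2 <- g2[g2 > 0L]
        s2 <- .bind_term(s, p1$var, complex_term(comps))
        out <- c(out, .match_elems(rest, g2, gmap, h, s2, in_complex))
      }
    }
    return(out)
  }
  # composite pattern element still containing variables
  for (k in names(gcnt)) {
    for (s2 in .match_term(p1, gmap[[k]], h, s)) {
      out <- c(out, .match_elems(rest, dec(gcnt, k), gmap, h, s2, in_complex))
    }
  }
  out
}

# match a pattern soup against a ground soup
.match_soup <- function(ps, gs, h, s) {
  ps <- apply_subst(ps, s)
  gc <- .counts_of(gs$elements)
  res <- .match_elems(ps$elements, gc$cnt, gc$map, h, s)
  out <- list()
  for (r in res) {
    if (is.null(ps$svar)) {
      if (sum(r$rest) == 0L) out[[length(out) + 1L]] <- r$s
    } else {
      left <- list()
      for (k in names(r$rest)) left <- c(left, rep(list(gc$map[[k]]), r$rest[[k]]))
      out[[length(out) + 1L]] <- .bind_soup(r$s, ps$svar, soup(left))
    }
  }
  out
}

#' Match a dish pattern against a ground dish
#'
#' Finds every substitution `s` such that applying `s` to `pattern` gives a
#' dish canonically equal to `target` — associative-commutative matching of
#' each location's soup, with element variables checked against their sort
#' constraints, at most one soup variable per location absorbing the
#' unmatched remainder, and an optional dish variable absorbing locations
#' the pattern does not mention. Without a dish variable the pattern must
#' mention exactly the target's locations.
#'
#' @param pattern An `ss_dish` pattern (or text for [parse_dish()]).
#' @param target A ground `ss_dish`.
#' @param hierarchy A [sort_hierarchy()] (e.g. `kb$hierarchy`).
#' @return Duplicate-free list of [substitution()]s, in a deterministic
#'   order; empty list when there is no match.
#' @examples
#' kb <- egf_fixture()
#' p <- parse_dish("{XOut | Egf ?xout:Things} {EgfRC | EgfR ?e:Things}")
#' d <- parse_dish("{XOut | Egf} {EgfRC | EgfR}")
#' match_dish(p, d, kb$hierarchy)
#' @export
match_dish <- function(pattern, target, hierarchy) {
  if (is.character(pattern)) pattern <- parse_dish(pattern)
  if (is.character(target)) target <- parse_dish(target)
  if (!is_ground(target)) stop("match target must be ground", call. = FALSE)
  ptags <- names(pattern$locations)
  ttags <- names(target$locations)
  if (is.null(pattern$dvar)) {
    if (!setequal(ptags, ttags)) return(list())
  } else {
    if (!all(ptags %in% ttags)) return(list())
  }
  subs <- list(substitution())
  for (tg in ptags) {
    nxt <- list()
    for (s in subs) {
      nxt <- c(nxt, .match_soup(pattern$locations[[tg]], target$locations[[tg]],
                                hierarchy, s))
    }
    subs <- nxt
    if (length(subs) == 0L) return(list())
  }
  if (!is.null(pattern$dvar)) {
    extra <- setdiff(ttags, ptags)
    frag <- dish(locations = target$locations[extra])
    subs <- lapply(subs, .bind_dish, var = pattern$dvar, val = frag)
  }
  keys <- vapply(subs, function(s) s$key, character(1))
  subs[!duplicated(keys)]
}
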