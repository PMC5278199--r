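#' Substitutions
#'
#' A substitution is a finite mapping from variables to replacement values:
#' element variables map to terms, soup variables to soups (which may
#' themselves end in a soup variable), and dish variables to dish fragments
#' (a partial dish, possibly ending in a dish variable). Substitutions
#' produced by matching and unification are idempotent: applying one twice
#' equals applying it once.
#'
#' @param terms Named list, element-variable name -> `ss_term`.
#' @param soups Named list, soup-variable name -> `ss_soup`.
#' @param dishes Named list, dish-variable name -> `ss_dish` fragment.
#' @return An object of class `ss_subst`.
#' @examples
#' s <- substitution(soups = list(xout = soup(entity("Egf"), svar = "rest")))
#' apply_subst(parse_dish("{XOut | ?xout:Things}"), s)
#' @export
substitution <- function(terms = list(), soups = list(), dishes = list()) {
  chk <- function(lst, cls, what) {
    if (length(lst)) {
      if (is.null(names(lst)) || any(names(lst) == "")) {
        stop("all ", what, " bindings must be named", call. = FALSE)
      }
      for (v in lst) if (!inherits(v, cls)) {
        stop(what, " bindings must be ", cls, " objects", call. = FALSE)
      }
      lst <- lst[.csort(names(lst))]
    }
    lst
  }
  terms <- chk(terms, "ss_term", "term")
  soups <- chk(soups, "ss_soup", "soup")
  dishes <- chk(dishes, "ss_dish", "dish")
  key <- paste(c(
    vapply(names(terms), function(v) paste0(v, "=", terms[[v]]$key), character(1)),
    vapply(names(soups), function(v) paste0(v, "=", soups[[v]]$key), character(1)),
    vapply(names(dishes), function(v) paste0(v, "=", dishes[[v]]$key), character(1))
  ), collapse = "; ")
  structure(list(terms = terms, soups = soups, dishes = dishes, key = key),
            class = "ss_subst")
}

#' @export
print.ss_subst <- function(x, ...) {
  if (subst_is_empty(x)) cat("(empty substitution)\n") else cat(x$key, "\n")
  invisible(x)
}

#' @rdname substitution
#' @export
subst_is_empty <- function(s) {
  length(s$terms) == 0L && length(s$soups) == 0L && length(s$dishes) == 0L
}

#' Apply a substitution
#'
#' All occurrences of bound variables are replaced simultaneously; variables
#' not bound by `s` survive. The result is ground iff `s` covers every
#' variable of `x`. When a sort `hierarchy` is supplied, each element
#' binding is checked against the variable's sort constraints and a
#' sort-violation error is raised on mismatch; a base variable of a modified
#' term may only be bound to a bare entity.
#'
#' @param x A term, soup, dish, or substitution (images rewritten).
#' @param s A [substitution()].
#' @param hierarchy Optional [sort_hierarchy()] for sort checking.
#' @return Object of the same class as `x`.
#' @export
apply_subst <- function(x, s, hierarchy = NULL) {
  UseMethod("apply_subst")
}

.check_binding_sorts <- function(var, val, hierarchy) {
  if (is.null(hierarchy)) return(invisible(TRUE))
  for (srt in var$sorts) {
    if (!sort_member(val, srt, hierarchy)) {
      stop("sort violation: binding for '", var$var, "' (", val$key,
           ") is not a member of sort ", srt, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
apply_subst.ss_term <- function(x, s, hierarchy = NULL) {
  switch(x$kind,
    entity = x,
    var = {
      b <- s$terms[[x$var]]
      if (is.null(b)) x else { .check_binding_sorts(x, b, hierarchy); b }
    },
    modified = {
      if (is.null(x$base_var)) return(x)
      b <- s$terms[[x$base_var$var]]
      if (is.null(b)) return(x)
      if (b$kind == "var") return(modified(b, x$mods))
      if (b$kind != "entity") {
        stop("sort violation: base of a modified term must bind a bare entity, got ",
             b$key, call. = FALSE)
      }
      .check_binding_sorts(x$base_var, b, hierarchy)
      modified(b$name, x$mods)
    },
    complex = complex_term(lapply(x$components, apply_subst, s = s, hierarchy = hierarchy))
  )
}

#' @export
apply_subst.ss_soup <- function(x, s, hierarchy = NULL) {
  elems <- lapply(x$elements, apply_subst, s = s, hierarchy = hierarchy)
  out <- soup(elems, svar = NULL)
  if (!is.null(x$svar)) {
    b <- s$soups[[x$svar]]
    tail <- if (is.null(b)) soup(svar = x$svar) else b
    out <- .soup_union(out, tail)
  }
  out
}

#' @export
apply_subst.ss_dish <- function(x, s, hierarchy = NULL) {
  locs <- lapply(x$locations, apply_subst, s = s, hierarchy = hierarchy)
  dvar <- x$dvar
  if (!is.null(x$dvar)) {
    b <- s$dishes[[x$dvar]]
    if (!is.null(b)) {
      shared <- intersect(names(locs), names(b$locations))
      for (tg in shared) {  # same tag on both sides: soups merge
        locs[[tg]] <- .soup_union(locs[[tg]], b$locations[[tg]])
      }
      extra <- setdiff(names(b$locations), shared)
      locs[extra] <- b$locations[extra]
      dvar <- b$dvar
    }
  }
  dish(locations = locs, dvar = dvar)
}

#' @export
apply_subst.ss_subst <- function(x, s, hierarchy = NULL) {
  substitution(
    terms = lapply(x$terms, apply_subst, s = s, hierarchy = hierarchy),
    soups = lapply(x$soups, apply_subst, s = s, hierarchy = hierarchy),
    dishes = lapply(x$dishes, apply_subst, s = s, hierarchy = hierarchy)
  )
}

#' Compose two substitutions
#'
#' `compose_subst(s1, s2)` is the substitution whose application equals
#' applying `s1` first and then `s2`: images of `s1` are rewritten by `s2`,
#' and bindings of `s2` for variables untouched by `s1` are appended.
#'
#' @param s1,s2 Substitutions.
#' @return An `ss_subst`.
#' @export
compose_subst <- function(s1, s2) {
  s1b <- apply_subst(s1, s2)
  substitution(
    terms = c(s1b$terms, s2$terms[setdiff(names(s2$terms), names(s1b$terms))]),
    soups = c(s1b$soups, s2$soups[setdiff(names(s2$soups), names(s1b$soups))]),
    dishes = c(s1b$dishes, s2$dishes[setdiff(names(s2$dishes), names(s1b$dishes))])
  )
}

# --- fresh-variable supply ---------------------------------------------------
# A counter environment seeded with every name already in use; fresh() skips
# collisions, so renamed-apart rules can never capture goal variables.
.fresh_env <- function(used = character(0)) {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$used <- as.character(used)
  e
}

.fresh <- function(fe, base = "v") {
  repeat {
    fe$n <- fe$n + 1L
    cand <- paste0(base, ".", fe$n)
    if (!(cand %in% fe$used)) {
      fe$used <- c(fe$used, cand)
      return(cand)
    }
  }
}

# rename every variable of a dish pattern to a fresh name; returns the renamed
# dish plus the renaming substitution
.rename_apart_dish <- function(d, fe) {
  vs <- .collect_vars(d)
  terms <- list(); soups <- list(); dishes <- list()
  for (v in vs$elem) terms[[v]] <- term_var(.fresh(fe), vs$sorts[[v]])
  for (v in vs$soup) soups[[v]] <- soup(svar = .fresh(fe))
  for (v in vs$dish) dishes[[v]] <- dish(dvar = .fresh(fe))
  s <- substitution(terms = terms, soups = soups, dishes = dishes)
  list(dish = apply_subst(d, s), subst = s)
}

# classify variables occurring in a dish: element vs soup vs dish, with the
# sort annotation of each element variable
.collect_vars <- function(d) {
  elem <- character(0); sorts <- list(); soupv <- character(0)
  walk_term <- function(t) {
    switch(t$kind,
      entity = NULL,
      var = { elem <<- c(elem, t$var); sorts[[t$var]] <<- t$sorts; NULL },
      modified = if (!is.null(t$base_var)) walk_term(t$base_var),
      complex = { for (cmp in t$components) walk_term(cmp); NULL }
    )
    invisible(NULL)
  }
  for (sp in d$locations) {
    for (e in sp$elements) walk_term(e)
    if (!is.null(sp$svar)) soupv <- c(soupv, sp$svar)
  }
  list(elem = unique(elem), sorts = sorts, soup = unique(soupv),
       dish = if (is.null(d$dvar)) character(0) else d$dvar)
}

# canonical form modulo variable renaming (dedup key for backward search):
# variables renamed A1, A2, ... in order of first occurrence in the canonical
# string
.rename_canonical <- function(d) {
  key <- d$key
  m <- gregexpr("\\?[A-Za-z][A-Za-z0-9._']*", key)
  toks <- regmatches(key, m)[[1]]
  if (length(toks) == 0L) return(key)
  seen <- unique(toks)
  new <- sprintf("?A%03d", match(toks, seen))
  regmatches(key, m) <- list(new)
  key
}
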