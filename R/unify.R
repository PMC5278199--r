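# Restricted AC unification over dish patterns.
#
# Fragment: element variables are sorted first-order variables (syntactic
# unification with sort meets, realised as conjunctive sort annotations);
# soup variables are restricted to at most one per soup per side and are
# solved by enumerating pairings of the fixed elements, the surplus on
# either side going to the other side's soup variable (with a fresh shared
# tail variable when both sides have one); dish variables likewise absorb
# the other side's surplus locations. This keeps the unifier set finite and
# complete for the fragment the engines use.

.occurs_in <- function(var, t) var %in% term_vars(t)

# unify two pattern terms (both already carry the accumulated substitution);
# returns a list of extended substitutions
.unify_term <- function(a, b, h, s, fe) {
  a <- apply_subst(a, s); b <- apply_subst(b, s)
  ag <- is_ground(a); bg <- is_ground(b)
  if (ag && bg) return(if (identical(a$key, b$key)) list(s) else list())
  if (a$kind == "var" && b$kind == "var") {
    if (identical(a$var, b$var)) return(list(s))
    msorts <- unique(c(a$sorts, b$sorts))
    if (!sorts_satisfiable(msorts, h)) return(list())
    f <- term_var(.fresh(fe), msorts)
    return(list(compose_subst(s, substitution(
      terms = stats::setNames(list(f, f), c(a$var, b$var))))))
  }
  if (b$kind == "var") { tmp <- a; a <- b; b <- tmp; tmp <- ag; ag <- bg; bg <- tmp }
  if (a$kind == "var") {
    if (.occurs_in(a$var, b)) return(list())
    if (bg) {
      for (srt in a$sorts) if (!sort_member(b, srt, h)) return(list())
      return(list(.bind_term(s, a$var, b)))
    }
    if (b$kind == "complex") {
      # a non-ground complex is only a member of Things
      if (!identical(a$sorts, "Things")) return(list())
      return(list(.bind_term(s, a$var, b)))
    }
    if (b$kind == "modified") {
      # strengthen the base variable to the meet of its sorts and a's
      bv <- b$base_var
      msorts <- unique(c(bv$sorts, a$sorts))
      if (!sorts_satisfiable(msorts, h)) return(list())
      f <- term_var(.fresh(fe), msorts)
      s2 <- compose_subst(s, substitution(terms = stats::setNames(list(f), bv$var)))
      return(list(.bind_term(s2, a$var, modified(f, b$mods))))
    }
    return(list())
  }
  if (a$kind == "modified" && b$kind == "modified") {
    if (!identical(.mod_keys(a$mods), .mod_keys(b$mods))) return(list())
    abase <- if (is.null(a$name)) a$base_var else entity(a$name)
    bbase <- if (is.null(b$name)) b$base_var else entity(b$name)
    return(.unify_term(abase, bbase, h, s, fe))
  }
  if (a$kind == "complex" && b$kind == "complex") {
    if (length(a$components) != length(b$components)) return(list())
    return(.unify_components(a$components, b$components, h, s, fe))
  }
  list()
}

# syntactic 1-1 AC unification of complex components
.unify_components <- function(A, B, h, s, fe) {
  if (length(A) == 0L) {
    return(if (length(B) == 0L) list(s) else list())
  }
  a1 <- A[[1L]]
  out <- list()
  bkeys <- vapply(B, function(t) apply_subst(t, s)$key, character(1))
  tried <- character(0)
  for (j in seq_along(B)) {
    if (bkeys[[j]] %in% tried) next
    tried <- c(tried, bkeys[[j]])
    for (s2 in .unify_term(a1, B[[j]], h, s, fe)) {
      out <- c(out, .unify_components(A[-1L], B[-j], h, s2, fe))
    }
  }
  out
}

# enumerate pairings between left and right soup elements; unpaired left
# elements are deferred to the right soup variable (if any) and vice versa
.unify_elems <- function(L, R, h, s, fe, has_rsvar, deferred = list()) {
  if (length(L) == 0L) {
    return(list(list(s = s, lrest = deferred, rrest = R)))
  }
  l1 <- L[[1L]]
  out <- list()
  rkeys <- vapply(R, function(t) apply_subst(t, s)$key, character(1))
  tried <- character(0)
  for (j in seq_along(R)) {
    if (rkeys[[j]] %in% tried) next
    tried <- c(tried, rkeys[[j]])
    for (s2 in .unify_term(l1, R[[j]], h, s, fe)) {
      out <- c(out, .unify_elems(L[-1L], R[-j], h, s2, fe, has_rsvar, deferred))
    }
  }
  if (has_rsvar) {
    out <- c(out, .unify_elems(L[-1L], R, h, s, fe, has_rsvar,
                               c(deferred, list(l1))))
  }
  out
}

.unify_soup <- function(ls, rs, h, s, fe) {
  ls <- apply_subst(ls, s); rs <- apply_subst(rs, s)
  res <- .unify_elems(ls$elements, rs$elements, h, s, fe, !is.null(rs$svar))
  out <- list()
  for (r in res) {
    s2 <- r$s
    lrest <- lapply(r$lrest, apply_subst, s = s2)
    rrest <- lapply(r$rrest, apply_subst, s = s2)
    vl <- ls$svar; vr <- rs$svar
    if (is.null(vl) && length(rrest) > 0L) next
    if (is.null(vr) && length(lrest) > 0L) next
    soups <- list()
    if (!is.null(vl) && !is.null(vr)) {
      w <- .fresh(fe)
      soups[[vl]] <- soup(rrest, svar = w)
      soups[[vr]] <- soup(lrest, svar = w)
    } else if (!is.null(vl)) {
      soups[[vl]] <- soup(rrest)
    } else if (!is.null(vr)) {
      soups[[vr]] <- soup(lrest)
    }
    if (length(soups)) s2 <- compose_subst(s2, substitution(soups = soups))
    out[[length(out) + 1L]] <- s2
  }
  out
}

# normalization key for a unifier: images of the originally visible
# variables, with variables invented during unification renamed canonically
.unifier_key <- function(s, orig_vars) {
  parts <- c(
    vapply(names(s$terms), function(v) paste0(v, "=", s$terms[[v]]$key), character(1)),
    vapply(names(s$soups), function(v) paste0(v, "=", s$soups[[v]]$key), character(1)),
    vapply(names(s$dishes), function(v) paste0(v, "=", s$dishes[[v]]$key), character(1))
  )
  key <- paste(parts, collapse = "; ")
  m <- gregexpr("\\?[A-Za-z][A-Za-z0-9._']*", key)
  toks <- regmatches(key, m)[[1]]
  if (length(toks)) {
    fresh_toks <- setdiff(unique(toks), paste0("?", orig_vars))
    if (length(fresh_toks)) {
      map <- stats::setNames(sprintf("?F%03d", seq_along(fresh_toks)), fresh_toks)
      new <- ifelse(toks %in% fresh_toks, map[toks], toks)
      regmatches(key, m) <- list(new)
    }
  }
  key
}

#' Unify two dish patterns
#'
#' Computes a finite, duplicate-free, complete set of unifiers for the
#' restricted fragment: substitutions `s` with
#' `apply_subst(left, s)` canonically equal to `apply_subst(right, s)`.
#' Every common ground instance of the two patterns is an instance of some
#' returned unifier. Soups are unified modulo associativity-commutativity
#' with at most one soup variable per soup per side; element variables
#' unify syntactically with sort meets (conjunctive sort annotations) and
#' an occurs check. The two patterns' variable namespaces are renamed apart
#' before solving unless `rename = FALSE`.
#'
#' @param left,right Dish patterns (`ss_dish` or text).
#' @param hierarchy A [sort_hierarchy()].
#' @param rename Rename `right`'s variables apart first (default `TRUE`).
#' @param fresh Internal fresh-variable supply (an environment from prior
#'   calls), or `NULL` to create one.
#' @return List of [substitution()]s (possibly empty), deterministic order.
#' @examples
#' kb <- vending_fixture()
#' unify_dishes("{VM | quarter quarter ?v:Things}", "{VM | quarter ?w:Things}",
#'              kb$hierarchy)
#' @export
unify_dishes <- function(left, right, hierarchy, rename = TRUE, fresh = NULL) {
  if (is.character(left)) left <- parse_dish(left)
  if (is.character(right)) right <- parse_dish(right)
  lv <- term_vars(left)
  fe <- if (is.null(fresh)) .fresh_env(c(lv, term_vars(right))) else fresh
  if (rename) right <- .rename_apart_dish(right, fe)$dish
  rv <- term_vars(right)
  if (length(intersect(lv, rv))) {
    stop("left and right share variable(s): ",
         paste(intersect(lv, rv), collapse = ", "),
         " (use rename = TRUE)", call. = FALSE)
  }
  ltags <- names(left$locations); rtags <- names(right$locations)
  shared <- intersect(ltags, rtags)
  lonly <- setdiff(ltags, rtags); ronly <- setdiff(rtags, ltags)
  if (length(lonly) && is.null(right$dvar)) return(list())
  if (length(ronly) && is.null(left$dvar)) return(list())
  subs <- list(substitution())
  for (tg in shared) {
    nxt <- list()
    for (s in subs) {
      nxt <- c(nxt, .unify_soup(left$locations[[tg]], right$locations[[tg]],
                                hierarchy, s, fe))
    }
    subs <- nxt
    if (length(subs) == 0L) return(list())
  }
  # dish-level surplus locations
  finish <- function(s) {
    dishes <- list()
    lsur <- lapply(right$locations[ronly], apply_subst, s = s)
    rsur <- lapply(left$locations[lonly], apply_subst, s = s)
    if (!is.null(left$dvar) && !is.null(right$dvar)) {
      w <- .fresh(fe)
      dishes[[left$dvar]] <- dish(locations = lsur, dvar = w)
      dishes[[right$dvar]] <- dish(locations = rsur, dvar = w)
    } else if (!is.null(left$dvar)) {
      if (length(lonly)) return(NULL)
      dishes[[left$dvar]] <- dish(locations = lsur)
    } else if (!is.null(right$dvar)) {
      if (length(ronly)) return(NULL)
      dishes[[right$dvar]] <- dish(locations = rsur)
    } else {
      if (length(lonly) || length(ronly)) return(NULL)
    }
    if (length(dishes)) s <- compose_subst(s, substitution(dishes = dishes))
    s
  }
  out <- list()
  for (s in subs) {
    s2 <- finish(s)
    if (!is.null(s2)) out[[length(out) + 1L]] <- s2
  }
  orig <- unique(c(lv, rv))
  keys <- vapply(out, .unifier_key, character(1), orig_vars = orig)
  out[!duplicated(keys)]
}
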