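# Identifier discipline: entity, sort, modification and variable names are
# plain identifiers; location tags likewise. Rule labels are free-form.
.is_ident <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[A-Za-z][A-Za-z0-9._']*$", x) && x != "none"
}

.stop_if_bad_ident <- function(x, what) {
  if (!.is_ident(x)) stop(what, " must be a nonempty identifier, got: ",
                          deparse(x), call. = FALSE)
}

# bytewise (locale-independent) sort, used everywhere order matters
.csort <- function(x) if (length(x)) sort(x, method = "radix") else x
.corder <- function(x) if (length(x)) order(x, method = "radix") else integer(0)

#' Protein/chemical modification marker
#'
#' A modification is a state marker attached to an entity, such as `Yphos`
#' (tyrosine phosphorylation) or `phos(TEY)` (phosphorylation on the TEY
#' motif). Modifications on a term form a set: attaching the same marker
#' twice is the same as attaching it once.
#'
#' @param name Modification name (identifier), e.g. `"Yphos"`.
#' @param arg Optional argument (identifier), e.g. `"TEY"` in `phos(TEY)`.
#' @return An object of class `ss_mod`.
#' @examples
#' modification("Yphos")
#' modification("phos", "TEY")
#' @export
modification <- function(name, arg = NULL) {
  .stop_if_bad_ident(name, "modification name")
  if (!is.null(arg)) .stop_if_bad_ident(arg, "modification argument")
  key <- if (is.null(arg)) name else paste0(name, "(", arg, ")")
  structure(list(name = name, arg = arg, key = key), class = "ss_mod")
}

.mod_keys <- function(mods) vapply(mods, function(m) m$key, character(1))

# normalize a list of ss_mod: dedupe + canonical order
.norm_mods <- function(mods) {
  if (length(mods) == 0L) return(list())
  keys <- .mod_keys(mods)
  mods <- mods[!duplicated(keys)]
  mods[.corder(.mod_keys(mods))]
}

# coerce "Yphos" / "phos(TEY)" strings or ss_mod objects
.as_mod <- function(m) {
  if (inherits(m, "ss_mod")) return(m)
  if (is.character(m) && length(m) == 1L) {
    hit <- regmatches(m, regexec("^([A-Za-z][A-Za-z0-9._']*)\\(([A-Za-z][A-Za-z0-9._']*)\\)$", m))[[1]]
    if (length(hit) == 3L) return(modification(hit[2L], hit[3L]))
    return(modification(m))
  }
  stop("cannot interpret modification: ", deparse(m), call. = FALSE)
}

.new_term <- function(kind, fields, key) {
  structure(c(list(kind = kind), fields, list(key = key)), class = "ss_term")
}

#' Terms: entities, modified entities, complexes, element variables
#'
#' Terms are the members of soups. `entity()` builds a basic entity such as
#' `Egf`; `modified()` an entity carrying a set of modifications, printed
#' `[EgfR - Yphos]`; `complex_term()` an association of two or more bound
#' terms, printed `(a : b)` — binding is associative and commutative, so
#' complexes are flat multisets of components; `term_var()` an element
#' variable carrying one or more sort constraints (a binding must satisfy
#' all of them).
#'
#' The base of a `modified()` term may itself be an element variable (the
#' `[gab:GabS - Yphos]` idiom: "a GabS protein, tyrosine-phosphorylated");
#' such a base variable only ever binds a bare entity.
#'
#' @param name Entity name (identifier).
#' @param mods Modifications: character vector and/or list of [modification()].
#' @param base For `modified()`: entity name or a `term_var()`.
#' @param ... For `complex_term()`: two or more terms (or a single list).
#' @param sorts For `term_var()`: character vector of sort names.
#' @return An object of class `ss_term`.
#' @examples
#' entity("Egf")
#' modified("EgfR", "Yphos")
#' complex_term(modified("EgfR", "Yphos"), entity("Egf"))
#' term_var("gab", "GabS")
#' modified(term_var("gab", "GabS"), "Yphos")
#' @export
entity <- function(name) {
  .stop_if_bad_ident(name, "entity name")
  .new_term("entity", list(name = name), name)
}

#' @rdname entity
#' @export
term_var <- function(name, sorts = "Things") {
  .stop_if_bad_ident(name, "variable name")
  stopifnot(is.character(sorts), length(sorts) >= 1L)
  for (s in sorts) .stop_if_bad_ident(s, "sort name")
  sorts <- .csort(unique(sorts))
  if (length(sorts) > 1L) sorts <- setdiff(sorts, "Things")  # Things is vacuous in a meet
  key <- paste0("?", name, ":", paste(sorts, collapse = "&"))
  .new_term("var", list(var = name, sorts = sorts), key)
}

#' @rdname entity
#' @export
modified <- function(base, mods) {
  if (is.character(base)) {
    .stop_if_bad_ident(base, "entity name")
    base_t <- NULL
    base_name <- base
  } else if (inherits(base, "ss_term") && base$kind == "var") {
    base_t <- base
    base_name <- NULL
  } else {
    stop("modified() base must be an entity name or an element variable", call. = FALSE)
  }
  mods <- .norm_mods(lapply(as.list(mods), .as_mod))
  if (length(mods) == 0L) {
    if (is.null(base_t)) return(entity(base_name))
    return(base_t)
  }
  base_key <- if (is.null(base_t)) base_name else base_t$key
  key <- paste0("[", base_key, " - ", paste(.mod_keys(mods), collapse = " "), "]")
  .new_term("modified", list(name = base_name, base_var = base_t, mods = mods), key)
}

#' @rdname entity
#' @export
complex_term <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1L]]) && !inherits(comps[[1L]], "ss_term")) {
    comps <- comps[[1L]]
  }
  flat <- list()
  for (cmp in comps) {
    if (!inherits(cmp, "ss_term")) stop("complex components must be terms", call. = FALSE)
    if (cmp$kind == "complex") flat <- c(flat, cmp$components) else flat <- c(flat, list(cmp))
  }
  if (length(flat) < 2L) stop("a complex needs at least 2 components", call. = FALSE)
  flat <- flat[.corder(vapply(flat, function(t) t$key, character(1)))]
  key <- paste0("(", paste(vapply(flat, function(t) t$key, character(1)),
                           collapse = " : "), ")")
  .new_term("complex", list(components = flat), key)
}

.term_keys <- function(terms) vapply(terms, function(t) t$key, character(1))

#' Soups: unordered multisets of terms
#'
#' A soup is the content of one location: a multiset of terms, optionally
#' extended by one collection variable of sort `Things` (a "soup variable")
#' standing for an arbitrary further sub-soup. Two soups with the same
#' element counts are equal regardless of construction order. The empty
#' soup prints as `none` and is the multiset identity.
#'
#' @param ... Terms (or a single list of terms).
#' @param svar Optional soup-variable name (at most one per soup).
#' @return An object of class `ss_soup`.
#' @examples
#' soup(entity("Egf"), entity("Erbb2"))
#' soup(svar = "xout")                  # pure collection variable
#' empty_soup()
#' @export
soup <- function(..., svar = NULL) {
  elems <- list(...)
  if (length(elems) == 1L && is.list(elems[[1L]]) && !inherits(elems[[1L]], "ss_term")) {
    elems <- elems[[1L]]
  }
  for (e in elems) if (!inherits(e, "ss_term")) {
    stop("soup elements must be terms", call. = FALSE)
  }
  if (!is.null(svar)) .stop_if_bad_ident(svar, "soup variable name")
  elems <- elems[.corder(.term_keys(elems))]
  ekeys <- .term_keys(elems)
  key <- if (length(elems) == 0L && is.null(svar)) {
    "none"
  } else {
    paste(c(ekeys, if (!is.null(svar)) paste0("?", svar, ":Things")), collapse = " ")
  }
  structure(list(elements = elems, svar = svar, key = key), class = "ss_soup")
}

#' @rdname soup
#' @export
empty_soup <- function() soup()

# soup union (elements concatenated, svar from whichever has one; both having
# one is an internal error except when identical)
.soup_union <- function(a, b) {
  sv <- a$svar
  if (!is.null(b$svar)) {
    if (!is.null(sv) && !identical(sv, b$svar)) {
      stop("internal: union of two soups with distinct soup variables", call. = FALSE)
    }
    sv <- b$svar
  }
  soup(c(a$elements, b$elements), svar = sv)
}

#' Dishes: the global system state
#'
#' A dish maps location tags (e.g. `XOut`, `CLm`, `NUc`) to soups. A ground
#' dish — one without variables of any kind — is a concrete system state; a
#' dish with variables is a pattern. A dish pattern may carry one dish-level
#' variable standing for further, unnamed locations.
#'
#' @param ... Named soups, one per location tag.
#' @param locations Alternatively, a named list of soups.
#' @param dvar Optional dish-variable name.
#' @return An object of class `ss_dish`.
#' @examples
#' dish(XOut = soup(entity("Egf")), EgfRC = soup(entity("EgfR")))
#' @export
dish <- function(..., locations = NULL, dvar = NULL) {
  locs <- if (is.null(locations)) list(...) else locations
  if (length(locs)) {
    tags <- names(locs)
    if (is.null(tags) || any(tags == "")) stop("every location needs a tag", call. = FALSE)
    if (anyDuplicated(tags)) stop("duplicate location tags", call. = FALSE)
    for (tg in tags) .stop_if_bad_ident(tg, "location tag")
    for (sp in locs) if (!inherits(sp, "ss_soup")) {
      stop("location contents must be soups", call. = FALSE)
    }
    locs <- locs[.csort(tags)]
  }
  if (!is.null(dvar)) .stop_if_bad_ident(dvar, "dish variable name")
  key <- if (length(locs) == 0L && is.null(dvar)) {
    "{}"
  } else {
    paste(c(vapply(names(locs), function(tg) paste0("{", tg, " | ", locs[[tg]]$key, "}"),
                   character(1)),
            if (!is.null(dvar)) paste0("?", dvar, ":Dish")),
          collapse = " ")
  }
  structure(list(locations = locs, dvar = dvar, key = key), class = "ss_dish")
}

#' Canonical string form
#'
#' Every term, soup and dish carries a canonical string computed at
#' construction: two objects equal up to soup/complex permutation have the
#' identical string, and the string parses back (see [parse_dish()]) to an
#' equal object. Used as the multiset/dedup key throughout the engines.
#'
#' @param x A term, soup, dish, rule or substitution.
#' @return A character scalar.
#' @examples
#' canonical(soup(entity("Egf"), entity("Erbb2")))
#' canonical(soup(entity("Erbb2"), entity("Egf")))  # identical
#' @export
canonical <- function(x) {
  if (!is.null(x$key)) return(x$key)
  stop("no canonical form for this object", call. = FALSE)
}

#' Groundness test
#'
#' A dish (or soup, or term) is ground when no variable of any kind —
#' element, soup or dish level — occurs in it. Forward rewriting starts from
#' ground dishes; backward narrowing starts from patterns.
#'
#' @param x A term, soup or dish.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_ground(dish(XOut = soup(entity("Egf"))))
#' is_ground(dish(XOut = soup(svar = "xout")))
#' @export
is_ground <- function(x) {
  UseMethod("is_ground")
}

#' @export
is_ground.ss_term <- function(x) {
  switch(x$kind,
    entity = TRUE,
    var = FALSE,
    modified = is.null(x$base_var),
    complex = all(vapply(x$components, is_ground, logical(1)))
  )
}

#' @export
is_ground.ss_soup <- function(x) {
  is.null(x$svar) && all(vapply(x$elements, is_ground, logical(1)))
}

#' @export
is_ground.ss_dish <- function(x) {
  is.null(x$dvar) && all(vapply(x$locations, is_ground, logical(1)))
}

# all variable names occurring in an object, by kind
term_vars <- function(x) {
  UseMethod("term_vars")
}

#' @export
term_vars.ss_term <- function(x) {
  switch(x$kind,
    entity = character(0),
    var = x$var,
    modified = if (is.null(x$base_var)) character(0) else x$base_var$var,
    complex = unique(unlist(lapply(x$components, term_vars)))
  )
}

#' @export
term_vars.ss_soup <- function(x) {
  unique(c(unlist(lapply(x$elements, term_vars)), x$svar))
}

#' @export
term_vars.ss_dish <- function(x) {
  unique(c(unlist(lapply(x$locations, term_vars)), x$dvar))
}

# counts of element keys in a soup (named integer vector) plus key->term map
.soup_counts <- function(s) {
  ks <- .term_keys(s$elements)
  if (length(ks) == 0L) return(integer(0))
  tab <- table(ks)
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt
}

#' @export
format.ss_mod <- function(x, ...) x$key
#' @export
format.ss_term <- function(x, ...) x$key
#' @export
format.ss_soup <- function(x, ...) x$key
#' @export
format.ss_dish <- function(x, ...) x$key
#' @export
print.ss_term <- function(x, ...) { cat(x$key, "\n"); invisible(x) }
#' @export
print.ss_soup <- function(x, ...) { cat(x$key, "\n"); invisible(x) }
#' @export
print.ss_dish <- function(x, ...) { cat(x$key, "\n"); invisible(x) }
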