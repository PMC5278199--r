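#' Rewrite rules
#'
#' A rule is a labeled transition between dish patterns modeling one
#' reaction: whenever the left-hand side matches (a part of) the current
#' dish, it may be replaced by the right-hand side. Modifiers — enzymes and
#' controls required but unchanged by the reaction — are written identically
#' on both sides. `conditions` lists extra sort-membership tests
#' `(variable, sort)`; they are merged into the variables' sort annotations,
#' so a condition is equivalent to strengthening the variable's sort.
#'
#' Invariants enforced: every variable of the right-hand side occurs on the
#' left (no invention of matter); both sides mention the same location tags;
#' condition variables occur on the left.
#'
#' @param label Rule label (free-form, unique within a knowledge base).
#' @param lhs,rhs Dish patterns (`ss_dish` or text parsed by [parse_dish()]).
#' @param conditions List of `list(var = , sort = )` membership tests.
#' @param source Optional free-text provenance note.
#' @return An object of class `ss_rule`.
#' @examples
#' rw_rule("001.EgfR.irt.Egf",
#'   "{XOut | Egf ?xout:Things} {EgfRC | EgfR ?egfrc:Things}",
#'   "{XOut | ?xout:Things} {EgfRC | ([EgfR - Yphos] : Egf) ?egfrc:Things}")
#' @export
rw_rule <- function(label, lhs, rhs, conditions = list(), source = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label), !grepl("\\s", label))
  if (is.character(lhs)) lhs <- parse_dish(lhs)
  if (is.character(rhs)) rhs <- parse_dish(rhs)
  stopifnot(inherits(lhs, "ss_dish"), inherits(rhs, "ss_dish"))
  for (cond in conditions) {
    if (!is.list(cond) || is.null(cond$var) || is.null(cond$sort)) {
      stop("conditions must be lists with fields 'var' and 'sort'", call. = FALSE)
    }
  }
  lv <- .collect_vars(lhs)
  rv <- .collect_vars(rhs)
  bad <- setdiff(c(rv$elem, rv$soup, rv$dish), c(lv$elem, lv$soup, lv$dish))
  if (length(bad)) {
    stop("rule ", label, ": right-hand side invents variable(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(lhs$locations), names(rhs$locations))) {
    stop("rule ", label, ": LHS and RHS must mention the same location tags",
         call. = FALSE)
  }
  cvars <- vapply(conditions, function(cd) cd$var, character(1))
  if (length(cvars) && !all(cvars %in% lv$elem)) {
    stop("rule ", label, ": condition variable(s) not on the LHS: ",
         paste(setdiff(cvars, lv$elem), collapse = ", "), call. = FALSE)
  }
  # fold conditions into the variables' sort annotations
  if (length(conditions)) {
    strengthen <- list()
    for (cd in conditions) {
      old <- lv$sorts[[cd$var]]
      strengthen[[cd$var]] <- term_var(cd$var, unique(c(old, cd$sort)))
    }
    s <- substitution(terms = strengthen)
    lhs <- apply_subst(lhs, s)
    rhs <- apply_subst(rhs, s)
  }
  structure(list(label = label, lhs = lhs, rhs = rhs, conditions = conditions,
                 source = source,
                 key = paste0("rl [", label, "]: ", lhs$key, " => ", rhs$key)),
            class = "ss_rule")
}

#' @export
print.ss_rule <- function(x, ...) { cat(x$key, "\n"); invisible(x) }

#' @export
format.ss_rule <- function(x, ...) x$key

#' Knowledge bases
#'
#' A knowledge base bundles the rewrite rules, the sort hierarchy, the
#' entity vocabulary (each entity with its principal sort), and named
#' initial dishes. [validate_kb()] checks the whole-KB invariants: unique
#' labels, declared entities and sorts everywhere, acyclic subsort graph,
#' and per-rule well-formedness.
#'
#' @param rules List of [rw_rule()] objects.
#' @param sorts Named list of sort memberships (see [sort_hierarchy()]).
#' @param entities Named character vector: entity name -> principal sort
#'   (use `"Things"` for entities with no finer sort).
#' @param dishes Named list of `ss_dish` initial states.
#' @return An object of class `ss_kb`.
#' @export
knowledge_base <- function(rules = list(), sorts = list(), entities = character(0),
                           dishes = list()) {
  if (length(entities)) {
    if (is.null(names(entities)) || any(names(entities) == "")) {
      stop("entities must be a named character vector (entity -> principal sort)",
           call. = FALSE)
    }
    entities <- entities[.csort(names(entities))]
  }
  # principal sorts feed the hierarchy as extra memberships
  members <- lapply(sorts, as.character)
  for (en in names(entities)) {
    srt <- entities[[en]]
    if (!identical(srt, "Things")) {
      members[[srt]] <- unique(c(members[[srt]], en))
    }
  }
  h <- sort_hierarchy(members, entities = names(entities))
  labels <- vapply(rules, function(r) r$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate rule labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  }
  names(rules) <- labels
  rules <- rules[.corder(labels)]
  if (length(dishes)) {
    if (is.null(names(dishes)) || any(names(dishes) == "")) {
      stop("dishes must be named", call. = FALSE)
    }
    dishes <- dishes[.csort(names(dishes))]
  }
  kb <- structure(list(rules = rules, hierarchy = h, entities = entities,
                       dishes = dishes), class = "ss_kb")
  validate_kb(kb)
  kb
}

#' @export
print.ss_kb <- function(x, ...) {
  cat("Knowledge base:", length(x$rules), "rule(s),",
      length(x$entities), "entities,",
      length(x$dishes), "dish(es)\n")
  for (r in x$rules) cat("  ", r$label, "\n")
  invisible(x)
}

# entity names occurring in an object (base names of terms, recursively)
.entity_names <- function(x) {
  if (inherits(x, "ss_dish")) {
    return(unique(unlist(lapply(x$locations, .entity_names))))
  }
  if (inherits(x, "ss_soup")) {
    return(unique(unlist(lapply(x$elements, .entity_names))))
  }
  switch(x$kind,
    entity = x$name,
    var = character(0),
    modified = if (is.null(x$name)) character(0) else x$name,
    complex = unique(unlist(lapply(x$components, .entity_names)))
  )
}

#' Validate a knowledge base
#'
#' Checks all structural invariants and signals an error naming the
#' offending rule, dish or entity. Returns the KB invisibly when valid.
#'
#' @param kb An `ss_kb`.
#' @return `kb`, invisibly.
#' @export
validate_kb <- function(kb) {
  h <- kb$hierarchy
  declared <- names(kb$entities)
  known_sorts <- sort_names(h)
  check_entities <- function(x, where) {
    missing <- setdiff(.entity_names(x), declared)
    if (length(missing)) {
      stop("undeclared entit", if (length(missing) > 1L) "ies" else "y",
           " in ", where, ": ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  check_var_sorts <- function(d, where) {
    vs <- .collect_vars(d)
    for (v in vs$elem) {
      bad <- setdiff(vs$sorts[[v]], known_sorts)
      if (length(bad)) {
        stop("unknown sort(s) ", paste(bad, collapse = ", "),
             " on variable '", v, "' in ", where, call. = FALSE)
      }
    }
  }
  for (srt in names(h$members)) {
    flat <- setdiff(h$members[[srt]], names(h$members))
    missing <- setdiff(flat, declared)
    if (length(missing)) {
      stop("sort ", srt, " lists undeclared entity(ies): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  for (r in kb$rules) {
    where <- paste0("rule ", r$label)
    check_entities(r$lhs, where); check_entities(r$rhs, where)
    check_var_sorts(r$lhs, where); check_var_sorts(r$rhs, where)
    for (cd in r$conditions) {
      if (!(cd$sort %in% known_sorts)) {
        stop("unknown sort ", cd$sort, " in condition of ", where, call. = FALSE)
      }
    }
  }
  for (dn in names(kb$dishes)) {
    check_entities(kb$dishes[[dn]], paste0("dish ", dn))
    check_var_sorts(kb$dishes[[dn]], paste0("dish ", dn))
  }
  invisible(kb)
}

#' Knowledge-base fingerprint
#'
#' A stable digest of the rule set, used to detect that a search solution
#' was produced against a different (stale) KB.
#'
#' @param kb An `ss_kb`.
#' @return Character scalar.
#' @export
kb_fingerprint <- function(kb) {
  paste(vapply(kb$rules, function(r) r$key, character(1)), collapse = "\n")
}

# ---- JSON serialization -----------------------------------------------------

.term_to_json <- function(t) {
  switch(t$kind,
    entity = list(kind = "entity", name = t$name),
    var = list(kind = "var", name = t$var, sorts = as.list(t$sorts)),
    modified = {
      base <- if (is.null(t$name)) .term_to_json(t$base_var) else
        list(kind = "entity", name = t$name)
      list(kind = "modified", base = base,
           mods = lapply(t$mods, function(m) {
             if (is.null(m$arg)) list(name = m$name) else list(name = m$name, arg = m$arg)
           }))
    },
    complex = list(kind = "complex", components = lapply(t$components, .term_to_json))
  )
}

.term_from_json <- function(j) {
  switch(j$kind,
    entity = entity(j$name),
    var = term_var(j$name, unlist(j$sorts)),
    modified = {
      base <- .term_from_json(j$base)
      base <- if (base$kind == "entity") base$name else base
      modified(base, lapply(j$mods, function(m) modification(m$name, m$arg)))
    },
    complex = complex_term(lapply(j$components, .term_from_json)),
    stop("unknown term kind in JSON: ", j$kind, call. = FALSE)
  )
}

.soup_to_json <- function(s) {
  list(elements = lapply(s$elements, .term_to_json),
       var = if (is.null(s$svar)) NULL else s$svar)
}

.soup_from_json <- function(j) {
  soup(lapply(j$elements, .term_from_json), svar = j$var)
}

.dish_to_json <- function(d) {
  list(locations = lapply(d$locations, .soup_to_json),
       var = if (is.null(d$dvar)) NULL else d$dvar)
}

.dish_from_json <- function(j) {
  locs <- lapply(j$locations, .soup_from_json)
  dish(locations = locs, dvar = j$var)
}

#' Read and write knowledge bases as JSON
#'
#' The on-disk format is a versioned JSON object:
#' `{"version": 1, "sorts": {...}, "entities": {...}, "rules": [...],
#' "dishes": {...}}` with dishes in the nested
#' `{"locations": {...}, "var": ...}` form. `load_kb()` accepts a file path
#' or a JSON string and validates the result; `save_kb()` writes
#' deterministically (fixed key order), so saving the same KB twice gives
#' byte-identical files.
#'
#' @param x A file path or JSON text.
#' @param kb An `ss_kb`.
#' @param path Output file path; `NULL` returns the JSON text.
#' @return `load_kb()`: an `ss_kb`. `save_kb()`: the JSON text, invisibly.
#' @export
load_kb <- function(x) {
  txt <- if (grepl("^\\s*\\{", x)) {
    x
  } else {
    if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
    paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  j <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                error = function(e) stop("KB parse error: ", conditionMessage(e),
                                         call. = FALSE))
  if (is.null(j$version) || j$version != 1) {
    stop("unsupported KB schema version: ", deparse(j$version), call. = FALSE)
  }
  entities <- vapply(j$entities, function(s) as.character(s), character(1))
  rules <- lapply(j$rules, function(rj) {
    rw_rule(rj$label, .dish_from_json(rj$lhs), .dish_from_json(rj$rhs),
            conditions = lapply(rj$conditions, function(cd) {
              list(var = cd$var, sort = cd$sort)
            }),
            source = rj$source)
  })
  dishes <- lapply(j$dishes, .dish_from_json)
  knowledge_base(rules = rules,
                 sorts = lapply(j$sorts, function(m) unlist(m, use.names = FALSE)),
                 entities = entities, dishes = dishes)
}

#' @rdname load_kb
#' @export
save_kb <- function(kb, path = NULL) {
  obj <- list(
    version = 1L,
    sorts = lapply(kb$hierarchy$members, as.list),
    entities = as.list(kb$entities),
    rules = lapply(unname(kb$rules), function(r) {
      out <- list(label = r$label, lhs = .dish_to_json(r$lhs),
                  rhs = .dish_to_json(r$rhs),
                  conditions = lapply(r$conditions, function(cd) {
                    list(var = cd$var, sort = cd$sort)
                  }))
      if (!is.null(r$source)) out$source <- r$source
      out
    }),
    dishes = lapply(kb$dishes, .dish_to_json)
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
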