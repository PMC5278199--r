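#' Sort hierarchies
#'
#' Rule-based signaling models type their variables with sorts: named,
#' possibly nested collections of entities, e.g. `GabS = {Gab1, Gab2}` or
#' `ErkS` below `BProtein`. A hierarchy is a mapping from each sort to its
#' members, where a member is either an entity name or another (sub)sort
#' name; the subsort graph must be acyclic. The distinguished top sort
#' `Things` contains every term (including complexes) and is always present
#' implicitly — it is the sort of soup variables.
#'
#' @param members Named list: sort name -> character vector of members
#'   (entity names and/or other sort names).
#' @param entities Character vector of all declared entity names (the
#'   universe; used to resolve which member names are entities).
#' @return An object of class `ss_sorts`.
#' @examples
#' h <- sort_hierarchy(
#'   list(BProtein = c("Egf", "ErkS"), ErkS = "Erks"),
#'   entities = c("Egf", "Erks")
#' )
#' sort_member(entity("Erks"), "BProtein", h)
#' @export
sort_hierarchy <- function(members = list(), entities = character(0)) {
  if (length(members)) {
    if (is.null(names(members)) || any(names(members) == "")) {
      stop("sort memberships must be named by sort", call. = FALSE)
    }
    members <- lapply(members, as.character)
    members <- members[.csort(names(members))]
  }
  if ("Things" %in% names(members)) {
    stop("'Things' is the implicit top sort and cannot be redefined", call. = FALSE)
  }
  h <- structure(list(members = members, entities = .csort(unique(as.character(entities))),
                      closures = new.env(parent = emptyenv())),
                 class = "ss_sorts")
  .check_acyclic(h)
  h
}

.check_acyclic <- function(h) {
  state <- new.env(parent = emptyenv())  # 1 = in progress, 2 = done
  visit <- function(s) {
    st <- state[[s]]
    if (identical(st, 2L)) return(invisible(NULL))
    if (identical(st, 1L)) stop("cyclic subsort graph at sort ", s, call. = FALSE)
    state[[s]] <- 1L
    for (m in h$members[[s]]) if (m %in% names(h$members)) visit(m)
    state[[s]] <- 2L
    invisible(NULL)
  }
  for (s in names(h$members)) visit(s)
  invisible(h)
}

#' @rdname sort_hierarchy
#' @export
sort_names <- function(h) c("Things", names(h$members))

#' Entity closure of a sort
#'
#' All entity names belonging to a sort by transitive closure of the
#' membership relation. `Things` closes over every declared entity.
#'
#' @param sort A sort name.
#' @param h A [sort_hierarchy()].
#' @return Character vector of entity names.
#' @export
sort_closure <- function(sort, h) {
  if (identical(sort, "Things")) return(h$entities)
  if (!(sort %in% names(h$members))) stop("unknown sort: ", sort, call. = FALSE)
  memo <- h$closures[[sort]]
  if (!is.null(memo)) return(memo)
  out <- character(0)
  for (m in h$members[[sort]]) {
    if (m %in% names(h$members)) out <- c(out, sort_closure(m, h)) else out <- c(out, m)
  }
  out <- .csort(unique(out))
  h$closures[[sort]] <- out
  out
}

# entity closure of a conjunction of sorts (intersection); NULL marks "all of
# Things", i.e. no entity restriction and complexes admitted
.sorts_closure <- function(sorts, h) {
  sorts <- setdiff(sorts, "Things")
  if (length(sorts) == 0L) return(NULL)
  out <- sort_closure(sorts[[1L]], h)
  for (s in sorts[-1L]) out <- intersect(out, sort_closure(s, h))
  out
}

#' @rdname sort_member
#' @export
sorts_satisfiable <- function(sorts, h) {
  cl <- .sorts_closure(sorts, h)
  is.null(cl) || length(cl) > 0L
}

#' Sort membership test
#'
#' Decides whether a term belongs to a sort: any term belongs to `Things`;
#' an entity or modified entity belongs to a sort iff its base entity name
#' is in the sort's entity closure; a complex belongs only to `Things`. For
#' a variable term the test is entailment: every possible instance of the
#' variable must lie in the sort.
#'
#' @param t An `ss_term`.
#' @param sort A declared sort name.
#' @param h A [sort_hierarchy()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' h <- sort_hierarchy(list(GabS = c("Gab1", "Gab2")), entities = c("Gab1", "Gab2", "Egf"))
#' sort_member(entity("Gab1"), "GabS", h)
#' sort_member(entity("Egf"), "GabS", h)
#' @export
sort_member <- function(t, sort, h) {
  if (identical(sort, "Things")) return(TRUE)
  if (!(sort %in% names(h$members))) stop("unknown sort: ", sort, call. = FALSE)
  cl <- sort_closure(sort, h)
  switch(t$kind,
    entity = t$name %in% cl,
    modified = {
      if (is.null(t$name)) {
        # variable base: entailment on the base variable's sorts
        bcl <- .sorts_closure(t$base_var$sorts, h)
        if (is.null(bcl)) FALSE else all(bcl %in% cl)
      } else {
        t$name %in% cl
      }
    },
    complex = FALSE,
    var = {
      vcl <- .sorts_closure(t$sorts, h)
      if (is.null(vcl)) FALSE else all(vcl %in% cl)
    }
  )
}
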