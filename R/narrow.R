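# Backward narrowing: topify rules, unify goals with rule right-hand sides,
# emit instantiated left-hand sides as most-general initial patterns.

#' Topify a rule
#'
#' Narrowing requires rules to apply at the top of the whole state term.
#' Topification adds (a) a fresh soup extension variable to both sides of
#' every location the rule mentions that does not already have one, and
#' (b) a fresh dish-level extension variable to both sides covering the
#' locations the rule does not mention. Ground rewriting with the topified
#' rule yields exactly the original transition relation; the operation is
#' idempotent up to variable renaming.
#'
#' @param rule An [rw_rule()].
#' @param kb The knowledge base (supplies variable names already in use).
#' @return A topified `ss_rule`.
#' @examples
#' kb <- egf_fixture()
#' topify(kb$rules[["001.EgfR.irt.Egf"]], kb)
#' @export
topify <- function(rule, kb = NULL) {
  used <- unique(c(term_vars(rule$lhs), term_vars(rule$rhs)))
  fe <- .fresh_env(used)
  lloc <- rule$lhs$locations
  rloc <- rule$rhs$locations
  for (tg in names(lloc)) {
    if (is.null(lloc[[tg]]$svar)) {
      sv <- .fresh(fe, "ext")
      lloc[[tg]] <- soup(lloc[[tg]]$elements, svar = sv)
      if (is.null(rloc[[tg]]$svar)) {
        rloc[[tg]] <- soup(rloc[[tg]]$elements, svar = sv)
      }
    }
  }
  ldv <- rule$lhs$dvar
  rdv <- rule$rhs$dvar
  if (is.null(ldv)) {
    dv <- .fresh(fe, "dext")
    ldv <- dv
    if (is.null(rdv)) rdv <- dv
  }
  rw_rule(rule$label,
          dish(locations = lloc, dvar = ldv),
          dish(locations = rloc, dvar = if (is.null(rdv)) ldv else rdv),
          conditions = rule$conditions, source = rule$source)
}

# rename all variables of a rule (consistently across lhs/rhs) to fresh names
.rename_apart_rule <- function(rule, fe) {
  lv <- .collect_vars(rule$lhs)
  rv <- .collect_vars(rule$rhs)
  terms <- list(); soups <- list(); dishes <- list()
  for (v in unique(c(lv$elem, rv$elem))) {
    srt <- if (!is.null(lv$sorts[[v]])) lv$sorts[[v]] else rv$sorts[[v]]
    terms[[v]] <- term_var(.fresh(fe), srt)
  }
  for (v in unique(c(lv$soup, rv$soup))) soups[[v]] <- soup(svar = .fresh(fe))
  for (v in unique(c(lv$dish, rv$dish))) dishes[[v]] <- dish(dvar = .fresh(fe))
  s <- substitution(terms = terms, soups = soups, dishes = dishes)
  list(lhs = apply_subst(rule$lhs, s), rhs = apply_subst(rule$rhs, s))
}

.new_backward_solution <- function(pattern, acc, path, depth, fp) {
  structure(list(initial_pattern = pattern, accumulated_substitution = acc,
                 rule_path = path, depth = depth, kb_fingerprint = fp),
            class = "ss_backward_solution")
}

#' @export
print.ss_backward_solution <- function(x, ...) {
  cat("Backward solution at depth", x$depth, "\n")
  cat("  initial pattern:", x$initial_pattern$key, "\n")
  cat("  rule path: ",
      if (length(x$rule_path)) paste(x$rule_path, collapse = " -> ") else "(none)", "\n")
  cat("  substitution:",
      if (subst_is_empty(x$accumulated_substitution)) "(identity)"
      else x$accumulated_substitution$key, "\n")
  invisible(x)
}

# restrict a substitution to a set of variable names
.restrict_subst <- function(s, vars) {
  substitution(terms = s$terms[intersect(names(s$terms), vars)],
               soups = s$soups[intersect(names(s$soups), vars)],
               dishes = s$dishes[intersect(names(s$dishes), vars)])
}

#' Backward narrowing search
#'
#' Searches for the most-general initial dish patterns from which the goal
#' pattern is reachable: each backward step unifies the current subgoal
#' with the right-hand side of a topified rule (renamed apart) and emits
#' the correspondingly instantiated left-hand side as a new, more-initial
#' pattern. Narrowing assigns values to variables, so — unlike forward
#' rewriting — the search works from symbolic states and returns, with each
#' pattern, the accumulated substitution for the goal's variables and the
#' rule path in forward application order.
#'
#' Solutions are enumerated by nondecreasing depth; the depth-0 identity
#' solution (the goal itself, reached by applying no rule) always comes
#' first. Rules are tried in lexicographic label order and unifiers in
#' their deterministic order, so solution numbering is reproducible.
#' Subgoal patterns already seen (up to variable renaming) are not
#' re-expanded. The goal's location set is taken literally: add a dish
#' variable (`?r:Dish`) to the goal to leave further locations open.
#'
#' @param kb An `ss_kb`.
#' @param goal A dish pattern (`ss_dish` or text); usually contains
#'   variables.
#' @param conditions Sort-membership tests `list(var =, sort =)` on goal
#'   variables.
#' @param max_depth Maximum number of backward steps.
#' @param max_solutions Stop after this many solutions.
#' @param subsume If `TRUE`, drop solutions whose initial pattern is a
#'   strict instance of an earlier solution's pattern (see [instance_of()]).
#' @return An object of class `ss_backward` with fields `solutions`,
#'   `status` (`"completed"` or `"truncated"` when `max_depth` cut branches
#'   off), and `goal`.
#' @examples
#' kb <- vending_fixture()
#' res <- backward_search(kb, "{VM | apple ?rest:Things}", max_depth = 2)
#' solutions_df(res)
#' @export
backward_search <- function(kb, goal, conditions = list(), max_depth = 3L,
                            max_solutions = Inf, subsume = FALSE) {
  if (is.character(goal)) goal <- parse_dish(goal)
  h <- kb$hierarchy
  fp <- kb_fingerprint(kb)
  gv <- .collect_vars(goal)
  if (length(conditions)) {
    strengthen <- list()
    for (cd in conditions) {
      if (!(cd$var %in% gv$elem)) {
        stop("condition variable '", cd$var, "' does not occur in the goal",
             call. = FALSE)
      }
      if (!sorts_satisfiable(unique(c(gv$sorts[[cd$var]], cd$sort)), h)) {
        stop("unsatisfiable sort conditions on goal variable '", cd$var, "'",
             call. = FALSE)
      }
      strengthen[[cd$var]] <- term_var(cd$var, unique(c(gv$sorts[[cd$var]], cd$sort)))
    }
    goal <- apply_subst(goal, substitution(terms = strengthen))
  }
  goal_vars <- term_vars(goal)
  fe <- .fresh_env(c(goal_vars, unlist(lapply(kb$rules, function(r) {
    c(term_vars(r$lhs), term_vars(r$rhs))
  }))))
  topified <- lapply(kb$rules, topify, kb = kb)
  labels <- .csort(names(kb$rules))

  seen <- new.env(parent = emptyenv())
  seen[[.rename_canonical(goal)]] <- TRUE
  queue <- list(list(pattern = goal, acc = substitution(), path = character(0),
                     depth = 0L))
  solutions <- list()
  status <- "completed"
  qi <- 1L
  while (qi <= length(queue)) {
    node <- queue[[qi]]; qi <- qi + 1L
    sol <- .new_backward_solution(node$pattern,
                                  .restrict_subst(node$acc, goal_vars),
                                  node$path, node$depth, fp)
    keep <- TRUE
    if (subsume && length(solutions)) {
      for (prev in solutions) {
        if (prev$depth <= node$depth &&
            instance_of(prev$initial_pattern, node$pattern, h) &&
            !instance_of(node$pattern, prev$initial_pattern, h)) {
          keep <- FALSE
          break
        }
      }
    }
    if (keep) solutions[[length(solutions) + 1L]] <- sol
    if (length(solutions) >= max_solutions) break
    if (node$depth >= max_depth) { status <- "truncated"; next }
    for (lb in labels) {
      rr <- .rename_apart_rule(topified[[lb]], fe)
      for (u in unify_dishes(rr$rhs, node$pattern, h, rename = FALSE, fresh = fe)) {
        new_pattern <- apply_subst(rr$lhs, u)
        k <- .rename_canonical(new_pattern)
        if (!is.null(seen[[k]])) next
        seen[[k]] <- TRUE
        queue[[length(queue) + 1L]] <-
          list(pattern = new_pattern, acc = compose_subst(node$acc, u),
               path = c(lb, node$path), depth = node$depth + 1L)
      }
    }
  }
  structure(list(solutions = solutions, status = status, goal = goal,
                 max_depth = max_depth),
            class = "ss_backward")
}

#' @export
print.ss_backward <- function(x, ...) {
  cat("Backward narrowing search:", length(x$solutions), "solution(s),",
      x$status, "\n")
  for (i in seq_along(x$solutions)) {
    cat("-- solution", i, "--\n")
    print(x$solutions[[i]])
  }
  invisible(x)
}

# one deterministic grounding of a pattern's variables over the KB's entities
.grounding_for <- function(vars, sorts, soupv, dishv, h) {
  terms <- list(); soups <- list(); dishes <- list()
  for (v in vars) {
    cl <- .sorts_closure(sorts[[v]], h)
    if (is.null(cl)) cl <- h$entities
    if (length(cl) == 0L) return(NULL)  # unsatisfiable sorts: no ground instance
    terms[[v]] <- entity(cl[[1L]])
  }
  for (v in soupv) soups[[v]] <- empty_soup()
  for (v in dishv) dishes[[v]] <- dish()
  substitution(terms = terms, soups = soups, dishes = dishes)
}

#' Validate a backward solution by forward replay
#'
#' Grounds the solution's initial pattern (element variables to the first
#' entity of their sort, soup and dish variables to empty), replays the
#' solution's rule path forward with [apply_rule()], and checks that the
#' correspondingly grounded goal instance is reached in exactly
#' `sol$depth` steps.
#'
#' @param sol An `ss_backward_solution`.
#' @param kb The knowledge base it was computed against.
#' @param goal The goal pattern the backward search started from.
#' @param max_states Cap on the replayed state-set breadth.
#' @return `TRUE` if the replay reaches the goal instance, else `FALSE`.
#' @export
ground_check <- function(sol, kb, goal, max_states = 5000L) {
  if (is.character(goal)) goal <- parse_dish(goal)
  h <- kb$hierarchy
  target_pat <- apply_subst(goal, sol$accumulated_substitution)
  # ground every variable left in either the initial pattern or the target
  combined_vars <- function(d) .collect_vars(d)
  vp <- combined_vars(sol$initial_pattern)
  vt <- combined_vars(target_pat)
  sorts <- vp$sorts
  for (v in names(vt$sorts)) if (is.null(sorts[[v]])) sorts[[v]] <- vt$sorts[[v]]
  theta <- .grounding_for(unique(c(vp$elem, vt$elem)), sorts,
                          unique(c(vp$soup, vt$soup)),
                          unique(c(vp$dish, vt$dish)), h)
  if (is.null(theta)) return(FALSE)
  init <- apply_subst(sol$initial_pattern, theta)
  target <- apply_subst(target_pat, theta)
  if (!is_ground(init) || !is_ground(target)) return(FALSE)
  states <- tryCatch(replay_path(kb, init, sol$rule_path, max_states = max_states),
                     error = function(e) list())
  target$key %in% vapply(states, function(d) d$key, character(1))
}

#' Pattern instance test (subsumption)
#'
#' Tests whether `specific` is a syntactic instance of `general`: whether
#' some substitution of `general`'s variables yields `specific` exactly
#' (modulo soup/complex permutation), with `specific`'s own variables
#' treated as rigid constants. Used by the optional subsumption filter of
#' [backward_search()].
#'
#' @param general,specific Dish patterns.
#' @param hierarchy A [sort_hierarchy()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' kb <- vending_fixture()
#' instance_of("{VM | ?v:Things}", "{VM | apple ?w:Things}", kb$hierarchy)
#' instance_of("{VM | apple ?w:Things}", "{VM | ?v:Things}", kb$hierarchy)
#' @export
instance_of <- function(general, specific, hierarchy) {
  if (is.character(general)) general <- parse_dish(general)
  if (is.character(specific)) specific <- parse_dish(specific)
  vs <- .collect_vars(specific)
  terms <- list(); soups <- list(); dishes <- list()
  members <- hierarchy$members
  entities <- hierarchy$entities
  rigid <- character(0)
  for (v in vs$elem) {
    mk <- paste0("RIGIDELEM.", v)
    terms[[v]] <- entity(mk)
    entities <- c(entities, mk)
    for (srt in setdiff(vs$sorts[[v]], "Things")) {
      members[[srt]] <- c(members[[srt]], mk)
    }
  }
  for (v in vs$soup) {
    mk <- paste0("RIGIDSOUP.", v)
    soups[[v]] <- soup(entity(mk))
    entities <- c(entities, mk)
    rigid <- c(rigid, mk)
  }
  for (v in vs$dish) {
    mk <- paste0("RIGIDDISH.", v)
    dishes[[v]] <- dish(locations = stats::setNames(list(empty_soup()), mk))
  }
  frozen <- apply_subst(specific,
                        substitution(terms = terms, soups = soups, dishes = dishes))
  h2 <- sort_hierarchy(members, entities = entities)
  h2$rigid <- rigid
  length(match_dish(general, frozen, h2)) > 0L
}
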