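#' Search goals
#'
#' A goal for [forward_search()]: a dish pattern (soup variables allowed),
#' optional sort-membership conditions on its element variables, and search
#' bounds. If the pattern has no dish-level variable a fresh one is added,
#' so a goal reads "the state contains these locations' contents" — write a
#' location without a soup variable to pin its full content, and list every
#' location to pin the whole dish. `min_steps = 1` is the default ("at
#' least one rewrite"); set `min_steps = 0` to accept the start state.
#'
#' @param pattern An `ss_dish` pattern or text for [parse_dish()].
#' @param conditions List of `list(var =, sort =)` membership tests on goal
#'   variables (conjunction; merged into the variables' sort annotations).
#' @param max_solutions Stop after this many solutions.
#' @param max_depth Do not search beyond this many rewrite steps.
#' @param min_steps Minimum number of rewrite steps for a solution.
#' @return An object of class `ss_goal`.
#' @examples
#' search_goal("{CLi | (Hras : GTP) ?th:Things}")
#' @export
search_goal <- function(pattern, conditions = list(), max_solutions = Inf,
                        max_depth = Inf, min_steps = 1L) {
  if (is.character(pattern)) pattern <- parse_dish(pattern)
  stopifnot(inherits(pattern, "ss_dish"), max_solutions >= 1, max_depth >= 0,
            min_steps >= 0)
  vs <- .collect_vars(pattern)
  if (length(conditions)) {
    strengthen <- list()
    for (cd in conditions) {
      if (!(cd$var %in% vs$elem)) {
        stop("condition variable '", cd$var, "' does not occur in the goal pattern",
             call. = FALSE)
      }
      strengthen[[cd$var]] <- term_var(cd$var, unique(c(vs$sorts[[cd$var]], cd$sort)))
    }
    pattern <- apply_subst(pattern, substitution(terms = strengthen))
  }
  if (is.null(pattern$dvar)) {
    fe <- .fresh_env(c(vs$elem, vs$soup))
    pattern <- dish(locations = pattern$locations, dvar = .fresh(fe, "rest"))
  }
  structure(list(pattern = pattern, conditions = conditions,
                 max_solutions = max_solutions, max_depth = max_depth,
                 min_steps = min_steps),
            class = "ss_goal")
}

#' Apply a rule to a ground dish
#'
#' Computes every successor state: one per distinct match of the rule's
#' left-hand side against the dish (locations the rule does not mention
#' pass through unchanged; a location the rule mentions but the dish lacks
#' is treated as empty). Successors are ground and returned in the
#' deterministic match order.
#'
#' @param rule An [rw_rule()].
#' @param d A ground `ss_dish`.
#' @param hierarchy A [sort_hierarchy()].
#' @return List of `list(dish = , subst = )`; empty when the rule does not
#'   apply.
#' @examples
#' kb <- egf_fixture()
#' apply_rule(kb$rules[["001.EgfR.irt.Egf"]],
#'            parse_dish("{XOut | Egf} {EgfRC | EgfR}"), kb$hierarchy)
#' @export
apply_rule <- function(rule, d, hierarchy) {
  if (!is_ground(d)) stop("apply_rule needs a ground dish", call. = FALSE)
  tags <- names(rule$lhs$locations)
  sub_locs <- lapply(tags, function(tg) {
    sp <- d$locations[[tg]]
    if (is.null(sp)) empty_soup() else sp
  })
  names(sub_locs) <- tags
  sub <- dish(locations = sub_locs)
  lhs <- rule$lhs
  if (!is.null(lhs$dvar)) {
    # topified rule: the dish variable absorbs the unmentioned locations
    sub <- d
  }
  out <- list()
  for (s in match_dish(lhs, sub, hierarchy)) {
    new_part <- apply_subst(rule$rhs, s)
    if (!is_ground(new_part)) {
      stop("internal: rule ", rule$label, " produced a non-ground successor",
           call. = FALSE)
    }
    locs <- d$locations
    locs[names(new_part$locations)] <- new_part$locations
    if (!is.null(lhs$dvar)) locs <- new_part$locations
    out[[length(out) + 1L]] <- list(dish = dish(locations = locs), subst = s)
  }
  out
}

.new_solution <- function(final_dish, bindings, path, depth, fp) {
  structure(list(final_dish = final_dish, bindings = bindings, path = path,
                 depth = depth, kb_fingerprint = fp),
            class = "ss_solution")
}

#' @export
print.ss_solution <- function(x, ...) {
  cat("Solution at depth", x$depth, "\n")
  cat("  path: ", if (length(x$path)) paste(x$path, collapse = " -> ") else "(none)", "\n")
  cat("  final:", x$final_dish$key, "\n")
  cat("  bindings:", if (subst_is_empty(x$bindings)) "(empty)" else x$bindings$key, "\n")
  invisible(x)
}

#' Forward breadth-first reachability search
#'
#' Explores the state space from a ground start dish by breadth-first
#' rewriting: the frontier is FIFO, rules apply in lexicographic label
#' order, matches of one rule in the deterministic match order, and states
#' already seen (by canonical form) are pruned, so the search terminates on
#' finite state spaces and solution numbering is reproducible. A solution
#' is recorded for every distinct match of the goal pattern against a
#' reached state at an admissible depth; solutions come out in
#' nondecreasing depth.
#'
#' @param kb An `ss_kb`.
#' @param start A ground `ss_dish`, or the name of a dish in `kb$dishes`.
#' @param goal An [search_goal()] (or a pattern accepted by it).
#' @param graph If `TRUE`, also return the explored transition graph.
#' @param max_states Exploration cap; exceeding it marks the run truncated.
#' @return An object of class `ss_search` with fields `solutions` (list of
#'   solutions), `n_states` (states explored), `status`
#'   (`"completed"`/`"truncated"`), and `edges` (a data frame, when
#'   `graph = TRUE`).
#' @examples
#' kb <- vending_fixture()
#' res <- forward_search(kb, "DollarDish", search_goal("{VM | apple ?m:Things}"))
#' res$solutions[[1]]$depth
#' @export
forward_search <- function(kb, start, goal, graph = FALSE, max_states = 10000L) {
  if (is.character(start)) {
    if (!(start %in% names(kb$dishes))) stop("no dish named '", start, "' in KB",
                                             call. = FALSE)
    start <- kb$dishes[[start]]
  }
  if (!inherits(goal, "ss_goal")) goal <- search_goal(goal)
  if (!is_ground(start)) stop("forward search starts from a ground dish", call. = FALSE)
  h <- kb$hierarchy
  fp <- kb_fingerprint(kb)
  labels <- .csort(names(kb$rules))

  states <- new.env(parent = emptyenv())   # expansion dedup, by canonical key
  solved <- new.env(parent = emptyenv())   # states that already yielded solutions
  queue <- list(list(dish = start, depth = 0L, path = character(0)))
  states[[start$key]] <- TRUE
  solutions <- list()
  edges_from <- character(0); edges_to <- character(0); edges_lab <- character(0)
  n_states <- 1L
  status <- "completed"
  qi <- 1L

  # Goal checks happen when a state is *reached* (before revisit pruning), so
  # a state equal to an earlier one — e.g. the start reproduced by a self-loop
  # rewrite — still counts as reached in >= 1 steps. Each state contributes
  # solutions at most once, at its first admissible depth.
  check_state <- function(d, depth, path) {
    if (depth < goal$min_steps || depth > goal$max_depth) return(invisible(NULL))
    if (!is.null(solved[[d$key]])) return(invisible(NULL))
    ms <- match_dish(goal$pattern, d, h)
    if (length(ms)) {
      solved[[d$key]] <- TRUE
      for (m in ms) {
        if (length(solutions) >= goal$max_solutions) break
        solutions[[length(solutions) + 1L]] <<-
          .new_solution(d, m, path, depth, fp)
      }
    }
    invisible(NULL)
  }
  check_state(start, 0L, character(0))

  while (qi <= length(queue) && length(solutions) < goal$max_solutions) {
    node <- queue[[qi]]; qi <- qi + 1L
    if (node$depth >= goal$max_depth) next
    for (lb in labels) {
      for (succ in apply_rule(kb$rules[[lb]], node$dish, h)) {
        nd <- succ$dish
        if (graph) {
          edges_from <- c(edges_from, node$dish$key)
          edges_to <- c(edges_to, nd$key)
          edges_lab <- c(edges_lab, lb)
        }
        check_state(nd, node$depth + 1L, c(node$path, lb))
        if (length(solutions) >= goal$max_solutions) break
        if (!is.null(states[[nd$key]])) next
        states[[nd$key]] <- TRUE
        n_states <- n_states + 1L
        if (n_states > max_states) { status <- "truncated"; break }
        queue[[length(queue) + 1L]] <-
          list(dish = nd, depth = node$depth + 1L, path = c(node$path, lb))
      }
      if (status == "truncated" || length(solutions) >= goal$max_solutions) break
    }
    if (status == "truncated") break
  }
  structure(list(solutions = solutions, n_states = n_states, status = status,
                 start = start, goal = goal,
                 edges = if (graph) {
                   unique(data.frame(from = edges_from, to = edges_to,
                                     label = edges_lab,
                                     stringsAsFactors = FALSE))
                 } else NULL),
            class = "ss_search")
}

#' @export
print.ss_search <- function(x, ...) {
  cat("Forward search:", length(x$solutions), "solution(s),",
      x$n_states, "state(s) explored,", x$status, "\n")
  for (i in seq_along(x$solutions)) {
    cat("-- solution", i, "--\n")
    print(x$solutions[[i]])
  }
  invisible(x)
}

#' Rule labels along a solution path
#'
#' The ordered rule labels applied to reach the solution's final state.
#' When `kb` is supplied, the solution's stored fingerprint is checked
#' against it and a stale-solution error is raised if the rule set changed.
#'
#' @param sol An `ss_solution`.
#' @param kb Optionally, the `ss_kb` the solution should belong to.
#' @return Character vector of labels in application order.
#' @export
path_labels <- function(sol, kb = NULL) {
  if (!is.null(kb) && !identical(sol$kb_fingerprint, kb_fingerprint(kb))) {
    stop("stale solution: the knowledge base has changed since this search",
         call. = FALSE)
  }
  sol$path
}

#' Replay a rule-label path
#'
#' Folds [apply_rule()] over the labels, starting from a ground dish and
#' keeping the set of all states reachable by that exact label sequence.
#'
#' @param kb An `ss_kb`.
#' @param start A ground `ss_dish` or dish name.
#' @param labels Character vector of rule labels.
#' @param max_states Cap on the breadth of the replayed state set.
#' @return List of ground dishes reachable by the sequence (possibly empty).
#' @export
replay_path <- function(kb, start, labels, max_states = 5000L) {
  if (is.character(start)) start <- kb$dishes[[start]]
  states <- list(start)
  for (lb in labels) {
    if (!(lb %in% names(kb$rules))) stop("unknown rule label: ", lb, call. = FALSE)
    nxt <- list()
    seen <- character(0)
    for (st in states) {
      for (succ in apply_rule(kb$rules[[lb]], st, kb$hierarchy)) {
        k <- succ$dish$key
        if (!(k %in% seen)) {
          seen <- c(seen, k)
          nxt[[length(nxt) + 1L]] <- succ$dish
        }
      }
    }
    states <- nxt
    if (length(states) == 0L) return(list())
    if (length(states) > max_states) stop("replay exceeded max_states", call. = FALSE)
  }
  states
}

#' Tabular summary of search solutions
#'
#' @param x An `ss_search` or `ss_backward` result.
#' @return A data frame with one row per solution.
#' @export
solutions_df <- function(x) {
  sols <- x$solutions
  data.frame(
    solution = seq_along(sols),
    depth = vapply(sols, function(s) s$depth, integer(1)),
    path = vapply(sols, function(s) paste(s$path, collapse = " -> "), character(1)),
    state = vapply(sols, function(s) {
      if (!is.null(s$final_dish)) s$final_dish$key else s$initial_pattern$key
    }, character(1)),
    stringsAsFactors = FALSE
  )
}
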