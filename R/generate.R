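# Seed-reproducible random knowledge bases, small enough that exhaustive
# oracles (brute-force matching, ground enumeration, forward replay) stay
# tractable in tests.

#' Generator configuration
#'
#' Controls the size and shape of random knowledge bases from
#' [generate_kb()]. The defaults keep state spaces small (a few hundred
#' reachable states at depth 4 or less), which is what the exhaustive
#' cross-checking oracles need.
#'
#' @param n_entities Number of entities (>= 1).
#' @param n_locations Number of location tags (>= 1).
#' @param n_rules Number of rewrite rules (>= 0).
#' @param max_soup_size Maximum extra terms per location in the initial dish.
#' @param max_rule_width Maximum reactant terms per location on a rule LHS.
#' @param p_modifier Probability that a rule carries a modifier term
#'   (required but unchanged, listed identically on both sides).
#' @param p_sort_condition Probability that a rule carries a sorted element
#'   variable with a membership condition.
#' @param p_transform Probability that a rule transforms one entity into
#'   another (all other rules conserve the entity multiset).
#' @param seed Integer seed; identical config and seed give an identical KB.
#' @return A `gen_config` list.
#' @export
gen_config <- function(n_entities = 4L, n_locations = 2L, n_rules = 3L,
                       max_soup_size = 3L, max_rule_width = 2L,
                       p_modifier = 0.3, p_sort_condition = 0.2,
                       p_transform = 0.2, seed = 1L) {
  stopifnot(n_entities >= 1, n_locations >= 1, n_rules >= 0,
            max_soup_size >= 1, max_rule_width >= 1,
            p_modifier >= 0, p_modifier <= 1,
            p_sort_condition >= 0, p_sort_condition <= 1,
            p_transform >= 0, p_transform <= 1)
  structure(list(n_entities = as.integer(n_entities),
                 n_locations = as.integer(n_locations),
                 n_rules = as.integer(n_rules),
                 max_soup_size = as.integer(max_soup_size),
                 max_rule_width = as.integer(max_rule_width),
                 p_modifier = p_modifier, p_sort_condition = p_sort_condition,
                 p_transform = p_transform, seed = as.integer(seed)),
            class = "gen_config")
}

# run code under a local RNG state without disturbing the caller's stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random knowledge base and initial dish
#'
#' Builds a random rule system over `n_entities` entities and `n_locations`
#' locations. Rules conserve the entity multiset by construction (terms are
#' shuffled between the rule's locations) except for a `p_transform`
#' fraction that swap one entity for another — mirroring nucleotide-
#' exchange reactions. Every rule's left-hand side is instantiable in the
#' returned initial dish, so generated systems always have transitions to
#' exercise. The KB contains two sorts: `SAll` (all entities) and `SOdd`
#' (every other entity), used for generated membership conditions.
#'
#' @param cfg A [gen_config()].
#' @return List with elements `kb` (an `ss_kb`, whose `dishes$Dish0` is the
#'   initial state) and `dish` (that same ground dish).
#' @examples
#' g <- generate_kb(gen_config(seed = 7))
#' g$kb
#' @export
generate_kb <- function(cfg = gen_config()) {
  stopifnot(inherits(cfg, "gen_config"))
  .with_seed(cfg$seed, {
    ents <- sprintf("E%02d", seq_len(cfg$n_entities))
    locs <- sprintf("L%d", seq_len(cfg$n_locations))
    sorts <- list(SAll = ents, SOdd = ents[seq(1L, cfg$n_entities, by = 2L)])
    entities <- stats::setNames(rep("Things", length(ents)), ents)

    pick <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]
    rules <- list()
    witness <- list()  # per-location terms the initial dish must contain
    for (i in seq_len(cfg$n_rules)) {
      width <- sample.int(min(2L, cfg$n_locations), 1L)
      rtags <- sort(sample(locs, width))
      lhs_terms <- stats::setNames(vector("list", width), rtags)
      for (tg in rtags) {
        k <- sample.int(cfg$max_rule_width, 1L)
        lhs_terms[[tg]] <- lapply(pick(ents, k), entity)
      }
      # redistribute the same terms over the same locations (conservation)
      all_terms <- unlist(lhs_terms, recursive = FALSE)
      assign_to <- pick(rtags, length(all_terms))
      rhs_terms <- stats::setNames(lapply(rtags, function(tg) list()), rtags)
      for (j in seq_along(all_terms)) {
        tg <- assign_to[[j]]
        rhs_terms[[tg]] <- c(rhs_terms[[tg]], all_terms[j])
      }
      conditions <- list()
      if (stats::runif(1) < cfg$p_transform && length(all_terms) > 0L) {
        # swap one produced entity for another (like a GDP -> GTP exchange)
        tg <- pick(rtags)
        if (length(rhs_terms[[tg]]) > 0L) {
          rhs_terms[[tg]][[1L]] <- entity(pick(ents))
        }
      }
      if (stats::runif(1) < cfg$p_modifier) {
        tg <- pick(rtags)
        m <- entity(pick(ents))
        lhs_terms[[tg]] <- c(lhs_terms[[tg]], list(m))
        rhs_terms[[tg]] <- c(rhs_terms[[tg]], list(m))
      }
      if (stats::runif(1) < cfg$p_sort_condition) {
        tg <- pick(rtags)
        vname <- sprintf("x%d", i)
        srt <- pick(c("SAll", "SOdd"))
        v <- term_var(vname, srt)
        lhs_terms[[tg]] <- c(lhs_terms[[tg]], list(v))
        rhs_terms[[tg]] <- c(rhs_terms[[tg]], list(v))
        conditions <- list(list(var = vname, sort = srt))
      }
      lloc <- list(); rloc <- list()
      for (tg in rtags) {
        sv <- sprintf("s%d%s", i, tg)
        lloc[[tg]] <- soup(lhs_terms[[tg]], svar = sv)
        rloc[[tg]] <- soup(rhs_terms[[tg]], svar = sv)
      }
      rules[[i]] <- rw_rule(sprintf("r%02d", i),
                            dish(locations = lloc), dish(locations = rloc),
                            conditions = conditions)
      for (tg in rtags) {
        inst <- lapply(lhs_terms[[tg]], function(t) {
          if (t$kind == "var") entity(sorts[[t$sorts[[1L]]]][[1L]]) else t
        })
        witness[[tg]] <- c(witness[[tg]], inst)
      }
    }
    # initial dish: a witness instance of every rule LHS plus random extras
    dish_locs <- stats::setNames(lapply(locs, function(tg) {
      extra <- lapply(pick(ents, sample.int(cfg$max_soup_size, 1L)), entity)
      soup(c(witness[[tg]], extra))
    }), locs)
    d0 <- dish(locations = dish_locs)
    kb <- knowledge_base(rules = rules, sorts = sorts, entities = entities,
                         dishes = list(Dish0 = d0))
    list(kb = kb, dish = d0)
  })
}
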