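# Textual dish syntax
#
#   dish   :=  ("{" TAG "|" soup "}")* [ dishvar ]
#   soup   :=  "none" | item+ [ soupvar ]
#   item   :=  primary (":" primary)*          (":" must be space-separated)
#   primary:=  Name | "[" base "-" mod+ "]" | "(" item ")" | elemvar
#   mod    :=  Name | Name "(" Name ")"
#   var    :=  ["?"]name":"Sort ("&"Sort)*     (no spaces around this colon)
#
# A variable token whose sort is exactly Things is a soup variable; sort Dish
# marks the dish-level variable; anything else is an element variable. A ":"
# written without surrounding whitespace is always the variable-sort colon;
# the complex-binding operator is the free-standing, space-separated ":".

.tokenize <- function(text) {
  text <- gsub("([{}|\\[\\]()])", " \\1 ", text, perl = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.tok_var <- function(tok) {
  # returns list(name, sorts) or NULL
  t2 <- sub("^\\?", "", tok)
  if (!grepl(":", t2, fixed = TRUE)) return(NULL)
  parts <- strsplit(t2, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("bad variable token: ", tok, call. = FALSE)
  sorts <- strsplit(parts[2L], "&", fixed = TRUE)[[1]]
  list(name = parts[1L], sorts = sorts)
}

# cursor-based recursive descent over a token vector held in an environment
.pstate <- function(toks) {
  e <- new.env(parent = emptyenv())
  e$toks <- toks
  e$i <- 1L
  e
}
.peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
.next_tok <- function(st) {
  tok <- .peek(st)
  if (is.null(tok)) stop("unexpected end of input", call. = FALSE)
  st$i <- st$i + 1L
  tok
}
.expect <- function(st, tok) {
  got <- .next_tok(st)
  if (!identical(got, tok)) stop("expected '", tok, "' but got '", got, "'", call. = FALSE)
}

.parse_primary <- function(st) {
  tok <- .next_tok(st)
  if (identical(tok, "(")) {
    t <- .parse_item(st)
    .expect(st, ")")
    return(t)
  }
  if (identical(tok, "[")) {
    bt <- .next_tok(st)
    bv <- .tok_var(bt)
    base <- if (is.null(bv)) bt else term_var(bv$name, bv$sorts)
    .expect(st, "-")
    mods <- list()
    repeat {
      nx <- .peek(st)
      if (is.null(nx)) stop("unterminated '['", call. = FALSE)
      if (identical(nx, "]")) { st$i <- st$i + 1L; break }
      mname <- .next_tok(st)
      if (identical(.peek(st), "(")) {
        st$i <- st$i + 1L
        arg <- .next_tok(st)
        .expect(st, ")")
        mods <- c(mods, list(modification(mname, arg)))
      } else {
        mods <- c(mods, list(modification(mname)))
      }
    }
    if (length(mods) == 0L) stop("modified term needs at least one modification", call. = FALSE)
    return(modified(base, mods))
  }
  v <- .tok_var(tok)
  if (!is.null(v)) {
    if (identical(v$sorts, "Things")) {
      stop("soup variable '", tok, "' not allowed inside a term", call. = FALSE)
    }
    return(term_var(v$name, v$sorts))
  }
  entity(tok)
}

.parse_item <- function(st) {
  t <- .parse_primary(st)
  comps <- list(t)
  while (identical(.peek(st), ":")) {
    st$i <- st$i + 1L
    comps <- c(comps, list(.parse_primary(st)))
  }
  if (length(comps) == 1L) comps[[1L]] else complex_term(comps)
}

.parse_soup_tokens <- function(st, stop_tok) {
  elems <- list()
  svar <- NULL
  if (identical(.peek(st), "none")) {
    st$i <- st$i + 1L
    if (!identical(.peek(st), stop_tok)) stop("'none' must stand alone in a soup", call. = FALSE)
    return(soup())
  }
  repeat {
    nx <- .peek(st)
    if (is.null(nx)) stop("unterminated soup", call. = FALSE)
    if (identical(nx, stop_tok)) break
    v <- .tok_var(nx)
    if (!is.null(v) && identical(v$sorts, "Things")) {
      st$i <- st$i + 1L
      if (!is.null(svar)) {
        stop("at most one soup variable per soup (saw '", svar, "' and '", v$name, "')",
             call. = FALSE)
      }
      svar <- v$name
      next
    }
    elems <- c(elems, list(.parse_item(st)))
  }
  soup(elems, svar = svar)
}

#' Parse the textual dish/soup/term syntax
#'
#' Inverse of the canonical string form: `parse_dish(canonical(d))` equals
#' `d` for every dish. Accepts the notation used throughout the
#' documentation: `{TAG | term term ...}` blocks, `none` for the empty soup,
#' `[Name - mod ...]` for modified entities, space-separated `:` for complex
#' binding, `name:Sort` (no spaces) for variables — sort `Things` makes a
#' soup variable, sort `Dish` the dish-level variable.
#'
#' @param text A character scalar.
#' @return `parse_dish()` an `ss_dish`; `parse_soup()` an `ss_soup`;
#'   `parse_term()` an `ss_term`.
#' @examples
#' parse_dish("{XOut | Egf} {EgfRC | EgfR}")
#' parse_dish("{EgfRC | ([EgfR - Yphos] : Egf) ?egfrc:Things}")
#' parse_term("[?gab:GabS - Yphos]")
#' @export
parse_dish <- function(text) {
  toks <- .tokenize(text)
  if (length(toks) == 0L || identical(toks, c("{", "}"))) return(dish())
  st <- .pstate(toks)
  locs <- list()
  dvar <- NULL
  repeat {
    nx <- .peek(st)
    if (is.null(nx)) break
    if (identical(nx, "{")) {
      st$i <- st$i + 1L
      tag <- .next_tok(st)
      .expect(st, "|")
      sp <- .parse_soup_tokens(st, "}")
      .expect(st, "}")
      if (tag %in% names(locs)) stop("duplicate location tag: ", tag, call. = FALSE)
      locs[[tag]] <- sp
      next
    }
    v <- .tok_var(nx)
    if (!is.null(v) && identical(v$sorts, "Dish")) {
      st$i <- st$i + 1L
      if (!is.null(dvar)) stop("at most one dish variable", call. = FALSE)
      dvar <- v$name
      next
    }
    stop("unexpected token at dish level: '", nx, "'", call. = FALSE)
  }
  dish(locations = locs, dvar = dvar)
}

#' @rdname parse_dish
#' @export
parse_soup <- function(text) {
  st <- .pstate(c(.tokenize(text), "END"))
  sp <- .parse_soup_tokens(st, "END")
  if (st$i != length(st$toks)) stop("trailing tokens in soup", call. = FALSE)
  sp
}

#' @rdname parse_dish
#' @export
parse_term <- function(text) {
  st <- .pstate(.tokenize(text))
  t <- .parse_item(st)
  if (!is.null(.peek(st))) stop("trailing tokens in term", call. = FALSE)
  t
}
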