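#' The EGF receptor signaling fixture
#'
#' A small, fully executable fragment of an EGF-response model. The initial
#' state `EgfDish` has seven locations: `XOut` (extracellular space, holding
#' the ligand Egf), `EgfRC` (the receptor-complex container, holding EgfR),
#' `CLo` (outer face of the plasma membrane, empty), `CLm` (the membrane:
#' Erbb2, Pag1, Plscr1), `CLi` (inner membrane face: the small GTPases
#' Cdc42, Hras and Kras loaded with GDP, plus Gnai1, Gnai3, Pld1), `CLc`
#' (cytoplasm) and `NUc` (nucleus: Atf1, Creb1, Elk1).
#'
#' Three rules chain into the Ras-activation fragment of the pathway:
#'
#' * `001.EgfR.irt.Egf` — extracellular Egf binds EgfR, which is tyrosine-
#'   phosphorylated: `Egf` leaves `XOut` and `([EgfR - Yphos] : Egf)` forms
#'   in `EgfRC`.
#' * `188.Shp2.irt.Egf` — with the ligand-bound receptor present, the
#'   phosphatase Shp2 moves from the cytoplasm to `EgfRC` and is tyrosine-
#'   phosphorylated.
#' * `529.Hras.irt.Egf` — with the active receptor complex and `[Shp2 -
#'   Yphos]` in `EgfRC`, a tyrosine-phosphorylated Gab-family protein
#'   (`[gab:GabS - Yphos]`, GabS = Gab1 or Gab2), a tyrosine-phosphorylated
#'   Ras activator (`RasActS` = RasGrp3 or Sos1) and Pi3k in the cytoplasm,
#'   Hras at the inner membrane switches its nucleotide load from GDP to
#'   GTP (activation).
#'
#' So that the three printed rules execute as a chain, the cytoplasm of
#' `EgfDish` carries Gab1 and Sos1 already tyrosine-phosphorylated (their
#' activating kinases are outside this fragment) and plain Shp2 (which rule
#' 188 phosphorylates). The sort hierarchy declares `ErkS <= BProtein` with
#' member Erks, `GabS = {Gab1, Gab2}`, `RasActS = {RasGrp3, Sos1}`, and a
#' `Chemical` sort for the nucleotides.
#'
#' @return An `ss_kb` with 3 rules and the `EgfDish` initial state.
#' @examples
#' kb <- egf_fixture()
#' kb$dishes$EgfDish
#' @export
egf_fixture <- function() {
  bprot <- c("Egf", "EgfR", "Erbb2", "Pag1", "Plscr1", "Cdc42", "Hras", "Kras",
             "Gnai1", "Gnai3", "Pld1", "Pi3k", "Abl1", "Akt1", "Araf",
             "ArhGap5", "Shp2", "Atf1", "Creb1", "Elk1")
  entities <- c(
    stats::setNames(rep("BProtein", length(bprot)), bprot),
    Gab1 = "GabS", Gab2 = "GabS",
    RasGrp3 = "RasActS", Sos1 = "RasActS",
    Erks = "ErkS",
    GDP = "Chemical", GTP = "Chemical"
  )
  sorts <- list(
    BProtein = c("ErkS", "GabS", "RasActS"),
    ErkS = character(0),
    GabS = character(0),
    RasActS = character(0),
    Chemical = character(0)
  )
  egf_dish <- dish(
    XOut = soup(entity("Egf")),
    EgfRC = soup(entity("EgfR")),
    CLo = empty_soup(),
    CLm = soup(entity("Erbb2"), entity("Pag1"), entity("Plscr1")),
    CLi = soup(complex_term(entity("Cdc42"), entity("GDP")),
               complex_term(entity("Hras"), entity("GDP")),
               complex_term(entity("Kras"), entity("GDP")),
               entity("Gnai1"), entity("Gnai3"), entity("Pld1")),
    CLc = soup(entity("Pi3k"), entity("Abl1"), entity("Akt1"), entity("Araf"),
               entity("ArhGap5"), entity("Shp2"),
               modified("Gab1", "Yphos"), modified("Sos1", "Yphos")),
    NUc = soup(entity("Atf1"), entity("Creb1"), entity("Elk1"))
  )
  r001 <- rw_rule(
    "001.EgfR.irt.Egf",
    "{XOut | Egf ?xout:Things} {EgfRC | EgfR ?egfrc:Things}",
    "{XOut | ?xout:Things} {EgfRC | ([EgfR - Yphos] : Egf) ?egfrc:Things}",
    source = "ligand binding and receptor autophosphorylation"
  )
  r188 <- rw_rule(
    "188.Shp2.irt.Egf",
    paste0("{EgfRC | ([EgfR - Yphos] : Egf) ?egfrc:Things}",
           " {CLc | Shp2 ?clc:Things}"),
    paste0("{EgfRC | ([EgfR - Yphos] : Egf) [Shp2 - Yphos] ?egfrc:Things}",
           " {CLc | ?clc:Things}"),
    source = "Shp2 phosphorylation and recruitment to the receptor complex"
  )
  r529 <- rw_rule(
    "529.Hras.irt.Egf",
    paste0("{EgfRC | ([EgfR - Yphos] : Egf) [Shp2 - Yphos] ?egfrc:Things}",
           " {CLc | [?gab:GabS - Yphos] [?rasact:RasActS - Yphos] Pi3k ?clc:Things}",
           " {CLi | (Hras : GDP) ?cli:Things}"),
    paste0("{EgfRC | ([EgfR - Yphos] : Egf) [Shp2 - Yphos] ?egfrc:Things}",
           " {CLc | [?gab:GabS - Yphos] [?rasact:RasActS - Yphos] Pi3k ?clc:Things}",
           " {CLi | (Hras : GTP) ?cli:Things}"),
    conditions = list(list(var = "gab", sort = "GabS"),
                      list(var = "rasact", sort = "RasActS")),
    source = "Hras GDP->GTP exchange at the inner membrane"
  )
  knowledge_base(rules = list(r001, r188, r529), sorts = sorts,
                 entities = entities, dishes = list(EgfDish = egf_dish))
}

#' The vending-machine fixture
#'
#' The classic multiset-rewriting teaching system: states are multisets of
#' products (apples, chocolate) and money (quarters, dollars) in a single
#' location `VM`. Three rules: a dollar becomes four quarters; a dollar
#' becomes a chocolate and one quarter; two quarters become an apple.
#' Initial dishes: `DollarDish` (one dollar) and `TwoQuarters`.
#'
#' @return An `ss_kb` with 3 rules and 2 dishes.
#' @examples
#' kb <- vending_fixture()
#' kb$rules[["dollar.to.quarters"]]
#' @export
vending_fixture <- function() {
  entities <- c(apple = "Item", chocolate = "Item", dollar = "Coin",
                quarter = "Coin")
  sorts <- list(Item = character(0), Coin = character(0))
  r_q <- rw_rule("dollar.to.quarters",
                 "{VM | dollar ?m:Things}",
                 "{VM | quarter quarter quarter quarter ?m:Things}")
  r_c <- rw_rule("dollar.to.chocolate",
                 "{VM | dollar ?m:Things}",
                 "{VM | chocolate quarter ?m:Things}")
  r_a <- rw_rule("quarters.to.apple",
                 "{VM | quarter quarter ?m:Things}",
                 "{VM | apple ?m:Things}")
  knowledge_base(
    rules = list(r_q, r_c, r_a), sorts = sorts, entities = entities,
    dishes = list(
      DollarDish = dish(VM = soup(entity("dollar"))),
      TwoQuarters = dish(VM = soup(entity("quarter"), entity("quarter")))
    )
  )
}
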