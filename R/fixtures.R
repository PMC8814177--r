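# Bundled pathway fixtures.
#
# Molecular weights are rounded literature values (UniProt subunit weights
# for the yeast enzymes, monoisotopic-ish weights for the metabolites); they
# only enter the simulation through the sphere radius, which depends on the
# cube root of the weight.  Initial concentrations below 1 mmol/l follow the
# published scaled values where printed (pyruvate 0.2, trehalose 0.015,
# NADH 0.086 mmol/l) and documented approximations elsewhere, flagged
# approx = TRUE and overridable via the `concentrations` argument.

.GLYCOLYSIS_SPECIES <- function() {
  m <- function(id, name, w, c, approx = TRUE)
    species_spec(id, name, "metabolite", w, c, approx)
  e <- function(id, name, w, c)
    species_spec(id, name, "enzyme", w, c, approx = TRUE)
  rbind(
    m("GLC",   "glucose",                     180.16, 0.900),
    m("ATP",   "ATP",                         507.18, 0.800),
    m("ADP",   "ADP",                         427.20, 0.600),
    m("G6P",   "glucose 6-phosphate",         260.14, 0.300),
    m("F6P",   "fructose 6-phosphate",        260.14, 0.200),
    m("F16bP", "fructose 1,6-bisphosphate",   340.12, 0.300),
    m("DHAP",  "dihydroxyacetone phosphate",  170.06, 0.250),
    m("GAP",   "glyceraldehyde 3-phosphate",  170.06, 0.060),
    m("NAD",   "NAD+",                        663.43, 0.600),
    m("NADH",  "NADH",                        665.44, 0.086, approx = FALSE),
    m("BPG",   "1,3-bisphosphoglycerate",     266.04, 0.002),
    m("P3G",   "3-phosphoglycerate",          186.06, 0.150),
    m("P2G",   "2-phosphoglycerate",          186.06, 0.050),
    m("PEP",   "phosphoenolpyruvate",         168.04, 0.100),
    m("PYR",   "pyruvate",                     88.06, 0.200, approx = FALSE),
    m("G3P",   "glycerol 3-phosphate",        172.07, 0.100),
    m("GLY",   "glycerol",                     92.09, 0.150),
    m("G1P",   "glucose 1-phosphate",         260.14, 0.100),
    m("UTP",   "UTP",                         484.14, 0.200),
    m("UDPG",  "UDP-glucose",                 566.30, 0.100),
    m("T6P",   "trehalose 6-phosphate",       422.28, 0.050),
    m("TRH",   "trehalose",                   342.30, 0.015, approx = FALSE),
    m("GLYG",  "glycogen (acceptor unit)",    666.58, 0.050),
    e("HXK1",  "hexokinase 1",               53738, 0.020),
    e("HXK2",  "hexokinase 2",               53944, 0.020),
    e("GLK1",  "glucokinase 1",              55377, 0.015),
    e("PGI1",  "glucose-6-phosphate isomerase", 61299, 0.030),
    e("PFK1",  "phosphofructokinase",       107974, 0.020),
    e("FBA1",  "fructose-bisphosphate aldolase", 39621, 0.030),
    e("TPI1",  "triosephosphate isomerase",  26795, 0.030),
    e("TDH1",  "glyceraldehyde-3-phosphate dehydrogenase 1", 35750, 0.020),
    e("TDH2",  "glyceraldehyde-3-phosphate dehydrogenase 2", 35847, 0.010),
    e("TDH3",  "glyceraldehyde-3-phosphate dehydrogenase 3", 35747, 0.030),
    e("PGK1",  "3-phosphoglycerate kinase",  44738, 0.030),
    e("GPM1",  "phosphoglycerate mutase",    27608, 0.030),
    e("ENO1",  "enolase 1",                  46816, 0.020),
    e("ENO2",  "enolase 2",                  46914, 0.020),
    e("CDC19", "pyruvate kinase",            54544, 0.030),
    e("GPD1",  "glycerol-3-phosphate dehydrogenase 1", 42869, 0.015),
    e("GPD2",  "glycerol-3-phosphate dehydrogenase 2", 49414, 0.010),
    e("GPP1",  "glycerol-3-phosphatase 1",   27946, 0.015),
    e("GPP2",  "glycerol-3-phosphatase 2",   27815, 0.010),
    e("PGM1",  "phosphoglucomutase 1",       63088, 0.010),
    e("PGM2",  "phosphoglucomutase 2",       63071, 0.010),
    e("UGP1",  "UTP-glucose-1-phosphate uridylyltransferase", 55989, 0.015),
    e("TPS1",  "trehalose-6-phosphate synthase", 56147, 0.010),
    e("TPS2",  "trehalose-6-phosphate phosphatase", 102939, 0.010),
    e("GSY1",  "glycogen synthase 1",        80539, 0.010),
    e("GSY2",  "glycogen synthase 2",        80989, 0.010))
}

.GLYCOLYSIS_REACTIONS <- function() {
  rx <- function(id, enz, sub, prod, rev, kcat, name = id)
    reaction_spec(id, enz, sub, prod, reversible = rev, kcat = kcat,
                  name = name)
  list(
    rx("R_HXK1", "HXK1", c(GLC = 1, ATP = 1), c(G6P = 1, ADP = 1), FALSE, 200,
       "hexokinase 1"),
    rx("R_HXK2", "HXK2", c(GLC = 1, ATP = 1), c(G6P = 1, ADP = 1), FALSE, 200,
       "hexokinase 2"),
    rx("R_GLK1", "GLK1", c(GLC = 1, ATP = 1), c(G6P = 1, ADP = 1), FALSE, 150,
       "glucokinase"),
    rx("R_PGI1", "PGI1", c(G6P = 1), c(F6P = 1), TRUE, 1000,
       "glucose-6-phosphate isomerase"),
    rx("R_PFK1", "PFK1", c(F6P = 1, ATP = 1), c(F16bP = 1, ADP = 1), FALSE,
       200, "phosphofructokinase"),
    rx("R_FBA1", "FBA1", c(F16bP = 1), c(DHAP = 1, GAP = 1), TRUE, 100,
       "fructose-bisphosphate aldolase"),
    rx("R_TPI1", "TPI1", c(DHAP = 1), c(GAP = 1), TRUE, 5000,
       "triosephosphate isomerase"),
    rx("R_TDH1", "TDH1", c(GAP = 1, NAD = 1), c(BPG = 1, NADH = 1), TRUE, 100,
       "glyceraldehyde-3-phosphate dehydrogenase 1"),
    rx("R_TDH2", "TDH2", c(GAP = 1, NAD = 1), c(BPG = 1, NADH = 1), TRUE, 100,
       "glyceraldehyde-3-phosphate dehydrogenase 2"),
    rx("R_TDH3", "TDH3", c(GAP = 1, NAD = 1), c(BPG = 1, NADH = 1), TRUE, 100,
       "glyceraldehyde-3-phosphate dehydrogenase 3"),
    rx("R_PGK1", "PGK1", c(BPG = 1, ADP = 1), c(P3G = 1, ATP = 1), TRUE, 800,
       "3-phosphoglycerate kinase"),
    rx("R_GPM1", "GPM1", c(P3G = 1), c(P2G = 1), TRUE, 400,
       "phosphoglycerate mutase"),
    rx("R_ENO1", "ENO1", c(P2G = 1), c(PEP = 1), TRUE, 80, "enolase 1"),
    rx("R_ENO2", "ENO2", c(P2G = 1), c(PEP = 1), TRUE, 80, "enolase 2"),
    rx("R_CDC19", "CDC19", c(PEP = 1, ADP = 1), c(PYR = 1, ATP = 1), FALSE,
       300, "pyruvate kinase"),
    rx("R_GPD1", "GPD1", c(DHAP = 1, NADH = 1), c(G3P = 1, NAD = 1), FALSE,
       70, "glycerol-3-phosphate dehydrogenase 1"),
    rx("R_GPD2", "GPD2", c(DHAP = 1, NADH = 1), c(G3P = 1, NAD = 1), FALSE,
       70, "glycerol-3-phosphate dehydrogenase 2"),
    rx("R_GPP1", "GPP1", c(G3P = 1), c(GLY = 1), FALSE, 100,
       "glycerol-3-phosphatase 1"),
    rx("R_GPP2", "GPP2", c(G3P = 1), c(GLY = 1), FALSE, 100,
       "glycerol-3-phosphatase 2"),
    rx("R_PGM1", "PGM1", c(G6P = 1), c(G1P = 1), TRUE, 100,
       "phosphoglucomutase 1"),
    rx("R_PGM2", "PGM2", c(G6P = 1), c(G1P = 1), TRUE, 100,
       "phosphoglucomutase 2"),
    rx("R_UGP1", "UGP1", c(G1P = 1, UTP = 1), c(UDPG = 1), FALSE, 100,
       "UTP-glucose-1-phosphate uridylyltransferase"),
    rx("R_TPS1", "TPS1", c(UDPG = 1, G6P = 1), c(T6P = 1), FALSE, 50,
       "trehalose-6-phosphate synthase"),
    rx("R_TPS2", "TPS2", c(T6P = 1), c(TRH = 1), FALSE, 50,
       "trehalose-6-phosphate phosphatase"),
    rx("R_GSY1", "GSY1", c(UDPG = 1), c(GLYG = 1), FALSE, 50,
       "glycogen synthase 1"),
    rx("R_GSY2", "GSY2", c(UDPG = 1), c(GLYG = 1), FALSE, 50,
       "glycogen synthase 2"))
}

#' Adapted yeast glycolysis network
#'
#' The glycolytic main branch from glucose to pyruvate together with the
#' glycerol, trehalose and glycogen branches, one reaction per isoenzyme
#' (hexokinases HXK1/HXK2 and glucokinase GLK1; TDH1/2/3; ENO1/2; ...), with
#' hexokinase/glucokinase, phosphofructokinase and pyruvate kinase
#' irreversible.  Fermentation (PDC/ADH), adenylate kinase, ATPase, the UDP
#' to UTP conversion and glucose transport are absent by construction.  All
#' initial concentrations are below 1 mmol/l; at full scale the model
#' instantiates ~3500 molecules in one attolitre.
#'
#' `scale` multiplies every particle count (with a floor of one particle per
#' species with non-zero concentration) for desk-scale runs.
#'
#' @param scale fraction of the full particle counts, in (0, 1].
#' @param concentrations optional named vector overriding initial
#'   concentrations (mmol/l) by species id, applied before scaling (e.g. a
#'   transcription of published per-species values).
#' @return a `pathway_model`.
#' @export
glycolysis_model <- function(scale = 1.0, concentrations = NULL) {
  stopifnot(scale > 0, scale <= 1)
  species <- .GLYCOLYSIS_SPECIES()
  if (!is.null(concentrations)) {
    idx <- match(names(concentrations), species$id)
    if (anyNA(idx)) stop("unknown species in concentration override: ",
                         paste(names(concentrations)[is.na(idx)],
                               collapse = ", "))
    species$initial_concentration[idx] <- as.numeric(concentrations)
    species$approx[idx] <- FALSE
  }
  volume <- 1e-18
  if (scale < 1) {
    full <- concentration_to_count(species$initial_concentration, volume)
    scaled <- ifelse(full > 0, pmax(1L, as.integer(round(scale * full))), 0L)
    species$initial_concentration <- count_to_concentration(scaled, volume)
  }
  pathway_model(species, .GLYCOLYSIS_REACTIONS(), volume = volume,
                provenance = "fixture:glycolysis")
}

#' Single irreversible reaction toy model
#'
#' One enzyme molecule (weight 54 kg/mol, radius ~25 Angstrom) converting a
#' pool of substrate molecules (radius ~4 Angstrom) into product.  With a
#' box-sized perception distance and the uniform binding law, binding is
#' never rate-limiting and the product production rate approaches kcat
#' (the Vmax limit of Michaelis-Menten kinetics), which makes this the
#' turnover-time oracle for the engine.
#'
#' @param n_substrate initial substrate molecule count.
#' @param kcat turnover number (1/s).
#' @return a `pathway_model` (1 aL volume).
#' @export
toy_single_reaction <- function(n_substrate = 500, kcat = 100) {
  stopifnot(n_substrate >= 1, kcat > 0)
  v <- 1e-18
  species <- rbind(
    species_spec("E", "enzyme", "enzyme", 54000,
                 count_to_concentration(1, v)),
    species_spec("S", "substrate", "metabolite", 220,
                 count_to_concentration(n_substrate, v)),
    species_spec("P", "product", "metabolite", 220, 0))
  pathway_model(species,
                list(reaction_spec("R_ES", "E", c(S = 1), c(P = 1),
                                   reversible = FALSE, kcat = kcat)),
                volume = v, provenance = "fixture:toy_single_reaction")
}

#' Reversible interconversion toy model
#'
#' One enzyme interconverting A and B with equal kcat in both directions
#' (the shape of the triosephosphate-isomerase step); exercises the
#' direction-fixing of the reaction automaton.
#'
#' @param n_a,n_b initial counts of A and B.
#' @param kcat turnover number, both directions (1/s).
#' @param reversible set `FALSE` for the irreversible A -> B variant.
#' @return a `pathway_model` (1 aL volume).
#' @export
toy_reversible_pair <- function(n_a = 120, n_b = 0, kcat = 100,
                                reversible = TRUE) {
  v <- 1e-18
  species <- rbind(
    species_spec("E", "isomerase", "enzyme", 27000,
                 count_to_concentration(2, v)),
    species_spec("A", "A", "metabolite", 170, count_to_concentration(n_a, v)),
    species_spec("B", "B", "metabolite", 170, count_to_concentration(n_b, v)))
  pathway_model(species,
                list(reaction_spec("R_AB", "E", c(A = 1), c(B = 1),
                                   reversible = reversible, kcat = kcat)),
                volume = v, provenance = "fixture:toy_reversible_pair")
}

#' Random connected pathway (fuzzing fixture)
#'
#' Deterministic per seed: `n_species` metabolites with random weights and
#' concentrations and `n_reactions` enzyme-catalysed reactions wired so the
#' network is connected (each reaction after the first consumes a species
#' already produced or consumed earlier).
#'
#' @param n_species number of metabolite species.
#' @param n_reactions number of reactions (each with its own enzyme).
#' @param seed RNG seed.
#' @return a valid `pathway_model`.
#' @export
random_pathway <- function(n_species = 6, n_reactions = 4, seed = 1) {
  stopifnot(n_species >= 2, n_reactions >= 1)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mids <- sprintf("M%02d", seq_len(n_species))
  eids <- sprintf("E%02d", seq_len(n_reactions))
  species <- rbind(
    do.call(rbind, lapply(seq_len(n_species), function(i)
      species_spec(mids[i], mids[i], "metabolite",
                   runif(1, 100, 1000),
                   count_to_concentration(sample(5:80, 1), 1e-18)))),
    do.call(rbind, lapply(seq_len(n_reactions), function(i)
      species_spec(eids[i], eids[i], "enzyme",
                   runif(1, 2e4, 1e5),
                   count_to_concentration(sample(1:4, 1), 1e-18)))))
  touched <- character(0)
  reactions <- vector("list", n_reactions)
  for (i in seq_len(n_reactions)) {
    anchor <- if (length(touched)) sample(touched, 1) else sample(mids, 1)
    others <- setdiff(mids, anchor)
    subs <- unique(c(anchor,
                     if (runif(1) < 0.4) sample(others, 1)))
    prods <- sample(setdiff(mids, subs), size = min(sample(1:2, 1),
                                                    n_species - length(subs)))
    sub <- rep(1L, length(subs)); names(sub) <- subs
    prod <- rep(1L, length(prods)); names(prod) <- prods
    reactions[[i]] <- reaction_spec(
      sprintf("R%02d", i), eids[i], sub, prod,
      reversible = runif(1) < 0.5,
      kcat = runif(1, 50, 2000))
    touched <- unique(c(touched, subs, prods))
  }
  pathway_model(species, reactions, volume = 1e-18,
                provenance = sprintf("fixture:random_pathway(seed=%d)", seed))
}

#' Catalogue of bundled fixtures
#'
#' @return data frame naming each fixture builder and its expected
#'   behaviour.
#' @export
fixture_catalog <- function() {
  data.frame(
    name = c("glycolysis", "toy_single_reaction", "toy_reversible_pair",
             "random_pathway"),
    builder = c("glycolysis_model", "toy_single_reaction",
                "toy_reversible_pair", "random_pathway"),
    behaviour = c(
      "adapted yeast glycolysis; regime-dependent glucose consumption",
      "product rate approaches kcat when binding is not limiting",
      "A:B ratio fluctuates around 1 at equilibrium",
      "connected random network for fuzz tests"),
    stringsAsFactors = FALSE)
}
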