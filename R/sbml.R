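#' Read a kinetic SBML model into a pathway model
#'
#' Purpose-built reader for the subset of SBML (Level 2/3) that the
#' agent-based representation consumes: species with initial concentrations,
#' reactions with reactants, products and modifiers, and `kcat` kinetic-law
#' parameters.  Rate-law mathematics is deliberately ignored.  Catalysing
#' enzymes are identified from reaction modifiers; every modifier species
#' gets the enzyme role.
#'
#' Molecular weights are not part of SBML; they are taken from a bundled
#' table covering the glycolysis species (see
#' `system.file("extdata", "molecular_weights.csv", package = "abmetab")`),
#' which can be extended or overridden via `weights`.
#'
#' @param path SBML file.
#' @param weights optional data frame with columns `id`, `molecular_weight`
#'   (g/mol) overriding/extending the bundled table; matched against species
#'   id and name.
#' @param default_kcat fallback turnover number (1/s) for reactions whose
#'   kinetic law carries no `kcat` parameter; `NULL` makes that an error.
#' @param concentration_factor multiplied into every initial concentration to
#'   convert the model's declared units into mmol/l (1 if the model already
#'   uses mmol/l, as yeast glycolysis models conventionally do).
#' @param default_weight_enzyme,default_weight_metabolite fallback molecular
#'   weights (g/mol) for species absent from the weight table (a warning
#'   lists them).
#' @return a `pathway_model` (unvalidated enzymes allowed: transport-like
#'   reactions without modifiers survive until [apply_exclusions()]).
#' @export
parse_sbml <- function(path, weights = NULL, default_kcat = NULL,
                       concentration_factor = 1,
                       default_weight_enzyme = 5e4,
                       default_weight_metabolite = 300) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in ", path, ": ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop("not an SBML document (root element <", root, ">)")

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")

  sid <- xml2::xml_attr(sp_nodes, "id")
  sname <- xml2::xml_attr(sp_nodes, "name")
  sname[is.na(sname)] <- sid[is.na(sname)]
  sconc <- suppressWarnings(as.numeric(
    xml2::xml_attr(sp_nodes, "initialConcentration")))

  # modifiers across all reactions define the enzyme set
  modifiers <- unique(xml2::xml_attr(
    xml2::xml_find_all(doc, ".//listOfModifiers/modifierSpeciesReference"),
    "species"))
  role <- ifelse(sid %in% modifiers, "enzyme", "metabolite")

  missing_enz_conc <- sid[role == "enzyme" & !is.finite(sconc)]
  if (length(missing_enz_conc))
    stop("enzyme species without an initial concentration: ",
         paste(missing_enz_conc, collapse = ", "),
         " (enzyme copy numbers are required to instantiate agents)")
  sconc[!is.finite(sconc)] <- 0
  sconc <- sconc * concentration_factor

  wtab <- .load_weight_table(weights)
  widx <- match(tolower(sid), tolower(wtab$id))
  nidx <- match(tolower(sname), tolower(wtab$id))
  widx[is.na(widx)] <- nidx[is.na(widx)]
  mw <- wtab$molecular_weight[widx]
  unknown <- is.na(mw)
  if (any(unknown)) {
    warning("no molecular weight for: ", paste(sid[unknown], collapse = ", "),
            "; using role-based defaults")
    mw[unknown] <- ifelse(role[unknown] == "enzyme",
                          default_weight_enzyme, default_weight_metabolite)
  }
  species <- data.frame(id = sid, name = sname, role = role,
                        molecular_weight = mw,
                        initial_concentration = sconc,
                        approx = unknown, stringsAsFactors = FALSE)

  reactions <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    rname <- xml2::xml_attr(node, "name")
    if (is.na(rname)) rname <- rid
    rev_attr <- xml2::xml_attr(node, "reversible")
    reversible <- is.na(rev_attr) || tolower(rev_attr) == "true"
    sub <- .sbml_stoich(node, "listOfReactants/speciesReference")
    prod <- .sbml_stoich(node, "listOfProducts/speciesReference")
    mods <- xml2::xml_attr(
      xml2::xml_find_all(node, "listOfModifiers/modifierSpeciesReference"),
      "species")
    enzyme <- if (length(mods)) mods[[1]] else NA_character_
    kcat <- .sbml_kcat(node)
    if (is.na(kcat)) {
      if (is.null(default_kcat))
        stop("reaction ", rid, " has no kcat parameter in its kinetic law; ",
             "supply default_kcat to proceed")
      kcat <- default_kcat
    }
    if (length(sub) == 0 || length(prod) == 0) return(NULL)
    reaction_spec(rid, enzyme, sub, prod, reversible = reversible,
                  kcat = kcat, name = rname)
  })
  reactions <- Filter(Negate(is.null), reactions)

  m <- pathway_model(species, reactions, provenance = basename(path),
                     validate = FALSE)
  validate_pathway_model(m, allow_missing_enzyme = TRUE)
  m
}

.sbml_stoich <- function(node, xpath) {
  refs <- xml2::xml_find_all(node, xpath)
  if (length(refs) == 0) return(integer(0))
  sp <- xml2::xml_attr(refs, "species")
  st <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
  st[is.na(st)] <- 1
  out <- as.integer(round(st))
  names(out) <- sp
  tapply(out, names(out), sum)[unique(sp)]
}

.sbml_kcat <- function(node) {
  pars <- xml2::xml_find_all(
    node, "kineticLaw//parameter | kineticLaw//localParameter")
  if (length(pars) == 0) return(NA_real_)
  pid <- tolower(xml2::xml_attr(pars, "id"))
  pnm <- tolower(xml2::xml_attr(pars, "name"))
  hit <- which(pid %in% c("kcat", "k_cat") | pnm %in% c("kcat", "k_cat"))
  if (length(hit) == 0) return(NA_real_)
  suppressWarnings(as.numeric(xml2::xml_attr(pars[hit[1]], "value")))
}

.load_weight_table <- function(weights = NULL) {
  path <- system.file("extdata", "molecular_weights.csv", package = "abmetab")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(weights)) {
    stopifnot(all(c("id", "molecular_weight") %in% names(weights)))
    keep <- !(tolower(tab$id) %in% tolower(weights$id))
    tab <- rbind(weights[, c("id", "molecular_weight")],
                 tab[keep, c("id", "molecular_weight")])
  }
  tab
}
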