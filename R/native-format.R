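#' Write a pathway model in the native structured format
#'
#' Versioned, human-readable XML: `<species>` entries carry weights (g/mol)
#' and initial concentrations (mmol/l), `<reaction>` entries carry the
#' catalysing isoenzyme, stoichiometry, reversibility and kcat (1/s), and
#' `<environment>` carries the volume.  A YAML mirror of the same schema is
#' produced when `path` ends in `.yaml`/`.yml`, which is convenient for
#' hand-written fixtures.
#'
#' @param model a `pathway_model`.
#' @param path output file (`.xml`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  validate_pathway_model(model, allow_missing_enzyme = TRUE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    return(.write_model_yaml(model, path))
  num <- function(x) formatC(x, digits = 17, format = "g")
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<pathway-model format-version="1" provenance="%s">',
            model$provenance),
    sprintf('  <environment volume="%s"/>', num(model$volume)),
    '  <species-list>')
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    lines <- c(lines, sprintf(
      '    <species id="%s" name="%s" role="%s" molecular-weight="%s" initial-concentration="%s" approx="%s"/>',
      s$id, s$name, s$role, num(s$molecular_weight),
      num(s$initial_concentration), tolower(s$approx)))
  }
  lines <- c(lines, '  </species-list>', '  <reaction-list>')
  for (r in model$reactions) {
    attrs <- sprintf('id="%s" name="%s" enzyme="%s" reversible="%s" kcat="%s"',
                     r$id, r$name, ifelse(is.na(r$enzyme), "", r$enzyme),
                     tolower(r$reversible), num(r$kcat))
    if (!is.null(r$kcat_reverse))
      attrs <- paste0(attrs, sprintf(' kcat-reverse="%s"', num(r$kcat_reverse)))
    lines <- c(lines, sprintf('    <reaction %s>', attrs))
    for (i in seq_along(r$substrates)) {
      km_attr <- ""
      if (!is.null(r$km) && names(r$substrates)[i] %in% names(r$km))
        km_attr <- sprintf(' km="%s"', num(r$km[[names(r$substrates)[i]]]))
      lines <- c(lines, sprintf(
        '      <substrate species="%s" stoichiometry="%d"%s/>',
        names(r$substrates)[i], as.integer(r$substrates[[i]]), km_attr))
    }
    for (i in seq_along(r$products))
      lines <- c(lines, sprintf(
        '      <product species="%s" stoichiometry="%d"/>',
        names(r$products)[i], as.integer(r$products[[i]])))
    lines <- c(lines, '    </reaction>')
  }
  lines <- c(lines, '  </reaction-list>', '</pathway-model>')
  writeLines(lines, path)
  invisible(path)
}

.write_model_yaml <- function(model, path) {
  obj <- list(
    format_version = 1L,
    provenance = model$provenance,
    environment = list(volume = model$volume),
    species = lapply(seq_len(nrow(model$species)), function(i) {
      s <- model$species[i, ]
      list(id = s$id, name = s$name, role = s$role,
           molecular_weight = s$molecular_weight,
           initial_concentration = s$initial_concentration,
           approx = s$approx)
    }),
    reactions = lapply(model$reactions, function(r) {
      out <- list(id = r$id, name = r$name, enzyme = r$enzyme,
                  reversible = r$reversible, kcat = r$kcat,
                  substrates = as.list(r$substrates),
                  products = as.list(r$products))
      if (!is.null(r$kcat_reverse)) out$kcat_reverse <- r$kcat_reverse
      if (!is.null(r$km)) out$km <- as.list(r$km)
      out
    }))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a pathway model from the native format
#'
#' Inverse of [write_model()]; `write_model()` then `read_model()` is the
#' identity.  Unknown schema versions and missing referenced species are
#' reported as errors with the offending element.
#'
#' @param path `.xml`, `.yaml` or `.yml` file.
#' @return a `pathway_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    return(.read_model_yaml(path))
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "pathway-model")
    stop("not a pathway-model file (root <", xml2::xml_name(doc), ">)")
  ver <- xml2::xml_attr(doc, "format-version")
  if (is.na(ver) || ver != "1")
    stop("unsupported pathway-model format version: ",
         ifelse(is.na(ver), "<missing>", ver))
  env <- xml2::xml_find_first(doc, "environment")
  volume <- as.numeric(xml2::xml_attr(env, "volume"))
  sp_nodes <- xml2::xml_find_all(doc, "species-list/species")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    role = xml2::xml_attr(sp_nodes, "role"),
    molecular_weight = as.numeric(xml2::xml_attr(sp_nodes, "molecular-weight")),
    initial_concentration =
      as.numeric(xml2::xml_attr(sp_nodes, "initial-concentration")),
    approx = tolower(xml2::xml_attr(sp_nodes, "approx")) == "true",
    stringsAsFactors = FALSE)
  rx_nodes <- xml2::xml_find_all(doc, "reaction-list/reaction")
  reactions <- lapply(rx_nodes, function(node) {
    enz <- xml2::xml_attr(node, "enzyme")
    if (!is.na(enz) && !nzchar(enz)) enz <- NA_character_
    subs <- xml2::xml_find_all(node, "substrate")
    prods <- xml2::xml_find_all(node, "product")
    if (length(subs) == 0 || length(prods) == 0)
      stop("reaction ", xml2::xml_attr(node, "id"),
           ": substrate and product lists must be non-empty")
    sub <- as.integer(xml2::xml_attr(subs, "stoichiometry"))
    names(sub) <- xml2::xml_attr(subs, "species")
    prod <- as.integer(xml2::xml_attr(prods, "stoichiometry"))
    names(prod) <- xml2::xml_attr(prods, "species")
    km_vals <- suppressWarnings(as.numeric(xml2::xml_attr(subs, "km")))
    km <- NULL
    if (any(!is.na(km_vals))) {
      km <- km_vals[!is.na(km_vals)]
      names(km) <- names(sub)[!is.na(km_vals)]
    }
    kr <- suppressWarnings(as.numeric(xml2::xml_attr(node, "kcat-reverse")))
    reaction_spec(
      id = xml2::xml_attr(node, "id"),
      enzyme = enz,
      substrates = sub, products = prod,
      reversible = tolower(xml2::xml_attr(node, "reversible")) == "true",
      kcat = as.numeric(xml2::xml_attr(node, "kcat")),
      kcat_reverse = if (is.na(kr)) NULL else kr,
      km = km,
      name = xml2::xml_attr(node, "name"))
  })
  m <- pathway_model(species, reactions, volume = volume,
                     provenance = xml2::xml_attr(doc, "provenance"),
                     validate = FALSE)
  validate_pathway_model(m, allow_missing_enzyme = TRUE)
  m
}

.read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$format_version) || obj$format_version != 1)
    stop("unsupported pathway-model format version: ",
         ifelse(is.null(obj$format_version), "<missing>", obj$format_version))
  species <- do.call(rbind, lapply(obj$species, function(s)
    data.frame(id = s$id, name = s$name, role = s$role,
               molecular_weight = s$molecular_weight,
               initial_concentration = s$initial_concentration,
               approx = isTRUE(s$approx), stringsAsFactors = FALSE)))
  reactions <- lapply(obj$reactions, function(r) {
    reaction_spec(
      id = r$id, enzyme = if (is.null(r$enzyme)) NA_character_ else r$enzyme,
      substrates = unlist(r$substrates), products = unlist(r$products),
      reversible = isTRUE(r$reversible), kcat = r$kcat,
      kcat_reverse = r$kcat_reverse,
      km = if (is.null(r$km)) NULL else unlist(r$km),
      name = if (is.null(r$name)) r$id else r$name)
  })
  m <- pathway_model(species, reactions, volume = obj$environment$volume,
                     provenance = obj$provenance, validate = FALSE)
  validate_pathway_model(m, allow_missing_enzyme = TRUE)
  m
}
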