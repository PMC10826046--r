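# Model serialization: a versioned JSON dialect and SBML Level 3 with the
# fbc flux-bounds/objective package.  Subsystem, organism and mass
# annotations ride in COBRA-style notes ("SUBSYSTEM: x") in SBML and as
# plain fields in JSON.  read(write(model)) is the identity on every field
# of the container; unknown top-level JSON fields are preserved opaquely.

JSON_FORMAT_NAME <- "community-flux-model"
JSON_FORMAT_VERSION <- 1L

#' Write a model to disk
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  model <- as_metabolic_model(model)
  if (format == "json") .write_model_json(model, path) else .write_model_sbml(model, path)
  invisible(path)
}

#' Read a model from disk
#'
#' @param path input file path.
#' @param format `"json"` or `"sbml"`; guessed from the extension.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "json") .read_model_json(path) else .read_model_sbml(path)
}

.write_model_json <- function(model, path) {
  rxns <- lapply(seq_len(nrow(model$reactions)), function(j) {
    col <- model$stoich[, j]
    nz <- which(abs(col) > 0)
    list(id = model$reactions$id[j],
         metabolites = as.list(stats::setNames(col[nz], rownames(model$stoich)[nz])),
         lower_bound = model$reactions$lb[j],
         upper_bound = model$reactions$ub[j],
         subsystem = model$reactions$subsystem[j],
         organism = model$reactions$organism[j])
  })
  obj <- c(list(format = JSON_FORMAT_NAME, version = JSON_FORMAT_VERSION,
                name = model$name,
                metabolites = model$metabolites,
                reactions = rxns,
                biomass = as.list(model$biomass_ids),
                exchanges = as.list(model$exchange_ids)),
           if (!is.null(model$masses)) list(masses = as.list(model$masses)),
           model$annotations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
}

.read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (!identical(obj$format, JSON_FORMAT_NAME)) {
    stop("not a ", JSON_FORMAT_NAME, " file: ", path)
  }
  if (!isTRUE(as.integer(obj$version) <= JSON_FORMAT_VERSION)) {
    stop("unsupported model format version: ", obj$version)
  }
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, compartment = m$compartment, name = m$name,
               stringsAsFactors = FALSE)))
  nr <- length(obj$reactions)
  rxns <- data.frame(
    id = vapply(obj$reactions, function(r) r$id, ""),
    lb = vapply(obj$reactions, function(r) as.numeric(r$lower_bound), 0),
    ub = vapply(obj$reactions, function(r) as.numeric(r$upper_bound), 0),
    subsystem = vapply(obj$reactions, function(r) r$subsystem %||% "", ""),
    organism = vapply(obj$reactions, function(r) {
      o <- r$organism
      if (is.null(o)) NA_character_ else as.character(o)
    }, ""),
    stringsAsFactors = FALSE)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (j in seq_len(nr)) {
    st <- unlist(obj$reactions[[j]]$metabolites)
    idx <- match(names(st), mets$id)
    if (anyNA(idx)) stop("reaction ", rxns$id[j], " references undeclared metabolite(s)")
    ti <- c(ti, idx); tj <- c(tj, rep(j, length(st))); tx <- c(tx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nrow(mets), nr),
                            dimnames = list(mets$id, rxns$id))
  biomass <- as.character(unlist(obj$biomass))
  if (!length(biomass)) warning("model has no biomass annotation")
  m <- metabolic_model(mets, rxns, S,
                       biomass_ids = biomass,
                       exchange_ids = as.character(unlist(obj$exchanges)),
                       masses = if (!is.null(obj$masses)) unlist(obj$masses),
                       name = obj$name %||% "model")
  known <- c("format", "version", "name", "metabolites", "reactions",
             "biomass", "exchanges", "masses")
  m$annotations <- obj[setdiff(names(obj), known)]
  m
}

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.note_block <- function(entries) {
  ps <- paste0("<p>", names(entries), ": ", unlist(entries), "</p>", collapse = "")
  paste0("<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">", ps, "</body></notes>")
}

.write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" xmlns:fbc=\"%s\" level=\"3\" version=\"1\" fbc:required=\"false\">",
            SBML_CORE_NS, SBML_FBC_NS),
    sprintf("<model id=\"%s\" fbc:strict=\"true\">", esc(model$name)),
    "<listOfCompartments>",
    sprintf("<compartment id=\"%s\" constant=\"true\"/>",
            unique(model$metabolites$compartment)),
    "</listOfCompartments>",
    "<listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    notes <- if (!is.null(model$masses))
      .note_block(list(MASS = model$masses[[model$metabolites$id[i]]])) else ""
    lines <- c(lines, sprintf(
      "<species id=\"%s\" name=\"%s\" compartment=\"%s\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" constant=\"false\">%s</species>",
      model$metabolites$id[i], esc(model$metabolites$name[i]),
      model$metabolites$compartment[i], notes))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  bnds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bnd_id <- function(v) sprintf("bnd_%d", match(v, bnds))
  lines <- c(lines,
             sprintf("<parameter id=\"%s\" value=\"%.17g\" constant=\"true\"/>",
                     bnd_id(bnds), bnds),
             "</listOfParameters>", "<listOfReactions>")
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    col <- model$stoich[, j]
    reac <- which(col < 0); prod <- which(col > 0)
    notes <- .note_block(list(SUBSYSTEM = r$subsystem,
                              ORGANISM = if (is.na(r$organism)) "" else r$organism))
    lines <- c(lines, sprintf(
      "<reaction id=\"%s\" reversible=\"%s\" fast=\"false\" fbc:lowerFluxBound=\"%s\" fbc:upperFluxBound=\"%s\">%s",
      r$id, tolower(r$lb < 0), bnd_id(r$lb), bnd_id(r$ub), notes))
    if (length(reac)) {
      lines <- c(lines, "<listOfReactants>",
                 sprintf("<speciesReference species=\"%s\" stoichiometry=\"%.17g\" constant=\"true\"/>",
                         rownames(model$stoich)[reac], -col[reac]),
                 "</listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "<listOfProducts>",
                 sprintf("<speciesReference species=\"%s\" stoichiometry=\"%.17g\" constant=\"true\"/>",
                         rownames(model$stoich)[prod], col[prod]),
                 "</listOfProducts>")
    }
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>")
  if (length(model$biomass_ids)) {
    lines <- c(lines,
      "<fbc:listOfObjectives fbc:activeObjective=\"obj\">",
      "<fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
      "<fbc:listOfFluxObjectives>",
      sprintf("<fbc:fluxObjective fbc:reaction=\"%s\" fbc:coefficient=\"1\"/>",
              model$biomass_ids),
      "</fbc:listOfFluxObjectives>", "</fbc:objective>", "</fbc:listOfObjectives>")
  }
  # exchange registry beyond the biomass objective: record explicitly
  lines <- c(lines, "</model>", "</sbml>")
  writeLines(lines, path)
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in ", path, ": ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_CORE_NS, fbc = SBML_FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  name <- xml2::xml_attr(model_node, "id")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  note_of <- function(node, key) {
    ps <- xml2::xml_text(xml2::xml_find_all(node, ".//s:notes//*[not(*)]", ns))
    hit <- grep(paste0("^", key, ": "), ps, value = TRUE)
    if (length(hit)) sub(paste0("^", key, ": "), "", hit[1]) else NA_character_
  }
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     name = xml2::xml_attr(sp, "name"),
                     stringsAsFactors = FALSE)
  mass_vals <- suppressWarnings(as.numeric(vapply(sp, note_of, "", key = "MASS")))
  masses <- if (!all(is.na(mass_vals))) stats::setNames(mass_vals, mets$id)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  nr <- length(rx)
  ids <- xml2::xml_attr(rx, "id")
  lb <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns)
  ub <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns)
  lbv <- ifelse(is.na(lb), -DEFAULT_BOUND, unname(parval[lb]))
  ubv <- ifelse(is.na(ub), DEFAULT_BOUND, unname(parval[ub]))
  subsys <- vapply(rx, note_of, "", key = "SUBSYSTEM")
  org <- vapply(rx, note_of, "", key = "ORGANISM")
  org[org == ""] <- NA_character_
  bad <- which(lbv > ubv)
  if (length(bad)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(ids[bad], collapse = ", "))
  }
  rxns <- data.frame(id = ids, lb = lbv, ub = ubv,
                     subsystem = ifelse(is.na(subsys), "", subsys),
                     organism = org, stringsAsFactors = FALSE)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (j in seq_len(nr)) {
    reac <- xml2::xml_find_all(rx[[j]], "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rx[[j]], "./s:listOfProducts/s:speciesReference", ns)
    add <- function(nodes, sign) {
      if (!length(nodes)) return()
      idx <- match(xml2::xml_attr(nodes, "species"), mets$id)
      ti <<- c(ti, idx); tj <<- c(tj, rep(j, length(idx)))
      tx <<- c(tx, sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")))
    }
    add(reac, -1); add(prod, 1)
  }
  S <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nrow(mets), nr),
                            dimnames = list(mets$id, ids))
  fo <- xml2::xml_find_all(doc, ".//fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  biomass <- unique(xml2::xml_attr(fo, "fbc:reaction", ns))
  if (!length(biomass)) warning("SBML file has no fbc objective; biomass_ids empty")
  # exchanges: boundary reactions touching exactly one species, excluding biomass
  nnz <- Matrix::colSums(S != 0)
  exchange <- ids[nnz == 1 & !(ids %in% biomass)]
  metabolic_model(mets, rxns, S, biomass_ids = biomass, exchange_ids = exchange,
                  masses = masses, name = if (is.na(name)) "model" else name)
}
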