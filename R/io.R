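#' Export a derived model as JSON
#'
#' Writes the dynamic species, the signed monomial rate terms (with rate
#' constant names) and the conservation laws with multiplicities.
#'
#' @param network a `ptm_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_model_json <- function(network, path) {
  laws <- split(network$laws[c("species", "multiplicity")],
                network$laws$law)
  obj <- list(
    n_reactions = network$n_reactions,
    partition = network$partition$blocks,
    species = network$species,
    terms = network$terms,
    conservation = unname(lapply(laws, function(l) {
      list(species = l$species, multiplicity = l$multiplicity)
    }))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a sweep as TSV
#'
#' One row per (grid value, replicate): the data behind a bistability
#' diagram.
#'
#' @param sweep a `ptm_sweep`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path) {
  tbl <- sweep$tbl
  out <- data.frame(grid_value = tbl$omega, replicate = tbl$replicate,
                    normalized_output = tbl$value, converged = tbl$converged)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a search trace as JSON lines
#'
#' One JSON record per accepted step, plus a `final` record.
#'
#' @param trace a `ptm_trace` from [run_search()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  tb <- trace$trace
  for (r in seq_len(nrow(tb))) {
    nu <- tb$nu[[r]]
    rec <- list(iteration = tb$iteration[r], partition = tb$partition[r],
                n_blocks = tb$n_blocks[r], score = tb$score[r],
                nu = if (is.null(nu)) NULL else
                  list(rates = as.list(nu$rates$values),
                       totals = nu$totals))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  writeLines(jsonlite::toJSON(
    list(final = trace$trace$partition[nrow(tb)], score = trace$score,
         termination = trace$termination, iterations = trace$iterations,
         evaluations = trace$evaluations),
    auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Export a derived model as SBML Level 3
#'
#' Writes one reversible binding reaction (`S + E <=> C`, mass-action with
#' forward constant `a` and reverse `d`) and one irreversible catalytic
#' reaction (`C -> P + E`, constant `k`) per PTM unit, on the merged
#' species. Intended for interoperability with SBML tooling; requires the
#' `xml2` package.
#'
#' @param network a `ptm_network` carrying rate constants.
#' @param path output file.
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path, model_id = "ptmnet_model") {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("SBML export requires the `xml2` package", call. = FALSE)
  }
  if (is.null(network$rates)) {
    stop("network carries no rate constants; rebuild with merge_network(p, rates)",
         call. = FALSE)
  }
  sid <- function(x) {
    x <- gsub("[^A-Za-z0-9]", "_", x)
    gsub("_+", "_", gsub("^_|_$", "", x))
  }
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = model_id)
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (sp in network$species) {
    xml2::xml_add_child(los, "species", id = sid(sp), name = sp,
                        compartment = "cell", initialConcentration = "0",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lop <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(network$rates$values)) {
    xml2::xml_add_child(lop, "parameter", id = nm,
                        value = format(network$rates$values[[nm]], digits = 17),
                        constant = "true")
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  rmap <- network$role_map
  add_ref <- function(parent, tag, species) {
    tab <- table(species)
    for (s in names(tab)) {
      xml2::xml_add_child(parent, tag, species = sid(s),
                          stoichiometry = as.character(tab[[s]]),
                          constant = "true")
    }
  }
  add_law <- function(rxn, mathtxt) {
    kl <- xml2::xml_add_child(rxn, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    apply_node <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(apply_node, "times")
    for (tok in mathtxt) xml2::xml_add_child(apply_node, "ci", tok)
  }
  for (i in seq_len(network$n_reactions)) {
    S <- rmap[[paste0("S", i)]]; E <- rmap[[paste0("E", i)]]
    C <- paste0("C", i); P <- rmap[[paste0("P", i)]]
    bind <- xml2::xml_add_child(lor, "reaction", id = paste0("binding_", i),
                                reversible = "true")
    add_ref(xml2::xml_add_child(bind, "listOfReactants"),
            "speciesReference", c(S, E))
    add_ref(xml2::xml_add_child(bind, "listOfProducts"),
            "speciesReference", C)
    add_law(bind, c(paste0("a", i), sid(S), sid(E)))
    cat_r <- xml2::xml_add_child(lor, "reaction", id = paste0("catalysis_", i),
                                 reversible = "false")
    add_ref(xml2::xml_add_child(cat_r, "listOfReactants"),
            "speciesReference", C)
    add_ref(xml2::xml_add_child(cat_r, "listOfProducts"),
            "speciesReference", c(P, E))
    add_law(cat_r, c(paste0("k", i), sid(C)))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
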