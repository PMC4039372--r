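# SBML Level 3 export/import of the reaction network.
#
# The writer emits species, global parameters (the rate constants plus the
# ambient light intensity as parameter "light"), and one reaction per
# elementary step with its kinetic law as MathML. The reader is restricted
# to the constructs the writer produces (times/plus/minus/divide/power over
# ci/cn), which covers mass-action and Hill laws; it reconstructs the
# parameter set by id and can evaluate the imported kinetic laws directly,
# so an export->import round trip reproduces the right-hand side exactly.

# kinetic laws as R-syntax formulas, one per reaction (the intensity is the
# global parameter `light`); kept in sync with .REACTIONS by a test that
# evaluates them against reaction_fluxes() on random states
.KINETIC_FORMULAS <- c(
  wcc_activation = "ka_wcc * light * WCC_d",
  wcc_adduct_decay = "kd_wcc * WCC_a",
  vvd_activation = "ka_vvd * light * VVD_d",
  vvd_adduct_decay = "kd_vvd * VVD_a",
  wcc_homodimerization = "kdim_wcc * WCC_a^2",
  wcc_homodimer_dissociation = "kundim_wcc * WCC_aa",
  wcc_homodimer_adduct_dissociation = "kpad_wcc * WCC_aa",
  vvd_homodimerization = "kdim_vvd * VVD_a^2",
  vvd_homodimer_dissociation = "kundim_vvd * VVD_aa",
  vvd_homodimer_adduct_dissociation = "kpad_vvd * VVD_aa",
  het_association = "l1 * WCC_a * VVD_a",
  het_dissociation = "lm1 * HET",
  het_adduct_decay_in_wcc = "l5 * HET",
  het_adduct_decay_in_vvd = "l5 * HET",
  tx_wc1_basal = "bas_wc1",
  tx_wc1_lre = "vmax_wc1 * WCC_aa^hill_lre / (K_wc1^hill_lre + WCC_aa^hill_lre)",
  tx_frq_lre = "vmax_frq * WCC_aa^hill_lre / (K_frq^hill_lre + WCC_aa^hill_lre)",
  tx_frq_cbox = "vc_frq * WCC_d^hill_cbox / (K_cbox^hill_cbox + WCC_d^hill_cbox)",
  tx_vvd_lre = "vmax_vvd * WCC_aa^hill_lre / (K_vvd^hill_lre + WCC_aa^hill_lre)",
  tx_vvd_basal = "bas_vvd",
  deg_m_wc1 = "dm_wc1 * m_wc1",
  deg_m_frq = "dm_frq * m_frq",
  deg_m_vvd = "dm_vvd * m_vvd",
  tl_wc1 = "ktl_wc1 * m_wc1",
  tl_frq = "ktl_frq * m_frq",
  tl_vvd = "ktl_vvd * m_vvd",
  deg_wcc_d = "dg_wcc_d * WCC_d",
  deg_wcc_a = "dg_wcc_a * WCC_a",
  deg_wcc_aa = "dg_wcc_aa * WCC_aa",
  deg_wcc_p = "dg_wcc_p * WCC_p",
  deg_het = "dg_het * HET",
  deg_vvd_d = "dg_vvd_d * VVD_d",
  deg_vvd_a = "dg_vvd_a * VVD_a",
  deg_vvd_aa = "dg_vvd_aa * VVD_aa",
  deg_frq_c = "dg_frq_c * FRQ_c",
  deg_frq_n = "dg_frq_n * FRQ_n",
  deg_frq_p = "dg_frq_p * FRQ_p",
  frq_nuclear_import = "kin_frq * FRQ_c",
  wcc_phosphorylation = "kph * FRQ_n * WCC_d / (K_ph + WCC_d)",
  wcc_dephosphorylation = "kdp * WCC_p / (1 + WCC_p / K_dp)",
  frq_phosphorylation = "kpf * FRQ_n")

.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"

# R expression -> MathML node (under parent), restricted operator set
.expr_to_mathml <- function(e, parent) {
  if (is.numeric(e)) {
    xml2::xml_add_child(parent, "cn", format(e, digits = 17))
  } else if (is.name(e)) {
    xml2::xml_add_child(parent, "ci", as.character(e))
  } else if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.expr_to_mathml(e[[2]], parent))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power",
                  stop("unsupported operator in kinetic law: ", op))
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, tag)
    for (k in 2:length(e)) .expr_to_mathml(e[[k]], ap)
    ap
  } else stop("unsupported kinetic-law construct: ", class(e))
}

# MathML node -> R-syntax string
.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(trimws(xml2::xml_text(node)))
  if (nm == "cn") return(trimws(xml2::xml_text(node)))
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    return(.mathml_to_expr(kids[[1]]))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- vapply(kids[-1], .mathml_to_expr, "")
    sym <- switch(op, plus = "+", minus = "-", times = "*",
                  divide = "/", power = "^",
                  stop("unsupported MathML operator: ", op))
    if (op == "minus" && length(args) == 1)
      return(paste0("(-", args, ")"))
    return(paste0("(", paste(args, collapse = paste0(" ", sym, " ")), ")"))
  }
  stop("unsupported MathML node: ", nm)
}

#' Export the model as SBML
#'
#' Writes an SBML Level 3 document with the 14 species, every rate
#' constant as a global parameter (plus the ambient light intensity as
#' parameter `light`), and one reaction per elementary step with its
#' kinetic law in MathML.
#'
#' @param params a `model_parameters` vector.
#' @param path output file.
#' @param initial_state named state vector used for initial amounts
#'   (default all-zero).
#' @param intensity value stored in the `light` parameter.
#' @param model_id SBML model id.
#' @return Invisibly, `path`.
#' @export
export_sbml <- function(params, path, initial_state = zero_state(),
                        intensity = 0,
                        model_id = "neurospora_photoadaptation") {
  params <- as_model_parameters(params)
  initial_state <- as_state(initial_state)
  doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS, level = "3",
                            version = "1")
  model <- xml2::xml_add_child(doc, "model", id = model_id)
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in .SPECIES)
    xml2::xml_add_child(sps, "species", id = s, compartment = "cell",
                        initialAmount = format(initial_state[[s]],
                                               digits = 17),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in .PARAM_NAMES)
    xml2::xml_add_child(pars, "parameter", id = nm,
                        value = format(params[[nm]], digits = 17),
                        constant = "true")
  xml2::xml_add_child(pars, "parameter", id = "light",
                      value = format(intensity, digits = 17),
                      constant = "false")
  rxns <- xml2::xml_add_child(model, "listOfReactions")
  S <- stoichiometry_matrix()
  for (r in reaction_names()) {
    rx <- xml2::xml_add_child(rxns, "reaction", id = r,
                              reversible = "false")
    st <- S[, r]
    if (any(st < 0)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in names(st)[st < 0])
        xml2::xml_add_child(lr, "speciesReference", species = s,
                            stoichiometry = format(-st[[s]]),
                            constant = "true")
    }
    if (any(st > 0)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in names(st)[st > 0])
        xml2::xml_add_child(lp, "speciesReference", species = s,
                            stoichiometry = format(st[[s]]),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = .MATHML_NS)
    .expr_to_mathml(str2lang(.KINETIC_FORMULAS[[r]]), math)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model from SBML
#'
#' Reads an SBML file written by [export_sbml()] (or any file restricted
#' to the same constructs) and returns the parameter set (matched by
#' parameter id), the initial state, the stoichiometry implied by the
#' reaction list, and the kinetic-law formulas.
#'
#' @param path SBML file.
#' @return List with `params` (a `model_parameters` vector), `intensity`,
#'   `initial_state`, `stoichiometry` (species x reactions matrix) and
#'   `kinetic_laws` (named character formulas in R syntax).
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pnodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- setNames(as.numeric(xml2::xml_attr(pnodes, "value")),
                    xml2::xml_attr(pnodes, "id"))
  intensity <- unname(pvals["light"])
  params <- as_model_parameters(pvals[setdiff(names(pvals), "light")])
  snodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  init <- setNames(as.numeric(xml2::xml_attr(snodes, "initialAmount")),
                   xml2::xml_attr(snodes, "id"))
  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ids <- xml2::xml_attr(rnodes, "id")
  species <- names(init)
  S <- matrix(0, nrow = length(species), ncol = length(ids),
              dimnames = list(species, ids))
  laws <- setNames(character(length(ids)), ids)
  for (k in seq_along(rnodes)) {
    rx <- rnodes[[k]]
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference"))
      S[xml2::xml_attr(sr, "species"), k] <-
        S[xml2::xml_attr(sr, "species"), k] -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference"))
      S[xml2::xml_attr(sr, "species"), k] <-
        S[xml2::xml_attr(sr, "species"), k] +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    math <- xml2::xml_find_first(rx, "./kineticLaw/math")
    laws[k] <- .mathml_to_expr(math)
  }
  list(params = params, intensity = intensity,
       initial_state = init[.SPECIES], stoichiometry = S,
       kinetic_laws = laws)
}

#' Evaluate the right-hand side of an imported SBML model
#'
#' Evaluates the imported kinetic laws at a state and light intensity and
#' applies the imported stoichiometry — an independent route to the time
#' derivative that is compared against [model_rhs()] in the test suite.
#'
#' @param imported result of [import_sbml()].
#' @param state named state vector.
#' @param intensity light intensity.
#' @return Named derivative vector.
#' @export
sbml_rhs <- function(imported, state, intensity) {
  env <- as.list(c(state, unclass(imported$params)))
  env$light <- intensity
  flux <- vapply(imported$kinetic_laws, function(f)
    eval(str2lang(f), envir = env), 0)
  drop(imported$stoichiometry %*% flux)
}
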