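#' Stoichiometric model container
#'
#' A \code{sm_model} bundles metabolites, reactions (with stoichiometry and
#' flux bounds in mmol/gDCW/h) and a biomass objective. Metabolite ids carry
#' a compartment suffix (\code{_c} cytosol, \code{_e} extracellular).
#' Exchange reactions touch a single extracellular metabolite and are
#' written in the export-positive convention (\code{"MET_e ->"}), so uptake
#' is a negative exchange flux.
#'
#' @param metabolites data frame with columns \code{id}, \code{name},
#'   \code{compartment}.
#' @param reactions data frame with columns \code{id}, \code{lb}, \code{ub},
#'   \code{subsystem}.
#' @param stoichiometry named list, one named numeric vector of signed
#'   coefficients per reaction id (negative = consumed).
#' @param objective_id reaction id maximized by \code{\link{solve_fba}}.
#' @return object of class \code{sm_model}.
#' @export
sm_model <- function(metabolites, reactions, stoichiometry, objective_id) {
  m <- structure(
    list(mets = tibble::as_tibble(metabolites),
         rxns = tibble::as_tibble(reactions),
         stoich = stoichiometry,
         objective_id = objective_id),
    class = "sm_model")
  m$rxns$is_exchange <- vapply(m$rxns$id, function(id)
    is_exchange_stoich(m$stoich[[id]], m$mets), logical(1))
  validate_model(m)
  m
}

is_exchange_stoich <- function(st, mets) {
  if (length(st) != 1L) return(FALSE)
  comp <- mets$compartment[match(names(st), mets$id)]
  identical(comp, "e")
}

#' @export
print.sm_model <- function(x, ...) {
  cat(sprintf("<sm_model> %d metabolites, %d reactions (%d exchanges)\n",
              nrow(x$mets), nrow(x$rxns), sum(x$rxns$is_exchange)))
  cat("objective:", x$objective_id, "\n")
  invisible(x)
}

#' Validate a stoichiometric model
#'
#' Checks id uniqueness, stoichiometry resolution, bound ordering, exchange
#' shape, objective resolution and closure of internal cofactor pairs
#' (NAD/NADH, ADP/ATP, MQ/MQH2 must not appear in any exchange reaction).
#' Errors describe the offending entry.
#'
#' @param model a \code{sm_model}.
#' @return the model, invisibly, if valid.
#' @export
validate_model <- function(model) {
  mets <- model$mets; rxns <- model$rxns
  if (nrow(rxns) == 0L) stop("model has no reactions")
  if (anyDuplicated(mets$id)) stop("duplicate metabolite id: ",
                                   mets$id[duplicated(mets$id)][1])
  if (anyDuplicated(rxns$id)) stop("duplicate reaction id: ",
                                   rxns$id[duplicated(rxns$id)][1])
  if (!all(mets$compartment %in% c("c", "e")))
    stop("compartment must be 'c' or 'e'")
  bad <- rxns$id[rxns$lb > rxns$ub]
  if (length(bad)) stop("lower bound exceeds upper bound in reaction ", bad[1])
  for (id in rxns$id) {
    st <- model$stoich[[id]]
    if (is.null(st) || length(st) == 0L)
      stop("empty stoichiometry in reaction ", id)
    missing <- setdiff(names(st), mets$id)
    if (length(missing))
      stop("reaction ", id, " references unknown metabolite ", missing[1])
  }
  if (!model$objective_id %in% rxns$id)
    stop("objective reaction not in model: ", model$objective_id)
  cof <- intersect(c("NAD_c", "NADH_c", "ADP_c", "ATP_c", "MQ_c", "MQH2_c"),
                   mets$id)
  for (id in rxns$id) {
    st <- model$stoich[[id]]
    if (!rxns$is_exchange[rxns$id == id] && length(st) > 1L) next
    hit <- intersect(names(st), cof)  # exchange or boundary drain
    if (length(hit))
      stop("internal cofactor ", hit[1],
           " appears in exchange/drain reaction ", id)
  }
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a \code{sm_model}.
#' @return dense matrix S (rows = metabolite ids, columns = reaction ids);
#'   S[i, j] is the signed coefficient of metabolite i in reaction j.
#' @export
s_matrix <- function(model) {
  S <- matrix(0, nrow(model$mets), nrow(model$rxns),
              dimnames = list(model$mets$id, model$rxns$id))
  for (id in model$rxns$id) {
    st <- model$stoich[[id]]
    S[names(st), id] <- st
  }
  S
}

## ---- reaction-equation grammar ------------------------------------------
## "1 PEP_c + 1 CO2_c + 1 ADP_c -> 1 OAA_c + 1 ATP_c"; coefficients
## optional; "->" irreversible, "<=>" reversible; "MET_e ->" exchange.

parse_equation <- function(eq, where = "") {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>"
           else if (grepl("->", eq, fixed = TRUE)) "->"
           else stop("equation missing '->' or '<=>'", where)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop("malformed equation", where)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (txt == "") return(numeric(0))
    if (grepl("^\\+", txt) || grepl("\\+$", txt))
      stop("dangling '+' in equation", where)
    st <- numeric(0)
    for (term in trimws(strsplit(txt, "+", fixed = TRUE)[[1]])) {
      if (term == "") stop("empty term in equation", where)
      toks <- strsplit(term, "\\s+")[[1]]
      if (length(toks) == 1L) { coef <- 1; met <- toks }
      else if (length(toks) == 2L) {
        coef <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(coef)) stop("bad coefficient '", toks[1], "'", where)
        met <- toks[2]
      } else stop("malformed term '", term, "'", where)
      if (!grepl("_[ce]$", met))
        stop("metabolite '", met, "' lacks _c/_e compartment suffix", where)
      st[met] <- (if (is.na(st[met])) 0 else st[met]) + sign * coef
    }
    st
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (is.na(st[m])) 0 else st[m]) + rhs[m]
  st <- st[st != 0]
  list(stoich = st, reversible = arrow == "<=>")
}

deparse_equation <- function(st, reversible) {
  side <- function(v) paste(sprintf("%g %s", abs(v), names(v)), collapse = " + ")
  lhs <- st[st < 0]; rhs <- st[st > 0]
  paste(if (length(lhs)) side(lhs) else "",
        if (reversible) "<=>" else "->",
        if (length(rhs)) side(rhs) else "") |> trimws()
}

#' Identify pure transport reactions
#'
#' A reaction is a pure transport step when every metabolite it touches is
#' translocated unchanged between compartments: each base species (id
#' without the compartment suffix) appears in more than one compartment
#' with coefficients summing to zero. Such reactions move material without
#' converting it, so they are not candidate enzymes for amplification.
#'
#' @param model a \code{sm_model}.
#' @param ids reaction ids (default: all).
#' @return named logical vector.
#' @export
is_transport_reaction <- function(model, ids = model$rxns$id) {
  vapply(ids, function(id) {
    st <- model$stoich[[id]]
    if (is.null(st)) stop("unknown reaction id: ", id)
    if (length(st) < 2L) return(FALSE)
    base <- sub("_[ce]$", "", names(st))
    comp <- sub("^.*_", "", names(st))
    all(vapply(unique(base), function(b) {
      i <- base == b
      length(unique(comp[i])) > 1L && abs(sum(st[i])) < 1e-12
    }, logical(1)))
  }, logical(1))
}

#' Add a reaction to a model
#'
#' @param model a \code{sm_model}.
#' @param id new unique reaction id.
#' @param equation reaction string in the TSV grammar; any new metabolites
#'   are added with the compartment implied by their suffix.
#' @param lb,ub flux bounds.
#' @param subsystem subsystem tag.
#' @return a new validated \code{sm_model}.
#' @export
add_reaction <- function(model, id, equation, lb, ub, subsystem = "") {
  if (id %in% model$rxns$id) stop("duplicate reaction id: ", id)
  p <- parse_equation(equation)
  new_mets <- setdiff(names(p$stoich), model$mets$id)
  if (length(new_mets))
    model$mets <- rbind(model$mets,
                        tibble::tibble(id = new_mets, name = new_mets,
                                       compartment = sub("^.*_", "", new_mets)))
  model$rxns <- rbind(model$rxns,
                      tibble::tibble(id = id, lb = lb, ub = ub,
                                     subsystem = subsystem,
                                     is_exchange = is_exchange_stoich(
                                       p$stoich, model$mets)))
  model$stoich[[id]] <- p$stoich
  validate_model(model)
  model
}

#' Read a stoichiometric model from TSV or minimal SBML
#'
#' The TSV dialect has columns \code{id}, \code{equation}, \code{lb},
#' \code{ub}, \code{subsystem}; metabolites and compartments are inferred
#' from the equations (suffix \code{_c}/\code{_e}). The SBML dialect reads a
#' minimal Level 3 subset: \code{listOfSpecies}, \code{listOfReactions} with
#' fbc flux bounds. Reversibility is encoded by \code{lb < 0}.
#'
#' @param path file path.
#' @param dialect "tsv" or "sbml".
#' @param objective_id objective reaction id; defaults to a reaction whose
#'   id contains "BIOMASS" (case-insensitive), else the last reaction.
#' @return validated \code{sm_model}.
#' @examples
#' m <- load_model_table(system.file("extdata", "toy_reductive_tca.tsv",
#'                                   package = "succinoflux"))
#' solve_fba(m)
#' @export
load_model_table <- function(path, dialect = c("tsv", "sbml"),
                             objective_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "sbml") return(load_model_sbml(path, objective_id))
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "equation", "lb", "ub", "subsystem")
  if (!all(need %in% names(tab)))
    stop("model TSV must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$id)) stop("duplicate reaction id: ",
                                  tab$id[duplicated(tab$id)][1])
  stoich <- list()
  for (i in seq_len(nrow(tab))) {
    p <- tryCatch(parse_equation(tab$equation[i],
                                 sprintf(" (row %d, reaction %s)", i, tab$id[i])),
                  error = function(e) stop("format error: ", conditionMessage(e),
                                           call. = FALSE))
    stoich[[tab$id[i]]] <- p$stoich
  }
  met_ids <- sort(unique(unlist(lapply(stoich, names))))
  mets <- tibble::tibble(id = met_ids, name = met_ids,
                         compartment = sub("^.*_", "", met_ids))
  if (is.null(objective_id)) {
    hit <- grep("BIOMASS", tab$id, ignore.case = TRUE, value = TRUE)
    objective_id <- if (length(hit)) hit[1] else tab$id[nrow(tab)]
  }
  sm_model(mets,
           tibble::tibble(id = tab$id, lb = as.numeric(tab$lb),
                          ub = as.numeric(tab$ub), subsystem = tab$subsystem),
           stoich, objective_id)
}

load_model_sbml <- function(path, objective_id = NULL) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"))
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pv <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                        xml2::xml_attr(params, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ids <- xml2::xml_attr(rx, "id")
  stoich <- list(); lb <- ub <- numeric(length(rx)); subsys <- character(length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    st <- numeric(0)
    for (node in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(node, "species")
      st[s] <- (if (is.na(st[s])) 0 else st[s]) -
        as.numeric(xml2::xml_attr(node, "stoichiometry"))
    }
    for (node in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(node, "species")
      st[s] <- (if (is.na(st[s])) 0 else st[s]) +
        as.numeric(xml2::xml_attr(node, "stoichiometry"))
    }
    stoich[[ids[i]]] <- st
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    lb[i] <- if (!is.na(lbp) && lbp %in% names(pv)) pv[[lbp]]
             else if (identical(xml2::xml_attr(r, "reversible"), "true")) -1000 else 0
    ub[i] <- if (!is.na(ubp) && ubp %in% names(pv)) pv[[ubp]] else 1000
    subsys[i] <- ""
  }
  if (is.null(objective_id)) {
    fo <- xml2::xml_find_first(doc, ".//listOfFluxObjectives/fluxObjective")
    objective_id <- if (!inherits(fo, "xml_missing")) xml2::xml_attr(fo, "reaction")
                    else {
                      hit <- grep("BIOMASS", ids, ignore.case = TRUE, value = TRUE)
                      if (length(hit)) hit[1] else ids[length(ids)]
                    }
  }
  sm_model(mets, tibble::tibble(id = ids, lb = lb, ub = ub, subsystem = subsys),
           stoich, objective_id)
}

#' Write a stoichiometric model as TSV
#'
#' Inverse of \code{\link{load_model_table}} for the TSV dialect:
#' \code{load_model_table(write_model_table(m))} reproduces ids,
#' stoichiometries and bounds exactly.
#'
#' @param model a valid \code{sm_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_table <- function(model, path) {
  validate_model(model)
  eqs <- vapply(model$rxns$id, function(id)
    deparse_equation(model$stoich[[id]], model$rxns$lb[model$rxns$id == id] < 0),
    character(1))
  tab <- data.frame(id = model$rxns$id, equation = eqs,
                    lb = model$rxns$lb, ub = model$rxns$ub,
                    subsystem = model$rxns$subsystem)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
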