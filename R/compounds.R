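#' Load a compound registry
#'
#' Parses a YAML compound registry into a named list of `compound_model`
#' objects. With no arguments the built-in seven-compound registry is
#' returned: the four parents (irinotecan, 5-FU, oxaliplatin, leucovorin)
#' and the three tracked active metabolites (SN-38, FUH2, folitixorin).
#'
#' @param path YAML file; `NULL` for the built-in registry.
#' @param warn emit validation warnings for unit-suspicious entries
#'   (default TRUE).
#' @return Named list of `compound_model` objects.
#' @export
load_compound_registry <- function(path = NULL, warn = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "compound_registry.yaml",
                        package = "colonpbpk", mustWork = TRUE)
  }
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw$compounds)) stop("registry has no 'compounds' key")
  out <- lapply(raw$compounds, as_compound_model)
  names(out) <- vapply(out, function(x) x$id, character(1))
  for (cmp in out) {
    findings <- validate_compound(cmp, registry = out)
    errs <- findings[findings$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0) {
      stop(sprintf("compound '%s': %s", cmp$id,
                   paste(errs$message, collapse = "; ")), call. = FALSE)
    }
    if (warn) {
      for (m in findings$message[findings$severity == "warning"]) {
        warning(sprintf("compound '%s': %s", cmp$id, m), call. = FALSE)
      }
    }
  }
  out
}

# clearance fields carrying value + unit (+ optional site)
.CL_FIELDS <- c("renal_clearance", "biliary_clearance",
                "enzymatic_clearance", "total_clearance")

as_compound_model <- function(x) {
  for (f in c("id", "name", "role")) {
    if (is.null(x[[f]])) abort_field(f, "missing mandatory field")
  }
  pc <- x$physchem
  for (f in c("molecular_weight", "logP", "solubility", "fraction_unbound")) {
    if (is.null(pc[[f]])) {
      abort_field(paste0(x$id, ".physchem.", f), "missing mandatory field")
    }
  }
  structure(list(
    id = x$id, name = x$name, role = x$role,
    physchem = pc,
    disposition = x$disposition,
    links = x$links %||% list()
  ), class = "compound_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a compound model
#'
#' Reports invariant violations and unit-suspicious entries as a findings
#' table; it never throws. Severity `"error"` marks genuine invariant
#' violations (non-positive molecular weight, unbound fraction outside
#' (0, 1], negative clearances, a Michaelis-Menten link without Km/Vmax on
#' the parent, no elimination route); severity `"warning"` marks values
#' carried as printed but flagged as suspicious (per-kg clearances too large
#' to be plasma clearances, mg/L solubility, a malformed printed logP).
#'
#' @param compound a `compound_model`.
#' @param registry optional registry list, used to check link targets.
#' @return data.frame with columns `severity`, `field`, `message`
#'   (zero rows when everything is clean).
#' @export
validate_compound <- function(compound, registry = NULL) {
  f <- list()
  add <- function(severity, field, message) {
    f[[length(f) + 1L]] <<- data.frame(severity = severity, field = field,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  pc <- compound$physchem
  if (!is.numeric(pc$molecular_weight) || pc$molecular_weight <= 0) {
    add("error", "molecular_weight", "molecular weight must be > 0")
  }
  fu <- pc$fraction_unbound
  if (!is.numeric(fu) || fu <= 0 || fu > 1) {
    add("error", "fraction_unbound", "fraction unbound must be in (0, 1]")
  }
  if (!is.null(pc$solubility$value) && pc$solubility$value < 0) {
    add("error", "solubility", "solubility must be >= 0")
  }
  if (identical(pc$solubility$unit, "mg/L")) {
    add("warning", "solubility",
        "solubility unit is mg/L while other entries use mg/mL; carried as printed")
  }
  if (!is.null(pc$logP_printed)) {
    add("warning", "logP",
        sprintf("printed lipophilicity '%s' is malformed; using %s",
                pc$logP_printed, format(pc$logP)))
  }
  dp <- compound$disposition
  n_routes <- 0L
  for (fld in .CL_FIELDS) {
    entry <- dp[[fld]]
    if (is.null(entry)) next
    n_routes <- n_routes + 1L
    if (!is.numeric(entry$value) || entry$value < 0) {
      add("error", fld, sprintf("%s must be >= 0", fld))
    } else if (grepl("/kg", entry$unit, ignore.case = TRUE) &&
               grepl("mL/min", entry$unit, ignore.case = TRUE) &&
               entry$value > 50) {
      add("warning", fld,
          sprintf("%s of %g mL/min/kg is implausibly large for a plasma clearance; used as printed",
                  fld, entry$value))
    }
  }
  if (n_routes == 0L && length(compound$links) == 0L) {
    add("error", "disposition", "compound has no elimination route")
  }
  for (lk in compound$links) {
    if (compound$role == "metabolite") {
      add("error", "links", "metabolites must not carry onward metabolic links")
    }
    fc <- lk$fraction_converted
    if (!is.numeric(fc) || fc < 0 || fc > 1) {
      add("error", "links", "fraction_converted must be in [0, 1]")
    }
    if (identical(lk$kinetics, "michaelis_menten") &&
        (is.null(dp$km) || is.null(dp$vmax))) {
      add("error", "links",
          "michaelis_menten link requires km and vmax on the parent")
    }
    if (!is.null(registry) && is.null(registry[[lk$metabolite]])) {
      add("error", "links",
          sprintf("link target '%s' not in registry", lk$metabolite))
    }
  }
  if (length(f) == 0L) {
    return(data.frame(severity = character(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, f)
}

#' Write a compound registry to YAML
#'
#' Inverse of [load_compound_registry()]; numeric values survive a
#' write/read round trip bit-exactly.
#'
#' @param registry named list of `compound_model` objects.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_compound_registry <- function(registry, path) {
  strip <- function(cmp) {
    out <- unclass(cmp)
    if (length(out$links) == 0L) out$links <- NULL
    out
  }
  yaml::write_yaml(list(compounds = lapply(unname(registry), strip)), path,
                   precision = 15)
  invisible(path)
}

#' Absolute clearances of a compound for one individual
#'
#' Converts the printed clearance entries to absolute L/min for a given body
#' weight: per-kg entries (mL/min/kg, L/h/kg) scale with weight, absolute
#' entries (mL/min, L/h) do not. Elimination-variability multipliers are
#' applied per route.
#'
#' @param compound a `compound_model`.
#' @param weight body weight, kg.
#' @param multipliers named multipliers
#'   (`renal`, `biliary`, `enzymatic`, `total`), default all 1.
#' @return List with `renal`, `biliary`, `enzymatic`, `total` (L/min; 0 when
#'   absent), `total_site` (`"liver"`/`"kidney"`/NA), and `km_umol_L`,
#'   `vmax_printed` for the Michaelis-Menten entries (NA when absent).
#' @export
compound_clearances <- function(compound, weight,
                                multipliers = c(renal = 1, biliary = 1,
                                                enzymatic = 1, total = 1)) {
  dp <- compound$disposition
  cl <- function(entry) {
    if (is.null(entry)) return(0)
    u <- tolower(entry$unit)
    switch(u,
           "ml/min/kg" = entry$value * weight / 1000,
           "ml/min"    = entry$value / 1000,
           "l/h"       = entry$value / 60,
           "l/h/kg"    = entry$value * weight / 60,
           "l/min"     = entry$value,
           stop(sprintf("unknown clearance unit '%s'", entry$unit)))
  }
  m <- function(route) if (route %in% names(multipliers)) multipliers[[route]] else 1
  list(
    renal = cl(dp$renal_clearance) * m("renal"),
    biliary = cl(dp$biliary_clearance) * m("biliary"),
    enzymatic = cl(dp$enzymatic_clearance) * m("enzymatic"),
    total = cl(dp$total_clearance) * m("total"),
    total_site = dp$total_clearance$site %||% NA_character_,
    km_umol_L = dp$km$value %||% NA_real_,   # nmol/mL == umol/L
    vmax_printed = dp$vmax$value %||% NA_real_,
    vmax_multiplier = m("enzymatic")
  )
}

#' Make an ad-hoc compound model
#'
#' Convenience constructor for reduced test systems and synthetic studies.
#'
#' @param id,name identifiers.
#' @param molecular_weight g/mol.
#' @param logP octanol-water log partition coefficient.
#' @param pKa,pKa_type optional ionisation constant and type
#'   (`"acid"`/`"base"`).
#' @param fraction_unbound plasma unbound fraction in (0, 1].
#' @param solubility,solubility_unit reference solubility.
#' @param renal_clearance,biliary_clearance,enzymatic_clearance,total_clearance
#'   optional `list(value=, unit=)` entries (total may carry `site`).
#' @param links optional list of metabolic links.
#' @param role `"parent"` or `"metabolite"`.
#' @return A `compound_model`.
#' @export
compound_model <- function(id, name = id, molecular_weight, logP,
                           pKa = NULL, pKa_type = "base",
                           fraction_unbound = 1,
                           solubility = 1, solubility_unit = "mg/mL",
                           renal_clearance = NULL, biliary_clearance = NULL,
                           enzymatic_clearance = NULL, total_clearance = NULL,
                           links = list(), role = "parent") {
  pk <- if (is.null(pKa)) NULL else list(value = pKa, type = pKa_type)
  structure(list(
    id = id, name = name, role = role,
    physchem = list(molecular_weight = molecular_weight, logP = logP,
                    pKa = pk,
                    solubility = list(value = solubility,
                                      unit = solubility_unit),
                    fraction_unbound = fraction_unbound),
    disposition = Filter(Negate(is.null),
                         list(renal_clearance = renal_clearance,
                              biliary_clearance = biliary_clearance,
                              enzymatic_clearance = enzymatic_clearance,
                              total_clearance = total_clearance)),
    links = links
  ), class = "compound_model")
}
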