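#' Compound specification (name and molecular weight)
#'
#' @param name Compound label.
#' @param molecular_weight Formula weight, g/mol (> 0).
#' @return A \code{compound_spec} object.
#' @export
compound_spec <- function(name, molecular_weight) {
  if (!is.numeric(molecular_weight) || !is.finite(molecular_weight) ||
      molecular_weight <= 0) {
    stop("compound_spec: molecular_weight must be > 0")
  }
  structure(list(name = as.character(name),
                 molecular_weight = molecular_weight),
            class = "compound_spec")
}

#' Built-in compound registry
#'
#' Reads the editable registry bundled at
#' \code{system.file("extdata", "compounds.csv", package = "pyrekin")}:
#' formula weights for the compounds of the pyrene/2,2'-diphenic acid (DIPA)
#' system. Pass \code{path} to use a custom registry of the same two-column
#' format (\code{name,molecular_weight}).
#'
#' @param name Optional compound name; if given, returns its
#'   \code{\link{compound_spec}} directly.
#' @param path Optional path to an alternative registry CSV.
#' @return A named list of \code{compound_spec}s, or a single spec.
#' @examples
#' compound_registry("pyrene")$molecular_weight # 202.25
#' @export
compound_registry <- function(name = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compounds.csv", package = "pyrekin")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  specs <- stats::setNames(
    lapply(seq_len(nrow(tab)),
           function(i) compound_spec(tab$name[i], tab$molecular_weight[i])),
    tab$name
  )
  if (is.null(name)) return(specs)
  if (!name %in% names(specs)) {
    stop("compound_registry: unknown compound '", name, "'; registry has: ",
         paste(names(specs), collapse = ", "))
  }
  specs[[name]]
}

.as_compound <- function(x) {
  if (inherits(x, "compound_spec")) return(x)
  if (is.character(x) && length(x) == 1) return(compound_registry(x))
  stop("expected a compound_spec or a registered compound name")
}

#' Convert a mass concentration to a molar concentration
#'
#' @param conc Concentration in mg/L (>= 0).
#' @param compound A \code{\link{compound_spec}} or registered name.
#' @return Concentration in mmol/L (\code{conc / molecular_weight}).
#' @export
mass_to_molar <- function(conc, compound) {
  compound <- .as_compound(compound)
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0)) {
    stop("mass_to_molar: conc must be >= 0")
  }
  conc / compound$molecular_weight
}

#' Molar yield of an intermediate from a degraded parent
#'
#' Percentage of the depleted parent (on a mole basis) that is present as
#' the intermediate:
#' \code{100 * (intermediate_formed/MW_int) / (parent_degraded/MW_parent)}.
#'
#' @param intermediate_formed Intermediate accumulated, mg/L (>= 0).
#' @param intermediate_cmpd \code{\link{compound_spec}} (or name) of the
#'   intermediate.
#' @param parent_degraded Parent depleted, mg/L (> 0).
#' @param parent_cmpd \code{\link{compound_spec}} (or name) of the parent.
#' @return Molar yield, percent.
#' @examples
#' # 23.0 mg/L DIPA accumulated while 47.3 mg/L pyrene was degraded:
#' molar_yield_percent(23.0, "DIPA", 47.3, "pyrene") # ~40.6
#' @export
molar_yield_percent <- function(intermediate_formed, intermediate_cmpd,
                                parent_degraded, parent_cmpd) {
  if (!is.numeric(parent_degraded) || any(!is.finite(parent_degraded)) ||
      any(parent_degraded <= 0)) {
    stop("molar_yield_percent: parent_degraded must be > 0")
  }
  100 * mass_to_molar(intermediate_formed, intermediate_cmpd) /
    mass_to_molar(parent_degraded, parent_cmpd)
}

#' Per-time-point molar yield over a time course
#'
#' For each sampling time, the molar yield of the intermediate formed since
#' time zero, \code{P(t) - P(0)}, against the parent degraded since time
#' zero, \code{S(0) - S(t)}, using per-time replicate means. Time points
#' where the parent depletion is not positive (including t = 0) are flagged
#' undefined (\code{NA} yield).
#'
#' @param data A \code{\link{time_course_data}} with a t = 0 parent
#'   observation.
#' @param parent_cmpd,intermediate_cmpd Compound specs or registered names.
#' @return data.frame with \code{time}, \code{parent_degraded},
#'   \code{intermediate_formed} (mg/L, replicate means), \code{yield_percent}
#'   (NA where undefined) and \code{defined}.
#' @export
timecourse_molar_yield <- function(data, parent_cmpd = "pyrene",
                                   intermediate_cmpd = "DIPA") {
  data <- time_course_data(as.data.frame(data))
  df <- as.data.frame(data)[!data$below_lod, , drop = FALSE]
  mean_at <- function(cmp) {
    sub <- df[df$compound == cmp, , drop = FALSE]
    stats::aggregate(conc ~ time, data = sub, FUN = mean)
  }
  par_m <- mean_at("parent")
  if (!any(par_m$time == 0)) {
    stop("timecourse_molar_yield: no t = 0 parent observation")
  }
  int_m <- mean_at("intermediate")
  S0 <- par_m$conc[par_m$time == 0]
  P0 <- if (any(int_m$time == 0)) int_m$conc[int_m$time == 0] else 0
  times <- sort(intersect(par_m$time, int_m$time))
  dep <- S0 - par_m$conc[match(times, par_m$time)]
  formed <- int_m$conc[match(times, int_m$time)] - P0
  defined <- dep > 0
  yield <- rep(NA_real_, length(times))
  yield[defined] <- molar_yield_percent(pmax(formed[defined], 0),
                                        intermediate_cmpd,
                                        dep[defined], parent_cmpd)
  data.frame(time = times, parent_degraded = dep,
             intermediate_formed = formed,
             yield_percent = yield, defined = defined)
}
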