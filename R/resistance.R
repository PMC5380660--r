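#' Decompose wall hydraulic resistance into medial and intimal parts
#'
#' The arterial wall layers lie in series, so total wall resistance is the
#' reciprocal of the measured hydraulic conductance, `R_WALL = 1 / Lp`; the
#' medial contribution follows from the radial medial permeability and
#' medial thickness, `R_MED = mu * T / K11`; and the intimal contribution
#' is the remainder, `R_INT = R_WALL - R_MED`.  A negative `R_INT`
#' (medial resistance exceeding the whole wall's) is physically
#' inconsistent; it is reported with a warning rather than clamped, so that
#' inconsistent inputs stay visible.
#'
#' @param lp Hydraulic conductance, m s^-1 Pa^-1 (> 0).  Vectorised.
#' @param thickness_um Medial thickness in micrometres (> 0).
#' @param k11 Radial medial permeability, m^2 (> 0).
#' @param viscosity_mu Dynamic viscosity, Pa s.
#' @return A data frame of class `"layer_resistances"` with `r_wall`,
#'   `r_med`, `r_int` (Pa s m^-1), `frac_med` and `frac_int` (fractions of
#'   `r_wall`; they sum to 1 exactly).
#' @export
decompose_resistance <- function(lp, thickness_um, k11,
                                 viscosity_mu = 6.913e-4) {
  if (any(!is.finite(lp)) || any(lp <= 0)) stop("`lp` must be positive")
  if (any(!is.finite(thickness_um)) || any(thickness_um <= 0))
    stop("`thickness_um` must be positive")
  if (any(!is.finite(k11)) || any(k11 <= 0)) stop("`k11` must be positive")
  if (!(viscosity_mu > 0)) stop("`viscosity_mu` must be positive")
  r_wall <- 1 / lp
  r_med <- viscosity_mu * (thickness_um * 1e-6) / k11
  r_int <- r_wall - r_med
  if (any(r_int < 0))
    warning("R_MED exceeds R_WALL for ", sum(r_int < 0), " record(s): ",
            "negative intimal resistance implies inconsistent inputs")
  out <- data.frame(r_wall = r_wall, r_med = r_med, r_int = r_int,
                    frac_med = r_med / r_wall, frac_int = r_int / r_wall)
  class(out) <- c("layer_resistances", "data.frame")
  out
}

#' Group means, SEMs and two-sample t-tests for specimen records
#'
#' Summarises each requested quantity per condition (mean and standard
#' error of the mean, SEM = sd / sqrt(n)) and compares the two conditions
#' with a two-sided t-test: paired when every specimen id appears in both
#' conditions, otherwise a classical (equal-variance) unpaired Student
#' test by default.
#'
#' @param records Data frame with a condition column, optionally an id
#'   column, and the quantity columns.
#' @param quantities Character vector of column names to summarise.
#' @param condition_col,id_col Column names.
#' @param test `"auto"`, `"paired"` or `"unpaired"`.
#' @param var_equal Classical Student test (`TRUE`, default) or Welch.
#' @return Object of class `"group_summary"`: `summary` (quantity,
#'   condition, n, mean, sem) and `tests` (quantity, method, p_value,
#'   mean difference and its direction).
#' @export
summarize_groups <- function(records, quantities,
                             condition_col = "condition",
                             id_col = "specimen_id",
                             test = c("auto", "paired", "unpaired"),
                             var_equal = TRUE) {
  test <- match.arg(test)
  stopifnot(is.data.frame(records), condition_col %in% names(records))
  missing_q <- setdiff(quantities, names(records))
  if (length(missing_q))
    stop("quantities not in `records`: ", paste(missing_q, collapse = ", "))
  conds <- unique(as.character(records[[condition_col]]))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summ <- do.call(rbind, lapply(quantities, function(q) {
    do.call(rbind, lapply(conds, function(cc) {
      x <- records[[q]][records[[condition_col]] == cc]
      data.frame(quantity = q, condition = cc, n = length(x),
                 mean = mean(x), sem = sem(x))
    }))
  }))
  tests <- NULL
  if (length(conds) == 2L) {
    ids1 <- records[[id_col]][records[[condition_col]] == conds[1]]
    ids2 <- records[[id_col]][records[[condition_col]] == conds[2]]
    can_pair <- !is.null(ids1) && length(ids1) == length(ids2) &&
      setequal(ids1, ids2) && !anyDuplicated(ids1)
    paired <- switch(test,
      auto = can_pair,
      paired = {
        if (!can_pair)
          stop("paired test requested but specimen ids do not match ",
               "one-to-one across conditions")
        TRUE
      },
      unpaired = FALSE)
    tests <- do.call(rbind, lapply(quantities, function(q) {
      d1 <- records[records[[condition_col]] == conds[1], ]
      d2 <- records[records[[condition_col]] == conds[2], ]
      tt <- tryCatch({
        if (paired) {
          d1 <- d1[order(d1[[id_col]]), ]
          d2 <- d2[order(d2[[id_col]]), ]
          stats::t.test(d1[[q]], d2[[q]], paired = TRUE)
        } else {
          stats::t.test(d1[[q]], d2[[q]], var.equal = var_equal)
        }
      }, error = function(e) NULL)   # e.g. zero-variance groups
      diff <- mean(d2[[q]]) - mean(d1[[q]])
      data.frame(quantity = q,
                 method = if (is.null(tt)) "t-test not computed" else
                   if (paired) "paired t-test" else
                   if (var_equal) "unpaired t-test (Student)" else
                     "unpaired t-test (Welch)",
                 p_value = if (is.null(tt)) NA_real_ else tt$p.value,
                 difference = diff,
                 direction = paste0(conds[2], ifelse(diff >= 0, " > ", " < "),
                                    conds[1]))
    }))
  }
  structure(list(summary = summ, tests = tests), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary>\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Sensitivity of the resistance decomposition to the assumed ECM permeability
#'
#' All simulations share one literature value of `k_ECM`; this check
#' rescales it and reports how the medial/intimal split of wall resistance
#' responds.  Because the Brinkman problem is linear in `k_ECM` at fixed
#' geometry (up to penalty effects), the default rule scales `K11`
#' proportionally; alternatively a `resolve_fun` may re-run the solver.
#'
#' @param records Data frame with columns `condition`, `lp`,
#'   `thickness_um` and `k11_m2`.
#' @param viscosity_mu Dynamic viscosity, Pa s.
#' @param scalings Numeric vector of `k_ECM` multipliers.
#' @param rescale_rule `"proportional"` or `"resolve"`.
#' @param resolve_fun For `"resolve"`: `function(record, scaling)`
#'   returning the re-solved `K11` in m^2.
#' @return Data frame: one row per scaling x condition with group-mean
#'   medial and intimal fractions of wall resistance.
#' @export
kecm_sensitivity <- function(records, viscosity_mu = 6.913e-4,
                             scalings = c(0.8, 1, 1.2),
                             rescale_rule = c("proportional", "resolve"),
                             resolve_fun = NULL) {
  rescale_rule <- match.arg(rescale_rule)
  stopifnot(all(c("condition", "lp", "thickness_um", "k11_m2") %in%
                names(records)))
  if (rescale_rule == "resolve" && !is.function(resolve_fun))
    stop('`resolve_fun` is required when rescale_rule = "resolve"')
  do.call(rbind, lapply(scalings, function(s) {
    k11s <- if (rescale_rule == "proportional") records$k11_m2 * s
            else vapply(seq_len(nrow(records)),
                        function(i) resolve_fun(records[i, ], s), numeric(1))
    dec <- decompose_resistance(records$lp, records$thickness_um, k11s,
                                viscosity_mu)
    agg <- stats::aggregate(cbind(frac_med, frac_int) ~ condition,
                            data = cbind(records["condition"], dec),
                            FUN = mean)
    data.frame(scaling = s, agg)
  }))
}

#' Published per-block permeability and geometry summary tables
#'
#' Loads the packaged fixture of printed study results: per-block radial
#' medial permeability for the baseline (n = 5 blocks) and constricted
#' (n = 4) groups, and group summaries of ECM volume fraction and medial
#' thickness.  The permeability table is printed without units in the
#' source; values are interpreted here on the 1e-18 m^2 scale of the
#' assumed ECM permeability, and that inference is flagged by the
#' `units_note` attribute.
#'
#' @return List with data frames `permeability` (condition, block, k11) and
#'   `geometry` (quantity, condition, mean, sem, n).
#' @export
load_published_tables <- function() {
  perm <- utils::read.csv(system.file("extdata",
                                      "published_permeability_blocks.csv",
                                      package = "mediaperm", mustWork = TRUE))
  geom <- utils::read.csv(system.file("extdata", "published_geometry.csv",
                                      package = "mediaperm", mustWork = TRUE))
  out <- list(permeability = perm, geometry = geom)
  attr(out, "units_note") <-
    "k11 printed without units; interpreted on the 1e-18 m^2 scale"
  out
}

#' Demo specimen table with synthetic conductance values
#'
#' Hydraulic conductances were not tabulated per specimen in the source
#' study, so this demo table pairs the published per-block permeabilities
#' with synthetic but physiologically plausible `Lp` and thickness values;
#' it exists to exercise the resistance decomposition, and no quantitative
#' result depends on it.
#'
#' @return Data frame: specimen_id, condition, lp, thickness_um, k11_m2.
#' @export
load_demo_specimens <- function() {
  utils::read.csv(system.file("extdata", "demo_specimens_synthetic.csv",
                              package = "mediaperm", mustWork = TRUE))
}
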