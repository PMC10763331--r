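# Fermentation arithmetic: unit conversions, molar yields, productivities,
# percent-of-theoretical, and shake-flask evaporation correction.

#' Compound metadata for fermentation arithmetic
#'
#' Molar masses (g/mol), carbon counts, and liquid densities (g/L, only for
#' liquid feed compounds) of the compounds involved in methanol
#' fermentations.
#'
#' @return a `data.frame` with columns `name`, `molar_mass`, `carbon_count`,
#'   `density`
#' @examples
#' compoundSpecs()
#' @export
compoundSpecs <- function() {
  data.frame(
    name = c("methanol", "malate", "succinate", "acetone", "isoprene",
      "pyruvate", "fumarate"),
    molar_mass = c(32.04, 134.09, 118.09, 58.08, 68.12, 88.06, 116.07),
    carbon_count = c(1L, 4L, 4L, 3L, 5L, 3L, 4L),
    density = c(792, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

.compound <- function(compound) {
  if (is.data.frame(compound)) return(compound)
  specs <- compoundSpecs()
  i <- match(tolower(compound), specs$name)
  if (is.na(i)) stop("unknown compound: ", compound, call. = FALSE)
  specs[i, , drop = FALSE]
}

#' Volume-percent to mass concentration
#'
#' Converts a %(v/v) concentration of a liquid compound to g/L via its
#' density (`g/L = percent/100 * density`). With `display = TRUE` the value
#' is rounded to the integer g/L convention such concentrations are usually
#' reported at (0.5 % v/v methanol = 3.96 g/L, displayed 4 g/L).
#'
#' @param percent concentration in % (v/v)
#' @param compound compound name or a row of [compoundSpecs()]; must have a
#'   density
#' @param display round for display
#' @return concentration in g/L
#' @examples
#' vvPercentToGL(0.5)                  # 3.96
#' vvPercentToGL(1, display = TRUE)    # 8
#' @export
vvPercentToGL <- function(percent, compound = "methanol", display = FALSE) {
  cp <- .compound(compound)
  if (is.na(cp$density)) {
    stop("compound ", cp$name, " has no density; %(v/v) undefined", call. = FALSE)
  }
  stopifnot(all(percent >= 0))
  out <- percent / 100 * cp$density
  if (display) round(out) else out
}

#' Mass concentration to molarity and back
#'
#' `gLToMM()` converts g/L to mM (`conc / molar_mass * 1000`); `mMToGL()`
#' is its inverse. The two compose to the identity.
#'
#' @param conc concentration in g/L (`gLToMM`) or mM (`mMToGL`)
#' @param compound compound name or a row of [compoundSpecs()]
#' @return concentration in mM, respectively g/L
#' @examples
#' gLToMM(6.7, "malate")   # 49.97 mM, the usual "50 mM"
#' gLToMM(4, "methanol")   # 124.8 mM
#' @export
gLToMM <- function(conc, compound) {
  cp <- .compound(compound)
  stopifnot(all(conc >= 0))
  conc / cp$molar_mass * 1000
}

#' @rdname gLToMM
#' @export
mMToGL <- function(conc, compound) {
  cp <- .compound(compound)
  stopifnot(all(conc >= 0))
  conc * cp$molar_mass / 1000
}

#' Molar product yield on substrate
#'
#' Moles of product formed per mole of substrate consumed, from mass
#' concentrations: `(product_gL / M_product) / (substrate_gL / M_substrate)`.
#' Invariant under common rescaling of both concentrations.
#'
#' @param product_gL product formed (g/L)
#' @param substrate_consumed_gL substrate consumed (g/L, must be > 0)
#' @param product,substrate compound names or rows of [compoundSpecs()]
#' @return yield in mol/mol
#' @examples
#' molarYield(13.4, 32.04, "malate", "methanol") # ~0.1
#' @export
molarYield <- function(product_gL, substrate_consumed_gL,
                       product = "malate", substrate = "methanol") {
  if (any(substrate_consumed_gL <= 0)) {
    stop("undefined yield: no substrate consumed", call. = FALSE)
  }
  stopifnot(all(product_gL >= 0))
  (product_gL / .compound(product)$molar_mass) /
    (substrate_consumed_gL / .compound(substrate)$molar_mass)
}

#' Volumetric productivity
#'
#' Titer divided by elapsed time, in g/L/d. With `display = TRUE` rounded
#' to one decimal (13.2 g/L over 4 days = 3.3 g/L/d).
#'
#' @param titer_gL final titer (g/L)
#' @param elapsed_days elapsed time (days, > 0)
#' @param display round for display
#' @return productivity in g/L/d
#' @examples
#' volumetricProductivity(13.2, 4) # 3.3
#' @export
volumetricProductivity <- function(titer_gL, elapsed_days, display = FALSE) {
  if (any(elapsed_days <= 0)) stop("elapsed time must be positive", call. = FALSE)
  stopifnot(all(titer_gL >= 0))
  out <- titer_gL / elapsed_days
  if (display) round(out, 1) else out
}

#' Percent of a reference value
#'
#' `percentOfTheoretical()` expresses an observed molar yield as a
#' percentage of a theoretical maximum; `percentRemaining()` expresses a
#' residual concentration as a percentage of the initial one. Both are
#' `100 * value / reference`, rounded to the integer percent convention
#' when `display = TRUE`.
#'
#' @param yield,theoretical_max observed and maximal yield (mol/mol,
#'   `theoretical_max > 0`)
#' @param residual_mM,initial_mM residual and initial concentration (mM,
#'   `initial_mM > 0`)
#' @param display round for display
#' @return a percentage
#' @examples
#' percentOfTheoretical(0.099, 0.25, display = TRUE) # 40
#' percentRemaining(91.2, gLToMM(vvPercentToGL(0.5), "methanol"),
#'   display = TRUE) # 73
#' @export
percentOfTheoretical <- function(yield, theoretical_max, display = FALSE) {
  if (any(theoretical_max <= 0)) {
    stop("theoretical maximum must be positive", call. = FALSE)
  }
  stopifnot(all(yield >= 0))
  out <- 100 * yield / theoretical_max
  if (display) round(out) else out
}

#' @rdname percentOfTheoretical
#' @export
percentRemaining <- function(residual_mM, initial_mM, display = FALSE) {
  if (any(initial_mM <= 0)) {
    stop("initial concentration must be positive", call. = FALSE)
  }
  stopifnot(all(residual_mM >= 0))
  out <- 100 * residual_mM / initial_mM
  if (display) round(out) else out
}

#' Evaporation correction of shake-flask measurements
#'
#' Shake flasks lose medium by evaporation; measured titers and optical
#' densities then overestimate the amounts actually present. From daily
#' flask weights, the current culture volume is estimated as
#' `V = V0 - weight_loss / medium_density`, and every concentration-like
#' column is referenced back to the initial volume:
#' `corrected = measured * V / V0`. The correction is per-timepoint
#' multiplicative, hence order-independent.
#'
#' @param series a `data.frame` with columns `time_h` (strictly increasing)
#'   and `weight_g`, plus any number of concentration/OD columns to correct
#' @param initial_volume_mL culture volume at the first timepoint
#' @param medium_density density of the evaporating medium (g/L,
#'   default 1000, i.e. water)
#' @return `series` with all non-`time_h`/`weight_g` columns corrected and
#'   an added `volume_mL` column
#' @examples
#' s <- data.frame(time_h = c(0, 24), weight_g = c(125, 122.5),
#'   malate_gL = c(0, 10))
#' evaporationCorrect(s, initial_volume_mL = 25)$malate_gL # 0, 9
#' @export
evaporationCorrect <- function(series, initial_volume_mL,
                               medium_density = 1000) {
  stopifnot(is.data.frame(series),
    all(c("time_h", "weight_g") %in% names(series)),
    initial_volume_mL > 0, medium_density > 0)
  if (is.unsorted(series$time_h, strictly = TRUE)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  loss_g <- series$weight_g[1] - series$weight_g
  vol <- initial_volume_mL - loss_g / medium_density * 1000
  if (any(vol <= 0)) {
    stop("implied culture volume is non-positive at time ",
      series$time_h[which(vol <= 0)[1]], " h", call. = FALSE)
  }
  out <- series
  fix <- setdiff(names(series), c("time_h", "weight_g"))
  for (col in fix) out[[col]] <- series[[col]] * vol / initial_volume_mL
  out$volume_mL <- vol
  out
}
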