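# Compartmental redox ratios from metabolite pools via near-equilibrium
# dehydrogenase relations:
#   cytosolic NADH/NAD+    = [Lac] / [Pyr]            * 1 / K_LDH
#   cytosolic NADPH/NADP+  = [Mal] / ([Pyr] [CO2])    * K_MDH   ([CO2] in uM)
#   mitochondrial NADPH/NADP+ = [Glu] / ([aKG] [NH4]) * K_GDH   ([NH4] in mM)
# Dissolved CO2 and ammonium are measured inputs, never defaulted.

.redox_constants <- list(K_LDH = 1.11e-4,      # dimensionless
                         K_MDH = 34.4e3,       # uM
                         K_GDH = 2.49e-3)      # mM

#' Equilibrium constants used for redox inference
#'
#' Read-only copies of the lactate, malate, and glutamate dehydrogenase
#' equilibrium constants (K_LDH = 1.11e-4; K_MDH = 34.4e3 uM;
#' K_GDH = 2.49e-3 mM).
#' @return Named list.
#' @export
redox_constants <- function() .redox_constants

# unit conversion factors to molar
.unit_to_molar <- c(M = 1, "mol/L" = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

#' Convert an intracellular amount to a concentration
#'
#' Divides a measured per-sample amount by the total intracellular volume
#' (cell count times per-cell volume; beta-cells average ~1100 um^3).
#'
#' @param amount Amount with unit given by `unit` (`"mol"`, `"mmol"`,
#'   `"umol"`, `"nmol"`, `"pmol"`, `"fmol"`).
#' @param cells Number of cells in the extract.
#' @param per_cell_volume Per-cell volume in um^3 (default 1100).
#' @param unit Unit of `amount`.
#' @return Concentration in molar (mol/L).
#' @export
to_concentration <- function(amount, cells, per_cell_volume = 1100,
                             unit = "mol") {
  if (cells <= 0) stop("cell count must be positive", call. = FALSE)
  if (per_cell_volume <= 0) stop("per-cell volume must be positive",
                                 call. = FALSE)
  scale <- c(mol = 1, mmol = 1e-3, umol = 1e-6, nmol = 1e-9, pmol = 1e-12,
             fmol = 1e-15)
  if (!unit %in% names(scale)) stop("unknown amount unit: ", unit,
                                    call. = FALSE)
  mol <- amount * scale[[unit]]
  litres <- cells * per_cell_volume * 1e-15   # um^3 -> L
  mol / litres
}

# normalize a concentration (value, unit) to molar
.to_molar <- function(value, unit) {
  if (!unit %in% names(.unit_to_molar)) {
    stop("unknown concentration unit: ", unit, call. = FALSE)
  }
  value * .unit_to_molar[[unit]]
}

#' Compute the compartmental redox panel
#'
#' @param pools Named list or vector of concentrations for `Lac`, `Pyr`,
#'   `Mal`, `Glu`, `AKG` (any consistent unit, see `unit`), plus the
#'   mandatory `CO2` and `NH4` concentrations. Alternatively a data frame
#'   with columns `metabolite`, `value`, `unit`.
#' @param unit Unit of the entries when `pools` is a plain vector/list
#'   (default `"uM"`).
#' @return A `redox_panel` with `cNADH_NAD`, `cNADPH_NADP`, `mNADPH_NADP`
#'   and the constants used.
#' @export
redox_panel <- function(pools, unit = "uM") {
  if (is.data.frame(pools)) {
    conc <- stats::setNames(
      mapply(.to_molar, pools$value, pools$unit),
      pools$metabolite)
  } else {
    conc <- stats::setNames(
      vapply(unlist(pools), .to_molar, 0, unit = unit), names(pools))
  }
  need <- c("Lac", "Pyr", "Mal", "Glu", "AKG", "CO2", "NH4")
  missing <- setdiff(need, names(conc))
  if (length(missing)) {
    stop("missing pool(s): ", paste(missing, collapse = ", "),
         " (CO2 and NH4 are mandatory inputs)", call. = FALSE)
  }
  for (d in c("Pyr", "AKG", "CO2", "NH4")) {
    if (conc[[d]] <= 0) stop("zero or negative denominator pool: ", d,
                             call. = FALSE)
  }
  K <- .redox_constants
  uM <- function(x) x * 1e6
  mM <- function(x) x * 1e3
  out <- list(
    cNADH_NAD = (conc[["Lac"]] / conc[["Pyr"]]) / K$K_LDH,
    cNADPH_NADP = uM(conc[["Mal"]]) /
      (uM(conc[["Pyr"]]) * uM(conc[["CO2"]])) * K$K_MDH,
    mNADPH_NADP = mM(conc[["Glu"]]) /
      (mM(conc[["AKG"]]) * mM(conc[["NH4"]])) * K$K_GDH,
    constants = K,
    conc_molar = conc)
  class(out) <- "redox_panel"
  out
}

#' @export
print.redox_panel <- function(x, ...) {
  cat("Redox panel (equilibrium estimates)\n")
  cat(sprintf("  cytosolic NADH/NAD+        %.4g\n", x$cNADH_NAD))
  cat(sprintf("  cytosolic NADPH/NADP+      %.4g\n", x$cNADPH_NADP))
  cat(sprintf("  mitochondrial NADPH/NADP+  %.4g\n", x$mNADPH_NADP))
  invisible(x)
}
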