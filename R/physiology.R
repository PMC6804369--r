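#' Relative water content (RWC)
#'
#' `RWC (%) = (FW - DW) / (TW - DW) * 100`, where FW is the fresh weight
#' at harvest, TW the turgid weight after imbibition and DW the dry
#' weight. A fully turgid sample (`FW = TW`) gives 100, a fully dry one
#' (`FW = DW`) gives 0. Values outside `[0, 100]` (e.g. from weighing
#' error) are returned as computed but flagged with a warning.
#'
#' @param FW,TW,DW Fresh, turgid and dry masses (g), `TW > DW`. Vectorised.
#' @return RWC in percent.
#' @examples
#' rwc(FW = 0.50, TW = 0.60, DW = 0.10)  # 80
#' @export
rwc <- function(FW, TW, DW) {
  if (anyNA(c(FW, TW, DW))) stop_invalid_input("masses must not be NA")
  if (any(TW <= DW)) stop_invalid_input("turgid weight must exceed dry weight")
  out <- (FW - DW) / (TW - DW) * 100
  if (any(out < 0 | out > 100))
    warning("RWC outside [0, 100]; check the weights", call. = FALSE)
  out
}

#' Gravimetric water content and field capacity of the substrate
#'
#' From the three weights of a watering-regime calibration (substrate at
#' saturation after free drainage, current state, and oven-dry):
#' gravimetric water content `theta_g = (current - dry) / dry` (g water
#' per g dry substrate) and water content as a percentage of maximum
#' water-holding capacity
#' `fc_percent = 100 * (current - dry) / (saturated - dry)`.
#'
#' @param current,dry,saturated Substrate masses in consistent units,
#'   `saturated > dry`. Vectorised.
#' @return A list with `theta_g` and `fc_percent`.
#' @examples
#' substrate_status(current = 2.4, dry = 2.0, saturated = 2.8)
#' @export
substrate_status <- function(current, dry, saturated) {
  if (anyNA(c(current, dry, saturated)))
    stop_invalid_input("masses must not be NA")
  if (any(dry <= 0)) stop_invalid_input("dry mass must be positive")
  if (any(saturated <= dry))
    stop_invalid_input("saturated mass must exceed dry mass")
  if (any(current < dry | current > saturated))
    warning("current mass outside [dry, saturated]; check the weights", call. = FALSE)
  list(theta_g = (current - dry) / dry,
       fc_percent = 100 * (current - dry) / (saturated - dry))
}

# Default molar extinction coefficients of the three assayed antioxidant
# enzymes: CAT follows H2O2 at 240 nm, APX follows ascorbate at 290 nm,
# POX follows tetraguaiacol at 470 nm.
enzyme_defaults <- list(
  CAT = list(epsilon = 38, epsilon_unit = "M-1cm-1"),
  APX = list(epsilon = 2.8, epsilon_unit = "mM-1cm-1"),
  POX = list(epsilon = 26.6, epsilon_unit = "mM-1cm-1"))

#' Antioxidant enzyme assay description
#'
#' @param enzyme `"CAT"`, `"APX"` or `"POX"`; fills the default extinction
#'   coefficient when `epsilon` is not given.
#' @param delta_A_per_min Absorbance change per minute (positive for
#'   either an increase or a decrease in optical density).
#' @param epsilon Molar extinction coefficient; unit given by
#'   `epsilon_unit` (`"M-1cm-1"` or `"mM-1cm-1"`).
#' @param epsilon_unit Unit tag of `epsilon`.
#' @param path_cm Cuvette path length in cm (default 1).
#' @param reaction_volume_ml Final reaction volume (ml).
#' @param extract_volume_ml Volume of enzyme extract in the reaction (ml).
#' @param protein_mg_per_ml Protein concentration of the extract (mg/ml).
#' @return An object of class `enzyme_assay`.
#' @export
enzyme_assay <- function(enzyme = c("CAT", "APX", "POX"), delta_A_per_min,
                         epsilon = NULL, epsilon_unit = NULL, path_cm = 1,
                         reaction_volume_ml = 1, extract_volume_ml,
                         protein_mg_per_ml) {
  enzyme <- match.arg(enzyme)
  if (is.null(epsilon)) {
    epsilon <- enzyme_defaults[[enzyme]]$epsilon
    epsilon_unit <- enzyme_defaults[[enzyme]]$epsilon_unit
  }
  if (is.null(epsilon_unit)) stop_invalid_input("epsilon_unit must accompany epsilon")
  epsilon_unit <- match.arg(epsilon_unit, c("M-1cm-1", "mM-1cm-1"))
  if (epsilon <= 0) stop_invalid_input("epsilon must be positive")
  if (delta_A_per_min < 0) stop_invalid_input("delta_A_per_min must be >= 0 (use the magnitude)")
  if (path_cm <= 0 || reaction_volume_ml <= 0 || extract_volume_ml <= 0)
    stop_invalid_input("path length and volumes must be positive")
  if (protein_mg_per_ml <= 0) stop_invalid_input("protein concentration must be positive")
  structure(list(enzyme = enzyme, delta_A_per_min = delta_A_per_min,
                 epsilon = epsilon, epsilon_unit = epsilon_unit,
                 path_cm = path_cm, reaction_volume_ml = reaction_volume_ml,
                 extract_volume_ml = extract_volume_ml,
                 protein_mg_per_ml = protein_mg_per_ml),
            class = "enzyme_assay")
}

#' Specific enzyme activity from an absorbance rate
#'
#' Beer--Lambert conversion of an absorbance rate into substrate turnover
#' per mg protein: the molar rate is
#' `delta_A_per_min / (epsilon * path_cm)` (mol L^-1 min^-1 for epsilon in
#' M^-1 cm^-1), scaled by the reaction volume to moles per minute and
#' divided by the protein mass in the assayed extract aliquot
#' (`extract_volume_ml * protein_mg_per_ml`).
#'
#' Activity is linear in `delta_A_per_min` and inversely linear in the
#' protein mass. Both a per-minute and a per-second figure are returned
#' with explicit unit tags; no silent conversion between the two time
#' bases is ever performed.
#'
#' @param assay An [enzyme_assay()].
#' @return A list with `umol_per_min_per_mg`, `umol_per_s_per_mg`,
#'   `protein_mg` and `enzyme`.
#' @examples
#' a <- enzyme_assay("CAT", delta_A_per_min = 0.038, extract_volume_ml = 1,
#'                   protein_mg_per_ml = 1)
#' enzyme_activity(a)$umol_per_min_per_mg  # 1
#' @export
enzyme_activity <- function(assay) {
  stopifnot(inherits(assay, "enzyme_assay"))
  eps_M <- if (assay$epsilon_unit == "mM-1cm-1") assay$epsilon * 1000 else assay$epsilon
  molar_per_min <- assay$delta_A_per_min / (eps_M * assay$path_cm)   # mol L^-1 min^-1
  mol_per_min <- molar_per_min * assay$reaction_volume_ml / 1000     # mol min^-1
  protein_mg <- assay$extract_volume_ml * assay$protein_mg_per_ml
  umol_min_mg <- mol_per_min * 1e6 / protein_mg
  list(umol_per_min_per_mg = umol_min_mg,
       umol_per_s_per_mg = umol_min_mg / 60,
       protein_mg = protein_mg,
       enzyme = assay$enzyme)
}

#' Convert a per-fresh-weight concentration to per dry weight
#'
#' Metabolite concentrations measured per mg fresh weight are expressed
#' per mg dry weight through the absolute water content `awc` of the
#' tissue (water mass fraction of fresh weight, `DW = FW * (1 - awc)`):
#' `conc_per_dw = conc_per_fw / (1 - awc)`.
#'
#' @param conc_per_fw Concentration per fresh weight (e.g. pmol/mg FW),
#'   non-negative. Vectorised.
#' @param awc Absolute water content fraction, in `[0, 1)`.
#' @return Concentration per dry weight, same amount units.
#' @examples
#' per_dw(10, awc = 0.5)  # 20
#' @export
per_dw <- function(conc_per_fw, awc) {
  if (anyNA(c(conc_per_fw, awc))) stop_invalid_input("inputs must not be NA")
  if (any(conc_per_fw < 0)) stop_invalid_input("concentrations must be non-negative")
  if (any(awc < 0 | awc >= 1)) stop_invalid_input("awc must lie in [0, 1)")
  conc_per_fw / (1 - awc)
}

#' Log2 fold change between treated and control means
#'
#' @param treated_mean,control_mean Positive means (e.g. pmol/mg DW).
#'   Vectorised.
#' @return `log2(treated_mean / control_mean)`.
#' @examples
#' log2_fold_change(11.7, 1)  # 3.55 at 2 d.p.
#' @export
log2_fold_change <- function(treated_mean, control_mean) {
  if (anyNA(c(treated_mean, control_mean)))
    stop_invalid_input("means must not be NA")
  if (any(treated_mean <= 0) || any(control_mean <= 0))
    stop_invalid_input("fold change needs strictly positive means")
  log2(treated_mean / control_mean)
}
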