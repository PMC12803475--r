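#' Feature catalog of the athlete screening survey
#'
#' Builds the catalog of the 45 screening features used by the risk-pattern
#' analysis, organised in three nested subsets: the full 45-feature set
#' (\code{"LE"}, literature plus exploratory extras), the 26-feature
#' literature-supported set (\code{"complete"}), and the 8-feature core set
#' (\code{"L"}) most strongly tied to sudden cardiac death. All features are
#' binary (finding present / absent) except numeric body-mass index and heart
#' rate, which are continuous.
#'
#' The printed numbering of the source survey is carried verbatim in
#' \code{feature_id}, including its defects: id 28 is skipped and id 38 is
#' used twice in the stress-ECG block (left axis deviation and lateral /
#' inferolateral T-wave inversion). Each feature therefore also has a unique
#' \code{key}, which is the canonical column name used throughout the
#' package. The 8-feature core set resolves printed id 38 to the stress
#' T-wave inversion; the 26-feature set resolves it to left axis deviation,
#' matching the printed subset listings. As a consequence the core set is a
#' subset of the 45-feature set but not of the 26-feature set (core features
#' 21 and 22 are absent from the printed 26-feature list); the catalog
#' encodes the listings as printed rather than repairing them.
#'
#' @return A data frame of class \code{feature_catalog} with columns
#'   \code{key} (unique identifier), \code{feature_id} (printed integer id),
#'   \code{name}, \code{category} (\code{"risk"}, \code{"resting_ecg"},
#'   \code{"stress_ecg"}), \code{value_type} (\code{"binary"} or
#'   \code{"continuous"}), and logical subset flags \code{in_L},
#'   \code{in_complete}, \code{in_LE}.
#' @examples
#' cat45 <- feature_catalog()
#' sum(cat45$in_L)        # 8
#' sum(cat45$in_complete) # 26
#' @export
feature_catalog <- function() {
  row <- function(key, id, name, category, type = "binary")
    data.frame(key = key, feature_id = id, name = name, category = category,
               value_type = type, stringsAsFactors = FALSE)

  risk <- rbind(
    row("r01_class_c_sport",          1L, "Class C Sport",                         "risk"),
    row("r02_family_heart_disease",   2L, "Family History of Heart Disease",       "risk"),
    row("r03_personal_heart_disease", 3L, "Personal History of Heart Disease",     "risk"),
    row("r04_syncope",                4L, "Syncope",                               "risk"),
    row("r05_eutocic_premature",      5L, "Eutocic Birth: Premature Delivery",     "risk"),
    row("r06_caesarean_premature",    6L, "Caesarean Section: Premature Delivery", "risk"),
    row("r07_pectus_excavatum",       7L, "Pectus Excavatum",                      "risk"),
    row("r08_bmi_numeric",            8L, "Body Mass Index (numeric)",             "risk", "continuous"),
    row("r09_bmi",                    9L, "Body Mass Index",                       "risk"),
    row("r10_blood_pressure",        10L, "Blood Pressure",                        "risk"),
    row("r11_heart_rate",            11L, "Heart Rate",                            "risk", "continuous"))

  ecg_slugs <- c("sinus_tach", "vent_extrasys", "atrial_arrhythmia",
                 "vent_arrhythmia", "crbbb", "clbbb", "av_block",
                 "right_axis_dev", "left_axis_dev", "twi_lateral",
                 "twi_anterior", "path_q_waves", "vent_preexcitation",
                 "st_depression", "prolonged_qtc", "brugada_t1", "wpw")
  ecg_names <- c("Sinus Tachycardia", "Ventricular Extrasystole",
                 "Atrial Arrhythmia", "Ventricular Arrhythmia",
                 "Complete Right Bundle Branch Block",
                 "Complete Left Bundle Branch Block", "Atrioventricular Block",
                 "Right Axis Deviation", "Left Axis Deviation",
                 "T-wave Inversion in the Lateral or Inferolateral Leads",
                 "T-wave Inversion in the Anterior Leads",
                 "Pathological Q Waves", "Ventricular Pre-excitation",
                 "ST-segment Depression", "Prolonged QTc",
                 "Brugada Type 1 Pattern", "Wolff-Parkinson-White Syndrome")

  # printed resting numbering runs 12..27 then jumps to 29;
  # printed stress numbering uses 38 twice and ends at 45
  resting_ids <- c(12:27, 29L)
  stress_ids  <- c(30:37, 38L, 38L, 39:45)
  # stress block has both left_axis_dev and twi_lateral at printed id 38
  stress_slugs <- c(ecg_slugs[1:9], "twi_lateral", ecg_slugs[11:17])
  stress_names <- c(ecg_names[1:9], ecg_names[10], ecg_names[11:17])

  resting <- do.call(rbind, Map(function(id, sl, nm)
    row(sprintf("e%02d_%s", id, sl), id, paste0(nm, " (Resting ECG)"),
        "resting_ecg"),
    resting_ids, ecg_slugs, ecg_names))
  stress <- do.call(rbind, Map(function(id, sl, nm)
    row(sprintf("s%02d_%s", id, sl), id, paste0(nm, " (Stress ECG)"),
        "stress_ecg"),
    stress_ids, stress_slugs, stress_names))

  cat45 <- rbind(risk, resting, stress)
  stopifnot(!anyDuplicated(cat45$key))

  cat45$in_LE <- TRUE
  cat45$in_L <- cat45$key %in% c(
    "r04_syncope", "r11_heart_rate", "e21_twi_lateral", "e22_twi_anterior",
    "e24_vent_preexcitation", "s38_twi_lateral", "s41_vent_preexcitation",
    "s43_prolonged_qtc")
  cat45$in_complete <-
    (cat45$category == "risk" & cat45$feature_id %in% c(1:3, 5:11)) |
    (cat45$category == "resting_ecg" &
       cat45$feature_id %in% c(12, 14, 15, 16, 18, 19, 20)) |
    (cat45$category == "stress_ecg" &
       (cat45$feature_id %in% c(30, 32, 33, 34, 36, 37, 39, 44) |
          cat45$key == "s38_left_axis_dev"))

  rownames(cat45) <- NULL
  class(cat45) <- c("feature_catalog", "data.frame")
  validate_catalog(cat45)
  cat45
}

validate_catalog <- function(cat) {
  stopifnot(
    sum(cat$in_L) == 8L,
    sum(cat$in_complete) == 26L,
    sum(cat$in_LE) == 45L,
    all(cat$in_LE[cat$in_L]),
    identical(sort(cat$key[cat$value_type == "continuous"]),
              c("r08_bmi_numeric", "r11_heart_rate")))
  invisible(cat)
}

#' Restrict a catalog to one of the named subsets
#'
#' @param catalog a \code{\link{feature_catalog}}
#' @param subset \code{"L"} (8 features), \code{"complete"} (26) or
#'   \code{"LE"} (45)
#' @return the catalog rows of the subset, in catalog order
#' @export
catalog_subset <- function(catalog, subset = c("L", "complete", "LE")) {
  subset <- match.arg(subset)
  flag <- switch(subset, L = catalog$in_L, complete = catalog$in_complete,
                 LE = catalog$in_LE)
  out <- catalog[flag, , drop = FALSE]
  rownames(out) <- NULL
  out
}
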