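# Structural constants of the age x frailty state space. Everything in the
# package indexes compartments as (age band, frailty state); band-major
# ordering is used whenever the 16 strata are flattened to a vector.

AGE_BANDS <- c("50-64", "65-74", "75-84", "85+")
AGE_WIDTHS <- c(15, 10, 10, Inf)

FRAILTY_STATES <- c("fit", "mild", "moderate", "severe")
EFI_LOWER <- c(0, 0.12, 0.24, 0.36)
EFI_UPPER <- c(0.12, 0.24, 0.36, Inf)

TRANSITION_TYPES <- c("fit_mild", "mild_moderate", "moderate_severe")

SERVICE_CATEGORY_TABLE <- data.frame(
  category = c("gp_face_to_face", "gp_home_visit", "gp_telephone",
               "gp_econsult", "outpatient", "ed_attendance",
               "elective_admission", "unplanned_admission", "critical_care"),
  sector = c(rep("primary", 4), rep("secondary_urgent", 5)),
  stringsAsFactors = FALSE
)

#' Age bands of the model
#'
#' The population aged 50 and over is split into four age bands: 50-64,
#' 65-74, 75-84 and 85+. Only the last band is open-ended; people leave it
#' by death alone.
#'
#' @return A data frame with columns `label` and `width_years`
#'   (`Inf` for the open-ended 85+ band).
#' @export
age_bands <- function() {
  data.frame(label = AGE_BANDS, width_years = AGE_WIDTHS,
             stringsAsFactors = FALSE)
}

#' Frailty states and their eFI score ranges
#'
#' Frailty severity follows the electronic Frailty Index (eFI, a 36-deficit
#' index scored deficits/36) categorised as fit (0 to <0.12), mild
#' (0.12 to <0.24), moderate (0.24 to <0.36) and severe (0.36 and above).
#' The eFI ranges are documentation: the model works on the four ordered
#' categories, and frailty never improves.
#'
#' @return A data frame with columns `label`, `efi_lower`, `efi_upper`
#'   (half-open intervals, upper bound excluded).
#' @export
frailty_states <- function() {
  data.frame(label = FRAILTY_STATES, efi_lower = EFI_LOWER,
             efi_upper = EFI_UPPER, stringsAsFactors = FALSE)
}

#' Health-service contact categories
#'
#' Nine contact categories split into two sectors: primary care (GP
#' face-to-face appointments, home visits, telephone appointments,
#' e-consultations) and secondary & urgent care (outpatient visits, ED
#' attendances, elective and unplanned hospital admissions, critical care
#' admissions).
#'
#' @return A data frame with columns `category` and `sector`.
#' @export
service_categories <- function() SERVICE_CATEGORY_TABLE

#' Names of the 16 population strata
#'
#' @param sep Separator between band and state label.
#' @return Character vector of length 16, band-major order
#'   (`"50-64.fit"`, `"50-64.mild"`, ..., `"85+.severe"`).
#' @export
stratum_names <- function(sep = ".") {
  as.vector(t(outer(AGE_BANDS, FRAILTY_STATES, paste, sep = sep)))
}

# flatten a 4x4 band x state matrix to the band-major 16-vector
flatten_stocks <- function(m) {
  v <- as.vector(t(m))
  names(v) <- stratum_names()
  v
}

# inverse of flatten_stocks
unflatten_stocks <- function(v) {
  m <- matrix(v, nrow = 4, ncol = 4, byrow = TRUE,
              dimnames = list(AGE_BANDS, FRAILTY_STATES))
  m
}
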