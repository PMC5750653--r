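#' Lean body weight (Janmahasatian, adult male)
#'
#' Semi-mechanistic lean body weight from total body weight and BMI,
#' using the male coefficients 9270 / 6680 / 216. Hemophilia A is
#' X-linked, so only the male form is provided.
#'
#' @param tbw_kg Total body weight in kg (positive).
#' @param bmi Body mass index in kg/m^2 (positive).
#' @return Lean body weight in kg. Vectorised over both arguments.
#' @details
#' \deqn{LBW = \frac{9270 \cdot TBW}{6680 + 216 \cdot BMI}}
#' For any BMI above 11.99 kg/m^2 (so in particular throughout the study
#' range 20.3--40.0), LBW is strictly below TBW. LBW increases with TBW at
#' fixed BMI and decreases with BMI at fixed TBW.
#' @examples
#' lean_body_weight(70, 22.86)
#' @export
lean_body_weight <- function(tbw_kg, bmi) {
  if (any(!is.finite(tbw_kg)) || any(tbw_kg <= 0))
    stop("'tbw_kg' must be positive and finite")
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("'bmi' must be positive and finite")
  9270 * tbw_kg / (6680 + 216 * bmi)
}

#' Ideal body weight (Lorentz, adult male)
#'
#' Height-only ideal body weight; independent of total body weight and BMI.
#'
#' @param height_cm Height in cm (positive; formula intended for adults,
#'   roughly 140--210 cm).
#' @return Ideal body weight in kg. Vectorised.
#' @details
#' \deqn{IBW = HT - 100 - (HT - 150)/4}
#' At 150 cm the correction term vanishes and IBW = 50 kg.
#' @examples
#' ideal_body_weight(170) # 65 kg
#' @export
ideal_body_weight <- function(height_cm) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop("'height_cm' must be positive and finite")
  height_cm - 100 - (height_cm - 150) / 4
}

#' Adjusted body weight
#'
#' Ideal body weight plus a fraction of the excess weight above it.
#'
#' @param tbw_kg Total body weight in kg.
#' @param ibw_kg Ideal body weight in kg.
#' @param fraction Fraction of the excess weight added back, in \[0, 1\].
#'   The study uses 0.25 and 0.40.
#' @return Adjusted body weight in kg. Vectorised over weights.
#' @details ABW(0) = IBW and ABW(1) = TBW exactly. When TBW < IBW (possible
#' for short, light subjects) the "excess" is negative and ABW lies between
#' TBW and IBW.
#' @examples
#' adjusted_body_weight(100, 65, 0.40) # 79 kg
#' @export
adjusted_body_weight <- function(tbw_kg, ibw_kg, fraction) {
  if (any(!is.finite(tbw_kg)) || any(tbw_kg <= 0))
    stop("'tbw_kg' must be positive and finite")
  if (any(!is.finite(ibw_kg)) || any(ibw_kg <= 0))
    stop("'ibw_kg' must be positive and finite")
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("'fraction' must lie in [0, 1]")
  ibw_kg + fraction * (tbw_kg - ibw_kg)
}

#' All body-weight metrics for a subject
#'
#' Bundles total, lean, ideal and adjusted (25% and 40%) body weight from a
#' subject's height, total body weight and BMI. The three inputs must be
#' mutually consistent: TBW = BMI x (HT/100)^2.
#'
#' @param height_cm Height in cm.
#' @param tbw_kg Total body weight in kg.
#' @param bmi Body mass index in kg/m^2.
#' @param check Verify TBW = BMI x height^2 consistency (default TRUE).
#' @return A data.frame with columns `tbw_kg`, `lbw_kg`, `ibw_kg`,
#'   `abw25_kg`, `abw40_kg`, one row per subject.
#' @examples
#' weight_metrics(170, 65.17, 22.55)
#' @export
weight_metrics <- function(height_cm, tbw_kg, bmi, check = TRUE) {
  n <- max(length(height_cm), length(tbw_kg), length(bmi))
  height_cm <- rep_len(height_cm, n)
  tbw_kg <- rep_len(tbw_kg, n)
  bmi <- rep_len(bmi, n)
  if (check) {
    # 0.05 kg slack admits inputs rounded to reporting precision
    bad <- abs(tbw_kg - bmi * (height_cm / 100)^2) > 0.05
    if (any(bad))
      stop("inconsistent anthropometrics: TBW must equal BMI x (height/100)^2 ",
           "(first offending row: ", which(bad)[1], ")")
  }
  ibw <- ideal_body_weight(height_cm)
  data.frame(
    tbw_kg = tbw_kg,
    lbw_kg = lean_body_weight(tbw_kg, bmi),
    ibw_kg = ibw,
    abw25_kg = adjusted_body_weight(tbw_kg, ibw, 0.25),
    abw40_kg = adjusted_body_weight(tbw_kg, ibw, 0.40)
  )
}

# map a metric label to its column in a population data.frame
.metric_column <- c(TBW = "tbw_kg", LBW = "lbw_kg", IBW = "ibw_kg",
                    ABW25 = "abw25_kg", ABW40 = "abw40_kg")

.metric_values <- function(population, metric) {
  metric <- match.arg(metric, names(.metric_column))
  population[[.metric_column[[metric]]]]
}
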