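#' Population pharmacokinetic model specification
#'
#' Constants of the published two-compartment FVIII population model
#' (Kovaltry / BAY 81-8973, adult and adolescent data): typical clearance
#' and central volume scale with lean body weight through power functions;
#' between-subject variability (BSV) is expressed as %CV and applied as
#' lognormal random effects on CL and V1. Residual unexplained variability
#' (RUV) constants are carried as metadata only: simulated activity levels
#' represent true levels and no assay error is added.
#'
#' @param cl_typical Typical clearance, dL/h (default 1.88).
#' @param q_typical Intercompartmental clearance, dL/h (default 1.90).
#' @param v1_typical Typical central volume, dL (default 30.0).
#' @param v2_typical Peripheral volume, dL (default 6.37).
#' @param lbw_reference Reference lean body weight, kg (default 51.1).
#' @param cl_lbw_exponent Power exponent of LBW on CL (default 0.610).
#' @param v1_lbw_exponent Power exponent of LBW on V1 (default 0.950).
#' @param bsv_cl_cv BSV of CL as a fraction (default 0.370).
#' @param bsv_v1_cv BSV of V1 as a fraction (default 0.112).
#' @param ruv_proportional_cv Proportional RUV as a fraction (metadata,
#'   default 0.267; never applied).
#' @param ruv_additive Additive RUV in IU/dL (metadata, default 1.10;
#'   never applied).
#' @return An object of class `pk_model_spec`.
#' @export
pk_model_spec <- function(cl_typical = 1.88, q_typical = 1.90,
                          v1_typical = 30.0, v2_typical = 6.37,
                          lbw_reference = 51.1,
                          cl_lbw_exponent = 0.610, v1_lbw_exponent = 0.950,
                          bsv_cl_cv = 0.370, bsv_v1_cv = 0.112,
                          ruv_proportional_cv = 0.267, ruv_additive = 1.10) {
  spec <- list(cl_typical = cl_typical, q_typical = q_typical,
               v1_typical = v1_typical, v2_typical = v2_typical,
               lbw_reference = lbw_reference,
               cl_lbw_exponent = cl_lbw_exponent,
               v1_lbw_exponent = v1_lbw_exponent,
               bsv_cl_cv = bsv_cl_cv, bsv_v1_cv = bsv_v1_cv,
               ruv_proportional_cv = ruv_proportional_cv,
               ruv_additive = ruv_additive)
  num <- unlist(spec[c("cl_typical", "q_typical", "v1_typical", "v2_typical",
                       "lbw_reference")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("model constants must be positive and finite")
  if (bsv_cl_cv < 0 || bsv_v1_cv < 0)
    stop("BSV coefficients of variation must be non-negative")
  structure(spec, class = "pk_model_spec")
}

#' Typical (population) PK parameters for a given lean body weight
#'
#' Applies the covariate power functions without any random effects:
#' CL = 1.88 x (LBW/51.1)^0.610 dL/h and V1 = 30.0 x (LBW/51.1)^0.950 dL
#' at the default constants; Q and V2 carry no covariate.
#'
#' @param spec A [pk_model_spec()].
#' @param lbw_kg Lean body weight(s), kg.
#' @return A data.frame with columns `cl`, `q`, `v1`, `v2` (dL/h and dL)
#'   and the (zero) random effects `eta_cl`, `eta_v1`; one row per subject.
#' @examples
#' typical_pk_parameters(pk_model_spec(), 51.1) # reference subject
#' @export
typical_pk_parameters <- function(spec = pk_model_spec(), lbw_kg) {
  if (!inherits(spec, "pk_model_spec")) stop("'spec' must be a pk_model_spec")
  if (any(!is.finite(lbw_kg)) || any(lbw_kg <= 0))
    stop("'lbw_kg' must be positive and finite")
  rel <- lbw_kg / spec$lbw_reference
  data.frame(
    cl = spec$cl_typical * rel^spec$cl_lbw_exponent,
    q = rep_len(spec$q_typical, length(lbw_kg)),
    v1 = spec$v1_typical * rel^spec$v1_lbw_exponent,
    v2 = rep_len(spec$v2_typical, length(lbw_kg)),
    eta_cl = 0, eta_v1 = 0
  )
}

#' Sample individual PK parameters with between-subject variability
#'
#' Lognormal random effects on CL and V1: each individual value is the
#' typical value times exp(eta), eta ~ Normal(0, omega^2) with
#' omega^2 = log(1 + CV^2), so the stated %CV is reproduced exactly and
#' the typical value is the population median. Q and V2 carry no BSV.
#'
#' @param spec A [pk_model_spec()].
#' @param lbw_kg Lean body weight(s), kg; one draw per element.
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return A data.frame as in [typical_pk_parameters()], with the sampled
#'   `eta_cl` and `eta_v1`.
#' @export
sample_pk_parameters <- function(spec = pk_model_spec(), lbw_kg, seed = NULL) {
  typ <- typical_pk_parameters(spec, lbw_kg)
  n <- nrow(typ)
  .run_seeded(seed, function() {
    omega_cl <- sqrt(log(1 + spec$bsv_cl_cv^2))
    omega_v1 <- sqrt(log(1 + spec$bsv_v1_cv^2))
    typ$eta_cl <- stats::rnorm(n, 0, omega_cl)
    typ$eta_v1 <- stats::rnorm(n, 0, omega_v1)
    typ$cl <- typ$cl * exp(typ$eta_cl)
    typ$v1 <- typ$v1 * exp(typ$eta_v1)
    typ
  })
}

#' Macro-constants of the two-compartment IV bolus model
#'
#' Converts micro parameters (CL, Q, V1, V2) to the hybrid rate constants
#' and coefficients of the bi-exponential unit-dose solution
#' C(t) = A exp(-alpha t) + B exp(-beta t), concentration per IU of bolus.
#'
#' @param params A data.frame (or list) with elements `cl`, `q`, `v1`,
#'   `v2`; vectorised over rows.
#' @return A data.frame with columns `alpha`, `beta` (1/h), `coef_a`,
#'   `coef_b` (1/dL) and logical `degenerate` (TRUE where the two phases
#'   coincide numerically and a one-compartment fallback is used).
#' @details With k10 = CL/V1, k12 = Q/V1, k21 = Q/V2:
#' alpha + beta = k10 + k12 + k21 and alpha x beta = k10 x k21, with
#' alpha > beta > 0; A = (alpha - k21)/(V1 (alpha - beta)),
#' B = (k21 - beta)/(V1 (alpha - beta)), so A + B = 1/V1.
#' @export
macro_constants <- function(params) {
  cl <- params$cl; q <- params$q; v1 <- params$v1; v2 <- params$v2
  if (any(c(cl, q, v1, v2) <= 0) || any(!is.finite(c(cl, q, v1, v2))))
    stop("PK parameters must be positive and finite")
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- s^2 - 4 * p
  degenerate <- disc <= (1e-12 * s^2)
  disc[degenerate] <- 0
  alpha <- (s + sqrt(disc)) / 2
  beta <- p / alpha
  coef_a <- (alpha - k21) / (v1 * (alpha - beta))
  coef_b <- (k21 - beta) / (v1 * (alpha - beta))
  if (any(degenerate)) {
    # indistinguishable phases: collapse to a one-compartment profile
    alpha[degenerate] <- s[degenerate] / 2
    beta[degenerate] <- s[degenerate] / 2
    coef_a[degenerate] <- 1 / v1[degenerate]
    coef_b[degenerate] <- 0
  }
  data.frame(alpha = alpha, beta = beta, coef_a = coef_a, coef_b = coef_b,
             degenerate = degenerate)
}
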