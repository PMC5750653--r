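#' Specification of a virtual study population
#'
#' Describes the two BMI-stratified cohorts of virtual adult males: a
#' normal-BMI group (uniform BMI on \[20.3, 29.6) kg/m^2) and an
#' overweight/obese group (uniform on \[29.6, 40.0) kg/m^2), each of
#' `n_per_group` subjects. Heights are drawn independently of BMI from a
#' truncated normal distribution representing NHANES adult males; total
#' body weight is BMI x (height/100)^2 exactly.
#'
#' @param n_per_group Subjects per BMI group (default 1000).
#' @param bmi_normal_range Numeric length 2, normal-BMI bin (kg/m^2).
#' @param bmi_high_range Numeric length 2, overweight/obese bin (kg/m^2).
#' @param height_mean_cm,height_sd_cm Mean and SD of the height
#'   distribution before truncation (cm). Defaults 175.7 and 7.4.
#' @param height_range_cm Truncation bounds for height (cm).
#' @param seed Optional integer seed; same seed gives a bit-identical
#'   population.
#' @return An object of class `population_spec` (a named list).
#' @seealso [generate_population()]
#' @export
population_spec <- function(n_per_group = 1000,
                            bmi_normal_range = c(20.3, 29.6),
                            bmi_high_range = c(29.6, 40.0),
                            height_mean_cm = 175.7,
                            height_sd_cm = 7.4,
                            height_range_cm = c(150, 200),
                            seed = NULL) {
  stopifnot(length(n_per_group) == 1, n_per_group >= 1,
            length(bmi_normal_range) == 2, length(bmi_high_range) == 2,
            length(height_range_cm) == 2)
  if (bmi_normal_range[1] >= bmi_normal_range[2] ||
      bmi_high_range[1] >= bmi_high_range[2])
    stop("BMI ranges must be ordered (low < high)")
  if (height_sd_cm < 0 || height_mean_cm <= 0 ||
      height_range_cm[1] >= height_range_cm[2] || height_range_cm[1] <= 0)
    stop("invalid height distribution parameters")
  structure(list(
    n_per_group = as.integer(n_per_group),
    bmi_normal_range = as.numeric(bmi_normal_range),
    bmi_high_range = as.numeric(bmi_high_range),
    height_mean_cm = height_mean_cm,
    height_sd_cm = height_sd_cm,
    height_range_cm = as.numeric(height_range_cm),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "population_spec")
}

# run fun() under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL uses (and advances) the current stream.
.run_seeded <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  fun()
}

# truncated-normal draws via inverse-CDF on a uniform restricted to the
# truncation probabilities
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a virtual patient population
#'
#' Draws the two BMI-stratified cohorts described by a [population_spec()]:
#' uniform BMI within each bin, heights i.i.d. truncated normal and
#' independent of BMI, TBW = BMI x (height/100)^2, and all derived weight
#' metrics.
#'
#' @param spec A [population_spec()].
#' @return A data.frame of class `fviii_population` with one row per
#'   subject and columns `patient_id`, `group` ("normal" or
#'   "overweight_obese"), `height_cm`, `bmi`, `tbw_kg`, `lbw_kg`,
#'   `ibw_kg`, `abw25_kg`, `abw40_kg`.
#' @examples
#' pop <- generate_population(population_spec(n_per_group = 50, seed = 1))
#' summarize_population(pop)
#' @export
generate_population <- function(spec = population_spec()) {
  if (!inherits(spec, "population_spec"))
    stop("'spec' must be a population_spec")
  .run_seeded(spec$seed, function() {
    one_group <- function(group, range, prefix) {
      n <- spec$n_per_group
      bmi <- stats::runif(n, range[1], range[2])
      ht <- .rtruncnorm(n, spec$height_mean_cm, spec$height_sd_cm,
                        spec$height_range_cm[1], spec$height_range_cm[2])
      tbw <- bmi * (ht / 100)^2
      cbind(
        data.frame(patient_id = sprintf("%s%04d", prefix, seq_len(n)),
                   group = group, height_cm = ht, bmi = bmi),
        weight_metrics(ht, tbw, bmi, check = FALSE)
      )
    }
    pop <- rbind(
      one_group("normal", spec$bmi_normal_range, "N"),
      one_group("overweight_obese", spec$bmi_high_range, "O")
    )
    rownames(pop) <- NULL
    class(pop) <- c("fviii_population", "data.frame")
    attr(pop, "spec") <- spec
    pop
  })
}

#' Summarize weight metrics by BMI group
#'
#' Per-group mean and median of every body-size metric.
#'
#' @param population A population data.frame from [generate_population()]
#'   (any data.frame with `group` and the metric columns works).
#' @return A data.frame with columns `group`, `metric`, `mean_kg`,
#'   `median_kg`.
#' @export
summarize_population <- function(population) {
  if (NROW(population) == 0) stop("empty population")
  cols <- .metric_column
  out <- do.call(rbind, lapply(split(population, population$group), function(g) {
    data.frame(group = g$group[1],
               metric = names(cols),
               mean_kg = vapply(cols, function(cl) mean(g[[cl]]), numeric(1)),
               median_kg = vapply(cols, function(cl) stats::median(g[[cl]]),
                                  numeric(1)))
  }))
  rownames(out) <- NULL
  out
}

#' Write a population cohort to CSV
#'
#' @param population Population data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  utils::write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.fviii_population <- function(x, ...) {
  cat("Virtual hemophilia A population:", nrow(x), "subjects\n")
  tab <- table(x$group)
  for (g in names(tab))
    cat(sprintf("  %-18s n = %d, BMI %.1f-%.1f kg/m^2\n", g, tab[[g]],
                min(x$bmi[x$group == g]), max(x$bmi[x$group == g])))
  cat("\n")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4) cat("... and", nrow(x) - 4, "more rows\n")
  invisible(x)
}
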