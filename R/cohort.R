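# Synthetic cohort generation and Kaggle-dialect CSV I/O ---------------------

#' Specify a synthetic stroke cohort
#'
#' Defines the statistical conditions of a simulated patient cohort in the
#' Kaggle stroke-prediction dialect: sample size, missing-completely-at-random
#' rate on `bmi`/`smoking_status`, stroke prevalence, planted log-odds effects
#' of the clinical predictors on the stroke label, and the two-component
#' glucose mixture (normoglycemic vs diabetic means, mg/dL).
#'
#' The default condition mirrors the real dataset the dialect comes from:
#' 5110 records, ~4 percent missing `bmi`, ~5 percent stroke prevalence, and
#' moderate planted effects of age, hypertension, heart disease, glucose and
#' BMI. `preset = "separable"` is a deliberately easy, near-noiseless regime
#' (balanced classes, steep logistic coefficients) used to demonstrate
#' end-to-end signal recovery.
#'
#' @param n_records number of records (>= 10).
#' @param missing_rate MCAR missingness fraction in `[0, 1)` applied to `bmi`
#'   and `smoking_status`.
#' @param stroke_prevalence target marginal P(stroke = 1).
#' @param effect_sizes named numeric vector of log-odds coefficients on
#'   `age`, `hypertension`, `heart_disease`, `avg_glucose_level`, `bmi`.
#' @param glucose_mixture numeric `c(mean_normal, mean_diabetic, sd)` in
#'   mg/dL.
#' @param diabetic_fraction mixture weight of the diabetic glucose component.
#' @param seed RNG seed.
#' @param preset `"realistic"` (default) or `"separable"`.
#' @return an object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_records = 200, seed = 1)
#' tab <- generate_cohort(spec)
#' @export
cohort_spec <- function(n_records = 5110,
                        missing_rate = 0.04,
                        stroke_prevalence = 0.05,
                        effect_sizes = c(age = 0.08, hypertension = 1.2,
                                         heart_disease = 1.0,
                                         avg_glucose_level = 0.02,
                                         bmi = 0.03),
                        glucose_mixture = c(92, 175, 20),
                        diabetic_fraction = 0.2,
                        seed = 1L,
                        preset = c("realistic", "separable")) {
  preset <- match.arg(preset)
  if (preset == "separable") {
    # near-noiseless regime: the outcome is dominated by the steep glucose
    # effect, so the two classes form well-separated glucose-driven groups
    if (missing(stroke_prevalence)) stroke_prevalence <- 0.4
    if (missing(effect_sizes))
      effect_sizes <- c(age = 0.05, hypertension = 1.5, heart_disease = 1.5,
                        avg_glucose_level = 0.3, bmi = 0.02)
    if (missing(diabetic_fraction)) diabetic_fraction <- 0.4
    if (missing(missing_rate)) missing_rate <- 0.02
  }
  if (!is.numeric(n_records) || n_records < 10)
    stop_arg("invalid cohort spec: n_records must be >= 10")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_arg("invalid cohort spec: missing_rate must be in [0, 1)")
  if (stroke_prevalence <= 0 || stroke_prevalence >= 1)
    stop_arg("invalid cohort spec: stroke_prevalence must be in (0, 1)")
  if (!all(is.finite(effect_sizes)))
    stop_arg("invalid cohort spec: effect sizes must be finite")
  if (length(glucose_mixture) != 3 || glucose_mixture[3] <= 0)
    stop_arg("invalid cohort spec: glucose_mixture must be (mean_normal, mean_diabetic, sd)")
  structure(list(n_records = as.integer(n_records),
                 missing_rate = missing_rate,
                 stroke_prevalence = stroke_prevalence,
                 effect_sizes = effect_sizes,
                 glucose_mixture = glucose_mixture,
                 diabetic_fraction = diabetic_fraction,
                 seed = as.integer(seed),
                 preset = preset),
            class = "cohort_spec")
}

#' Generate a synthetic stroke cohort
#'
#' Draws a cohort in the Kaggle dialect. The stroke label follows a logistic
#' model on age, hypertension, heart disease, average glucose and BMI with
#' the spec's log-odds coefficients; the intercept is solved numerically so
#' the marginal prevalence matches `stroke_prevalence`. MCAR missingness at
#' `missing_rate` is applied to `bmi` and `smoking_status` only. Fully
#' reproducible for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return a [feature_table()] with the 10 modelling predictors, stroke
#'   labels and record ids.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_arg("spec must be a cohort_spec")
  sc <- cohort_schema()
  n <- spec$n_records
  with_seed(spec$seed, {
    age <- round(clamp(stats::rnorm(n, 45, 22), 1, 90), 0)
    gender <- sample(c("Female", "Male", "Other"), n, replace = TRUE,
                     prob = c(0.58, 0.415, 0.005))
    hypertension <- stats::rbinom(n, 1, clamp(0.02 + 0.0025 * age, 0, 1))
    heart_disease <- stats::rbinom(n, 1, clamp(0.01 + 0.0015 * age, 0, 1))
    ever_married <- ifelse(age >= 20,
                           ifelse(stats::runif(n) < 0.85, "Yes", "No"), "No")
    work_type <- ifelse(age < 17, "children",
                        sample(c("Private", "Self-employed", "Govt_job",
                                 "Never_worked"), n, replace = TRUE,
                               prob = c(0.70, 0.17, 0.11, 0.02)))
    residence <- sample(c("Urban", "Rural"), n, replace = TRUE)
    diabetic <- stats::runif(n) < spec$diabetic_fraction
    glucose <- ifelse(diabetic,
                      stats::rnorm(n, spec$glucose_mixture[2],
                                   spec$glucose_mixture[3]),
                      stats::rnorm(n, spec$glucose_mixture[1],
                                   spec$glucose_mixture[3]))
    glucose <- round(clamp(glucose, 50, 300), 2)
    bmi <- round(clamp(stats::rnorm(n, 28.5, 7), 12, 60), 1)
    smoking <- sample(c("never smoked", "formerly smoked", "smokes",
                        "Unknown"), n, replace = TRUE,
                      prob = c(0.37, 0.17, 0.16, 0.30))

    ef <- spec$effect_sizes
    lp <- ef[["age"]] * (age - mean(age)) +
      ef[["hypertension"]] * hypertension +
      ef[["heart_disease"]] * heart_disease +
      ef[["avg_glucose_level"]] * (glucose - mean(glucose)) +
      ef[["bmi"]] * (bmi - mean(bmi))
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) -
                           spec$stroke_prevalence,
                         c(-50, 50), tol = 1e-10)$root
    stroke <- stats::rbinom(n, 1, stats::plogis(b0 + lp))

    df <- data.frame(id = seq_len(n), gender = gender, age = age,
                     hypertension = hypertension,
                     heart_disease = heart_disease,
                     ever_married = ever_married, work_type = work_type,
                     Residence_type = residence,
                     avg_glucose_level = glucose, bmi = bmi,
                     smoking_status = smoking, stroke = stroke,
                     stringsAsFactors = FALSE)

    if (spec$missing_rate > 0) {
      miss_bmi <- stats::runif(n) < spec$missing_rate
      miss_smk <- stats::runif(n) < spec$missing_rate
      df$bmi[miss_bmi] <- NA_real_
      df$smoking_status[miss_smk] <- NA_character_
    }
    cohort_from_frame(df)
  })
}

# build a feature_table from a dialect data.frame (NA marks missing)
cohort_from_frame <- function(df) {
  sc <- cohort_schema()
  codebook <- list()
  n <- nrow(df)
  values <- matrix(NA_real_, n, length(sc$predictors),
                   dimnames = list(NULL, sc$predictors))
  for (attr in sc$predictors) {
    col <- df[[attr]]
    if (attr %in% sc$categorical) {
      col <- as.character(col)
      lv <- sort(unique(col[!is.na(col)]))
      codebook[[attr]] <- lv
      values[, attr] <- match(col, lv)
    } else {
      values[, attr] <- as.numeric(col)
    }
  }
  labels <- if ("stroke" %in% names(df) && !all(is.na(df$stroke)))
    as.integer(df$stroke) else NULL
  feature_table(values, is.na(values), sc$predictors, codebook,
                labels, as.integer(df$id))
}

#' Read a cohort CSV in the Kaggle stroke dialect
#'
#' The header must match the dialect exactly (case-sensitive). The literal
#' string `"N/A"` and empty cells are treated as missing and masked.
#'
#' @param path path to a CSV file.
#' @param encode if `TRUE` (default) categorical levels are mapped to
#'   deterministic integer codes (alphabetical level order) and a
#'   [feature_table()] is returned; if `FALSE` the raw dialect `data.frame`
#'   is returned.
#' @return a `feature_table` (or `data.frame` when `encode = FALSE`).
#' @export
read_cohort <- function(path, encode = TRUE) {
  if (!file.exists(path)) stop_arg("cohort file not found: %s", path)
  sc <- cohort_schema()
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(sc$columns, names(df))
  extra_cols <- setdiff(names(df), sc$columns)
  if (length(missing_cols) || length(extra_cols))
    stop_arg("schema error: %s%s",
             if (length(missing_cols))
               paste0("missing column(s) ",
                      paste(missing_cols, collapse = ", ")) else "",
             if (length(extra_cols))
               paste0(if (length(missing_cols)) "; " else "",
                      "unknown column(s) ",
                      paste(extra_cols, collapse = ", ")) else "")
  df <- df[, sc$columns]
  for (nm in sc$columns) {
    df[[nm]][df[[nm]] %in% c("N/A", "")] <- NA
  }
  numcols <- c("id", "age", "hypertension", "heart_disease",
               "avg_glucose_level", "bmi", "stroke")
  for (nm in numcols) df[[nm]] <- as.numeric(df[[nm]])
  if (!encode) return(df)
  cohort_from_frame(df)
}

#' Write a cohort to CSV in the Kaggle stroke dialect
#'
#' Categorical codes are decoded to their original string levels; masked
#' cells are serialized as the literal `N/A`.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  validate_feature_table(table)
  df <- as.data.frame(table)
  for (nm in names(df)) {
    col <- df[[nm]]
    col <- as.character(col)
    col[is.na(col)] <- "N/A"
    df[[nm]] <- col
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_arg("cannot write cohort to '%s'", path)
  invisible(path)
}
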