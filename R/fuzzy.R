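# Trapezoidal fuzzification and the six-code comorbidity risk rule base -----

#' Trapezoidal membership function
#'
#' `max(min((x - a)/(b - a), 1, (d - x)/(d - c)), 0)` for ordered corners
#' `a <= b <= c <= d`; equals 1 on the plateau `[b, c]` and 0 outside
#' `[a, d]`. Degenerate equal corners are handled by one-sided limits
#' (a vertical shoulder: membership jumps at the shared corner).
#'
#' @param x numeric vector of inputs (feature units).
#' @param corners numeric `c(a, b, c, d)`, non-decreasing.
#' @return membership values in `[0, 1]`.
#' @export
trapezoid_membership <- function(x, corners) {
  if (length(corners) != 4 || is.unsorted(corners))
    stop_arg("corners must be four non-decreasing values a <= b <= c <= d")
  a <- corners[1]; b <- corners[2]; cc <- corners[3]; d <- corners[4]
  left <- if (b > a) (x - a) / (b - a) else ifelse(x >= b, 1, 0)
  right <- if (d > cc) (d - x) / (d - cc) else ifelse(x <= cc, 1, 0)
  pmax(pmin(left, 1, right), 0)
}

#' Build the comorbidity fuzzy rule base
#'
#' Six risk codes over the 2 x 2 grid of the diabetes class (`dia_cls`,
#' derived from average glucose) and the heart-disease class (`hea_cls`):
#'
#' * code 1 — normal: `dia_cls = 0` and `hea_cls = 0`;
#' * code 2 — high diabetes risk: `dia_cls = 1`, `hea_cls = 0`, record
#'   glucose above the diabetic-mean threshold `xx`;
#' * code 3 — moderate diabetes risk: `dia_cls = 1`, `hea_cls = 0`,
#'   glucose between the normal mean and `xx`;
#' * code 4 — combined risk: `dia_cls = 1` and `hea_cls = 1` (the otherwise
#'   unhandled cell of the grid);
#' * code 5 — high heart risk: `hea_cls = 1`, `dia_cls = 0`, heart proxy
#'   above `w`;
#' * code 6 — moderate heart risk: `hea_cls = 1`, `dia_cls = 0`, proxy
#'   below `w`.
#'
#' The thresholds default to aggregate means: `xx` is the mean glucose among
#' diabetic-class records, `w` the mean of the heart-risk proxy (age) among
#' heart-disease records, and `alpha0` the mean glucose among normal-class
#' records. Membership functions per code are trapezoids on the relevant
#' feature axis used to grade the crisp output.
#'
#' @param xx diabetic glucose threshold (mg/dL).
#' @param w heart-risk proxy threshold (years of age).
#' @param alpha0 normal-class mean glucose (mg/dL).
#' @param glucose_cut crisp cut deriving `dia_cls` from average glucose
#'   (default 125 mg/dL).
#' @return an object of class `fuzzy_rule_base`.
#' @export
fuzzy_rule_base <- function(xx = 175, w = 68, alpha0 = 92,
                            glucose_cut = 125) {
  if (!all(is.finite(c(xx, w, alpha0, glucose_cut))))
    stop_arg("rule-base thresholds must be finite")
  if (xx <= alpha0)
    stop_arg("diabetic threshold xx must exceed the normal mean alpha0")
  spread_g <- xx - alpha0
  spread_w <- max(w / 4, 1)
  structure(list(
    xx = xx, w = w, alpha0 = alpha0, glucose_cut = glucose_cut,
    # membership trapezoids on the glucose axis (codes 2,3) and the
    # heart-proxy axis (codes 5,6); code 1 and 4 are crisp cells
    mf = list(
      # right plateaus extend beyond the physiological range so extreme
      # values never decay back toward the milder code
      dia = c(alpha0, xx, max(400, xx + spread_g), max(500, xx + 2 * spread_g)),
      hea = c(w - 2 * spread_w, w, max(150, w + spread_w),
              max(200, w + 2 * spread_w))
    ),
    codes = 1:6), class = "fuzzy_rule_base")
}

#' @export
print.fuzzy_rule_base <- function(x, ...) {
  cat(sprintf(paste0("<fuzzy_rule_base> 6 codes; xx = %.1f mg/dL, ",
                     "w = %.1f, alpha0 = %.1f, glucose cut = %.1f\n"),
              x$xx, x$w, x$alpha0, x$glucose_cut))
  invisible(x)
}

#' Assign a comorbidity risk code
#'
#' Applies the rule base to one record. Exactly one code in `1..6` is
#' produced for every input (the rule table is exhaustive and mutually
#' exclusive over the class grid and threshold comparisons).
#'
#' @param dia_cls diabetes class, 0 or 1.
#' @param hea_cls heart-disease class, 0 or 1.
#' @param alpha_dia record's glucose aggregate (mg/dL), compared with `xx`.
#' @param alpha_hea record's heart-risk proxy, compared with `w`.
#' @param rules a [fuzzy_rule_base()].
#' @return integer risk code in `1..6`.
#' @export
assign_risk_code <- function(dia_cls, hea_cls, alpha_dia, alpha_hea,
                             rules = fuzzy_rule_base()) {
  stopifnot(dia_cls %in% c(0, 1), hea_cls %in% c(0, 1))
  if (dia_cls == 0 && hea_cls == 0) return(1L)
  if (dia_cls == 1 && hea_cls == 1) return(4L)
  if (dia_cls == 1) {
    if (alpha_dia > rules$xx) return(2L) else return(3L)
  }
  if (alpha_hea > rules$w) return(5L) else return(6L)
}

#' Centroid defuzzification over activated codes
#'
#' `g = sum(code * activation) / sum(activation)`, a convex combination of
#' the activated codes, so the crisp value always lies within the code
#' range. If all activations are zero the hard-assigned code is returned
#' (with a message).
#'
#' @param activations nonnegative activation per code.
#' @param codes integer codes (same length).
#' @param hard_code fallback code when all activations are zero.
#' @return the crisp scalar.
#' @export
defuzzify_crisp <- function(activations, codes, hard_code = codes[1]) {
  if (length(activations) != length(codes))
    stop_arg("activations and codes must align")
  if (any(activations < 0)) stop_arg("activations must be nonnegative")
  tot <- sum(activations)
  if (tot == 0) {
    message("defuzzify_crisp: all activations zero; returning hard code")
    return(as.numeric(hard_code))
  }
  sum(codes * activations) / tot
}

#' Fuzzy risk coding of a cohort
#'
#' Derives per record the diabetes class (glucose above `glucose_cut`), the
#' heart class (`heart_disease` column), the hard risk code via
#' [assign_risk_code()], and a graded crisp value: the membership of the
#' record's glucose (codes 2/3) or heart proxy (codes 5/6) in the rule
#' base's trapezoid blends the hard code with its milder neighbour, so the
#' crisp value slides between adjacent codes as the evidence weakens. Codes
#' 1 and 4 are crisp cells.
#'
#' @param table a complete [feature_table()] containing
#'   `avg_glucose_level`, `heart_disease` and `age`.
#' @param rules a [fuzzy_rule_base()]; by default thresholds are derived
#'   from the cohort's aggregate statistics.
#' @return object of class `fuzzy_risk`: integer `codes`, numeric `crisp`
#'   (in `[1, 6]`), the `rules` used.
#' @export
fuzzy_risk_codes <- function(table, rules = NULL) {
  X <- masked_matrix(table)
  need <- c("avg_glucose_level", "heart_disease", "age")
  if (!all(need %in% colnames(X)))
    stop_arg("table must carry %s", paste(need, collapse = ", "))
  glu <- X[, "avg_glucose_level"]
  hea <- X[, "heart_disease"]
  age <- X[, "age"]
  if (anyNA(glu) || anyNA(hea) || anyNA(age))
    stop_arg("fuzzy risk coding requires complete glucose/heart/age")
  if (is.null(rules)) {
    cut <- 125
    dia0 <- glu > cut
    xx <- if (any(dia0)) mean(glu[dia0]) else cut * 1.4
    a0 <- if (any(!dia0)) mean(glu[!dia0]) else cut * 0.7
    w <- if (any(hea == 1)) mean(age[hea == 1]) else mean(age)
    rules <- fuzzy_rule_base(xx = xx, w = w, alpha0 = min(a0, xx - 1),
                             glucose_cut = cut)
  }
  dia_cls <- as.integer(glu > rules$glucose_cut)
  n <- length(glu)
  codes <- integer(n)
  crisp <- numeric(n)
  for (i in seq_len(n)) {
    code <- assign_risk_code(dia_cls[i], hea[i], glu[i], age[i], rules)
    codes[i] <- code
    crisp[i] <- switch(as.character(code),
      "1" = 1,
      "4" = 4,
      "2" = { mu <- trapezoid_membership(glu[i], rules$mf$dia)
              defuzzify_crisp(c(mu, 1 - mu), c(2, 3), 2) },
      "3" = { mu <- trapezoid_membership(glu[i], rules$mf$dia)
              defuzzify_crisp(c(mu, 1 - mu), c(2, 3), 3) },
      "5" = { mu <- trapezoid_membership(age[i], rules$mf$hea)
              defuzzify_crisp(c(mu, 1 - mu), c(5, 6), 5) },
      "6" = { mu <- trapezoid_membership(age[i], rules$mf$hea)
              defuzzify_crisp(c(mu, 1 - mu), c(5, 6), 6) })
  }
  structure(list(codes = codes, crisp = crisp, rules = rules,
                 dia_cls = dia_cls, hea_cls = as.integer(hea)),
            class = "fuzzy_risk")
}

#' Enumerate the rule base over its input domain
#'
#' Walks every combination of `dia_cls`, `hea_cls` and threshold comparison
#' outcome and returns the set of reachable codes (used to verify the rule
#' table is a total function onto `{1, ..., 6}`).
#'
#' @param rules a [fuzzy_rule_base()].
#' @return sorted integer vector of reachable codes.
#' @export
enumerate_risk_codes <- function(rules = fuzzy_rule_base()) {
  lo_g <- rules$alpha0 + 0.1 * (rules$xx - rules$alpha0)
  hi_g <- rules$xx + 1
  combos <- expand.grid(dia = 0:1, hea = 0:1,
                        glu = c(lo_g, hi_g),
                        proxy = c(rules$w - 1, rules$w + 1))
  codes <- mapply(function(d, h, g, p)
    assign_risk_code(d, h, g, p, rules),
    combos$dia, combos$hea, combos$glu, combos$proxy)
  sort(unique(as.integer(codes)))
}
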