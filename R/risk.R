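# Organ-dose aggregation, the linear organ-dose vs effective-diameter model,
# and the BEIR VII excess relative risk (ERR) of lung cancer.
#
# ERR(e, a, D) = beta_s * D * exp(gamma * e_star) * (a / 60)^eta, with
# e_star = (e - 30)/10 for exposure age e < 30 and 0 otherwise.  beta is
# sex-specific with its published 95% CI; gamma and eta are the lung-cancer
# age modifiers.  The model is linear in equivalent dose D (Sv), so dose
# ratios map to ERR ratios exactly.

#' Mean organ dose from an absolute dose grid
#'
#' Arithmetic mean over the voxels of the organ mask, with 1-sigma
#' statistical uncertainty propagated from history batches.
#'
#' @param dose a `dose_grid` in cGy (see [to_absolute()])
#' @param mask an [organ_mask()]
#' @param patient_id patient identifier
#' @param protocol_label "3DCT" or "4DCT"
#' @return one-row data.frame: patient_id, organ, protocol, dose_cgy,
#'   sigma_cgy
#' @export
organ_mean_dose <- function(dose, mask, patient_id = NA_character_,
                            protocol_label = NA_character_) {
  stopifnot(inherits(mask, "organ_mask"))
  rm_ <- region_mean(dose, mask)
  data.frame(patient_id = patient_id, organ = mask$organ,
             protocol = protocol_label, dose_cgy = rm_$mean,
             sigma_cgy = rm_$sigma)
}

#' Fit organ dose against patient effective diameter
#'
#' Ordinary least squares for the linear size-dose model
#' `dose = intercept + slope * effective_diameter` fitted per organ and
#' protocol.
#'
#' @param records data.frame with columns `patient_id`, `dose_cgy` and
#'   optionally `organ`, `protocol` (must each be single-valued)
#' @param diameters named vector of effective diameters (mm) indexed by
#'   patient id, or a data.frame with `patient_id`,
#'   `effective_diameter_mm`
#' @return object of class `dose_size_fit`: intercept_cgy,
#'   slope_cgy_per_mm, r_squared, n_points, organ, protocol, se
#' @export
fit_dose_vs_diameter <- function(records, diameters) {
  stopifnot(is.data.frame(records), nrow(records) >= 3)
  if (is.data.frame(diameters))
    diameters <- setNames(diameters$effective_diameter_mm,
                          diameters$patient_id)
  organ <- if ("organ" %in% names(records)) unique(records$organ) else NA
  protocol <- if ("protocol" %in% names(records))
    unique(records$protocol) else NA
  if (length(organ) != 1 || length(protocol) != 1)
    stop("fit one organ and one protocol at a time")
  d <- diameters[as.character(records$patient_id)]
  if (anyNA(d)) stop("missing diameters for some patient ids")
  if (var(d) == 0) stop("constant diameters: singular design")
  fit <- lm(records$dose_cgy ~ d)
  s <- summary(fit)
  structure(list(intercept_cgy = unname(coef(fit)[1]),
                 slope_cgy_per_mm = unname(coef(fit)[2]),
                 r_squared = s$r.squared,
                 se = unname(s$coefficients[, "Std. Error"]),
                 n_points = nrow(records), organ = organ,
                 protocol = protocol),
            class = "dose_size_fit")
}

#' @export
print.dose_size_fit <- function(x, ...) {
  cat(sprintf("<dose_size_fit> %s/%s: dose = %.4g %+.4g * d  (R2 = %.3f, n = %d)\n",
              x$organ, x$protocol, x$intercept_cgy, x$slope_cgy_per_mm,
              x$r_squared, x$n_points))
  invisible(x)
}

#' Predict organ dose at a given effective diameter
#'
#' Negative extrapolations are clamped to zero with a warning.
#'
#' @param fit a [fit_dose_vs_diameter()] result, or a list with
#'   `intercept_cgy` and `slope_cgy_per_mm`
#' @param diameter_mm effective diameter(s) in mm
#' @return predicted dose(s) in cGy
#' @export
predict_dose <- function(fit, diameter_mm) {
  p <- fit$intercept_cgy + fit$slope_cgy_per_mm * diameter_mm
  if (any(p < 0)) {
    warning("negative predicted dose clamped to 0 (extrapolation)")
    p <- pmax(p, 0)
  }
  p
}

#' BEIR VII lung-cancer ERR parameters
#'
#' Sex-specific beta with 95% CI (per Sv), exposure-age modifier gamma,
#' attained-age modifier eta, and the pivots of the age rules.
#'
#' @param beta_male,beta_female point estimates with CI bounds
#' @param gamma,eta age-modifier exponents for lung cancer
#' @return object of class `err_params`
#' @export
err_params <- function(beta_male = c(est = 0.32, lo = 0.15, hi = 0.70),
                       beta_female = c(est = 1.40, lo = 0.94, hi = 2.1),
                       gamma = -0.30, eta = -1.4) {
  for (b in list(beta_male, beta_female)) {
    if (any(b <= 0)) stop("beta values must be > 0")
    if (!(b["lo"] < b["est"] && b["est"] < b["hi"]))
      stop("beta CI must bracket the point estimate")
  }
  structure(list(beta_male = beta_male, beta_female = beta_female,
                 gamma = gamma, eta = eta, exposure_pivot = 30,
                 pivot_scale = 10, attained_pivot = 60),
            class = "err_params")
}

#' Excess relative risk of lung cancer (BEIR VII)
#'
#' @param sex "male" or "female"
#' @param e age at exposure (years)
#' @param a attained age (years), > 0
#' @param D equivalent lung dose (Sv), >= 0
#' @param params an [err_params()]
#' @return one-row data.frame: err, lo, hi (95% CI from the beta bounds,
#'   other parameters fixed), sex, e, a, D
#' @export
#' @examples
#' err("male", e = 40, a = 60, D = 1)    # both modifiers unity: ERR = beta
#' err("female", e = 40, a = 60, D = 1)
err <- function(sex = c("male", "female"), e, a, D, params = err_params()) {
  sex <- match.arg(sex)
  stopifnot(inherits(params, "err_params"))
  if (any(D < 0)) stop("dose must be >= 0")
  if (any(a <= 0)) stop("attained age must be > 0")
  if (any(e < 0)) stop("exposure age must be >= 0")
  beta <- if (sex == "male") params$beta_male else params$beta_female
  e_star <- ifelse(e < params$exposure_pivot,
                   (e - params$exposure_pivot) / params$pivot_scale, 0)
  mod <- exp(params$gamma * e_star) * (a / params$attained_pivot)^params$eta
  data.frame(err = unname(beta["est"]) * D * mod,
             lo = unname(beta["lo"]) * D * mod,
             hi = unname(beta["hi"]) * D * mod,
             sex = sex, e = e, a = a, D = D)
}

#' Cohort lung-cancer risk and 4DCT:3DCT risk ratio
#'
#' Computes per-patient ERR for both protocol arms from lung doses and
#' summarizes the 4DCT:3DCT risk ratio.  Equivalent dose uses a radiation
#' weighting factor of 1 for photons (1 cGy absorbed = 0.01 Sv), so each
#' patient's ERR ratio equals their lung-dose ratio exactly.
#'
#' @param records data.frame of lung doses: columns `patient_id`,
#'   `protocol` ("3DCT"/"4DCT"), `dose_cgy`
#' @param patients data.frame: `patient_id`, `age`, `sex`
#' @param params an [err_params()]
#' @param attained_age attained age for evaluation; default exposure age +
#'   20 years
#' @return list: `per_patient` (ERR and CI per patient and protocol, plus
#'   the patient's ratio), `mean_ratio`, `ratio_of_means`
#' @export
cohort_risk <- function(records, patients, params = err_params(),
                        attained_age = NULL) {
  stopifnot(all(c("patient_id", "protocol", "dose_cgy") %in% names(records)),
            all(c("patient_id", "age", "sex") %in% names(patients)))
  out <- NULL
  ratios <- c()
  for (pid in unique(patients$patient_id)) {
    pr <- records[records$patient_id == pid, ]
    d3 <- pr$dose_cgy[pr$protocol == "3DCT"]
    d4 <- pr$dose_cgy[pr$protocol == "4DCT"]
    if (length(d3) != 1 || length(d4) != 1) {
      warning("patient ", pid, " missing a protocol arm: skipped")
      next
    }
    p <- patients[patients$patient_id == pid, ][1, ]
    a <- if (is.null(attained_age)) p$age + 20 else attained_age
    r3 <- err(p$sex, e = p$age, a = a, D = d3 * 0.01, params = params)
    r4 <- err(p$sex, e = p$age, a = a, D = d4 * 0.01, params = params)
    r3$patient_id <- r4$patient_id <- pid
    r3$protocol <- "3DCT"; r4$protocol <- "4DCT"
    out <- rbind(out, r3, r4)
    ratios <- c(ratios, setNames(r4$err / r3$err, pid))
  }
  if (is.null(out)) stop("no patient had both protocol arms")
  m3 <- mean(out$err[out$protocol == "3DCT"])
  m4 <- mean(out$err[out$protocol == "4DCT"])
  list(per_patient = out, patient_ratios = ratios,
       mean_ratio = mean(ratios), ratio_of_means = m4 / m3)
}
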