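# Evaluate the linear predictor of a fitted model at arbitrary
# (age, year) cells, using stored indices for in-sample years and
# caller-supplied index values for out-of-sample years.

model_eta_at <- function(model, ages, years, k1 = NULL, k2 = NULL,
                         gamma = NULL, freeze_gamma = FALSE) {
  spec <- model$spec
  nx <- length(ages)
  nt <- length(years)

  # resolve age indices for models with per-age profiles
  if (spec$has_static_age || spec$bilinear_terms >= 1L) {
    ai <- match(round(ages, 9), round(model$ages, 9))
    if (anyNA(ai)) {
      stop(sprintf(
        "age %g is not a fitted age-group midpoint for model %s",
        ages[which(is.na(ai))[1L]], spec$name
      ))
    }
  }

  # resolve period indices
  resolve_k <- function(stored, supplied, label) {
    out <- numeric(nt)
    in_sample <- match(years, model$years)
    miss <- which(is.na(in_sample))
    out[!is.na(in_sample)] <- stored[in_sample[!is.na(in_sample)]]
    if (length(miss) > 0L) {
      if (is.null(supplied)) {
        stop(sprintf(
          "year(s) %s are out of sample and no '%s' values were supplied; forecast the index first (see fit_index_model/forecast_index)",
          paste(years[miss], collapse = ", "), label
        ))
      }
      sup <- supplied
      if (!is.null(names(sup))) {
        sv <- sup[as.character(years[miss])]
        if (anyNA(sv)) {
          stop(sprintf("'%s' values missing for year(s) %s", label,
                       paste(years[miss][is.na(sv)], collapse = ", ")))
        }
        out[miss] <- sv
      } else {
        if (length(sup) != length(miss)) {
          stop(sprintf("'%s' must supply one value per out-of-sample year",
                       label))
        }
        out[miss] <- sup
      }
    }
    out
  }

  eta <- matrix(0, nx, nt)
  if (spec$has_static_age) eta <- eta + model$a[ai]
  if (spec$cbd_structure) {
    kk1 <- resolve_k(model$k1, k1, "k1")
    kk2 <- resolve_k(model$k2, k2, "k2")
    eta <- eta + rep(kk1, each = nx) + outer(ages - model$x_bar, kk2)
  } else if (spec$bilinear_terms >= 1L) {
    kk1 <- resolve_k(model$k1, k1, "k1")
    eta <- eta + outer(model$b1[ai], kk1)
    if (spec$bilinear_terms >= 2L) {
      kk2 <- resolve_k(model$k2, k2, "k2")
      eta <- eta + outer(model$b2[ai], kk2)
    }
  } else if (spec$name == "APC") {
    kk1 <- resolve_k(model$k1, k1, "k1")
    eta <- eta + rep(kk1, each = nx)
  }

  if (needs_cohort(spec)) {
    lab <- outer(-ages, years, `+`)
    gval <- matrix(NA_real_, nx, nt)
    # in-sample cohorts via the pooling map built at fit time
    mapped <- model$cohort_raw_map[as.character(as.vector(lab))]
    known <- !is.na(mapped)
    gval[known] <- model$gamma[as.character(mapped[known])]
    if (!is.null(gamma)) {
      sup <- gamma[as.character(as.vector(lab))]
      use <- !known & !is.na(sup)
      gval[use] <- sup[use]
      known <- known | use
    }
    if (any(!known)) {
      if (!freeze_gamma) {
        stop(sprintf(
          "cohort(s) %s were not observed in the fitting period and no 'gamma' values were supplied",
          paste(utils::head(sort(unique(as.vector(lab)[!known])), 5),
                collapse = ", ")
        ))
      }
      last_gamma <- model$gamma[length(model$gamma)]
      warning(sprintf(
        "%d cells belong to cohorts outside the fitting period; cohort effect frozen at its last estimated value (%.4g)",
        sum(!known), last_gamma
      ))
      gval[!known] <- last_gamma
    }
    eta <- eta + switch(spec$cohort_term,
      free_slope = model$b2[ai] * gval,
      unit_slope = gval,
      cbd_slope = (model$x_c - ages) * gval
    )
  }
  dimnames(eta) <- list(as.character(ages), as.character(years))
  eta
}

#' Predicted death probabilities from a fitted model
#'
#' Evaluates `q_hat = expit(eta)` at the requested ages and years. For
#' years inside the fitting period the stored period indices are used;
#' for later years the caller must supply forecast index values (see
#' [forecast_index()]), and for models with a cohort term, values for
#' unseen cohorts (or `freeze_gamma = TRUE` to hold the cohort effect at
#' its last estimated value, with a warning).
#'
#' @param model A converged `fitted_mortality_model`.
#' @param ages Age-group midpoints (default: the fitted ages).
#' @param years Calendar years (default: the fitted years).
#' @param k1,k2 Optional index values for out-of-sample years, either
#'   named by year or in year order.
#' @param gamma Optional named cohort-effect values for unseen cohorts.
#' @param freeze_gamma Hold the cohort effect at its last estimated
#'   value for unseen cohorts (default `FALSE`).
#' @return Matrix of probabilities in (0, 1), ages x years.
#' @export
predict_q <- function(model, ages = NULL, years = NULL, k1 = NULL,
                      k2 = NULL, gamma = NULL, freeze_gamma = FALSE) {
  if (!inherits(model, "fitted_mortality_model")) {
    stop("'model' must be a fitted_mortality_model")
  }
  if (!isTRUE(model$converged)) {
    stop(sprintf(
      "model %s did not converge (%d iterations); refusing to predict from a non-converged fit",
      model$spec$name, model$n_iter
    ))
  }
  if (is.null(ages)) ages <- model$ages
  if (is.null(years)) years <- model$years
  expit(model_eta_at(model, ages, years, k1 = k1, k2 = k2, gamma = gamma,
                     freeze_gamma = freeze_gamma))
}
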