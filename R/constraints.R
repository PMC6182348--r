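#' Normalise model parameters to their identifiability constraints
#'
#' The bilinear predictors are invariant under rescaling `(b, k) ->
#' (b/s, s k)` and under location shifts of the indices absorbed into the
#' static age profile. This function transforms raw parameters so the
#' model's declared constraints hold exactly while leaving every
#' predictor value (hence every fitted probability) unchanged:
#' for an LC-type term `b' = b / sum(b)`, `k' = sum(b) * (k - k[t0])`,
#' `a' = a + b * k[t0]` with `t0` the first fitted year; cohort effects
#' are recentred at the reference cohort (first cohort, or sum-to-zero
#' for RH/M8) with the compensation absorbed into `a` (or into `k1`,
#' `k2` for M8).
#'
#' @param model A `fitted_mortality_model`, or a plain list of raw
#'   parameter vectors (fields among `a`, `b1`, `k1`, `b2`, `k2`,
#'   `gamma`, `x_c`, `x_bar`).
#' @param spec The [model_spec()]; defaults to `model$spec`.
#' @return The same kind of object with normalised parameters. The
#'   operation is idempotent.
#' @examples
#' p <- apply_identifiability_constraints(
#'   list(a = c(0, 0), b1 = c(2, 2), k1 = c(1, 3)), spec = "LC"
#' )
#' p$b1  # 0.5 0.5
#' p$k1  # 0 8
#' @export
apply_identifiability_constraints <- function(model, spec = NULL) {
  if (is.null(spec)) spec <- model$spec
  spec <- as_model_spec(spec)
  par <- model

  normalise_bilinear <- function(b, k, a) {
    s <- sum(b)
    if (abs(s) < 1e-12) {
      stop("degenerate scale: age loadings sum to 0, term is unidentified")
    }
    list(b = b / s, k = s * (k - k[1L]), a = a + b * k[1L])
  }

  if (spec$name %in% c("LC", "LC2", "LCC")) {
    n1 <- normalise_bilinear(par$b1, par$k1, par$a)
    par$b1 <- n1$b; par$k1 <- n1$k; par$a <- n1$a
    if (spec$name == "LC2") {
      n2 <- normalise_bilinear(par$b2, par$k2, par$a)
      par$b2 <- n2$b; par$k2 <- n2$k; par$a <- n2$a
    }
    if (spec$name == "LCC") {
      n2 <- normalise_bilinear(par$b2, par$gamma, par$a)
      par$b2 <- n2$b
      par$gamma[] <- n2$k
      par$a <- n2$a
    }
  } else if (spec$name == "APC") {
    par$a <- par$a + par$k1[1L] + par$gamma[1L]
    par$k1 <- par$k1 - par$k1[1L]
    par$gamma <- par$gamma - par$gamma[1L]
  } else if (spec$name == "RH") {
    s <- sum(par$b1)
    if (abs(s) < 1e-12) {
      stop("degenerate scale: age loadings sum to 0, term is unidentified")
    }
    par$b1 <- par$b1 / s
    par$k1 <- s * par$k1
    m <- mean(par$k1)
    par$k1 <- par$k1 - m
    par$a <- par$a + par$b1 * m
    g <- mean(par$gamma)
    par$gamma <- par$gamma - g
    par$a <- par$a + g
  } else if (spec$name == "M8") {
    g <- mean(par$gamma)
    par$gamma <- par$gamma - g
    par$k1 <- par$k1 + (par$x_c - par$x_bar) * g
    par$k2 <- par$k2 - g
  }
  # CBD: no constraints
  par
}
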