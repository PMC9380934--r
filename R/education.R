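# Education placement: cumulative-logit prediction of the proportion of the
# cohort in each of three school settings (mainstream < mainstream with
# support < special provision) from cohort mean scores, evaluated once at
# primary and once at secondary entry; or fixed observed mixes (scenario 2).

#' Ordered-logit education placement model
#'
#' @param beta_vabs,beta_iq score coefficients (negative: higher-functioning
#'   cohorts are more likely to be in mainstream settings).
#' @param cut1 cut-point below "mainstream with support".
#' @param cut2 cut-point below "specialist schooling"; must exceed `cut1`.
#' @return object of class `edu_logit`.
#' @export
edu_logit <- function(beta_vabs, beta_iq, cut1, cut2) {
  if (!(cut1 < cut2)) stop("ordered-logit cut-points must satisfy cut1 < cut2")
  structure(list(beta_vabs = beta_vabs, beta_iq = beta_iq, cut1 = cut1, cut2 = cut2),
            class = "edu_logit")
}

#' Education placement probabilities
#'
#' Cumulative-logistic category probabilities with latent index
#' `eta = beta_vabs * vabs + beta_iq * iq`:
#' `P(mainstream) = plogis(cut1 - eta)`,
#' `P(mainstream or supported) = plogis(cut2 - eta)`, and the supported and
#' special probabilities by differencing.  With the (negative) default
#' coefficients this orientation gives higher mainstream probability for
#' higher-functioning cohorts; the opposite orientation produces ~100%
#' special placement for any plausible scores.
#'
#' @param model an [edu_logit()] model.
#' @param iq,vabs cohort mean scores.
#' @return named numeric vector `(mainstream, supported, special)`, summing
#'   to 1 exactly.
#' @export
placement_probs <- function(model, iq, vabs) {
  stopifnot(inherits(model, "edu_logit"), is.finite(iq), is.finite(vabs))
  eta <- model$beta_vabs * vabs + model$beta_iq * iq
  p1 <- stats::plogis(model$cut1 - eta)
  p12 <- stats::plogis(model$cut2 - eta)
  c(mainstream = p1, supported = p12 - p1, special = 1 - p12)
}

# the two fitted placement models held in a parameter set
.edu_models <- function(m) {
  list(primary = edu_logit(m["edu_pri_vabs"], m["edu_pri_iq"], m["edu_pri_cut1"], m["edu_pri_cut2"]),
       secondary = edu_logit(m["edu_sec_vabs"], m["edu_sec_iq"], m["edu_sec_cut1"], m["edu_sec_cut2"]))
}

#' Observed education placement mixes
#'
#' Fixed placement proportions applied in the educational-outcomes scenario,
#' in which children attend the same type of school throughout childhood.
#'
#' @param arm `"ABA"` or `"TAU"`.
#' @param params an [aba_parameters()] object (defaults used if omitted).
#' @return named probability vector `(mainstream, supported, special)`.
#' @export
observed_placement <- function(arm = c("ABA", "TAU"), params = aba_parameters()) {
  arm <- match.arg(arm)
  m <- param_means(params)
  pre <- paste0("obs_", tolower(arm), "_")
  p <- c(mainstream = unname(m[paste0(pre, "mainstream")]),
         supported = unname(m[paste0(pre, "supported")]),
         special = unname(m[paste0(pre, "special")]))
  p / sum(p)
}
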