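# Link helpers, covariate scaling and the GLM suite on profile tables

#' Scaled logarithm of positive counts
#'
#' Natural-log transform followed by z-scoring (mean 0, s.d. 1), used for
#' the number of distinct transcriptomes so that main effects and the
#' interaction are interpretable at the average log count.
#'
#' @param x Positive counts.
#' @return Numeric vector with mean 0 and s.d. 1.
#' @examples
#' scale_log(c(1, exp(1), exp(2)))
#' @export
scale_log <- function(x) {
  if (any(is.na(x)) || any(x <= 0))
    stop("scale_log() requires strictly positive, non-missing counts")
  lx <- log(x)
  s <- sd(lx)
  if (!is.finite(s) || s == 0)
    stop("scale_log() is undefined for constant input (zero s.d.)")
  (lx - mean(lx)) / s
}

#' Inverse link functions
#'
#' `inverse_logit(x) = 1 / (1 + exp(-x))` maps a logit-scale linear
#' predictor to a probability; `inverse_log(x) = exp(x)` maps a log-scale
#' linear predictor to an expected count.
#'
#' @param x Value(s) on the link scale.
#' @return Probability in (0, 1), or positive expected count.
#' @examples
#' inverse_logit(0)        # 0.5
#' inverse_log(1.04)       # about 2.8
#' @export
inverse_logit <- function(x) 1 / (1 + exp(-x))

#' @rdname inverse_logit
#' @export
inverse_log <- function(x) exp(x)

#' Fit a generalized linear model on a profile table
#'
#' Thin wrapper around [stats::glm()] (iteratively reweighted least squares)
#' for the binomial, poisson and quasibinomial families used by the
#' plasticity analysis. Non-convergence and (quasi-)separation are reported
#' via the `converged` and `boundary` fields rather than silently returned.
#'
#' @param formula Model formula.
#' @param data Data frame (e.g. from [profile_table()] or [record_table()]).
#' @param family One of `"binomial"`, `"poisson"`, `"quasibinomial"` or a
#'   family object.
#' @return The fitted `glm` object, with an extra attribute `"diagnostics"`
#'   (list with `converged` and `boundary`).
#' @export
fit_plasticity_glm <- function(formula, data, family = "binomial") {
  if (is.character(family))
    family <- switch(family,
                     binomial = binomial(link = "logit"),
                     poisson = poisson(link = "log"),
                     quasibinomial = quasibinomial(link = "logit"),
                     stop("unsupported family: ", family))
  fit <- glm(formula, data = data, family = family,
             control = list(epsilon = 1e-8, maxit = 100))
  diag <- list(converged = fit$converged, boundary = fit$boundary)
  if (!fit$converged)
    warning("GLM did not converge for ", deparse(formula))
  if (fit$boundary)
    warning("GLM fit on boundary (possible separation) for ",
            deparse(formula))
  attr(fit, "diagnostics") <- diag
  fit
}

#' Wald summary of a fitted model
#'
#' Estimates, 95% Wald confidence intervals and z-test p-values on the link
#' scale, in a table mirroring the usual reporting layout.
#'
#' @param fit A fitted `glm`, `lm` or `ztnb` object.
#' @return Data frame with columns `term`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
wald_table <- function(fit) {
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- b / se
  data.frame(term = names(b),
             estimate = as.numeric(b),
             ci_low = as.numeric(b - qnorm(0.975) * se),
             ci_high = as.numeric(b + qnorm(0.975) * se),
             p_value = as.numeric(2 * pnorm(-abs(z))),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit the plasticity model suite on a population
#'
#' Fits, where the data permit, the models of the plasticity analysis:
#' \describe{
#'   \item{plasticity}{binomial-logit: plastic ~ sensitive (all genomes).}
#'   \item{n_phenotypes}{zero-truncated negative binomial (log):
#'     n_phenotypes ~ sensitive.}
#'   \item{uncertainty}{quasibinomial-logit: uncertainty ~ sensitive.}
#'   \item{viability}{binomial-logit: viable in all environments ~ plastic,
#'     sensitive-transcriptome genomes only.}
#'   \item{phen_by_cost}{zero-truncated negative binomial (log):
#'     n_phenotypes ~ scaled log transcriptomes x viability cost.}
#'   \item{tlen}{linear model on genome x environment records:
#'     transcriptome length ~ plastic * sensitive (viable records).}
#'   \item{io}{poisson-log on viable records of plastic genomes:
#'     input-output executions inside tandem repeats ~ sensitive.}
#' }
#' Models whose design is degenerate at the current scale (a constant
#' predictor or response) are returned as `NULL` with the reason recorded
#' in the `skipped` element.
#'
#' @param population A `dg_population`, or a list with precomputed
#'   `profiles` table ([profile_table()]) and `records` table
#'   ([record_table()]).
#' @return An object of class `dg_models`: list of fits plus `skipped`.
#' @export
plasticity_models <- function(population) {
  if (inherits(population, "dg_population")) {
    tbl <- profile_table(population)
    rec <- record_table(population)
  } else {
    tbl <- population$profiles
    rec <- population$records
  }
  tbl <- tbl[!is.na(tbl$quadrant), ]
  fits <- list()
  skipped <- character()

  can_vary <- function(x) length(unique(x[!is.na(x)])) > 1

  try_fit <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      structure(conditionMessage(e), class = "dg_fit_error"))
    if (inherits(res, "dg_fit_error")) {
      skipped[name] <<- as.character(res)
    } else {
      fits[[name]] <<- res
    }
  }

  # plasticity ~ sensitivity
  if (can_vary(tbl$sensitive) && can_vary(tbl$plastic)) {
    try_fit("plasticity",
            fit_plasticity_glm(plastic ~ sensitive, tbl, "binomial"))
  } else skipped["plasticity"] <- "constant response or predictor"

  # number of phenotypes ~ sensitivity (zero-truncated NB)
  if (can_vary(tbl$sensitive) && can_vary(tbl$n_phenotypes)) {
    try_fit("n_phenotypes", ztnb(n_phenotypes ~ sensitive, tbl))
  } else skipped["n_phenotypes"] <- "constant response or predictor"

  # uncertainty ~ sensitivity
  if (can_vary(tbl$sensitive) && can_vary(tbl$uncertainty)) {
    try_fit("uncertainty",
            fit_plasticity_glm(uncertainty ~ sensitive, tbl, "quasibinomial"))
  } else skipped["uncertainty"] <- "constant response or predictor"

  # viability ~ plasticity, sensitive-transcriptome genomes only
  sens <- tbl[tbl$sensitive, ]
  if (nrow(sens) > 2 && can_vary(sens$plastic) && can_vary(sens$viable_all)) {
    try_fit("viability",
            fit_plasticity_glm(viable_all ~ plastic, sens, "binomial"))
  } else skipped["viability"] <- "too few sensitive genomes or constant"

  # phenotypes ~ scaled log transcriptomes x cost
  ok <- tbl$n_transcriptomes > 0
  sub <- tbl[ok, ]
  if (nrow(sub) > 4 && can_vary(sub$n_transcriptomes) &&
      can_vary(sub$cost) && can_vary(sub$n_phenotypes)) {
    sub$transcriptomes <- scale_log(sub$n_transcriptomes)
    try_fit("phen_by_cost",
            ztnb(n_phenotypes ~ transcriptomes * cost, sub))
  } else skipped["phen_by_cost"] <- "degenerate design at this scale"

  # transcriptome length ~ plastic * sensitive, on viable records
  rv <- rec[rec$viable, ]
  if (nrow(rv) > 4 && can_vary(rv$plastic) && can_vary(rv$sensitive)) {
    f <- if (can_vary(paste(rv$plastic, rv$sensitive)))
      transcriptome_length ~ plastic * sensitive
    else transcriptome_length ~ plastic + sensitive
    try_fit("tlen", lm(f, data = rv))
  } else skipped["tlen"] <- "degenerate design at this scale"

  # io executions in repeats ~ sensitivity, plastic organisms' viable records
  rp <- rv[rv$plastic & !is.na(rv$io_in_repeats), ]
  if (nrow(rp) > 2 && can_vary(rp$sensitive)) {
    try_fit("io",
            fit_plasticity_glm(io_in_repeats ~ sensitive, rp, "poisson"))
  } else skipped["io"] <- "no contrast among plastic genomes"

  structure(list(fits = fits, skipped = skipped,
                 n_profiles = nrow(tbl), n_records = nrow(rec)),
            class = "dg_models")
}

#' @export
print.dg_models <- function(x, ...) {
  cat("<dg_models> fitted:", paste(names(x$fits), collapse = ", "), "\n")
  if (length(x$skipped))
    cat("  skipped:", paste(names(x$skipped), x$skipped, sep = " (",
                            collapse = "), "), ")\n")
  invisible(x)
}

#' Back-transformed report of a model suite
#'
#' Collects the Wald tables of all fitted models and adds the
#' back-transformed estimate for each coefficient (inverse logit for
#' binomial/quasibinomial fits, inverse log for poisson and zero-truncated
#' negative binomial fits, identity for linear fits).
#'
#' @param models A `dg_models` object.
#' @return Data frame with one row per model term.
#' @export
models_report <- function(models) {
  out <- lapply(names(models$fits), function(nm) {
    fit <- models$fits[[nm]]
    if (is.null(fit)) return(NULL)
    wt <- wald_table(fit)
    wt$model <- nm
    link <- if (inherits(fit, "ztnb")) "log"
      else if (inherits(fit, "glm")) fit$family$link
      else "identity"
    wt$back_transformed <- switch(link,
      logit = inverse_logit(wt$estimate),
      log = inverse_log(wt$estimate),
      wt$estimate)
    wt[, c("model", "term", "estimate", "ci_low", "ci_high", "p_value",
           "back_transformed")]
  })
  do.call(rbind, out)
}

#' Reference coefficient estimates from the original large-scale study
#'
#' Coefficient estimates (link scale) from the generalized linear models of
#' a published large-scale analysis of 512,000 genomes x 1000 environments,
#' shipped as a plain-text table. They are the inputs to the back-transformed
#' summary quantities (probabilities and expected counts) that the package
#' reproduces analytically via [inverse_logit()] and [inverse_log()].
#'
#' @return Data frame with columns `model`, `family`, `term`, `estimate`,
#'   `ci_low`, `ci_high`, `n_obs`.
#' @export
reference_estimates <- function() {
  path <- system.file("extdata", "reference_fits.csv", package = "digiplast")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Back-transformed summary quantities from the reference estimates
#'
#' Recomputes, from the link-scale reference coefficients, the headline
#' back-transformed quantities of the plasticity analysis: probabilities of
#' plasticity and viability, expected numbers of distinct phenotypes,
#' expected input-output executions, phenotypic uncertainty by transcriptome
#' sensitivity, and the linear-model transcriptome-length predictions.
#' Probabilities are reported in percent.
#'
#' @param est Reference estimates, as returned by [reference_estimates()].
#' @return Named numeric vector.
#' @export
reference_quantities <- function(est = reference_estimates()) {
  g <- function(model, term) {
    v <- est$estimate[est$model == model & est$term == term]
    stopifnot(length(v) == 1)
    v
  }
  pl_i <- g("plasticity", "(Intercept)")
  pl_s <- g("plasticity", "sensitive")
  np_i <- g("n_phenotypes", "(Intercept)")
  np_s <- g("n_phenotypes", "sensitive")
  un_i <- g("uncertainty", "(Intercept)")
  un_s <- g("uncertainty", "sensitive")
  vi_i <- g("viability", "(Intercept)")
  vi_p <- g("viability", "plastic")
  zt_i <- g("phen_by_cost", "(Intercept)")
  zt_t <- g("phen_by_cost", "transcriptomes")
  zt_c <- g("phen_by_cost", "cost")
  zt_x <- g("phen_by_cost", "transcriptomes:cost")
  tl_i <- g("tlen", "(Intercept)")
  tl_p <- g("tlen", "plastic")
  tl_s <- g("tlen", "sensitive")
  tl_x <- g("tlen", "plastic:sensitive")
  io_i <- g("io", "(Intercept)")
  io_p <- g("io", "plastic")
  c(
    prob_plastic_genetic_pct     = 100 * inverse_logit(pl_i + pl_s),
    prob_plastic_nongenetic_pct  = 100 * inverse_logit(pl_i),
    n_phenotypes_genetic         = inverse_log(np_i + np_s),
    n_phenotypes_nongenetic      = inverse_log(np_i),
    prob_viable_plastic_pct      = 100 * inverse_logit(vi_i + vi_p),
    prob_viable_single_pct       = 100 * inverse_logit(vi_i),
    n_phenotypes_no_cost         = inverse_log(zt_i),
    n_phenotypes_cost            = inverse_log(zt_i + zt_c),
    n_phenotypes_no_cost_1sd     = inverse_log(zt_i + zt_t),
    n_phenotypes_cost_1sd        = inverse_log(zt_i + zt_c + zt_t + zt_x),
    io_nongenetic                = inverse_log(io_i),
    io_genetic                   = inverse_log(io_i + io_p),
    tlen_plastic_sensitive       = tl_i + tl_p + tl_s + tl_x,
    tlen_plastic_robust          = tl_i + tl_p,
    uncertainty_sensitive        = inverse_logit(un_i + un_s),
    uncertainty_robust           = inverse_logit(un_i)
  )
}
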