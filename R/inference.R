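#' Fit the phase-by-location linear mixed-effects model
#'
#' REML fit of (possibly transformed) synchrony values on
#' `phase * location` with random intercepts for seizures (per-patient
#' table) or for patients and seizures-within-patients (pooled table).
#' Phase has the four ictal levels; location is either the five scalp
#' regions or the eight electrodes, depending on `level`.
#'
#' The optional response transforms operate on the baseline-adjusted scale,
#' which is bounded below by construction: a single adjusted entry is
#' >= -1, so regional averages of five entries are >= -1 and electrode
#' totals of seven entries are >= -7. With `lb` the level's lower bound,
#' `"log"` is `log(v - lb)` and `"sqrt"` is `sqrt(v - lb)` (for regions
#' these are the familiar `log(1 + v)` and `sqrt(1 + v)`). With
#' `transform = "auto"` the identity fit is used unless its residual
#' skewness exceeds 1, in which case the log is applied (falling back to
#' the square root when values touch the bound, where the log is
#' undefined).
#'
#' @param table A synchrony table from [build_synchrony_table()] (rows of
#'   several patients may be concatenated for a pooled fit).
#' @param level `"electrode"` or `"region"`: which rows to model.
#' @param transform `"auto"`, `"identity"`, `"log"` or `"sqrt"`.
#' @param skew_threshold Residual skewness above which `"auto"` transforms.
#' @return Object of class `icoh_lmm`: list with the `lme4` fit (`fit`),
#'   `transform`, `level`, `pooled`, `data`, and convergence diagnostics
#'   (`messages`).
#' @export
fit_lmm <- function(table, level = c("electrode", "region"),
                    transform = c("auto", "identity", "log", "sqrt"),
                    skew_threshold = 1) {
  level <- match.arg(level)
  transform <- match.arg(transform)
  d <- table[table$level == level, , drop = FALSE]
  if (!nrow(d)) stop("no rows at level '", level, "'", call. = FALSE)
  d$phase <- factor(as.character(d$phase), levels = ictal_phases())
  if (anyNA(d$phase) || nlevels(droplevels(d$phase)) != 4L)
    stop("the model needs all four ictal phase levels", call. = FALSE)
  d$location <- factor(d$location)
  d$patient_id <- factor(d$patient_id)
  d$seizure <- factor(paste(d$patient_id, d$seizure_index, sep = ":"))
  if (length(unique(d$seizure)) < 2L)
    stop("need at least 2 seizures to fit the mixed model", call. = FALSE)
  if (stats::var(d$value) == 0)
    stop("degenerate response: synchrony values are constant", call. = FALSE)
  lb <- if (level == "electrode") -7 else -1   # theoretical lower bounds
  if (any(d$value < lb - 1e-9))
    stop("adjusted synchrony values below ", lb, ": input is not a baseline-",
         "adjusted ", level, "-level table", call. = FALSE)
  pooled <- nlevels(d$patient_id) > 1L
  rand <- if (pooled) "(1 | patient_id) + (1 | seizure)" else "(1 | seizure)"

  apply_tf <- function(v, tf)
    switch(tf, identity = v, log = log(v - lb), sqrt = sqrt(v - lb))
  fit_one <- function(tf) {
    d$.resp <- apply_tf(d$value, tf)
    msgs <- character(0)
    fit <- withCallingHandlers(
      tryCatch(
        lme4::lmer(stats::as.formula(paste(".resp ~ phase * location +", rand)),
                   data = d, REML = TRUE),
        error = function(e)
          stop("mixed model failed to converge (", conditionMessage(e),
               "); consider dropping the interaction or rescaling the response",
               call. = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    list(fit = fit, messages = msgs)
  }

  if (transform == "auto") {
    f0 <- fit_one("identity")
    if (abs(skewness(stats::residuals(f0$fit))) > skew_threshold) {
      transform <- if (min(d$value) > lb + 1e-9) "log" else "sqrt"
      f0 <- fit_one(transform)
    } else transform <- "identity"
    res <- f0
  } else {
    if (transform == "log" && min(d$value) <= lb + 1e-9)
      stop("log transform undefined at the lower bound ", lb, "; use sqrt",
           call. = FALSE)
    res <- fit_one(transform)
  }
  structure(list(fit = res$fit, transform = transform, level = level,
                 pooled = pooled, data = d, messages = res$messages),
            class = "icoh_lmm")
}

#' @export
print.icoh_lmm <- function(x, ...) {
  cat("<icoh_lmm> level=", x$level, ", transform=", x$transform,
      ", pooled=", x$pooled,
      if (length(x$messages)) paste0(", ", length(x$messages), " fit message(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Type II Wald chi-square analysis-of-deviance table
#'
#' Tests each fixed term (phase, location, phase:location) after all other
#' terms except those containing it, with large-sample Wald chi-square
#' statistics on the REML fit.
#'
#' @param model An `icoh_lmm`.
#' @return Data frame with `term`, `chisq`, `df`, `p`.
#' @export
type2_wald <- function(model) {
  stopifnot(inherits(model, "icoh_lmm"))
  a <- tryCatch(
    car::Anova(model$fit, type = "II", test.statistic = "Chisq"),
    error = function(e) stop("Type II Wald test failed (", conditionMessage(e),
                             "): check for aliased terms", call. = FALSE))
  data.frame(term = rownames(a), chisq = a$Chisq, df = a$Df,
             p = a$`Pr(>Chisq)`, row.names = NULL)
}

#' Dunnett contrasts against the termination phase
#'
#' For every location, the three contrasts `termination - pre_ictal`,
#' `termination - onset` and `termination - post_ictal` on the model's
#' response scale, with family-wise multivariate-t Dunnett adjustment
#' applied per location family (three contrasts each) and large-sample
#' degrees of freedom.
#'
#' @param model An `icoh_lmm`.
#' @param seed Seed for the multivariate-t quadrature (kept local).
#' @return Object of class `dunnett_result`: data frame with `location`,
#'   `phase` (the comparison phase), `estimate` (termination minus phase),
#'   `se`, `p_raw`, `p_adj`.
#' @export
dunnett_vs_termination <- function(model, seed = 1) {
  stopifnot(inherits(model, "icoh_lmm"))
  emm <- emmeans::emmeans(model$fit, ~ phase | location, lmer.df = "asymptotic")
  con <- emmeans::contrast(emm, method = "trt.vs.ctrl", ref = "termination",
                           reverse = TRUE)
  raw <- as.data.frame(summary(con, adjust = "none"))
  adj <- local_seed(seed, as.data.frame(summary(con, adjust = "mvt")))
  phase <- sub("^termination - ", "", raw$contrast)
  out <- data.frame(location = as.character(raw$location),
                    phase = gsub("[()]", "", phase),
                    estimate = raw$estimate, se = raw$SE,
                    p_raw = raw$p.value, p_adj = pmin(1, adj$p.value))
  # the mvt quadrature is numerically exact to ~1e-4; never report below raw
  out$p_adj <- pmax(out$p_adj, out$p_raw)
  structure(out, class = c("dunnett_result", "data.frame"))
}

#' Terminal-hypersynchronization calls
#'
#' A location is called positive when the termination phase exceeds the
#' comparison phases with Dunnett-adjusted significance and a positive
#' contrast sign. Under `rule = "all"` (default) all three comparison
#' phases must be exceeded; `rule = "any"` requires only one.
#'
#' @param dunnett A `dunnett_result`.
#' @param alpha Significance level (default 0.05).
#' @param rule `"all"` or `"any"`.
#' @return Named logical vector, one call per location.
#' @export
call_terminal_hypersync <- function(dunnett, alpha = 0.05,
                                    rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(dunnett, "dunnett_result"))
  hit <- dunnett$p_adj < alpha & dunnett$estimate > 0
  agg <- tapply(hit, dunnett$location, if (rule == "all") all else any)
  out <- as.logical(agg)
  names(out) <- names(agg)
  out
}
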