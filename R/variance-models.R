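# Variance partitioning of daily colony-level metrics.
#
# Uninformed model: metric ~ 1 + (1 | colony)           -> baseline R
# Informed model:   metric ~ drivers + (1|colony) + (1|date)
# Both are Gaussian random-intercept models estimated by REML; colony
# repeatability is the adjusted ICC var_colony / (var_colony + var_date +
# var_resid), marginal/conditional R2 follow the usual mixed-model
# variance-share definitions, and confidence intervals come from a
# parametric bootstrap.

#' Specify a variance-partitioning model
#'
#' @param response name of the metric column to model.
#' @param fixed character vector of fixed-effect column names (empty for
#'   the uninformed model).
#' @param random random-intercept grouping factors; `"colony_id"` or
#'   `c("colony_id", "date")`.
#' @param subset optional named list (`net_type`, `season`) recording which
#'   data slice the spec is for.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response, fixed = character(),
                       random = "colony_id", subset = NULL) {
  if (!length(random) || !"colony_id" %in% random)
    stop_cn("random effects must include colony_id")
  if (!all(random %in% c("colony_id", "date")))
    stop_cn("random effects may only be colony_id and date")
  structure(list(response = response, fixed = as.character(fixed),
                 random = random, subset = subset),
            class = "model_spec")
}

#' Uninformed model spec: colony random intercept only
#' @param response metric column name.
#' @param subset optional subset tag.
#' @return a `model_spec`.
#' @export
uninformed_spec <- function(response, subset = NULL)
  model_spec(response, character(), "colony_id", subset)

#' Informed model spec: drivers as fixed effects, colony + date random
#' @param response metric column name.
#' @param fixed driver column names.
#' @param subset optional subset tag.
#' @return a `model_spec`.
#' @export
informed_spec <- function(response, fixed, subset = NULL)
  model_spec(response, fixed, c("colony_id", "date"), subset)

is_balanced_oneway <- function(table, spec) {
  length(spec$fixed) == 0 && identical(spec$random, "colony_id") &&
    length(unique(table(table$colony_id))) == 1
}

# Closed-form REML for the balanced one-way random-intercept model: the
# ANOVA estimator, truncated at the boundary (where the residual variance
# becomes the pooled total variance, matching the reduced iid model).
balanced_oneway_fit <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g); n <- length(y) / k
  gm <- tapply(y, g, mean)
  grand <- mean(y)
  msb <- n * sum((gm - grand)^2) / (k - 1)
  msw <- sum((y - gm[g])^2) / (length(y) - k)
  vb <- (msb - msw) / n
  if (vb > 0) list(var_colony = vb, var_resid = msw, boundary = FALSE)
  else list(var_colony = 0, var_resid = stats::var(y), boundary = TRUE)
}

#' Fit a variance-partitioning linear mixed model
#'
#' Gaussian random-intercept model estimated by REML. The balanced
#' uninformed case (no fixed effects, colony intercepts, equal rows per
#' colony) is solved in closed form via the one-way ANOVA estimator, which
#' coincides with the REML solution there; all other specs are fitted with
#' [lme4::lmer()]. `var_fixed` is the sample variance of the fixed-effect
#' linear predictor over the modelled rows.
#'
#' @param table model table containing the response, fixed-effect columns
#'   and grouping factors.
#' @param spec a [model_spec()].
#' @param method `"auto"` (default), `"reml"` (force lme4) or `"anova"`
#'   (force the closed form; errors if not applicable).
#' @return object of class `variance_decomposition`: `beta` (data.frame of
#'   estimates, SEs and Wald 95% intervals), `var_colony`, `var_date`,
#'   `var_resid`, `var_fixed`, `n_obs`, `converged`, `singular`, `method`,
#'   `spec`, and `fit` (the merMod object, lme4 path only).
#' @export
fit_lmm <- function(table, spec, method = c("auto", "reml", "anova")) {
  method <- match.arg(method)
  cols <- c(spec$response, spec$fixed, spec$random)
  assert_columns(table, cols, "model table")
  table <- table[stats::complete.cases(table[, cols, drop = FALSE]), ,
                 drop = FALSE]
  for (g in spec$random)
    if (length(unique(table[[g]])) < 2)
      stop_cn("grouping factor %s has fewer than 2 levels", g)
  y <- table[[spec$response]]
  use_anova <- switch(method,
                      anova = TRUE,
                      reml = FALSE,
                      auto = is_balanced_oneway(table, spec))
  if (use_anova && !is_balanced_oneway(table, spec))
    stop_cn("closed-form path needs the balanced uninformed design")
  if (use_anova) {
    f <- balanced_oneway_fit(y, table$colony_id)
    beta <- data.frame(term = "(Intercept)", estimate = mean(y),
                       se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       stringsAsFactors = FALSE)
    vd <- list(beta = beta, var_colony = f$var_colony, var_date = 0,
               var_resid = f$var_resid, var_fixed = 0,
               n_obs = length(y), converged = TRUE, singular = f$boundary,
               method = "anova", spec = spec, fit = NULL)
    return(structure(vd, class = "variance_decomposition"))
  }
  rhs <- c(if (length(spec$fixed)) spec$fixed else "1",
           sprintf("(1 | %s)", spec$random))
  form <- stats::as.formula(paste(spec$response, "~",
                                  paste(rhs, collapse = " + ")))
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(form, data = table, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  X <- stats::model.matrix(fit)
  var_fixed <- if (length(spec$fixed))
    stats::var(as.numeric(X %*% b)) else 0
  vd <- list(beta = data.frame(term = names(b), estimate = unname(b),
                               se = unname(se),
                               ci_low = unname(b - 1.96 * se),
                               ci_high = unname(b + 1.96 * se),
                               stringsAsFactors = FALSE),
             var_colony = get_vc("colony_id"),
             var_date = get_vc("date"),
             var_resid = vc$vcov[vc$grp == "Residual"],
             var_fixed = var_fixed,
             n_obs = stats::nobs(fit),
             converged = length(msgs) == 0,
             convergence_messages = msgs,
             singular = lme4::isSingular(fit),
             method = "reml", spec = spec, fit = fit)
  structure(vd, class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "<variance_decomposition> %s (%s): var_colony=%.4g var_date=%.4g var_resid=%.4g var_fixed=%.4g (n=%d)\n",
    x$spec$response, x$method, x$var_colony, x$var_date, x$var_resid,
    x$var_fixed, x$n_obs))
  invisible(x)
}

#' Colony repeatability from a fitted decomposition
#'
#' Adjusted intraclass correlation: the colony variance share among the
#' non-fixed variance, `var_colony / (var_colony + var_date + var_resid)`.
#' Set `include_fixed = TRUE` for the alternative denominator that also
#' counts the fixed-effect variance.
#'
#' @param vd a `variance_decomposition`.
#' @param include_fixed include `var_fixed` in the denominator.
#' @return repeatability in `[0, 1]`.
#' @export
repeatability <- function(vd, include_fixed = FALSE) {
  denom <- vd$var_colony + vd$var_date + vd$var_resid +
    if (include_fixed) vd$var_fixed else 0
  if (!is.finite(denom) || denom <= 0)
    stop_cn("all variance components are zero; repeatability undefined")
  vd$var_colony / denom
}

#' Marginal and conditional R-squared
#'
#' Variance shares on the total scale: marginal = fixed effects only,
#' conditional = fixed plus random effects.
#'
#' @param vd a `variance_decomposition`.
#' @return list `r2_marginal`, `r2_conditional`.
#' @export
r2_marginal_conditional <- function(vd) {
  total <- vd$var_fixed + vd$var_colony + vd$var_date + vd$var_resid
  if (!is.finite(total) || total <= 0)
    stop_cn("total variance is zero; R2 undefined")
  list(r2_marginal = vd$var_fixed / total,
       r2_conditional = (vd$var_fixed + vd$var_colony + vd$var_date) / total)
}

# Vectorized parametric bootstrap for the balanced one-way closed form:
# simulate B studies from the fitted components and re-estimate R per
# column with pure matrix arithmetic.
boot_oneway_parametric <- function(vd, table, B) {
  g <- factor(table$colony_id)
  k <- nlevels(g); N <- length(g); n <- N / k
  mu <- vd$beta$estimate[1]
  u <- matrix(stats::rnorm(k * B, 0, sqrt(vd$var_colony)), k, B)
  e <- matrix(stats::rnorm(N * B, 0, sqrt(vd$var_resid)), N, B)
  y <- mu + u[as.integer(g), , drop = FALSE] + e
  gs <- rowsum(y, g)                 # k x B group sums
  gm <- gs / n
  grand <- colMeans(y)
  ssb <- n * (colSums(gm^2) - k * grand^2)
  msb <- ssb / (k - 1)
  ssw <- colSums(y^2) - n * colSums(gm^2)
  msw <- ssw / (N - k)
  vb <- pmax(0, (msb - msw) / n)
  vw <- ifelse(vb > 0, msw, (colSums(y^2) - N * grand^2) / (N - 1))
  vb / (vb + vw)
}

# 95% interval from the bootstrap draws: Efron's bias-corrected (BC)
# percentile by default (better small-sample calibration for skewed
# variance ratios), or the plain 2.5/97.5 percentiles.
ci_from_boot <- function(boot, R, ci_type) {
  ok <- boot[!is.na(boot)]
  if (!length(ok)) return(c(NA_real_, NA_real_))
  if (ci_type == "percentile")
    return(stats::quantile(ok, c(0.025, 0.975), names = FALSE))
  p <- mean(ok < R)
  p <- min(max(p, 1 / (length(ok) + 1)), length(ok) / (length(ok) + 1))
  z0 <- stats::qnorm(p)
  probs <- stats::pnorm(2 * z0 + c(-1, 1) * stats::qnorm(0.975))
  stats::quantile(ok, probs, names = FALSE)
}

#' Bootstrap confidence interval for colony repeatability
#'
#' Refits the model on `B` bootstrap datasets and returns a 95% interval
#' of the resampled repeatability. The default `"parametric"` bootstrap
#' simulates new responses from the fitted model (new random effects and
#' residuals) and refits, which propagates the between-colony sampling
#' error that row resampling cannot; `"stratified"` resamples colony-day
#' rows with replacement within each colony (each colony kept at its
#' observed row count). The interval is Efron's bias-corrected percentile
#' by default (`ci_type = "percentile"` gives the plain 2.5/97.5
#' percentiles). Non-convergent refits are dropped and counted.
#'
#' @param table model table.
#' @param spec a [model_spec()].
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param type `"parametric"` (default) or `"stratified"`.
#' @param ci_type `"bc"` (default) or `"percentile"`.
#' @param method passed to [fit_lmm()].
#' @return object of class `repeatability_estimate`: `R`, `ci_low`,
#'   `ci_high`, `n_bootstrap`, `n_failed`, `type`, `ci_type`, `boot` (the
#'   resampled values).
#' @export
bootstrap_repeatability <- function(table, spec, B = 1000, seed = 1L,
                                    type = c("parametric", "stratified"),
                                    ci_type = c("bc", "percentile"),
                                    method = "auto") {
  type <- match.arg(type)
  ci_type <- match.arg(ci_type)
  vd <- fit_lmm(table, spec, method = method)
  R <- repeatability(vd)
  boot <- with_seed(seed, {
    if (type == "parametric" && vd$method == "anova") {
      boot_oneway_parametric(vd, table, B)
    } else if (type == "parametric") {
      sims <- stats::simulate(vd$fit, nsim = B)
      vapply(seq_len(B), function(b) {
        tb <- table
        tb[[spec$response]] <- sims[[b]]
        tryCatch(repeatability(fit_lmm(tb, spec, method = method)),
                 error = function(e) NA_real_)
      }, numeric(1))
    } else {
      rows_by_colony <- split(seq_len(nrow(table)), table$colony_id)
      vapply(seq_len(B), function(b) {
        idx <- unlist(lapply(rows_by_colony, function(ix)
          ix[sample.int(length(ix), length(ix), replace = TRUE)]),
          use.names = FALSE)
        tryCatch(repeatability(fit_lmm(table[idx, , drop = FALSE], spec,
                                       method = method)),
                 error = function(e) NA_real_)
      }, numeric(1))
    }
  })
  failed <- sum(is.na(boot))
  if (failed > 0.1 * B)
    warning(sprintf("%d of %d bootstrap refits failed", failed, B))
  ci <- ci_from_boot(boot, R, ci_type)
  structure(list(R = R, ci_low = ci[1], ci_high = ci[2],
                 n_bootstrap = B, n_failed = failed, type = type,
                 ci_type = ci_type, boot = boot),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("<repeatability_estimate> R = %.3f [%.3f, %.3f] (%s, B = %d)\n",
              x$R, x$ci_low, x$ci_high, x$type, x$n_bootstrap))
  invisible(x)
}

#' Variance inflation factors of the fixed-effect design
#'
#' VIF per design column from the inverse correlation matrix of the
#' fixed-effects-only design (factors expanded to their treatment
#' contrasts).
#'
#' @param table model table.
#' @param fixed character vector of fixed-effect column names (or a
#'   `model_spec`).
#' @return named numeric vector of VIFs (all >= 1).
#' @export
compute_vif <- function(table, fixed) {
  if (inherits(fixed, "model_spec")) fixed <- fixed$fixed
  if (length(fixed) < 2)
    stop_cn("VIF needs at least 2 fixed effects")
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(fixed, collapse = " + "))),
    data = table)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_cn("constant design column(s): %s",
            paste(colnames(X)[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  Rinv <- tryCatch(solve(R), error = function(e) {
    qrX <- qr(X)
    drop_cols <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop_cn("perfectly collinear design column(s): %s",
            paste(drop_cols, collapse = ", "))
  })
  stats::setNames(diag(Rinv), colnames(X))
}

#' Partial residuals ("corrected" metric values) for one driver
#'
#' Subtracts from the response the fitted contribution of every other
#' fixed effect and the predicted random-effect contributions, leaving
#' intercept + focal term + residual. These are the values plotted against
#' a single driver.
#'
#' @param table model table the model was fitted on.
#' @param vd a `variance_decomposition` from the lme4 path.
#' @param focal name of the focal fixed effect (a term in the model).
#' @return data.frame with `colony_id`, `date` (when present), the focal
#'   column and `corrected`.
#' @export
partial_residuals <- function(table, vd, focal) {
  if (is.null(vd$fit))
    stop_cn("partial_residuals needs an lme4 fit (method = 'reml')")
  if (!focal %in% vd$spec$fixed)
    stop_cn("focal covariate %s is not a fixed effect of the model", focal)
  fit <- vd$fit
  tt <- stats::terms(fit, fixed.only = TRUE)
  X <- stats::model.matrix(tt, stats::model.frame(fit))
  b <- lme4::fixef(fit)
  asgn <- attr(X, "assign")
  terms_lab <- attr(tt, "term.labels")
  focal_cols <- which(asgn %in% which(terms_lab == focal))
  other_cols <- setdiff(seq_along(b), c(1L, focal_cols))  # keep intercept
  y <- stats::model.frame(fit)[[1L]]
  re_part <- stats::fitted(fit) - as.numeric(X %*% b)
  corrected <- y - as.numeric(X[, other_cols, drop = FALSE] %*%
                                b[other_cols]) - re_part
  used <- stats::complete.cases(
    table[, c(vd$spec$response, vd$spec$fixed, vd$spec$random),
          drop = FALSE])
  out <- table[used, intersect(c("colony_id", "date", focal), names(table)),
               drop = FALSE]
  out$corrected <- corrected
  rownames(out) <- NULL
  out
}

#' Simulate a balanced repeatability study at the metric level
#'
#' Gaussian responses `y = mu + colony + date + resid` on a balanced
#' colonies-by-days grid (dates shared across colonies), for parameter
#' recovery and coverage experiments with known variance components.
#'
#' @param n_colonies,n_days grid size.
#' @param var_colony,var_date,var_resid true variance components.
#' @param mu grand mean.
#' @param seed integer seed.
#' @return data.frame `colony_id`, `date`, `y`.
#' @export
simulate_repeatability_data <- function(n_colonies = 12, n_days = 30,
                                        var_colony = 1, var_date = 0,
                                        var_resid = 1, mu = 0, seed = 1L) {
  with_seed(seed, {
    colonies <- sprintf("c%02d", seq_len(n_colonies))
    days <- as.character(as.Date("2017-03-01") + seq_len(n_days) - 1)
    grid <- expand.grid(colony_id = colonies, date = days,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    u <- stats::setNames(stats::rnorm(n_colonies, 0, sqrt(var_colony)),
                         colonies)
    v <- stats::setNames(stats::rnorm(n_days, 0, sqrt(var_date)), days)
    grid$y <- mu + u[grid$colony_id] + v[grid$date] +
      stats::rnorm(nrow(grid), 0, sqrt(var_resid))
    grid[order(grid$colony_id, grid$date), ]
  })
}
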