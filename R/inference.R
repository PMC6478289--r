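#' Size dependence of differential growth-rate indices
#'
#' For each (sex, measure, day) cell, ordinary least-squares regression of
#' the day's growth rate on `covariate_mass` — the mass recorded one day
#' before the 24 h period, so rate and covariate share no measurement. A flat
#' slope means the index is size-independent and sex comparisons are not
#' confounded by the sexes' different average sizes: under cubic growth the
#' allometric rate is exactly flat while the relative rate declines with
#' mass.
#'
#' @param records A tibble from [rate_table()] carrying `covariate_mass`.
#' @param days Day indices to analyse (default days 2 and 3, which are most
#'   safely inside the free-growth phase).
#' @return A tibble with one row per (sex, measure, day): `slope`,
#'   `slope_se`, `intercept`, `p_slope` (two-sided test of slope = 0), `n`.
#' @export
size_dependence <- function(records, days = c(2, 3)) {
  need <- c("sex", "measure", "day", "value", "covariate_mass")
  stopifnot(all(need %in% names(records)))
  sub <- records[records$day %in% days & !is.na(records$covariate_mass) &
                   !is.na(records$value), ]
  if (nrow(sub) == 0L) stop("no usable records for the requested days",
                            call. = FALSE)
  cells <- split(sub, interaction(sub$sex, sub$measure, sub$day, drop = TRUE))
  out <- lapply(cells, function(cl) {
    if (nrow(cl) < 3L)
      stop("size_dependence: fewer than 3 points for sex ", cl$sex[1],
           ", measure ", cl$measure[1], ", day ", cl$day[1], call. = FALSE)
    fit <- stats::lm(value ~ covariate_mass, data = cl)
    cf <- summary(fit)$coefficients
    has_slope <- "covariate_mass" %in% rownames(cf)
    tibble::tibble(sex = cl$sex[1], measure = cl$measure[1], day = cl$day[1],
                   slope = unname(stats::coef(fit)["covariate_mass"]),
                   slope_se = if (has_slope) cf["covariate_mass", 2] else NA_real_,
                   intercept = unname(stats::coef(fit)[1]),
                   p_slope = if (has_slope) cf["covariate_mass", 4] else NA_real_,
                   n = nrow(cl))
  })
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$measure, .data$day, .data$sex)
}

# ---- shared mixed-ANOVA machinery ------------------------------------------

sum_contrasts <- function(dat, vars) {
  stats::setNames(lapply(vars, function(v) stats::contr.sum), vars)
}

check_two_levels <- function(dat, vars) {
  for (v in vars) {
    if (nlevels(droplevels(dat[[v]])) < 2)
      stop("singular design: factor `", v,
           "` has fewer than 2 observed levels", call. = FALSE)
  }
}

check_full_rank <- function(X, labels) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    asn <- attr(X, "assign")[dropped]
    term <- unique(ifelse(asn == 0, "(Intercept)", labels[asn]))
    stop("singular design: term `", paste(term, collapse = ", "),
         "` is aliased", call. = FALSE)
  }
}

# Marginal (Type III) Wald F tests from estimated fixed effects and their
# covariance, with externally supplied denominator df per term.
wald_type3 <- function(beta, V, assign, labels, ddf) {
  rows <- lapply(seq_along(labels), function(j) {
    idx <- which(assign == j)
    q <- length(idx)
    bj <- beta[idx]
    Fj <- drop(crossprod(bj, solve(V[idx, idx, drop = FALSE], bj))) / q
    pj <- stats::pf(Fj, q, ddf[j], lower.tail = FALSE)
    tibble::tibble(term = labels[j], F = Fj, ndf = q, ddf = ddf[j], p = pj)
  })
  dplyr::bind_rows(rows)
}

# Factor-specific R^2: each term's Type III sum of squares as a share of the
# total (corrected) sum of squares, from an OLS companion fit with the same
# fixed effects. A transparent approximation to mixed-model R^2 partitions.
type3_r2 <- function(formula, dat, factor_vars) {
  fit <- stats::lm(formula, data = dat,
                   contrasts = sum_contrasts(dat, factor_vars))
  a3 <- car::Anova(fit, type = "III")
  ss <- a3[["Sum Sq"]]
  names(ss) <- rownames(a3)
  y <- stats::model.response(stats::model.frame(fit))
  total <- sum((y - mean(y))^2)
  keep <- setdiff(names(ss), c("(Intercept)", "Residuals"))
  stats::setNames(ss[keep] / total, keep)
}

# REML fit via lme4, with convergence monitoring. Returns NULL on failure so
# callers can fall back to the method-of-moments route.
fit_reml <- function(formula, dat, factor_vars) {
  failed <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(formula, data = dat, REML = TRUE,
                 contrasts = sum_contrasts(dat, factor_vars)),
      error = function(e) NULL),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        failed <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || failed) return(NULL)
  fit
}

#' Mixed ANOVA for a growth-curve descriptor
#'
#' Tests the sex difference in one per-individual descriptor with a mixed
#' linear model: fixed effects sex and host plant, a random brood intercept
#' (broods are families, so sibs are not independent), variance components by
#' REML, and marginal (Type III) F tests. Denominator degrees of freedom are
#' derived from the number of larvae (`n - rank(X)`), not estimated by
#' Satterthwaite-type approximations. Each factor's effect size is reported
#' as its Type III sum-of-squares share of the total sum of squares (an
#' approximate, clearly-defined partition; see the vignette).
#'
#' On REML non-convergence the fit falls back to a method-of-moments /
#' generalized-least-squares route, flagged in the `method` attribute.
#'
#' @param features A feature table from [extract_features()].
#' @param response Name of a numeric column of `features`.
#' @param method `"reml"` (default, with automatic fallback) or `"moments"`.
#' @return A tibble with columns `term, F, ndf, ddf, p, R2`; attributes
#'   `varcomp` (named variance components) and `method`.
#' @export
feature_anova <- function(features, response, method = c("reml", "moments")) {
  method <- match.arg(method)
  if (!response %in% names(features))
    stop("`response` must name a column of `features`", call. = FALSE)
  if (!is.numeric(features[[response]]))
    stop("`response` must be numeric", call. = FALSE)
  dat <- data.frame(y = features[[response]],
                    sex = factor(features$sex, levels = c("F", "M")),
                    host = factor(features$host),
                    brood = factor(features$brood_id))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat <- droplevels(dat)
  if (nlevels(dat$brood) < 2)
    stop("need at least 2 broods", call. = FALSE)
  check_two_levels(dat, c("sex", "host"))
  X <- stats::model.matrix(~ sex + host, dat,
                           contrasts.arg = sum_contrasts(dat, c("sex", "host")))
  labels <- attr(stats::terms(~ sex + host), "term.labels")
  check_full_rank(X, labels)
  n <- nrow(dat)
  ddf <- rep(n - ncol(X), length(labels))   # larva-based, containment-style

  used <- method
  est <- NULL
  if (method == "reml") {
    fit <- fit_reml(y ~ sex + host + (1 | brood), dat, c("sex", "host"))
    if (is.null(fit)) {
      used <- "moments"
    } else {
      vc <- as.data.frame(lme4::VarCorr(fit))
      est <- list(beta = lme4::fixef(fit), V = as.matrix(stats::vcov(fit)),
                  assign = attr(lme4::getME(fit, "X"), "assign"),
                  varcomp = c(brood = vc$vcov[vc$grp == "brood"],
                              residual = vc$vcov[vc$grp == "Residual"]))
    }
  }
  if (used == "moments") {
    est <- gls_brood(dat$y, X, dat$brood)
    est$assign <- attr(X, "assign")
  }

  out <- wald_type3(est$beta, est$V, est$assign, labels, ddf)
  r2 <- type3_r2(y ~ sex + host, dat, c("sex", "host"))
  out$R2 <- unname(r2[out$term])
  attr(out, "varcomp") <- est$varcomp
  attr(out, "method") <- used
  out
}

# Method-of-moments variance components (one-way brood structure on OLS
# residuals) followed by exact GLS given those components.
gls_brood <- function(y, X, brood) {
  ols <- stats::lm.fit(X, y)
  res <- ols$residuals
  ni <- tabulate(brood)
  a <- nlevels(brood)
  N <- length(y)
  bm <- tapply(res, brood, mean)
  MSB <- sum(ni * (bm - mean(res))^2) / (a - 1)
  MSW <- sum((res - bm[as.integer(brood)])^2) / (N - a)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  sb2 <- max(0, (MSB - MSW) / n0)
  se2 <- MSW
  p <- ncol(X)
  XtViX <- matrix(0, p, p)
  XtViy <- numeric(p)
  for (b in levels(brood)) {
    sel <- which(brood == b)
    nb <- length(sel)
    Xb <- X[sel, , drop = FALSE]
    yb <- y[sel]
    shrink <- sb2 / (se2 + nb * sb2)
    # (se2 I + sb2 J)^{-1} = (I - shrink * J) / se2
    Xs <- colSums(Xb)
    ys <- sum(yb)
    XtViX <- XtViX + (crossprod(Xb) - shrink * tcrossprod(Xs)) / se2
    XtViy <- XtViy + (crossprod(Xb, yb) - shrink * Xs * ys) / se2
  }
  Vb <- solve(XtViX)
  beta <- drop(Vb %*% XtViy)
  names(beta) <- colnames(X)
  list(beta = beta, V = Vb,
       varcomp = c(brood = sb2, residual = se2))
}

#' Repeated-measures mixed ANOVA for differential growth rates
#'
#' Treats the day-specific growth rates of each larva as repeated
#' measurements and tests, per measure: fixed effects sex, day (as a numeric
#' covariate, centred), host plant, sex:day and sex:plant; random intercepts
#' for brood and for individual larva (nested in brood); REML variance
#' components; marginal (Type III) F tests. A flat sex:day interaction is the
#' diagnostic that the analysed window really is free growth — growth tapering
#' earlier in one sex would show up there.
#'
#' Denominator degrees of freedom are derived from the number of larvae, not
#' of measurements, to avoid pseudoreplication: between-subject terms (sex,
#' plant, sex:plant) get `n_larvae - p_between` (with `p_between` the count
#' of between-subject fixed-effect columns, intercept included) and
#' within-subject terms (day, sex:day) get `n_obs - n_larvae - p_within`.
#'
#' @param records A tibble from [rate_table()]; each measure present is
#'   analysed separately.
#' @param method `"reml"` (default, with method-of-moments fallback on
#'   non-convergence) or `"moments"`.
#' @return A tibble with columns `measure, term, F, ndf, ddf, p, R2`;
#'   attributes `varcomp` and `method` (named per measure).
#' @export
repeated_anova <- function(records, method = c("reml", "moments")) {
  method <- match.arg(method)
  need <- c("individual_id", "sex", "brood_id", "host", "day", "measure", "value")
  stopifnot(all(need %in% names(records)))
  res <- list()
  varcomps <- list()
  methods <- character()
  for (ms in unique(records$measure)) {
    sub <- records[records$measure == ms & !is.na(records$value), ]
    if (length(unique(sub$day)) < 2L)
      stop("repeated_anova: records for measure `", ms,
           "` cover a single day; no repeated structure", call. = FALSE)
    dat <- data.frame(value = sub$value,
                      sex = factor(sub$sex, levels = c("F", "M")),
                      host = factor(sub$host),
                      brood = factor(sub$brood_id),
                      id = factor(sub$individual_id),
                      day_c = sub$day - mean(sub$day))
    dat <- droplevels(dat)
    if (nlevels(dat$brood) < 2) stop("need at least 2 broods", call. = FALSE)
    check_two_levels(dat, c("sex", "host"))
    fx <- value ~ sex + day_c + host + sex:day_c + sex:host
    X <- stats::model.matrix(fx, dat,
                             contrasts.arg = sum_contrasts(dat, c("sex", "host")))
    labels <- attr(stats::terms(fx), "term.labels")
    check_full_rank(X, labels)
    assign <- attr(X, "assign")
    n_obs <- nrow(dat)
    n_larvae <- nlevels(dat$id)
    within <- grepl("day_c", labels)
    q <- vapply(seq_along(labels), function(j) sum(assign == j), integer(1))
    p_between <- 1L + sum(q[!within])
    p_within <- sum(q[within])
    ddf <- ifelse(within, n_obs - n_larvae - p_within, n_larvae - p_between)

    used <- method
    est <- NULL
    if (method == "reml") {
      fit <- fit_reml(value ~ sex + day_c + host + sex:day_c + sex:host +
                        (1 | brood) + (1 | id), dat, c("sex", "host"))
      if (is.null(fit)) {
        used <- "moments"
      } else {
        vc <- as.data.frame(lme4::VarCorr(fit))
        est <- list(beta = lme4::fixef(fit), V = as.matrix(stats::vcov(fit)),
                    assign = attr(lme4::getME(fit, "X"), "assign"),
                    varcomp = c(individual = vc$vcov[vc$grp == "id"],
                                brood = vc$vcov[vc$grp == "brood"],
                                residual = vc$vcov[vc$grp == "Residual"]))
      }
    }
    if (used == "moments") {
      est <- gls_nested(dat$value, X, dat$brood, dat$id)
      est$assign <- assign
    }

    out <- wald_type3(est$beta, est$V, est$assign, labels, ddf)
    r2 <- type3_r2(fx, dat, c("sex", "host"))
    out$R2 <- unname(r2[out$term])
    out$term <- sub("day_c", "day", out$term)
    out <- dplyr::mutate(out, measure = ms, .before = 1)
    res[[ms]] <- out
    varcomps[[ms]] <- est$varcomp
    methods[ms] <- used
  }
  out <- dplyr::bind_rows(res)
  attr(out, "varcomp") <- varcomps
  attr(out, "method") <- methods
  out
}

# Method-of-moments components for the nested brood/individual/day structure
# (computed from OLS residuals via nested mean squares), then exact GLS.
gls_nested <- function(y, X, brood, id) {
  ols <- stats::lm.fit(X, y)
  res <- ols$residuals
  N <- length(y)
  n_id <- nlevels(id)
  n_br <- nlevels(brood)
  id_mean <- tapply(res, id, mean)
  id_n <- tabulate(id)
  id_brood <- brood[!duplicated(id)]
  names(id_brood) <- id[!duplicated(id)]
  # within-individual (day-level) component
  se2 <- sum((res - id_mean[as.integer(id)])^2) / max(1, N - n_id)
  # between-individual within brood
  br_of_id <- id_brood[levels(id)]
  br_mean_of_ids <- tapply(id_mean, br_of_id, mean)
  k_bar <- mean(id_n)
  ms_ind <- sum((id_mean - br_mean_of_ids[as.character(br_of_id)])^2) /
    max(1, n_id - n_br)
  si2 <- max(0, ms_ind - se2 / k_bar)
  # between-brood
  m_bar <- n_id / n_br
  ms_br <- sum((br_mean_of_ids - mean(id_mean))^2) / max(1, n_br - 1)
  sb2 <- max(0, ms_br - si2 / m_bar - se2 / (k_bar * m_bar))
  p <- ncol(X)
  XtViX <- matrix(0, p, p)
  XtViy <- numeric(p)
  for (b in levels(brood)) {
    sel <- which(brood == b)
    Xb <- X[sel, , drop = FALSE]
    yb <- y[sel]
    Zi <- stats::model.matrix(~ 0 + factor(as.character(id[sel])))
    Vb <- se2 * diag(length(sel)) + si2 * tcrossprod(Zi) + sb2
    Vinv <- solve(Vb)
    XtViX <- XtViX + crossprod(Xb, Vinv %*% Xb)
    XtViy <- XtViy + crossprod(Xb, Vinv %*% yb)
  }
  Vbeta <- solve(XtViX)
  beta <- drop(Vbeta %*% XtViy)
  names(beta) <- colnames(X)
  list(beta = beta, V = Vbeta,
       varcomp = c(individual = si2, brood = sb2, residual = se2))
}
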