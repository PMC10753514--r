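## Inferential layer: heteroscedastic linear mixed models with AICc
## selection, Wald chi-square tests, marginal means with Bonferroni pairwise
## contrasts, Welch ANOVA + Games-Howell for variability indices, and
## group-balance checks. nlme does the likelihood maximization; AICc,
## selection and all summaries are computed here.

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects + variance
#'   parameters).
#' @param n number of observations.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Model data hygiene: consistent factor coding, complete cases.
prepare_model_data <- function(data, response) {
  dt <- data.table::as.data.table(data)
  need <- c("bird_id", "method", "t_air", "age", "mass", response)
  dt <- dt[stats::complete.cases(dt[, need, with = FALSE]), need, with = FALSE]
  dt[, method := factor(method)]
  dt[, t_air := factor(t_air, levels = sort(unique(t_air), decreasing = TRUE))]
  dt[, age := factor(age)]
  as.data.frame(dt)
}

fit_one_lmm <- function(formula, data, est_method) {
  nlme::lme(fixed = formula, random = ~ 1 | bird_id,
            weights = nlme::varIdent(form = ~ 1 | method),
            data = data, method = est_method,
            control = nlme::lmeControl(maxIter = 200, msMaxIter = 300,
                                       opt = "optim"))
}

#' Fit candidate mixed models and select by AICc
#'
#' Fits the candidate set (main effects of method, ambient temperature, age
#' and body mass; optionally method x ambient temperature and/or method x age
#' interactions) as heteroscedastic linear mixed models: random bird
#' intercept and method-specific residual variances (varIdent). Candidates
#' are fitted with maximum likelihood, compared by AICc, and the winner is
#' refitted with REML for parameter estimation.
#'
#' @param data analysis table with columns `bird_id`, `method`, `t_air`,
#'   `age`, `mass` and the response.
#' @param response `"rmr_w"` or `"tb_mean"` (any column name works).
#' @return list of class `"tb_lmm_selection"`: `aicc_table` (one row per
#'   candidate with k, logLik, AICc, dAICc, converged), `best` (candidate
#'   name), `fit` (REML refit of the winner), `fit_ml`, `data`, `response`.
#' @export
fit_candidates_and_select <- function(data, response) {
  df <- prepare_model_data(data, response)
  base <- sprintf("%s ~ method + t_air + age + mass", response)
  cands <- list(
    no_interaction = stats::as.formula(base),
    method_x_tair = stats::as.formula(paste(base, "+ method:t_air")),
    method_x_age = stats::as.formula(paste(base, "+ method:age")),
    both_interactions = stats::as.formula(
      paste(base, "+ method:t_air + method:age"))
  )
  n <- nrow(df)
  rows <- lapply(names(cands), function(nm) {
    fit <- tryCatch(fit_one_lmm(cands[[nm]], df, "ML"),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(list(model = nm, k = NA_real_, logLik = NA_real_,
                  aicc = NA_real_, converged = FALSE, fit = NULL))
    }
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    list(model = nm, k = k, logLik = as.numeric(ll),
         aicc = aicc(as.numeric(ll), k, n), converged = TRUE, fit = fit)
  })
  tab <- data.table::rbindlist(lapply(rows, function(r) r[1:5]))
  if (all(!tab$converged)) stop("no candidate model converged")
  if (any(!tab$converged)) {
    warning("candidate(s) failed to converge and were excluded: ",
            paste(tab$model[!tab$converged], collapse = ", "))
  }
  tab[, dAICc := aicc - min(aicc, na.rm = TRUE)]
  best <- tab$model[which.min(tab$aicc)]
  fit_reml <- fit_one_lmm(cands[[best]], df, "REML")
  out <- list(aicc_table = tab[], best = best, fit = fit_reml,
              fit_ml = rows[[which.min(tab$aicc)]]$fit,
              formula = cands[[best]], data = df, response = response)
  class(out) <- "tb_lmm_selection"
  out
}

#' @export
print.tb_lmm_selection <- function(x, ...) {
  cat(sprintf("Mixed-model selection for %s (ML fits, AICc):\n", x$response))
  print(x$aicc_table[, list(model, k, logLik = round(logLik, 2),
                            AICc = round(aicc, 2), dAICc = round(dAICc, 2))])
  cat(sprintf("selected: %s (refitted with REML)\n", x$best))
  invisible(x)
}

#' Wald chi-square tests for fixed-effect terms
#'
#' Marginal Wald tests: for each fixed-effect term, the chi-square statistic
#' `b' V^-1 b` over that term's coefficient block (treatment contrasts).
#'
#' @param selection a `tb_lmm_selection` (or pass an `lme` fit plus `data`).
#' @return `data.table` with `term`, `chisq`, `df`, `p`.
#' @export
wald_chisq <- function(selection) {
  fit <- selection$fit
  df <- selection$data
  fixed <- stats::formula(fit)
  X <- stats::model.matrix(fixed, df)
  asn <- attr(X, "assign")
  labels <- attr(stats::terms(fixed), "term.labels")
  b <- nlme::fixef(fit)
  V <- stats::vcov(fit)
  out <- lapply(seq_along(labels), function(j) {
    idx <- which(asn == j)
    stat <- drop(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% b[idx])
    list(term = labels[j], chisq = stat, df = length(idx),
         p = stats::pchisq(stat, length(idx), lower.tail = FALSE))
  })
  data.table::rbindlist(out)
}

#' Estimated marginal means on a reference grid
#'
#' Model-based group means: the reference grid crosses all levels of the
#' model's factors, holds numeric covariates (body mass) at their grand
#' mean, and averages predictions with equal weights over the factors not in
#' `specs`.
#'
#' @param selection a `tb_lmm_selection`.
#' @param specs character vector of factors to keep (e.g. `"method"`,
#'   `c("method", "t_air")`, `"t_air"`).
#' @return `data.table` with the `specs` columns, `emmean` and `se`;
#'   carries the averaged design matrix and fixed-effect covariance as
#'   attributes for contrast computation.
#' @export
emmeans_grid <- function(selection, specs) {
  fit <- selection$fit
  df <- selection$data
  fixed <- stats::formula(fit)
  vars <- all.vars(stats::delete.response(stats::terms(fixed)))
  fac_vars <- vars[vapply(df[vars], is.factor, TRUE)]
  num_vars <- setdiff(vars, fac_vars)
  bad <- setdiff(specs, fac_vars)
  if (length(bad) > 0) stop("specs must be model factors; unknown: ",
                            paste(bad, collapse = ", "))
  lev <- lapply(df[fac_vars], levels)
  grid <- do.call(expand.grid, c(lev, list(stringsAsFactors = FALSE)))
  for (v in fac_vars) grid[[v]] <- factor(grid[[v]], levels = lev[[v]])
  for (v in num_vars) grid[[v]] <- mean(df[[v]])
  X <- stats::model.matrix(stats::delete.response(stats::terms(fixed)), grid)
  key <- interaction(grid[specs], drop = FALSE, lex.order = TRUE)
  Xa <- rowsum(X, key) / as.vector(table(key))
  b <- nlme::fixef(fit)
  V <- stats::vcov(fit)
  est <- drop(Xa %*% b)
  Vg <- Xa %*% V %*% t(Xa)
  combos <- unique(grid[specs])
  combos <- combos[order(interaction(combos, lex.order = TRUE)), , drop = FALSE]
  out <- data.table::as.data.table(combos)
  out[, emmean := est]
  out[, se := sqrt(diag(Vg))]
  attr(out, "V") <- Vg
  attr(out, "specs") <- specs
  out[]
}

#' Pairwise contrasts of marginal means with Bonferroni correction
#'
#' All pairwise differences between marginal means, optionally within the
#' levels of a `by` factor (each `by` level is its own Bonferroni family;
#' with `by = NULL` all pairs form one family). Tests use the normal (z)
#' approximation.
#'
#' @param emm output of [emmeans_grid()].
#' @param by optional factor name in the grid splitting contrast families.
#' @return `data.table` with `contrast`, `by` column (if any), `estimate`,
#'   `se`, `z`, `p_raw`, `p_adj`.
#' @export
pairwise_contrasts <- function(emm, by = NULL) {
  V <- attr(emm, "V")
  specs <- attr(emm, "specs")
  vary <- setdiff(specs, by)
  if (length(vary) == 0) stop("nothing left to contrast")
  groups <- if (is.null(by)) list(seq_len(nrow(emm)))
            else split(seq_len(nrow(emm)), emm[[by]])
  labels <- apply(as.data.frame(emm)[, vary, drop = FALSE], 1, paste,
                  collapse = " ")
  rows <- lapply(groups, function(idx) {
    if (length(idx) < 2) return(NULL)
    prs <- utils::combn(idx, 2)
    i1 <- prs[1, ]; i2 <- prs[2, ]
    est <- emm$emmean[i1] - emm$emmean[i2]
    sed <- sqrt(diag(V)[i1] + diag(V)[i2] - 2 * V[cbind(i1, i2)])
    z <- est / sed
    p <- 2 * stats::pnorm(-abs(z))
    d <- data.table::data.table(
      contrast = paste(labels[i1], "-", labels[i2]),
      estimate = est, se = sed, z = z, p_raw = p,
      p_adj = pmin(1, ncol(prs) * p))
    if (!is.null(by)) d[[by]] <- emm[[by]][i1]
    d
  })
  out <- data.table::rbindlist(rows)
  if (!is.null(by)) data.table::setcolorder(out, c("contrast", by))
  out[]
}

#' Likelihood-ratio test of the random bird intercept
#'
#' Compares the selected REML mixed model against the same fixed-effect and
#' variance structure without the random intercept (generalized least
#' squares), on one degree of freedom.
#'
#' @param selection a `tb_lmm_selection`.
#' @return list with `stat`, `df`, `p`.
#' @export
random_effect_lrt <- function(selection) {
  g <- nlme::gls(model = selection$formula,
                 weights = nlme::varIdent(form = ~ 1 | method),
                 data = selection$data, method = "REML")
  stat <- 2 * (as.numeric(stats::logLik(selection$fit)) -
                 as.numeric(stats::logLik(g)))
  list(stat = stat, df = 1, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F for k groups with unequal variances, from the standard formulas
#' with weights `w_i = n_i / s_i^2` and Satterthwaite-type denominator
#' degrees of freedom.
#'
#' @param values numeric vector of observations.
#' @param groups grouping vector (coerced to factor).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(values, groups) {
  g <- factor(groups)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2) stop("Welch ANOVA requires at least 2 groups")
  ni <- tapply(values, g, length)
  if (any(ni < 2)) stop("each group needs n >= 2")
  mi <- tapply(values, g, mean)
  vi <- tapply(values, g, stats::var)
  if (any(vi <= 0)) stop("zero within-group variance")
  wi <- ni / vi
  w <- sum(wi)
  mw <- sum(wi * mi) / w
  a <- sum(wi * (mi - mw)^2) / (k - 1)
  lambda <- sum((1 - wi / w)^2 / (ni - 1))
  f <- a / (1 + 2 * (k - 2) * lambda / (k^2 - 1))
  df2 <- (k^2 - 1) / (3 * lambda)
  list(F = f, df1 = k - 1, df2 = df2,
       p = stats::pf(f, k - 1, df2, lower.tail = FALSE))
}

#' Games-Howell pairwise comparisons
#'
#' Post hoc pairwise tests for unequal variances and sample sizes: the
#' studentized-range statistic `q = |m_i - m_j| / sqrt((s_i^2/n_i +
#' s_j^2/n_j)/2)` with Welch-Satterthwaite degrees of freedom, referred to
#' the studentized-range distribution with `k` groups.
#'
#' @inheritParams welch_anova
#' @return `data.table` with `group1`, `group2`, `estimate`, `se`, `q`,
#'   `df`, `p`.
#' @export
games_howell <- function(values, groups) {
  g <- factor(groups)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2) stop("Games-Howell requires at least 2 groups")
  ni <- tapply(values, g, length)
  if (any(ni < 2)) stop("each group needs n >= 2")
  mi <- tapply(values, g, mean)
  vi <- tapply(values, g, stats::var)
  if (any(vi <= 0)) stop("zero within-group variance")
  prs <- utils::combn(levels(g), 2)
  out <- lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    se2 <- vi[a] / ni[a] + vi[b] / ni[b]
    df <- se2^2 / ((vi[a] / ni[a])^2 / (ni[a] - 1) +
                     (vi[b] / ni[b])^2 / (ni[b] - 1))
    q <- abs(mi[a] - mi[b]) / sqrt(se2 / 2)
    list(group1 = a, group2 = b, estimate = unname(mi[a] - mi[b]),
         se = unname(sqrt(se2)), q = unname(q), df = unname(df),
         p = stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
  })
  data.table::rbindlist(out)
}

#' Group-balance checks of the experimental design
#'
#' One-way ANOVA of each body-mass variable across methods, and Pearson's
#' chi-squared tests of the age x method and sex x method contingency
#' tables.
#'
#' @param birds bird table with `method`, mass columns, `age`, `sex`.
#' @param mass_vars mass columns to test.
#' @return list with `mass` (`data.table`: variable, F, df1, df2, p) and
#'   `age`, `sex` (each: statistic, df, p).
#' @export
balance_checks <- function(birds,
                           mass_vars = c("mass_capture", "mass_pre",
                                         "mass_post")) {
  b <- as.data.frame(birds)
  b$method <- factor(b$method)
  if (any(table(b$method) < 2)) stop("need >= 2 birds per method")
  mass <- data.table::rbindlist(lapply(mass_vars, function(v) {
    fit <- stats::aov(b[[v]] ~ b$method)
    s <- summary(fit)[[1]]
    list(variable = v, F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
         p = s$`Pr(>F)`[1])
  }))
  chisq_of <- function(v) {
    tab <- table(b[[v]], b$method)
    if (any(tab == 0)) warning("empty cell(s) in ", v, " x method table")
    ct <- suppressWarnings(stats::chisq.test(tab))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
  }
  list(mass = mass, age = chisq_of("age"), sex = chisq_of("sex"))
}
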