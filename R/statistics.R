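#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. The reported `U` is
#' the statistic of the first sample (`x`): the number of `(x, y)` pairs
#' with `x > y`, counting ties as 1/2 — the convention matters because
#' printed U values depend on which sample is "first". The two-sided p
#' value is exact (full enumeration of rank configurations) when
#' `n1 * n2 <= 400` and the data are tie-free; otherwise a normal
#' approximation with tie-corrected variance is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"` (default: exact when feasible), `"exact"` or
#'   `"normal"`.
#' @return List of class `mann_whitney`: `U`, `p.value`, `method`,
#'   `n` (the two sample sizes).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = (n1 * n2 <= 400) && !ties)
  if (use_exact && ties)
    stop("exact p value is unavailable with ties; use mode = 'normal'")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE,
                       alternative = "two.sided"))
  structure(list(U = unname(U), p.value = wt$p.value,
                 method = if (use_exact) "exact" else "normal (tie-corrected)",
                 n = c(n1 = n1, n2 = n2)),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.2f (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$U, x$n[1L], x$n[2L], x$p.value, x$method))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with 1 degree of
#' freedom (no Yates continuity correction).
#'
#' @param tab 2x2 matrix of non-negative integer counts with all row and
#'   column margins positive.
#' @return List of class `chi2_2x2`: `statistic`, `df`, `p.value`,
#'   `expected`.
#' @export
chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all table margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = 1L,
                 p.value = ct$p.value, expected = ct$expected),
            class = "chi2_2x2")
}

#' @export
print.chi2_2x2 <- function(x, ...) {
  cat(sprintf("Pearson chi-square(1) = %.3f, p = %.4g\n",
              x$statistic, x$p.value))
  invisible(x)
}

#' Covariate-adjusted group comparison (MANCOVA-style)
#'
#' Fits, per dependent variable, the linear model
#' `dv ~ covariate + group` and tests the group term (F test of the
#' group effect adjusted for the covariate; with two groups and no
#' interaction this coincides with the type-III test). Across the DV
#' set, Wilks' lambda for the group term is reported from the
#' corresponding multivariate fit. A covariate with zero variance is
#' dropped, reducing each model to a one-way ANOVA.
#'
#' @param dvs Data frame or matrix of dependent variables (columns).
#' @param group Factor (or coercible) of group labels, >= 2 levels.
#' @param covariate Numeric covariate (e.g. average head motion).
#' @return List of class `ancova_group`: `per_dv` (data frame with
#'   columns `dv`, `F`, `df1`, `df2`, `p`), `wilks` (list `lambda`,
#'   `F`, `df1`, `df2`, `p`), and `n`.
#' @export
ancova_group <- function(dvs, group, covariate) {
  dvs <- as.data.frame(dvs)
  group <- droplevels(as.factor(group))
  covariate <- as.numeric(covariate)
  n <- nrow(dvs)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (length(group) != n || length(covariate) != n)
    stop("dvs, group and covariate must have equal lengths")
  use_cov <- stats::var(covariate) > 0
  n_par <- 1L + (nlevels(group) - 1L) + as.integer(use_cov)
  if (n <= n_par) stop("more parameters than observations")
  dat <- data.frame(.group = group, .cov = covariate)
  rhs_full <- if (use_cov) ".cov + .group" else ".group"
  rhs_red <- if (use_cov) ".cov" else "1"

  per_dv <- do.call(rbind, lapply(names(dvs), function(v) {
    dat$.y <- dvs[[v]]
    full <- stats::lm(stats::as.formula(paste(".y ~", rhs_full)), data = dat)
    if (any(is.na(stats::coef(full))))
      stop("rank-deficient design for dependent variable ", v)
    red <- stats::lm(stats::as.formula(paste(".y ~", rhs_red)), data = dat)
    a <- stats::anova(red, full)
    data.frame(dv = v, F = a$F[2L], df1 = a$Df[2L], df2 = a$Res.Df[2L],
               p = a$`Pr(>F)`[2L], stringsAsFactors = FALSE)
  }))
  rownames(per_dv) <- NULL

  wilks <- NULL
  if (ncol(dvs) >= 2L) {  # multivariate statistic needs >= 2 responses
    Y <- as.matrix(dvs)
    mfit <- stats::manova(stats::as.formula(paste("Y ~", rhs_full)),
                          data = dat)
    ms <- summary(mfit, test = "Wilks")$stats
    grow <- grep("\\.group", rownames(ms))[1L]
    wilks <- list(lambda = ms[grow, "Wilks"], F = ms[grow, "approx F"],
                  df1 = ms[grow, "num Df"], df2 = ms[grow, "den Df"],
                  p = ms[grow, "Pr(>F)"])
  }

  structure(list(per_dv = per_dv, wilks = wilks, n = n,
                 covariate_used = use_cov),
            class = "ancova_group")
}

#' @export
print.ancova_group <- function(x, ...) {
  cat(sprintf("Covariate-adjusted group comparison (n = %d)\n", x$n))
  for (i in seq_len(nrow(x$per_dv)))
    cat(sprintf("  %-16s F(%d, %d) = %.3f, p = %.4g\n",
                x$per_dv$dv[i], x$per_dv$df1[i], x$per_dv$df2[i],
                x$per_dv$F[i], x$per_dv$p[i]))
  if (!is.null(x$wilks))
    cat(sprintf("  Wilks' lambda = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
                x$wilks$lambda, x$wilks$df1, x$wilks$df2, x$wilks$F,
                x$wilks$p))
  invisible(x)
}

#' Hierarchical forward-stepwise regression with a forced covariate
#'
#' Step 1 fits the forced covariate(s) alone. At each later step the
#' candidate with the smallest entry p value (the t/partial-F test of
#' its coefficient when added to the current model) enters if
#' `p <= p_enter`; selection stops when no remaining candidate
#' qualifies. Pure forward by default; setting `p_remove` (e.g. 0.10)
#' additionally removes a previously entered candidate whose p value
#' rises above it.
#'
#' @param y Numeric response (e.g. NWC pain score).
#' @param candidates Data frame of candidate predictors.
#' @param forced Data frame (or numeric vector) of covariates forced
#'   into every model.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Optional removal threshold; `NULL` (default)
#'   disables removal.
#' @return List of class `stepwise_result`: `steps` (one entry per
#'   model: `terms` data frame with `term`, `B`, `SE`, `std_B`, `p`;
#'   plus `r_squared`, `F`, `df1`, `df2`, `p_model`), `selected`
#'   (candidates in the final model, in entry order), `p_enter`.
#' @export
forward_stepwise <- function(y, candidates, forced, p_enter = 0.05,
                             p_remove = NULL) {
  candidates <- as.data.frame(candidates)
  if (is.null(dim(forced))) forced <- data.frame(covariate = forced)
  forced <- as.data.frame(forced)
  n <- length(y)
  if (nrow(candidates) != n || nrow(forced) != n)
    stop("y, candidates and forced must have equal lengths")
  if (n <= ncol(candidates) + ncol(forced) + 1L)
    stop("too few observations for the candidate set")
  dat <- cbind(forced, candidates)
  dat$.y <- y
  sdy <- stats::sd(y)

  fit_model <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  }
  describe <- function(fit) {
    sm <- summary(fit)
    co <- sm$coefficients
    term <- rownames(co)
    std_B <- vapply(term, function(tm) {
      if (tm == "(Intercept)" || sdy == 0) return(NA_real_)
      co[tm, "Estimate"] * stats::sd(dat[[tm]]) / sdy
    }, numeric(1))
    fs <- sm$fstatistic
    list(terms = data.frame(term = term, B = co[, "Estimate"],
                            SE = co[, "Std. Error"], std_B = unname(std_B),
                            p = co[, "Pr(>|t|)"], row.names = NULL,
                            stringsAsFactors = FALSE),
         r_squared = sm$r.squared,
         F = if (is.null(fs)) NA_real_ else unname(fs[1L]),
         df1 = if (is.null(fs)) NA_real_ else unname(fs[2L]),
         df2 = if (is.null(fs)) NA_real_ else unname(fs[3L]),
         p_model = if (is.null(fs)) NA_real_ else
           stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  }

  included <- character(0)
  remaining <- names(candidates)
  steps <- list(describe(fit_model(names(forced))))
  repeat {
    if (!length(remaining)) break
    entry_p <- vapply(remaining, function(cand) {
      fit <- fit_model(c(names(forced), included, cand))
      co <- stats::coef(fit)
      if (anyNA(co))
        stop("candidate '", cand, "' is collinear with the current model")
      summary(fit)$coefficients[cand, "Pr(>|t|)"]
    }, numeric(1))
    best <- names(entry_p)[which.min(entry_p)]
    if (entry_p[[best]] > p_enter) break
    included <- c(included, best)
    remaining <- setdiff(remaining, best)
    if (!is.null(p_remove) && length(included) > 1L) {
      fit <- fit_model(c(names(forced), included))
      pv <- summary(fit)$coefficients[included, "Pr(>|t|)"]
      drop <- included[pv > p_remove]
      drop <- setdiff(drop, best)
      if (length(drop)) {
        included <- setdiff(included, drop)
        remaining <- union(remaining, drop)
      }
    }
    steps[[length(steps) + 1L]] <- describe(fit_model(c(names(forced),
                                                        included)))
  }
  structure(list(steps = steps, selected = included, forced = names(forced),
                 p_enter = p_enter, p_remove = p_remove),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Forward-stepwise regression (forced: %s; p_enter = %g)\n",
    paste(x$forced, collapse = ", "), x$p_enter))
  for (i in seq_along(x$steps)) {
    st <- x$steps[[i]]
    cat(sprintf("Step %d: R^2 = %.3f, F(%g, %g) = %.3f, p = %.4g\n",
                i, st$r_squared, st$df1, st$df2, st$F, st$p_model))
    print(format(st$terms, digits = digits), row.names = FALSE)
  }
  if (!length(x$selected)) cat("No candidate entered the model.\n")
  invisible(x)
}

#' @export
summary.stepwise_result <- function(object, ...) {
  final <- object$steps[[length(object$steps)]]
  cat(sprintf("Final model (%d step%s): R^2 = %.3f; selected: %s\n",
              length(object$steps),
              if (length(object$steps) > 1L) "s" else "",
              final$r_squared,
              if (length(object$selected))
                paste(object$selected, collapse = ", ") else "none"))
  invisible(final)
}
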