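#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on g - 1 degrees
#' of freedom (wraps `stats::kruskal.test`).
#'
#' @param values numeric vector (or list of per-group vectors).
#' @param groups group labels (ignored when `values` is a list).
#' @return list with `statistic` (H), `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_dynfc("kruskal_wallis: need >= 2 groups")
  if (any(tabulate(groups) == 0)) stop_dynfc("kruskal_wallis: empty group")
  if (length(unique(values)) == 1)
    stop_dynfc("kruskal_wallis: all values identical, H undefined")
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(values))
}

#' One-way ANCOVA via a partial F-test
#'
#' Compares the full linear model (group indicators + covariates) with the
#' covariates-only model; the reported F is the extra-sum-of-squares
#' (partial) F for the group factor.
#'
#' Disease duration, when used as a covariate, is undefined for healthy
#' controls; with `duration_mode = "impute_centered"` it is centered
#' within patients and set to 0 for controls (flagged in the output), with
#' `"drop"` it is removed from the covariate set.
#'
#' @param values per-subject response vector.
#' @param groups group labels.
#' @param covariates data frame of nuisance covariates (may include
#'   `disease_duration` with `NA` for controls).
#' @param duration_mode `"impute_centered"` (default) or `"drop"`.
#' @return list with `statistic` (F), `p`, `df`, `group_means` (adjusted),
#'   `covariates`, `duration_mode`.
#' @export
ancova_edge <- function(values, groups, covariates = NULL,
                        duration_mode = c("impute_centered", "drop")) {
  duration_mode <- match.arg(duration_mode)
  groups <- factor(groups)
  dat <- data.frame(.y = values, .g = groups)
  cov_names <- character()
  if (!is.null(covariates) && ncol(as.data.frame(covariates))) {
    covariates <- as.data.frame(covariates)
    if ("disease_duration" %in% names(covariates)) {
      dd <- covariates$disease_duration
      if (duration_mode == "drop") {
        covariates$disease_duration <- NULL
      } else {
        obs <- !is.na(dd)
        dd[obs] <- dd[obs] - mean(dd[obs])
        dd[!obs] <- 0
        covariates$disease_duration <- dd
      }
    }
    cov_names <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  rhs0 <- if (length(cov_names))
    paste(cov_names, collapse = " + ") else "1"
  fit0 <- lm(stats::as.formula(paste(".y ~", rhs0)), data = dat)
  fit1 <- lm(stats::as.formula(paste(".y ~ .g +", rhs0)), data = dat)
  if (any(is.na(coef(fit1))))
    stop_dynfc("ancova_edge: rank-deficient design")
  an <- anova(fit0, fit1)
  list(statistic = an$F[2], p = an$`Pr(>F)`[2],
       df = c(an$Df[2], an$Res.Df[2]),
       group_means = tapply(values, groups, mean),
       covariates = cov_names, duration_mode = duration_mode)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values (monotone) and the rejection mask at
#' `q < alpha`.
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha rejection level (default 0.05).
#' @return list with `q`, `reject`, `m` (family size).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_dynfc("fdr_bh: p-values must be finite and in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = q < alpha, m = length(p))
}

#' FDR-corrected post hoc pairwise comparisons
#'
#' Pairwise two-group versions of the omnibus test: Wilcoxon rank-sum
#' after a Kruskal-Wallis omnibus (`test = "rank"`), or a pairwise
#' two-group ANCOVA partial F after an ANCOVA omnibus
#' (`test = "ancova"`). Benjamini-Hochberg correction is applied over the
#' pairwise family.
#'
#' @param values per-subject response.
#' @param groups group labels.
#' @param test `"rank"` or `"ancova"`.
#' @param covariates covariates for the ANCOVA variant.
#' @param alpha FDR level.
#' @param ... passed to [ancova_edge()].
#' @return data frame with one row per pair: `group_a`, `group_b`,
#'   `statistic`, `p`, `q`, `reject`.
#' @export
posthoc_pairwise <- function(values, groups, test = c("rank", "ancova"),
                             covariates = NULL, alpha = 0.05, ...) {
  test <- match.arg(test)
  groups <- factor(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sel <- groups %in% c(a, b)
    if (test == "rank") {
      wt <- suppressWarnings(wilcox.test(values[groups == a],
                                         values[groups == b]))
      data.frame(group_a = a, group_b = b,
                 statistic = unname(wt$statistic), p = wt$p.value)
    } else {
      cv <- if (is.null(covariates)) NULL
            else covariates[sel, , drop = FALSE]
      fit <- ancova_edge(values[sel], droplevels(groups[sel]), cv, ...)
      data.frame(group_a = a, group_b = b,
                 statistic = fit$statistic, p = fit$p)
    }
  })
  out <- do.call(rbind, res)
  bh <- fdr_bh(out$p, alpha)
  out$q <- bh$q
  out$reject <- bh$reject
  out
}

#' Covariate-adjusted partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' both on the covariates (plus intercept); two-tailed t-test on
#' `n - p - 2` degrees of freedom. With no covariates this is the plain
#' Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data frame / matrix of covariates.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  p_cov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= p_cov + 2) stop_dynfc("partial_correlation: insufficient df")
  sx0 <- sd(x); sy0 <- sd(y)
  if (p_cov > 0) {
    X <- cbind(1, as.matrix(covariates))
    q <- qr(X)
    x <- qr.resid(q, x)
    y <- qr.resid(q, y)
  }
  if (sd(x) <= 1e-10 * max(sx0, 1e-12) || sd(y) <= 1e-10 * max(sy0, 1e-12))
    stop_dynfc("partial_correlation: zero residual variance")
  r <- cor(x, y)
  df <- n - p_cov - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df, n = n)
}
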