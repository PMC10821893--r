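# The statistical decision policy: evaluate distributional assumptions,
# then run the mandated comparison. Normality is screened per group by
# Shapiro-Wilk at alpha = 0.05 and variance homogeneity by
# median-centred Levene; both groups must pass normality for the
# parametric route. Results always report mean +/- s.e.m. (sd/sqrt(n)).

.sem <- function(v) stats::sd(v) / sqrt(length(v))

.descriptives <- function(values, groups) {
  lv <- unique(groups)
  data.frame(group = lv,
             n = vapply(lv, function(g) sum(groups == g), 0L),
             mean = vapply(lv, function(g) mean(values[groups == g]),
                           0),
             sem = vapply(lv, function(g) .sem(values[groups == g]),
                          0))
}

#' Assess distributional assumptions per group
#'
#' Shapiro-Wilk normality per group and a median-centred Levene test of
#' variance homogeneity, both at the given alpha. Groups with fewer
#' than 3 observations (or degenerate zero-variance samples) get an
#' indeterminate (NA) normality flag, which routes downstream
#' comparisons to the nonparametric test.
#'
#' @param values numeric vector of measurements.
#' @param groups group label per measurement.
#' @param alpha screening level.
#' @return list with \code{normal} (named logical, NA = indeterminate),
#'   \code{shapiro_p}, \code{homoscedastic}, \code{levene_p},
#'   \code{alpha}.
#' @export
assessAssumptions <- function(values, groups, alpha = 0.05) {
  lv <- unique(groups)
  sw <- vapply(lv, function(g) {
    v <- values[groups == g]
    if (length(v) < 3L || stats::sd(v) == 0) return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  names(sw) <- lv
  normal <- sw >= alpha
  lev_p <- if (length(lv) >= 2L && all(table(groups) >= 2L)) {
    tryCatch(
      car::leveneTest(values ~ factor(groups),
                      center = stats::median)[1L, "Pr(>F)"],
      error = function(e) NA_real_)
  } else NA_real_
  list(normal = normal, shapiro_p = sw,
       homoscedastic = if (is.na(lev_p)) NA else lev_p >= alpha,
       levene_p = lev_p, alpha = alpha)
}

# midrank Mann-Whitney U of group a versus pooled sample
.mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact two-sided p by full enumeration of group assignments; the null
# distribution of U is symmetric about n1*n2/2 under exchangeability,
# also with midrank ties
.mw_exact_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  mu <- n1 * (n - n1) / 2
  obs <- abs(.mw_u(a, b) - mu)
  combos <- utils::combn(n, n1)
  offs <- n1 * (n1 + 1) / 2
  us <- colSums(matrix(r[combos], nrow = n1)) - offs
  mean(abs(us - mu) >= obs - 1e-9)
}

.mw_approx_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u <- .mw_u(a, b)
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)  # continuity corr.
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Two-group comparison with the normality-gated policy
#'
#' If both groups pass Shapiro-Wilk normality screening, a two-tailed
#' Student's t test is run (Welch's correction when the Levene screen
#' rejects variance homogeneity); otherwise a two-tailed Mann-Whitney U
#' test, exact by full enumeration when min(n1, n2) <= 8 and by normal
#' approximation with tie and continuity correction otherwise.
#' Zero-variance degenerate pairs fall back to the rank route, flagged.
#' The result records which route was taken.
#'
#' @param a,b numeric vectors, one per group (each n >= 2).
#' @param alpha screening level for the assumption tests.
#' @param exactMax largest min(n1, n2) for which the exact U
#'   distribution is enumerated.
#' @return a \linkS4class{StatResult}.
#' @examples
#' compareTwoGroups(rnorm(8), rnorm(8, 2))
#' @export
compareTwoGroups <- function(a, b, alpha = 0.05, exactMax = 8L) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  values <- c(a, b)
  groups <- rep(c("a", "b"), c(length(a), length(b)))
  flags <- assessAssumptions(values, groups, alpha)
  parametric <- isTRUE(all(flags$normal))
  desc <- .descriptives(values, groups)
  if (parametric && (stats::sd(a) > 0 || stats::sd(b) > 0)) {
    welch <- isFALSE(flags$homoscedastic)
    tt <- stats::t.test(a, b, var.equal = !welch)
    flags$route <- if (welch) "welch_t" else "student_t"
    return(StatResult(
      if (welch) "Welch t test (two-tailed)" else
        "Student t test (two-tailed)",
      statistic = c(t = unname(tt$statistic),
                    df = unname(tt$parameter)),
      pValue = tt$p.value, descriptives = desc,
      assumptions = flags))
  }
  if (parametric) flags$degenerate_fallback <- TRUE
  exact <- min(length(a), length(b)) <= exactMax
  u <- .mw_u(a, b)
  p <- if (exact) .mw_exact_p(a, b) else .mw_approx_p(a, b)
  flags$route <- if (exact) "mann_whitney_exact" else
    "mann_whitney_approx"
  StatResult(
    paste0("Mann-Whitney U test (two-tailed, ",
           if (exact) "exact" else "normal approximation", ")"),
    statistic = c(U = u), pValue = p, descriptives = desc,
    assumptions = flags)
}

#' Fixed-effects factorial ANOVA with post-hoc comparisons
#'
#' Ordinary least-squares one- or two-way ANOVA (two factors include
#' their interaction), with Tukey HSD or Sidak-corrected pairwise
#' post-hoc comparisons between the (cell) means. For a one-way design
#' the headline p value is the factor's; for a two-way design it is the
#' interaction's, with every term reported in the statistic vector and
#' the full ANOVA table in the assumptions.
#'
#' @param table data.frame with a \code{value} column and the factor
#'   columns named in \code{factors}.
#' @param factors character, 1 or 2 factor column names.
#' @param posthoc \code{"tukey"} or \code{"sidak"}.
#' @return a \linkS4class{StatResult} with the pairwise table in
#'   \code{posthocTable(x)}.
#' @export
compareFactorial <- function(table, factors, posthoc = c("tukey",
                                                         "sidak")) {
  posthoc <- match.arg(posthoc)
  stopifnot("value" %in% names(table), length(factors) %in% 1:2,
            all(factors %in% names(table)))
  for (f in factors) table[[f]] <- factor(table[[f]])
  cell <- interaction(table[factors], drop = FALSE, sep = ":")
  if (any(table(cell) < 2L))
    stop("every design cell needs at least 2 units (empty cell?)")
  if (any(vapply(table[factors], nlevels, 0L) < 2L))
    stop("every factor needs at least 2 levels")
  fml <- stats::as.formula(paste("value ~",
                                 paste(factors, collapse = " * ")))
  fit <- stats::aov(fml, data = table)
  atab <- summary(fit)[[1L]]
  terms <- trimws(rownames(atab))
  fstats <- atab[["F value"]]
  pvals <- atab[["Pr(>F)"]]
  keep <- !is.na(fstats)
  statv <- stats::setNames(fstats[keep], paste0("F_", terms[keep]))
  headline <- if (length(factors) == 1L) pvals[1L] else
    pvals[which(terms == paste(factors, collapse = ":"))]
  ph <- if (posthoc == "tukey") {
    term <- paste(factors, collapse = ":")
    tk <- stats::TukeyHSD(fit, which = term)[[term]]
    data.frame(contrast = rownames(tk), diff = tk[, "diff"],
               lwr = tk[, "lwr"], upr = tk[, "upr"],
               p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    ires <- which(terms == "Residuals")
    mse <- atab[ires, "Mean Sq"]
    dfres <- atab[ires, "Df"]
    means <- tapply(table$value, cell, mean)
    ns <- tapply(table$value, cell, length)
    pr <- utils::combn(names(means), 2L)
    m <- ncol(pr)
    rows <- lapply(seq_len(m), function(i) {
      g1 <- pr[1L, i]; g2 <- pr[2L, i]
      diff <- means[[g1]] - means[[g2]]
      se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
      tv <- diff / se
      p <- 2 * stats::pt(-abs(tv), dfres)
      data.frame(contrast = paste(g1, g2, sep = "-"), diff = diff,
                 t = tv, p_unadj = p,
                 p_adj = min(1, 1 - (1 - p)^m))
    })
    do.call(rbind, rows)
  }
  desc <- .descriptives(table$value, as.character(cell))
  StatResult(
    paste0(length(factors), "-way ANOVA with ",
           if (posthoc == "tukey") "Tukey HSD" else "Sidak",
           " post-hoc"),
    statistic = statv, pValue = headline, descriptives = desc,
    assumptions = list(anova_table = atab, posthoc = posthoc),
    posthoc = ph)
}

.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- .perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, p + (p >= k))))
}

#' Spearman rank correlation with exact small-n p value
#'
#' Spearman's rho on midranks (ties allowed). The two-sided p value is
#' computed by exhaustive enumeration of all n! rank permutations for
#' n <= 8 and by the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @param exactMax largest n for which the permutation distribution is
#'   enumerated.
#' @return a \linkS4class{StatResult} with statistic \code{rho}.
#' @export
spearmanCorrelation <- function(x, y, exactMax = 8L) {
  stopifnot(length(x) == length(y), length(x) >= 4L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exactMax) {
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    P <- .perms(n)
    M <- matrix(ryc[P], nrow(P), n)
    rhos <- as.vector(M %*% rxc) /
      sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation (exact permutation)"
  } else {
    tv <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tv), n - 2))
    method <- "Spearman rank correlation (t approximation)"
  }
  StatResult(method, statistic = c(rho = rho), pValue = p,
             descriptives = data.frame(group = "xy", n = n,
                                       mean = NA_real_,
                                       sem = NA_real_),
             assumptions = list(ties_x = anyDuplicated(x) > 0,
                                ties_y = anyDuplicated(y) > 0))
}
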