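#' Brown-Forsythe test for homogeneity of variances
#'
#' Levene's test with group medians as centres (the Brown-Forsythe
#' variant), via `car::leveneTest`.
#'
#' @param values numeric vector of observations.
#' @param groups factor (or coercible) of group labels.
#' @return p-value.
#' @export
brown_forsythe <- function(values, groups) {
  groups <- as.factor(groups)
  res <- car::leveneTest(values ~ groups, center = stats::median)
  res[1, "Pr(>F)"]
}

#' D'Agostino-Pearson omnibus normality test (K2)
#'
#' Combines the D'Agostino skewness z and the Anscombe-Glynn kurtosis z
#' into K2 = z_skew^2 + z_kurt^2, referred to a chi-squared distribution
#' with 2 degrees of freedom. Requires at least 8 observations.
#'
#' @param x numeric vector.
#' @return list with `K2`, `p`, `z_skew`, `z_kurt`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test needs at least 8 observations",
                   call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  if (m2 == 0) stop("zero variance", call. = FALSE)

  # skewness z (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- ((1 - 2 / (9 * A)) - term) / sqrt(2 / (9 * A))

  K2 <- z_skew^2 + z_kurt^2
  list(K2 = K2, p = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise rank-sum z tests on the pooled ranks with the tie correction,
#' two-sided normal p-values adjusted by Bonferroni over all pairs.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return data.frame with `pair`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("nothing to compare", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(
    pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
    z = res["z", ],
    p = res["p", ],
    p_adj = pmin(1, res["p", ] * ncol(pairs)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Maximum-likelihood Box-Cox lambda over [-2, 2] for a one-way layout.
boxcox_lambda <- function(values, groups, lambdas = seq(-2, 2, by = 0.05)) {
  df <- data.frame(y = values, g = as.factor(groups))
  bc <- MASS::boxcox(y ~ g, data = df, lambda = lambdas, plotit = FALSE)
  bc$x[which.max(bc$y)]
}

boxcox_transform <- function(values, lambda) {
  if (abs(lambda) < 1e-8) log(values) else (values^lambda - 1) / lambda
}

#' Compare replicate groups with an assumption-driven decision tree
#'
#' Implements the analysis decision tree used for grouped editing-rate
#' comparisons: variances are tested for homogeneity with the
#' Brown-Forsythe test and ANOVA residuals for normality with the
#' D'Agostino-Pearson K2 test; when both pass, a one-way ANOVA with Tukey's
#' post hoc test is reported. When assumptions fail but the data are
#' strictly positive, a Box-Cox transformation (maximum-likelihood lambda
#' over \[-2, 2\]) is applied and the assumptions re-tested on the
#' transformed data; if they then hold, the ANOVA/Tukey analysis is run on
#' the transformed values. Otherwise the Kruskal-Wallis test with Dunn's
#' post hoc test (Bonferroni-adjusted) is used. Groups of identical
#' constants are reported as an explicit no-variance outcome.
#'
#' @param samples named list of numeric replicate vectors (at least two
#'   groups with at least three replicates each).
#' @param alpha significance level for the reported omnibus decision.
#' @param assumption_alpha level used for the assumption tests (default
#'   0.05).
#' @return object of class `group_comparison`: `path_taken` (one of
#'   `anova_tukey`, `boxcox_anova_tukey`, `kruskal_dunn`, `no_variance`),
#'   `brown_forsythe_p`, `dagostino_K2_p`, `omnibus_p`, `significant`,
#'   `pairwise` (data.frame of pair and adjusted p), `boxcox_lambda`.
#' @export
compare_groups <- function(samples, alpha = 0.05, assumption_alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("nothing to compare: need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(samples, length, integer(1)) < 3L)) {
    stop("each group needs at least 3 replicates", call. = FALSE)
  }
  if (is.null(names(samples))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(names(samples), vapply(samples, length, integer(1))),
                   levels = names(samples))

  fit <- stats::aov(values ~ groups)
  resid <- stats::residuals(fit)
  if (stats::var(values) == 0 || max(abs(resid)) < 1e-12) {
    return(structure(
      list(path_taken = "no_variance", brown_forsythe_p = NA_real_,
           dagostino_K2_p = NA_real_, omnibus_p = NA_real_,
           significant = FALSE, pairwise = NULL, boxcox_lambda = NA_real_),
      class = "group_comparison"
    ))
  }

  assess <- function(v) {
    f <- stats::aov(v ~ groups)
    list(bf_p = brown_forsythe(v, groups),
         k2_p = dagostino_k2(stats::residuals(f))$p,
         fit = f)
  }
  anova_result <- function(f, path, a0, lambda = NA_real_) {
    p <- summary(f)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(f)$groups
    structure(
      list(path_taken = path, brown_forsythe_p = a0$bf_p,
           dagostino_K2_p = a0$k2_p, omnibus_p = p,
           significant = p < alpha,
           pairwise = data.frame(pair = rownames(tk),
                                 adjusted_p = tk[, "p adj"],
                                 row.names = NULL, stringsAsFactors = FALSE),
           boxcox_lambda = lambda),
      class = "group_comparison"
    )
  }

  a0 <- assess(values)
  if (a0$bf_p > assumption_alpha && a0$k2_p > assumption_alpha) {
    return(anova_result(a0$fit, "anova_tukey", a0))
  }

  if (all(values > 0)) {
    lambda <- boxcox_lambda(values, groups)
    tv <- boxcox_transform(values, lambda)
    a1 <- assess(tv)
    if (a1$bf_p > assumption_alpha && a1$k2_p > assumption_alpha) {
      return(anova_result(a1$fit, "boxcox_anova_tukey", a0, lambda = lambda))
    }
  }

  kw <- stats::kruskal.test(values, groups)
  dn <- dunn_test(values, groups)
  structure(
    list(path_taken = "kruskal_dunn", brown_forsythe_p = a0$bf_p,
         dagostino_K2_p = a0$k2_p, omnibus_p = kw$p.value,
         significant = kw$p.value < alpha,
         pairwise = data.frame(pair = dn$pair, adjusted_p = dn$p_adj,
                               stringsAsFactors = FALSE),
         boxcox_lambda = NA_real_),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group comparison: path =", x$path_taken,
      "| omnibus p =", format(x$omnibus_p, digits = 4), "\n")
  if (!is.null(x$pairwise)) {
    print(x$pairwise)
  }
  invisible(x)
}
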