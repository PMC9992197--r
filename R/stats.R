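#' Shapiro-Wilk normality gate
#'
#' Thin wrapper returning a verdict that drives the correlation-method
#' choice (Pearson when all inputs pass, Spearman otherwise). Constant
#' samples are flagged degenerate rather than raising.
#'
#' @param x numeric sample (n >= 3).
#' @param alpha gate level (default 0.05).
#' @return list(W, p, normal, degenerate).
#' @export
shapiroGate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("normality gate needs at least 3 observations")
  if (stats::sd(x) == 0)
    return(list(W = NA_real_, p = NA_real_, normal = FALSE,
                degenerate = TRUE))
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value,
       normal = sw$p.value >= alpha, degenerate = FALSE)
}

# rank-based H statistic with tie correction (used by the permutation path)
.kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  sums <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  H <- 12 / (n * (n + 1)) * sum(sums^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  tc <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tc > 0) H <- H / tc
  H
}

#' Kruskal-Wallis comparison of independent groups
#'
#' Rank-based H with tie correction and a chi-square reference p (via
#' stats::kruskal.test). For small samples (total n <= 10 by default) an
#' exact permutation p — the proportion of all reassignments of the
#' observations to the group sizes with H at least as large — can be
#' requested. If all values are identical the convention H = 0, p = 1 is
#' returned.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length (>= 2 groups, total n >= 3).
#' @param exact FALSE (chi-square), TRUE (permutation), or "auto"
#'   (permutation when total n <= 10).
#' @return list(H, p, df, method).
#' @examples
#' kruskalWallis(1:9, rep(1:3, each = 3))$H  # 7.2
#' @export
kruskalWallis <- function(values, groups, exact = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (length(values) < 3) stop("need total n >= 3")
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  groups <- droplevels(groups)
  if (length(unique(values)) == 1)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1, method = "degenerate"))
  doExact <- isTRUE(exact) ||
    (identical(exact, "auto") && length(values) <= 10)
  if (doExact) {
    H <- .kw_h(values, groups)
    p <- .kw_exact_p(values, groups, H)
    return(list(H = H, p = p, df = nlevels(groups) - 1,
                method = "exact permutation"))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), method = "chi-square")
}

# Exact permutation p by full enumeration of group assignments. Ranks and
# the tie correction are invariant under reassignment, so only per-group
# rank sums change across the enumeration.
.kw_exact_p <- function(values, groups, Hobs) {
  r <- rank(values)
  n <- length(r)
  ns <- as.integer(table(droplevels(as.factor(groups))))
  k <- length(ns)
  ties <- table(values)
  tc <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tc <= 0) return(1)
  const <- 12 / (n * (n + 1))
  count <- 0L; total <- 0L
  recurse <- function(remaining, gi, acc) {
    if (gi == k) {
      s <- acc + sum(r[remaining])^2 / ns[k]
      H <- (const * s - 3 * (n + 1)) / tc
      total <<- total + 1L
      if (H >= Hobs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    sets <- utils::combn(remaining, ns[gi])
    for (j in seq_len(ncol(sets))) {
      sel <- sets[, j]
      recurse(setdiff(remaining, sel), gi + 1L,
              acc + sum(r[sel])^2 / ns[gi])
    }
  }
  recurse(seq_len(n), 1L, 0)
  count / total
}

#' Pairwise post hoc rank tests with Bonferroni adjustment
#'
#' Two-sample Mann-Whitney (Wilcoxon rank-sum) tests for every group
#' pair, with p-values multiplied by the number of pairs and clipped at 1.
#'
#' @param values numeric observations. @param groups group labels.
#' @return data.frame(contrast, p_raw, p_bonf), one row per pair, with
#'   contrast names "A-B" in group-level order.
#' @export
pairwisePosthoc <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2) stop("post hoc comparisons need at least 2 groups")
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  praw <- vapply(seq_len(m), function(j) {
    a <- values[groups == pairs[1, j]]
    b <- values[groups == pairs[2, j]]
    if (length(unique(c(a, b))) == 1) return(1)
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }, numeric(1))
  data.frame(contrast = paste(pairs[1, ], pairs[2, ], sep = "-"),
             p_raw = praw, p_bonf = pmin(1, praw * m),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p p-values in [0, 1].
#' @param q target false-discovery rate (default 0.05).
#' @return list(adjusted, reject) where `reject` is the step-up rejection
#'   set at level q (equivalently adjusted p <= q).
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04, 0.25))$reject  # first four TRUE
#' @export
bhFdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Correlation between a clinical feature and spectral power
#'
#' Pearson when both variables pass the Shapiro-Wilk gate, Spearman
#' otherwise; the method used is recorded.
#'
#' @param clinical,power paired numeric vectors (n >= 4).
#' @param alpha gate level for the normality decision.
#' @return list(R, p, method, n).
#' @export
clinicalCorrelation <- function(clinical, power, alpha = 0.05) {
  ok <- is.finite(clinical) & is.finite(power)
  clinical <- clinical[ok]; power <- power[ok]
  if (length(clinical) < 4) stop("correlation needs at least 4 pairs")
  if (stats::sd(clinical) == 0 || stats::sd(power) == 0)
    stop("zero variance in one of the correlated variables")
  g1 <- shapiroGate(clinical, alpha); g2 <- shapiroGate(power, alpha)
  method <- if (isTRUE(g1$normal) && isTRUE(g2$normal)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(clinical, power, method = method,
                                         exact = FALSE))
  list(R = unname(ct$estimate), p = ct$p.value, method = method,
       n = length(clinical))
}

#' Two-sample t-test from summary statistics
#'
#' Independent-samples t computed from printed means, SDs and group
#' sizes, for reproducing demographic-table comparisons when raw data are
#' unavailable.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (sd > 0, n >= 2).
#' @param variant "welch" (default) or "pooled".
#' @return list(t, df, p) with a two-sided p.
#' @examples
#' summaryTTest(84.63, 4.79, 24, 107.79, 8.03, 24)$p  # << 0.001
#' @export
summaryTTest <- function(mean1, sd1, n1, mean2, sd2, n2,
                         variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be > 0")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
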