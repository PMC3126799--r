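#' Paired Wilcoxon signed-rank test with an exact tied-data distribution
#'
#' Computes the signed-rank statistic W+ (sum of midranks of positive
#' differences after dropping zero differences) and its p-values under the
#' exact permutation distribution over all 2^n sign assignments, obtained by
#' the shift algorithm (a convolution over doubled midranks, so ties are
#' handled exactly). For \code{n} above \code{exactLimit} a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x first sample, or the vector of differences when \code{y} is NULL
#' @param y optional second sample, paired with \code{x}
#' @param exactLimit largest n for which the exact distribution is enumerated
#' @return list with \code{statistic} (W+), \code{n} (nonzero differences),
#'   p-values \code{p.greater}, \code{p.less}, \code{p.two.sided}, and
#'   \code{method}
#' @examples
#' # nine positive differences: one-sided p = 1/512
#' wilcoxonSignedRank(rep(1, 9) + (1:9) / 100)$p.greater
#' @export
wilcoxonSignedRank <- function(x, y = NULL, exactLimit = 25L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (length(d) < 2) stop("need at least 2 pairs")
  d <- d[!is.na(d)]
  nz <- d != 0
  if (!any(nz)) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, n = 0L, p.greater = 1, p.less = 1,
                p.two.sided = 1, method = "degenerate"))
  }
  d <- d[nz]
  n <- length(d)
  r <- rank(abs(d))                       # midranks for ties
  W <- sum(r[d > 0])
  if (n <= exactLimit) {
    r2 <- as.integer(round(2 * r))        # doubled ranks are integers
    total <- sum(r2)
    # shift algorithm: counts[w + 1] = number of sign assignments with
    # doubled positive-rank sum w
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    top <- 0L
    for (ri in r2) {
      new <- counts
      new[(ri + 1L):(top + ri + 1L)] <-
        new[(ri + 1L):(top + ri + 1L)] + counts[1L:(top + 1L)]
      counts <- new
      top <- top + ri
    }
    tot <- 2^n
    w2 <- as.integer(round(2 * W))
    pGreater <- sum(counts[(w2 + 1L):(total + 1L)]) / tot
    pLess <- sum(counts[1L:(w2 + 1L)]) / tot
    # the distribution is symmetric about total/2: reflect for two-sided
    mirror <- total - w2
    pTwo <- if (w2 > mirror) {
      pGreater + sum(counts[1L:(mirror + 1L)]) / tot
    } else if (w2 < mirror) {
      pLess + sum(counts[(mirror + 1L):(total + 1L)]) / tot
    } else 1
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2) / 4)
    zG <- (W - mu - 0.5) / sigma
    zL <- (W - mu + 0.5) / sigma
    pGreater <- pnorm(zG, lower.tail = FALSE)
    pLess <- pnorm(zL)
    pTwo <- min(1, 2 * min(pGreater, pLess))
    method <- "normal approximation"
  }
  list(statistic = W, n = n, p.greater = pGreater, p.less = pLess,
       p.two.sided = min(1, pTwo), method = method)
}

#' Paired t-test on condition pairs
#'
#' Thin wrapper around \code{stats::t.test(paired = TRUE)} with an explicit
#' error for degenerate (zero-variance) differences.
#'
#' @param x,y paired samples
#' @return list with \code{statistic} (t), \code{df}, \code{p.two.sided},
#'   \code{p.greater}, \code{p.less}
#' @export
pairedT <- function(x, y) {
  d <- as.numeric(x) - as.numeric(y)
  if (length(d) < 2) stop("need at least 2 pairs")
  if (sd(d) == 0)
    stop("differences have zero variance; the paired t statistic is degenerate")
  ht <- t.test(x, y, paired = TRUE)
  tt <- unname(ht$statistic)
  df <- unname(ht$parameter)
  list(statistic = tt, df = df,
       p.two.sided = ht$p.value,
       p.greater = pt(tt, df, lower.tail = FALSE),
       p.less = pt(tt, df))
}

#' One-way repeated-measures ANOVA
#'
#' Tests a condition main effect on a complete subject x condition matrix,
#' removing the subject effect as a blocking factor; F has degrees of freedom
#' (k - 1, (k - 1)(n - 1)).
#'
#' @param mat numeric matrix, subjects x conditions (complete, no NA)
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p.value} and the
#'   aov \code{table}
#' @export
rmAnova <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells in the subject x condition matrix")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  long <- data.frame(
    value = as.vector(mat),
    subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    condition = factor(rep(colnames(mat), each = nrow(mat))))
  fit <- aov(value ~ subject + condition, data = long)
  tab <- summary(fit)[[1]]
  i <- grep("^condition", trimws(rownames(tab)))
  Fv <- tab[i, "F value"]; pv <- tab[i, "Pr(>F)"]
  # exactly collinear condition means leave 0/0; report no effect
  if (tab[i, "Sum Sq"] <= 1e-12 * max(sum(tab[, "Sum Sq"]), 1)) {
    Fv <- 0; pv <- 1
  }
  list(F = Fv, df1 = tab[i, "Df"],
       df2 = tab[nrow(tab), "Df"], p.value = pv,
       table = tab)
}

#' Pairwise post-hoc comparisons with familywise correction
#'
#' All pairwise paired tests between the columns of a subject x condition
#' matrix, adjusted for multiple comparisons (Holm step-down by default,
#' which controls the familywise error rate without sphericity assumptions).
#'
#' @param mat numeric matrix, subjects x conditions
#' @param method adjustment method, see \code{\link[stats]{p.adjust}}
#' @param test "t" for paired t-tests or "wilcoxon" for exact signed-rank
#' @return data.frame with columns a, b, p.raw, p.adjusted
#' @export
multipleComparisons <- function(mat, method = "holm",
                                test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  pairs <- utils::combn(colnames(mat), 2)
  p <- apply(pairs, 2, function(ab) {
    d <- mat[, ab[1]] - mat[, ab[2]]
    if (test == "t") {
      # degenerate pairs: no evidence of a difference when all zero,
      # otherwise undefined under the t model
      if (sd(d) == 0) return(if (all(d == 0)) 1 else NA_real_)
      pairedT(mat[, ab[1]], mat[, ab[2]])$p.two.sided
    } else {
      suppressWarnings(
        wilcoxonSignedRank(mat[, ab[1]], mat[, ab[2]])$p.two.sided)
    }
  })
  data.frame(a = pairs[1, ], b = pairs[2, ], p.raw = p,
             p.adjusted = p.adjust(p, method = method),
             stringsAsFactors = FALSE)
}
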