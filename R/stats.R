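#' Shapiro-Francia W' normality test
#'
#' W' is the squared correlation between the ordered sample and the expected
#' standard-normal order statistics approximated by Blom scores
#' qnorm((i - 3/8) / (n + 1/4)); the p-value uses Royston's normalising
#' transformation of log(1 - W').  Valid for 5 <= n <= 5000.
#'
#' @param x numeric sample without missing values.
#' @return An \code{htest}-style list with \code{statistic} (W'),
#'   \code{p.value} and \code{method}; the \code{branch} element carries the
#'   machine-readable tag \code{"shapiro_francia"}.
#' @export
shapiroFrancia <- function(x) {
    x <- sort(x)
    n <- length(x)
    if (n < 5 || n > 5000)
        stop("Shapiro-Francia requires 5 <= n <= 5000")
    if (sd(x) == 0) stop("sample is constant; W' undefined")
    m <- qnorm(((1:n) - 3 / 8) / (n + 1 / 4))
    W <- cor(x, m)^2
    u <- log(n); v <- log(u)
    z <- (log(1 - W) - (-1.2725 + 1.0521 * (v - u))) /
         (1.0308 - 0.26758 * (v + 2 / u))
    structure(list(statistic = c("W'" = W),
                   p.value = pnorm(z, lower.tail = FALSE),
                   method = "Shapiro-Francia normality test",
                   branch = "shapiro_francia", n = n,
                   data.name = deparse(substitute(x))),
              class = "htest")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test.  For n1, n2 <= \code{exactMax} the p-value is
#' exact, by full enumeration of all choose(n1 + n2, n1) assignments of the
#' pooled (mid-)ranks to the first sample - correct under ties as well.
#' Larger samples use the tie-corrected normal approximation (no continuity
#' correction).
#'
#' @param x,y numeric samples (missing values dropped).
#' @param exactMax enumeration cutoff per group; default 9.
#' @return \code{htest}-style list; \code{branch} is
#'   \code{"mann_whitney_exact"} or \code{"mann_whitney_normal"}.
#' @export
mannWhitneyU <- function(x, y, exactMax = 9) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 1 || n2 < 1) stop("empty sample after dropping missing values")
    r <- rank(c(x, y), ties.method = "average")
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    if (n1 <= exactMax && n2 <= exactMax) {
        sel <- combn(n1 + n2, n1)
        Us <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
        p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
        branch <- "mann_whitney_exact"
    } else {
        N <- n1 + n2
        ties <- table(r)
        sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
        if (sig2 <= 0) {
            p <- 1
        } else {
            p <- min(1, 2 * pnorm(-abs(U - mu) / sqrt(sig2)))
        }
        branch <- "mann_whitney_normal"
    }
    structure(list(statistic = c(U = U), p.value = p,
                   method = paste0("Mann-Whitney U test (",
                                   sub("mann_whitney_", "", branch), " p)"),
                   branch = branch, n = c(n1 = n1, n2 = n2),
                   data.name = "x vs y"),
              class = "htest")
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties; rho is the Pearson correlation of the ranks, and the
#' two-sided p-value uses the t approximation
#' t = rho sqrt((n - 2) / (1 - rho^2)).  Pairs with a missing value in
#' either variable are dropped (pairwise deletion).  A constant vector
#' yields a flagged, undefined result (rho and p are NA) rather than an
#' error.
#'
#' @param x,y paired numeric samples.
#' @return \code{htest}-style list with \code{estimate} (rho),
#'   \code{p.value}, \code{n}; \code{branch} is \code{"spearman"} and
#'   \code{degenerate} is TRUE when rho is undefined.
#' @export
spearmanCorr <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4) stop("need at least 4 complete pairs")
    degenerate <- sd(x) == 0 || sd(y) == 0
    if (degenerate) {
        rho <- NA_real_; p <- NA_real_
    } else {
        rho <- cor(rank(x, ties.method = "average"),
                   rank(y, ties.method = "average"))
        if (abs(rho) >= 1) {
            p <- 0
        } else {
            tstat <- rho * sqrt((n - 2) / (1 - rho^2))
            p <- 2 * pt(-abs(tstat), n - 2)
        }
    }
    structure(list(estimate = c(rho = rho), p.value = p,
                   method = "Spearman rank correlation (t approximation)",
                   branch = "spearman", n = n, degenerate = degenerate,
                   data.name = "x vs y"),
              class = "htest")
}

#' Normality-gated two-sample comparison
#'
#' The statistical layer of the global and ROI tables: both samples are
#' screened with the Shapiro-Francia test at \code{alphaNormality}; if both
#' pass, groups are compared with the two-sided pooled-variance Student
#' t-test, otherwise with the Mann-Whitney U test (exact for small groups).
#' Samples too small for the normality screen (n < 5) or constant samples
#' take the nonparametric branch.  Missing values are dropped per sample.
#'
#' @param x,y numeric samples (>= 3 non-missing each).
#' @param alphaNormality significance level of the normality gate.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return \code{htest}-style list; \code{branch} records the test actually
#'   used (\code{"t"}, \code{"mann_whitney_exact"} or
#'   \code{"mann_whitney_normal"}) and \code{normalityP} the two gate
#'   p-values (NA where the gate could not run).
#' @export
twoSampleCompare <- function(x, y, alphaNormality = 0.05, welch = FALSE) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3)
        stop("need at least 3 non-missing observations per group")
    sfp <- vapply(list(x, y), function(s) {
        if (length(s) < 5 || sd(s) == 0) return(NA_real_)
        shapiroFrancia(s)$p.value
    }, 0)
    normal <- !anyNA(sfp) && all(sfp > alphaNormality)
    if (normal) {
        tt <- t.test(x, y, var.equal = !welch)
        res <- structure(list(statistic = tt$statistic, p.value = tt$p.value,
                              method = tt$method, branch = "t",
                              n = c(n1 = length(x), n2 = length(y)),
                              normalityP = sfp, data.name = "x vs y"),
                         class = "htest")
    } else {
        res <- mannWhitneyU(x, y)
        res$normalityP <- sfp
    }
    res
}

## Group descriptive mirroring the table convention: mean (sd) when the
## normality gate passed, median (IQR) otherwise.
groupDescriptive <- function(x, normal) {
    x <- x[!is.na(x)]
    if (normal)
        sprintf("%.3g (%.2g)", mean(x), sd(x))
    else
        sprintf("%.3g (%.2g)", median(x), IQR(x))
}
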