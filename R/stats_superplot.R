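#' Summarize a hierarchical (superplot) measurement table
#'
#' A superplot table has one row per cell with columns \code{condition},
#' \code{experiment}, \code{cell} and \code{value}, cells being nested in
#' independent experiments. At \code{level = "cell"} the summary pools all
#' cells of a condition; at \code{level = "experiment"} each experiment is
#' first reduced to its mean and the condition mean is the unweighted mean
#' of experiment means (the superplot convention), with SD taken across
#' experiment means. With a single experiment the experiment-level SD is
#' undefined (\code{NA}) and flagged.
#'
#' @param table data.frame with columns condition, experiment, cell, value.
#' @param level "cell" or "experiment".
#' @return data.frame with one row per condition: mean, sd, n (number of
#'   units at the chosen level), sd_defined.
#' @export
aggregateSuperplot <- function(table, level = c("cell", "experiment")) {
  level <- match.arg(level)
  need <- c("condition", "experiment", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns condition, experiment, value")
  if (!all(is.finite(table$value))) stop("values must be finite")
  if (level == "cell") {
    agg <- aggregate(value ~ condition, table,
                     function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
    out <- data.frame(condition = agg$condition,
                      mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                      n = as.integer(agg$value[, "n"]))
    out$sd_defined <- out$n >= 2L
    return(out)
  }
  expMeans <- aggregate(value ~ condition + experiment, table, mean)
  agg <- aggregate(value ~ condition, expMeans,
                   function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(condition = agg$condition,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]))
  out$sd_defined <- out$n >= 2L
  out$sd[!out$sd_defined] <- NA_real_
  out
}

.stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

.comparisonRow <- function(test, pair, statistic, df, p, adjP = p) {
  data.frame(test = test, pair = pair, statistic = statistic, df = df,
             p = p, adj_p = adjP, stars = as.character(.stars(adjP)),
             significant = adjP < 0.05)
}

#' Two-sided Student's t-test (pooled variance)
#'
#' Classical two-sample pooled-variance t-test (or paired t-test) with
#' df = n_a + n_b - 2. When the pooled variance is zero: equal means give
#' t = 0, p = 1 by convention; unequal means are degenerate and raise an
#' error.
#'
#' @param groupA,groupB numeric vectors (each n >= 2).
#' @param paired logical; paired test on the differences.
#' @param labels length-2 character, group names for the pair label.
#' @return one-row comparison data.frame (test, pair, statistic, df, p,
#'   adj_p, stars, significant).
#' @export
studentsT <- function(groupA, groupB, paired = FALSE,
                      labels = c("A", "B")) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  pairLab <- paste(labels, collapse = " vs ")
  if (paired) {
    d <- groupA - groupB
    if (sd(d) == 0) {
      if (mean(d) == 0)
        return(.comparisonRow("paired t", pairLab, 0, length(d) - 1L, 1))
      stop("degenerate paired t-test: zero variance with nonzero difference")
    }
    res <- stats::t.test(groupA, groupB, paired = TRUE)
  } else {
    if (var(groupA) == 0 && var(groupB) == 0) {
      if (mean(groupA) == mean(groupB))
        return(.comparisonRow("Student t", pairLab, 0,
                              length(groupA) + length(groupB) - 2L, 1))
      stop("degenerate t-test: zero pooled variance with unequal means")
    }
    res <- stats::t.test(groupA, groupB, var.equal = TRUE)
  }
  .comparisonRow(if (paired) "paired t" else "Student t", pairLab,
                 unname(res$statistic), unname(res$parameter), res$p.value)
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with df (k - 1, N - k). Zero within-group
#' variance with equal group means gives F = 0, p = 1; with unequal means
#' the statistic is unbounded and reported as \code{Inf} with p = 0 and the
#' degenerate flag set.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return one-row comparison data.frame with an extra \code{degenerate}
#'   column.
#' @export
oneWayAnova <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  k <- length(groups); N <- length(v)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1))
  gm <- mean(v)
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - gm)^2, 1))
  df1 <- k - 1L; df2 <- N - k
  pairLab <- paste(names(groups), collapse = ",")
  if (ssw == 0) {
    if (ssb == 0) {
      out <- .comparisonRow("one-way ANOVA", pairLab, 0, df1, 1)
      out$degenerate <- FALSE
    } else {
      out <- .comparisonRow("one-way ANOVA", pairLab, Inf, df1, 0)
      out$degenerate <- TRUE
    }
    out$df2 <- df2
    return(out)
  }
  f <- (ssb / df1) / (ssw / df2)
  out <- .comparisonRow("one-way ANOVA", pairLab, f, df1,
                        pf(f, df1, df2, lower.tail = FALSE))
  out$degenerate <- FALSE
  out$df2 <- df2
  out
}

#' Tukey HSD all-pairs comparisons
#'
#' Tukey's honestly-significant-difference test on all group pairs, based on
#' the studentized range with the within-group mean square; unbalanced
#' designs use the Tukey-Kramer standard error (equivalent to the harmonic
#' mean of the pair's sizes). Delegates to \code{stats::TukeyHSD} on a
#' one-way \code{aov} fit.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return comparison data.frame, one row per pair; \code{statistic} is the
#'   pair's mean difference and \code{adj_p} the familywise-adjusted p.
#' @export
tukeyHsd <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1))
  if (ssw == 0) {
    # no within-group variance: identical means give p = 1, otherwise the
    # studentized range is unbounded
    combs <- utils::combn(names(groups), 2)
    rows <- lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      d <- mean(groups[[b]]) - mean(groups[[a]])
      .comparisonRow("Tukey HSD", paste(a, "vs", b), d,
                     sum(lengths(groups)) - length(groups),
                     if (d == 0) 1 else 0)
    })
    return(do.call(rbind, rows))
  }
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  hsd <- TukeyHSD(aov(v ~ g))$g
  pairs <- rownames(hsd)
  pairs <- vapply(strsplit(pairs, "-", fixed = TRUE),
                  function(x) paste(x[2], "vs", x[1]), "")
  out <- .comparisonRow("Tukey HSD", pairs, unname(hsd[, "diff"]),
                        length(v) - length(groups), unname(hsd[, "p adj"]),
                        unname(hsd[, "p adj"]))
  rownames(out) <- NULL
  out
}

## Monte-Carlo sample of the Dunnett max-|t| null for given group sizes:
## draws correlated treatment-vs-control t statistics sharing one chi-square
## variance estimate, returns the max |t| per draw
.dunnettNullSample <- function(nControl, nTreat, df, nMc) {
  m <- length(nTreat)
  # t_i = (Zbar_i - Zbar_0) / (s * sqrt(1/n_i + 1/n_0)) under H0
  z0 <- rnorm(nMc, 0, 1 / sqrt(nControl))
  s <- sqrt(rchisq(nMc, df) / df)
  mx <- rep(0, nMc)
  for (i in seq_len(m)) {
    zi <- rnorm(nMc, 0, 1 / sqrt(nTreat[i]))
    ti <- (zi - z0) / (s * sqrt(1 / nTreat[i] + 1 / nControl))
    mx <- pmax(mx, abs(ti))
  }
  mx
}

#' Dunnett many-to-one comparisons by seeded Monte Carlo
#'
#' Compares every treatment group against the control with familywise error
#' control. Each raw statistic is the usual two-sample t built on the pooled
#' within-group mean square (df = N - k); the familywise adjustment is the
#' tail probability of the max-|t| Dunnett null distribution, estimated by
#' seeded Monte Carlo (correlated normal means sharing a single chi-square
#' variance draw), so adjusted p-values are reproducible for a fixed seed
#' and their Monte-Carlo standard error is reported alongside.
#'
#' @param controlGroup numeric vector (n >= 2).
#' @param treatmentGroups named list of numeric vectors.
#' @param nMc number of Monte-Carlo draws of the null max-|t|.
#' @param seed integer seed for the draws.
#' @return comparison data.frame, one row per treatment, with columns
#'   \code{p} (unadjusted two-sided t), \code{adj_p} (familywise), and
#'   \code{mc_se} (MC standard error of adj_p).
#' @export
dunnettMC <- function(controlGroup, treatmentGroups, nMc = 1e5, seed = 1L) {
  stopifnot(length(controlGroup) >= 2, length(treatmentGroups) >= 1)
  if (is.null(names(treatmentGroups)))
    names(treatmentGroups) <- paste0("trt", seq_along(treatmentGroups))
  groups <- c(list(control = controlGroup), treatmentGroups)
  k <- length(groups)
  N <- sum(lengths(groups))
  df <- N - k
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1))
  if (ssw == 0) stop("degenerate: zero within-group variance")
  msw <- ssw / df
  n0 <- length(controlGroup)
  nTr <- lengths(treatmentGroups)
  tObs <- vapply(seq_along(treatmentGroups), function(i) {
    (mean(treatmentGroups[[i]]) - mean(controlGroup)) /
      sqrt(msw * (1 / nTr[i] + 1 / n0))
  }, 1)
  mx <- withr::with_seed(seed, .dunnettNullSample(n0, nTr, df, nMc))
  adj <- vapply(tObs, function(t) mean(mx >= abs(t)), 1)
  praw <- 2 * pt(abs(tObs), df, lower.tail = FALSE)
  out <- .comparisonRow("Dunnett (MC)",
                        paste(names(treatmentGroups), "vs control"),
                        tObs, df, praw, pmax(adj, praw))
  out$mc_se <- sqrt(out$adj_p * (1 - out$adj_p) / nMc)
  rownames(out) <- NULL
  out
}
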