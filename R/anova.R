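# Balanced two-way fixed-effects ANOVA with interaction, by definitional
# sums of squares, for the temporal-window x intensity robustness design.
# Restricting to balanced designs keeps Types I/II/III identical, so no
# silent modelling choice is made; unbalanced input is refused with the
# deficient cell named.

#' Two-way ANOVA for accuracy tables
#'
#' Expects a balanced design: every combination of the two factors must
#' have the same number of replicates (at least 2). Sums of squares are
#' definitional:
#' \deqn{SS_A = bn \sum_a (\bar y_{a..} - \bar y)^2,\quad
#'       SS_B = an \sum_b (\bar y_{.b.} - \bar y)^2,}
#' \deqn{SS_{AB} = n \sum_{a,b} (\bar y_{ab.} - \bar y_{a..} - \bar y_{.b.}
#'       + \bar y)^2,\quad SS_W = \sum (y - \bar y_{ab.})^2,}
#' with `F = MS / MS_W` and p-values from the F survival function. A
#' factor with zero between-group variance reports F = 0 and p = 1; a
#' positive effect with zero residual variance reports F = Inf and p = 0.
#'
#' @param table data.frame with columns `tw` (factor A), `pai` (factor B)
#'   and `accuracy` (response); any replicate column is ignored.
#' @param alpha significance level echoed in the result (default 0.05).
#' @return an [AnovaResult-class].
#' @examples
#' tab <- expand.grid(tw = c(1, 5), pai = c("SD", "LPA", "MVPA"),
#'                    replicate = 1:3)
#' tab$accuracy <- 0.95 + 0.01 * as.integer(tab$pai) + rnorm(nrow(tab), 0, 0.01)
#' twoWayAnova(tab)
#' @export
twoWayAnova <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table), all(c("tw", "pai", "accuracy") %in% names(table)))
  A <- factor(table$tw)
  B <- factor(table$pai)
  y <- as.numeric(table$accuracy)
  counts <- base::table(A, B)
  if (any(counts < 2)) {
    bad <- which(counts < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("unbalanced design: cell (tw=%s, pai=%s) has %d replicate(s); need >= 2",
                 levels(A)[bad[1]], levels(B)[bad[2]],
                 counts[bad[1], bad[2]]))
  }
  if (length(unique(as.vector(counts))) != 1L) {
    bad <- which(counts != max(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("unbalanced design: cell (tw=%s, pai=%s) has %d replicate(s) but others have %d",
                 levels(A)[bad[1]], levels(B)[bad[2]],
                 counts[bad[1], bad[2]], max(counts)))
  }
  a <- nlevels(A); b <- nlevels(B); n <- as.vector(counts)[1]
  grand <- mean(y)
  meanA <- tapply(y, A, mean)
  meanB <- tapply(y, B, mean)
  cellMean <- tapply(y, list(A, B), mean)
  ssA <- b * n * sum((meanA - grand)^2)
  ssB <- a * n * sum((meanB - grand)^2)
  ssAB <- n * sum((cellMean - outer(meanA, rep(1, b)) -
                     outer(rep(1, a), meanB) + grand)^2)
  ssW <- sum((y - cellMean[cbind(A, B)])^2)
  ssT <- sum((y - grand)^2)
  dfA <- a - 1; dfB <- b - 1; dfAB <- dfA * dfB; dfW <- a * b * (n - 1)
  msW <- ssW / dfW
  fp <- function(ss, df) {
    ms <- ss / df
    if (ms <= 0) return(c(0, 1))                 # no between-group variance
    if (msW <= 0) return(c(Inf, 0))              # perfect separation
    f <- ms / msW
    c(f, pf(f, df, dfW, lower.tail = FALSE))
  }
  rA <- fp(ssA, dfA); rB <- fp(ssB, dfB); rAB <- fp(ssAB, dfAB)
  tab <- data.frame(
    term = c("tw", "pai", "tw:pai", "within", "total"),
    ss = c(ssA, ssB, ssAB, ssW, ssT),
    df = c(dfA, dfB, dfAB, dfW, a * b * n - 1),
    ms = c(ssA / dfA, ssB / dfB, ssAB / dfAB, msW, NA),
    F = c(rA[1], rB[1], rAB[1], NA, NA),
    p = c(rA[2], rB[2], rAB[2], NA, NA))
  new("AnovaResult", table = tab, alpha = alpha)
}

#' Cell and margin summaries of an accuracy table
#'
#' Mean and sample standard deviation (n - 1 denominator) of accuracy per
#' (tw, pai) cell, per tw margin, per pai margin, and overall, formatted
#' as "mean (SD)". The SD of a single observation is NA.
#'
#' @param table data.frame with columns `tw`, `pai`, `accuracy`.
#' @return data.frame with columns tw, pai (NA for margins), n, mean, sd,
#'   formatted.
#' @export
summarizeAccuracy <- function(table) {
  stopifnot(is.data.frame(table), all(c("tw", "pai", "accuracy") %in% names(table)))
  if (nrow(table) == 0L) stop("empty accuracy table")
  msd <- function(y) {
    s <- if (length(y) >= 2L) sd(y) else NA_real_
    c(n = length(y), mean = mean(y), sd = s)
  }
  rows <- list()
  for (tw in unique(table$tw)) {
    for (pai in unique(table$pai)) {
      y <- table$accuracy[table$tw == tw & table$pai == pai]
      if (length(y)) rows[[length(rows) + 1L]] <-
          data.frame(tw = as.character(tw), pai = as.character(pai), t(msd(y)))
    }
    y <- table$accuracy[table$tw == tw]
    rows[[length(rows) + 1L]] <-
      data.frame(tw = as.character(tw), pai = NA_character_, t(msd(y)))
  }
  for (pai in unique(table$pai)) {
    y <- table$accuracy[table$pai == pai]
    rows[[length(rows) + 1L]] <-
      data.frame(tw = NA_character_, pai = as.character(pai), t(msd(y)))
  }
  rows[[length(rows) + 1L]] <-
    data.frame(tw = NA_character_, pai = NA_character_, t(msd(table$accuracy)))
  out <- do.call(rbind, rows)
  out$formatted <- ifelse(is.na(out$sd),
                          sprintf("%.4g (NA)", out$mean),
                          sprintf("%.4g (%.4g)", out$mean, out$sd))
  rownames(out) <- NULL
  out
}

#' Read an accuracy table CSV
#'
#' Expected columns: `tw,pai,replicate,accuracy`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readAccuracyTable <- function(path) {
  df <- utils::read.csv(path)
  need <- c("tw", "pai", "accuracy")
  if (!all(need %in% names(df))) {
    stop("accuracy table must have columns tw, pai, accuracy")
  }
  df
}

#' Write an ANOVA result as JSON
#' @param result an [AnovaResult-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeAnova <- function(result, path) {
  stopifnot(is(result, "AnovaResult"))
  jsonlite::write_json(list(alpha = result@alpha, table = result@table),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
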