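## Nonparametric association battery for the cohort analysis.
##
## All summaries (median, quartiles) use the nearest-rank quantile
## convention (type 1), matching percentileCutoff().

.q1 <- function(x, p) unname(quantile(x, p, type = 1, na.rm = TRUE))

.summarize <- function(values, groups) {
  do.call(rbind, lapply(split(values, groups), function(v)
    data.frame(n = sum(!is.na(v)), median = .q1(v, 0.5),
               q25 = .q1(v, 0.25), q75 = .q1(v, 0.75))))
}

#' Mann-Whitney U comparison of a continuous variable between two groups
#'
#' Two-sided Mann-Whitney U test. The exact null distribution is used when
#' the smaller group has at most 12 observations and there are no ties;
#' otherwise the normal approximation with tie correction (and continuity
#' correction) is used. Group summaries are medians and quartiles in the
#' nearest-rank convention.
#'
#' @param values numeric vector.
#' @param groups two-level factor/vector aligned to `values`.
#' @return list of class `"groupComparison"`: `test`, `statistic` (U of the
#'   first group), `p_value`, `summaries` (per-group n/median/q25/q75),
#'   `exact`.
#' @export
compareGroupsContinuous <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) != 2L || any(table(groups) == 0L))
    stop("data error: need two non-empty groups")
  x <- values[groups == levels(groups)[1L]]
  y <- values[groups == levels(groups)[2L]]
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 12L && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  structure(list(test = "Mann-Whitney U",
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value, exact = exact,
                 groups = levels(groups),
                 summaries = .summarize(values, groups)),
            class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(x$test, ": statistic =", format(x$statistic),
      ", p =", format.pval(x$p_value), if (isTRUE(x$exact)) "(exact)", "\n")
  print(x$summaries)
  invisible(x)
}

#' Spearman rank correlation
#'
#' Tie-aware Spearman correlation (average ranks) with a two-sided
#' asymptotic p-value.
#'
#' @param x,y numeric vectors of equal length (pairs with `NA` dropped).
#' @return list `rho`, `p_value`, `n`.
#' @export
correlateSpearman <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("data error: need at least 3 complete pairs")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Exact test of a 2x2 contingency table
#'
#' Fisher's exact test (two-sided, point-probability method) with the
#' sample odds ratio; 0.5 is added to every cell for the odds ratio when
#' any cell is zero (the p-value is computed on the uncorrected table).
#'
#' @param table 2x2 integer matrix of counts.
#' @return list `odds_ratio`, `p_value`, `table`.
#' @examples
#' exact2x2(matrix(c(5, 5, 5, 5), 2))  # OR 1, p 1
#' @export
exact2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  ht <- fisher.test(table)
  t2 <- if (any(table == 0)) table + 0.5 else table
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = or, p_value = ht$p.value, table = table)
}

#' Wilcoxon signed-rank comparison of paired samples
#'
#' Two-sided signed-rank test on the paired differences; zero differences
#' are dropped before ranking. When no non-zero differences remain, or only
#' one pair differs, the p-value is 1 by convention and a warning is
#' issued. Exactness follows the same rule as
#' [compareGroupsContinuous()] (n <= 12, no tied absolute differences).
#'
#' @param before,after numeric vectors of equal length.
#' @return list of class `"groupComparison"`: `test`, `statistic` (V),
#'   `p_value`, `n_used`.
#' @export
pairedCompare <- function(before, after) {
  stopifnot(length(before) == length(after))
  keep <- !is.na(before) & !is.na(after)
  d <- (after - before)[keep]
  nz <- d != 0
  out <- list(test = "Wilcoxon signed rank", statistic = NA_real_,
              p_value = 1, n_used = sum(nz))
  if (!any(nz)) {
    warning("all paired differences are zero; p = 1 by convention")
  } else if (sum(nz) < 2L) {
    warning("only one non-zero paired difference; p = 1 (n too small)")
    out$statistic <- unname(suppressWarnings(wilcox.test(d[nz])$statistic))
  } else {
    dd <- d[nz]
    exact <- length(dd) <= 12L && anyDuplicated(abs(dd)) == 0L
    ht <- suppressWarnings(wilcox.test(dd, exact = exact, correct = TRUE))
    out$statistic <- unname(ht$statistic)
    out$p_value <- ht$p.value
  }
  class(out) <- "groupComparison"
  out
}

#' Friedman omnibus test with Dunn's pairwise follow-up
#'
#' Friedman rank test over k paired conditions, followed by Dunn's
#' z statistic for every condition pair with a multiplicity adjustment
#' (Bonferroni over all tested pairs by default).
#'
#' @param conditionMatrix numeric matrix, subjects in rows, conditions in
#'   columns (column names label the conditions).
#' @param pAdjust adjustment method passed to [stats::p.adjust()].
#' @return list `friedman` (`chisq`, `df`, `p_value`) and `pairwise`
#'   data.frame (`a`, `b`, `z`, `p_value`, `p_adjusted`).
#' @export
multiPairedCompare <- function(conditionMatrix, pAdjust = "bonferroni") {
  m <- as.matrix(conditionMatrix)
  stopifnot(ncol(m) >= 2L, nrow(m) >= 2L, !anyNA(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("cond", seq_len(ncol(m)))
  ht <- friedman.test(m)
  chisq <- unname(ht$statistic)
  pval <- ht$p.value
  if (is.nan(chisq)) {
    # fully tied rows: no between-condition variation at all
    chisq <- 0
    pval <- 1
  }
  ranks <- t(apply(m, 1L, rank))
  rbar <- colMeans(ranks)
  k <- ncol(m); n <- nrow(m)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2L)
  pw <- data.frame(
    a = colnames(m)[pairs[1L, ]], b = colnames(m)[pairs[2L, ]],
    z = (rbar[pairs[2L, ]] - rbar[pairs[1L, ]]) / se)
  pw$p_value <- 2 * pnorm(-abs(pw$z))
  pw$p_adjusted <- p.adjust(pw$p_value, method = pAdjust)
  rownames(pw) <- NULL
  list(friedman = list(chisq = chisq, df = unname(ht$parameter),
                       p_value = pval),
       pairwise = pw)
}

## Resolve one association variable from the epitope matrix or the records.
.resolveVariable <- function(name, em, records) {
  labels <- epitopeInfo(em)$label
  if (name == "any_epitope_positive") return(subjectTotals(em) > 0)
  if (name == "n_epitopes") return(subjectTotals(em))
  if (name == "mean_epitope_intensity") {
    v <- rowMeans(intensityMatrix(em), na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    return(v)
  }
  if (name %in% labels) return(positiveMatrix(em)[, name])
  if (name == "group") {
    g <- subjectInfo(em)$group
    return(g == sort(unique(g))[1L])  # binary indicator of the first group
  }
  if (!name %in% names(records))
    stop("specification error: unknown variable '", name, "'")
  idx <- match(subjectInfo(em)$subject_id, records$subject_id)
  records[[name]][idx]
}

.isBinary <- function(v) is.logical(v) || all(v %in% c(0, 1, NA))

#' Run a declared battery of epitope/covariate associations
#'
#' For each requested pair of variables, dispatches on type:
#' binary x binary through [exact2x2()], binary x continuous through
#' [compareGroupsContinuous()], continuous x continuous through
#' [correlateSpearman()]. Variables are resolved from the epitope matrix
#' (epitope labels, `any_epitope_positive`, `n_epitopes`,
#' `mean_epitope_intensity`, `group`) or from the subject records (matched
#' by `subject_id`). Rows with a constant variable are emitted with
#' `p_value = NA` and a warning. Significance is flagged at alpha = 0.05
#' with no multiplicity correction across the table (mirroring common
#' practice in seroprevalence studies); apply [stats::p.adjust()] to the
#' `p_value` column for a corrected view.
#'
#' @param em an [EpitopeMatrix].
#' @param records subject-record data.frame (see [deriveSerologyFlags()]).
#' @param spec data.frame with columns `lhs` and `rhs` (variable names).
#' @return data.frame: `lhs`, `rhs`, `test`, `n`, `estimate`, `p_value`,
#'   `significant`.
#' @export
buildAssociationTable <- function(em, records, spec) {
  stopifnot(is(em, "EpitopeMatrix"), all(c("lhs", "rhs") %in% names(spec)))
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    lhs <- .resolveVariable(spec$lhs[i], em, records)
    rhs <- .resolveVariable(spec$rhs[i], em, records)
    keep <- !is.na(lhs) & !is.na(rhs)
    lhs <- lhs[keep]; rhs <- rhs[keep]
    base <- data.frame(lhs = spec$lhs[i], rhs = spec$rhs[i], test = NA,
                       n = length(lhs), estimate = NA_real_,
                       p_value = NA_real_, significant = NA)
    if (length(unique(lhs)) < 2L || length(unique(rhs)) < 2L) {
      warning("degenerate association (constant variable): ",
              spec$lhs[i], " vs ", spec$rhs[i])
      base$test <- "none (degenerate)"
      return(base)
    }
    bl <- .isBinary(lhs); br <- .isBinary(rhs)
    if (bl && br) {
      res <- exact2x2(table(factor(as.logical(lhs), levels = c(FALSE, TRUE)),
                            factor(as.logical(rhs), levels = c(FALSE, TRUE))))
      base$test <- "Fisher exact"
      base$estimate <- res$odds_ratio
      base$p_value <- res$p_value
    } else if (xor(bl, br)) {
      bin <- if (bl) lhs else rhs
      cont <- if (bl) rhs else lhs
      res <- compareGroupsContinuous(cont, as.logical(bin))
      base$test <- "Mann-Whitney U"
      base$estimate <- res$statistic
      base$p_value <- res$p_value
    } else {
      res <- correlateSpearman(as.numeric(lhs), as.numeric(rhs))
      base$test <- "Spearman"
      base$estimate <- res$rho
      base$p_value <- res$p_value
    }
    base$significant <- base$p_value < 0.05
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
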