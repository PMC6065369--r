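#' 2x2 contingency table of exposure by outcome
#'
#' Per-study counts for the exposure-outcome analysis (e.g. hormone
#' replacement therapy use by lymph-node dissemination status):
#' \code{a} exposed/outcome+, \code{b} exposed/outcome-,
#' \code{c} unexposed/outcome+, \code{d} unexposed/outcome-.
#'
#' @param a,b,c,d non-negative integer counts, total > 0.
#' @param study_id optional study identifier.
#' @return An object of class \code{"contingency_2x2"}.
#' @examples
#' contingency_2x2(20, 10, 5, 40)
#' @export
contingency_2x2 <- function(a, b, c, d, study_id = NA_character_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) <= 0) stop("table total must be positive")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), study_id = study_id),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table%s:\n",
              if (!is.na(x$study_id)) paste0(" [", x$study_id, "]") else ""))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("exposed", "unexposed"),
                              c("outcome+", "outcome-")))
  print(m)
  invisible(x)
}

.as_table_list <- function(tables) {
  if (inherits(tables, "contingency_2x2")) return(list(tables))
  if (is.data.frame(tables)) {
    need <- c("exp_pos", "exp_neg", "unexp_pos", "unexp_neg")
    stopifnot(all(need %in% names(tables)))
    ids <- if ("study_id" %in% names(tables)) as.character(tables$study_id)
           else as.character(seq_len(nrow(tables)))
    return(lapply(seq_len(nrow(tables)), function(i) {
      cnt <- unlist(tables[i, need])
      if (anyNA(cnt) || any(cnt < 0))
        return(structure(list(a = NA, b = NA, c = NA, d = NA,
                              study_id = ids[i]),
                         class = "contingency_2x2_invalid"))
      contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4], study_id = ids[i])
    }))
  }
  stopifnot(is.list(tables))
  tables
}

#' Apply the study inclusion filter
#'
#' A study enters the meta-analysis only if both treatment groups (exposed
#' and unexposed) have at least \code{min_per_group} patients; the
#' boundary is inclusive. Tables with missing or negative counts are
#' excluded with reason \code{"incomplete counts"}.
#'
#' @param tables a list of [contingency_2x2()] objects, a single table, or
#'   a data frame with columns \code{study_id}, \code{exp_pos},
#'   \code{exp_neg}, \code{unexp_pos}, \code{unexp_neg} (negative values
#'   act as missing-data sentinels).
#' @param min_per_group minimum patients per treatment group (default 10).
#' @return Data frame with \code{study_id}, group sizes, \code{included}
#'   and \code{reason}.
#' @export
filter_studies <- function(tables, min_per_group = 10) {
  tl <- .as_table_list(tables)
  out <- lapply(seq_along(tl), function(i) {
    tb <- tl[[i]]
    id <- if (!is.null(tb$study_id) && !is.na(tb$study_id)) tb$study_id
          else as.character(i)
    if (inherits(tb, "contingency_2x2_invalid") || anyNA(unlist(tb[c("a", "b", "c", "d")])))
      return(data.frame(study_id = id, n_exposed = NA_integer_,
                        n_unexposed = NA_integer_, included = FALSE,
                        reason = "incomplete counts"))
    ne <- tb$a + tb$b; nu <- tb$c + tb$d
    reason <- ""
    if (ne < min_per_group) reason <- sprintf("exposed group < %d",
                                              min_per_group)
    else if (nu < min_per_group) reason <- sprintf("unexposed group < %d",
                                                   min_per_group)
    data.frame(study_id = id, n_exposed = ne, n_unexposed = nu,
               included = reason == "", reason = reason)
  })
  do.call(rbind, out)
}

#' Odds ratio of a 2x2 table
#'
#' \code{(a d) / (b c)}. When any cell is zero the Haldane-Anscombe
#' continuity correction (0.5 added to all four cells) is applied and the
#' result carries a \code{"corrected"} attribute.
#'
#' @param table a [contingency_2x2()].
#' @param correction \code{"auto"} applies the 0.5 correction when any
#'   cell is zero; \code{"none"} errors when the denominator is zero.
#' @return Odds ratio (numeric scalar; attribute \code{"corrected"}
#'   TRUE/FALSE).
#' @examples
#' odds_ratio(contingency_2x2(20, 10, 5, 40))  # 16
#' @export
odds_ratio <- function(table, correction = c("auto", "none")) {
  stopifnot(inherits(table, "contingency_2x2"))
  correction <- match.arg(correction)
  cnt <- c(table$a, table$b, table$c, table$d)
  if (any(cnt == 0)) {
    if (correction == "none") {
      if (table$b * table$c == 0)
        stop("zero denominator; enable the continuity correction")
      or <- (table$a * table$d) / (table$b * table$c)
      return(structure(or, corrected = FALSE))
    }
    cc <- cnt + 0.5
    return(structure((cc[1] * cc[4]) / (cc[2] * cc[3]), corrected = TRUE))
  }
  structure((table$a * table$d) / (table$b * table$c), corrected = FALSE)
}

# hypergeometric support and point probabilities given the margins,
# conditional on a (top-left cell)
.hyper_support <- function(table) {
  m <- table$a + table$b        # exposed row total
  n2 <- table$c + table$d       # unexposed row total
  k <- table$a + table$c        # outcome+ column total
  lo <- max(0L, k - n2)
  hi <- min(m, k)
  list(m = m, n2 = n2, k = k, support = lo:hi)
}

#' Two-sided Fisher's exact test p value
#'
#' Conditional on the table margins, sums the hypergeometric probabilities
#' of all outcomes no more probable than the observed one (the
#' point-probability method, the convention of standard statistical
#' software; probability ties are compared with a 1e-7 relative
#' tolerance).
#'
#' @param table a [contingency_2x2()].
#' @return Two-sided p value in (0, 1].
#' @examples
#' fisher_exact_p(contingency_2x2(3, 0, 0, 3))  # 0.1
#' @export
fisher_exact_p <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  hs <- .hyper_support(table)
  probs <- stats::dhyper(hs$support, hs$m, hs$n2, hs$k)
  pobs <- stats::dhyper(table$a, hs$m, hs$n2, hs$k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# P(X >= a) and P(X <= a) under the noncentral hypergeometric with odds
# ratio psi, computed from normalized log weights
.nchyper_tails <- function(a, hs, psi) {
  s <- hs$support
  lw <- lchoose(hs$m, s) + lchoose(hs$n2, hs$k - s) + s * log(psi)
  lw <- lw - max(lw)
  w <- exp(lw)
  tot <- sum(w)
  c(upper = sum(w[s >= a]) / tot, lower = sum(w[s <= a]) / tot)
}

#' Conditional exact confidence interval for the odds ratio
#'
#' Cornfield-type exact interval: each bound inverts a one-sided
#' noncentral hypergeometric tail test at \code{(1 - level) / 2},
#' conditional on the table margins. The lower bound is 0 when the
#' observed cell is at the minimum of its support, and the upper bound is
#' infinite at the maximum. A mid-p variant (half weight on the observed
#' outcome) gives somewhat shorter intervals.
#'
#' @param table a [contingency_2x2()].
#' @param level confidence level (default 0.95).
#' @param midp use the mid-p tail definition (default FALSE).
#' @return Numeric vector \code{c(low, high)}.
#' @export
exact_ci <- function(table, level = 0.95, midp = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"), level > 0, level < 1)
  hs <- .hyper_support(table)
  if (hs$m == 0 || hs$n2 == 0 || hs$k == 0 || hs$k == hs$m + hs$n2)
    stop("degenerate margins: a row or column total is zero")
  alpha <- (1 - level) / 2
  a <- table$a
  tail_up <- function(lpsi) {
    t <- .nchyper_tails(a, hs, exp(lpsi))
    p <- t["upper"]
    if (midp) p <- p - 0.5 * (t["upper"] + t["lower"] - 1)
    unname(p) - alpha
  }
  tail_lo <- function(lpsi) {
    t <- .nchyper_tails(a, hs, exp(lpsi))
    p <- t["lower"]
    if (midp) p <- p - 0.5 * (t["upper"] + t["lower"] - 1)
    unname(p) - alpha
  }
  lim <- 50   # log-odds-ratio search range
  low <- if (a == min(hs$support)) 0
         else exp(stats::uniroot(tail_up, c(-lim, lim), tol = 1e-10)$root)
  high <- if (a == max(hs$support)) Inf
          else exp(stats::uniroot(tail_lo, c(-lim, lim), tol = 1e-10)$root)
  c(low = low, high = high)
}

#' Per-study exact odds-ratio forest table
#'
#' Applies the inclusion filter, then computes for every included study
#' the odds ratio, the conditional exact confidence interval and the
#' two-sided Fisher exact p value. Excluded studies are listed separately
#' with their reasons. A Mantel-Haenszel pooled odds ratio across the
#' included studies is computed on request (per-study reporting is the
#' primary output; pooling is an extension).
#'
#' @param tables tables in any form accepted by [filter_studies()].
#' @param level confidence level for the intervals.
#' @param min_per_group inclusion filter bound.
#' @param pool compute the Mantel-Haenszel pooled odds ratio (default
#'   FALSE).
#' @return List with \code{results} (data frame: study_id, or, ci_low,
#'   ci_high, p, n_exposed, n_unexposed, or_corrected), \code{exclusions}
#'   (study_id, reason) and \code{pooled_or} (or NULL).
#' @export
forest_table <- function(tables, level = 0.95, min_per_group = 10,
                         pool = FALSE) {
  tl <- .as_table_list(tables)
  flt <- filter_studies(tl, min_per_group = min_per_group)
  rows <- list(); mh_num <- 0; mh_den <- 0
  for (i in seq_along(tl)) {
    if (!flt$included[i]) next
    tb <- tl[[i]]
    or <- odds_ratio(tb)
    ci <- tryCatch(exact_ci(tb, level = level),
                   error = function(e) c(low = NA_real_, high = NA_real_))
    n <- tb$a + tb$b + tb$c + tb$d
    mh_num <- mh_num + tb$a * tb$d / n
    mh_den <- mh_den + tb$b * tb$c / n
    rows[[length(rows) + 1L]] <- data.frame(
      study_id = flt$study_id[i], or = as.numeric(or),
      ci_low = ci[["low"]], ci_high = ci[["high"]],
      p = fisher_exact_p(tb),
      n_exposed = flt$n_exposed[i], n_unexposed = flt$n_unexposed[i],
      or_corrected = isTRUE(attr(or, "corrected")))
  }
  results <- if (length(rows)) do.call(rbind, rows)
             else data.frame(study_id = character(0), or = numeric(0),
                             ci_low = numeric(0), ci_high = numeric(0),
                             p = numeric(0), n_exposed = integer(0),
                             n_unexposed = integer(0),
                             or_corrected = logical(0))
  excl <- flt[!flt$included, c("study_id", "reason")]
  rownames(excl) <- NULL
  pooled <- if (pool && mh_den > 0) mh_num / mh_den else NULL
  list(results = results, exclusions = excl, pooled_or = pooled)
}
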