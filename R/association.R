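## Post-processing of association summary statistics: Wald confidence
## intervals for odds ratios from 2x2 counts, and family-wise error-rate
## adjustment of nominal p-values within phenotype families.

#' Odds ratio and Wald (log-scale) confidence interval from a 2x2 table
#'
#' For counts `a, b, c, d` (exposed-case, exposed-control, unexposed-case,
#' unexposed-control), the odds ratio is `ad / bc` and the confidence
#' interval is `exp(log(OR) -/+ z * SE)` with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param a,b,c,d non-negative counts.
#' @param alpha two-sided level (default 0.05 for a 95% interval).
#' @param continuity add 0.5 to every cell (Haldane-Anscombe) — required to
#'   handle zero cells, off by default.
#' @return list: `or`, `ci_low`, `ci_high`, `alpha`.
#' @examples
#' odds_ratio_ci(20, 80, 10, 90)  # OR 2.25, CI ~ (0.994, 5.09)
#' @export
odds_ratio_ci <- function(a, b, c, d, alpha = 0.05, continuity = FALSE) {
  counts <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts == 0) && !continuity) {
    stop(paste("zero cell in the 2x2 table; rerun with continuity = TRUE",
               "to apply the +0.5 correction to every cell"), call. = FALSE)
  }
  if (continuity) counts <- counts + 0.5
  or <- (counts["a"] * counts["d"]) / (counts["b"] * counts["c"])
  se <- sqrt(sum(1 / counts))
  z <- qnorm(1 - alpha / 2)
  list(or = unname(or),
       ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)),
       alpha = alpha)
}

#' Family-wise error-rate adjustment of p-values
#'
#' Bonferroni (`min(1, m * p)`, the default: it reproduces the adjusted
#' values of the emulated analysis exactly) or Holm's step-down procedure
#' (sorted `p_(i)` multiplied by `m - i + 1`, running maximum enforced,
#' capped at 1).  Input order is preserved.
#'
#' @param p_values numeric vector of nominal p-values in (0, 1].
#' @param method `"bonferroni"` or `"holm"`.
#' @param m family size; defaults to `length(p_values)` but may be larger
#'   when only part of a family is supplied.
#' @return adjusted p-values, same order as the input.
#' @examples
#' fwer_adjust(0.002, m = 22)  # 0.044
#' @export
fwer_adjust <- function(p_values, method = c("bonferroni", "holm"),
                        m = length(p_values)) {
  method <- match.arg(method)
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(p_values)) {
    stop("family size m cannot be smaller than the number of p-values",
         call. = FALSE)
  }
  if (method == "bonferroni") {
    return(pmin(1, m * p_values))
  }
  o <- order(p_values)
  ranked <- pmin(1, cummax((m - seq_along(o) + 1L) * p_values[o]))
  out <- numeric(length(p_values))
  out[o] <- ranked
  out
}

#' Post-process an association summary table
#'
#' For each row, computes the odds ratio and Wald confidence interval when
#' 2x2 counts (`a`, `b`, `c`, `d`) are present (a reported `or` column is
#' kept when counts are absent), and adjusts nominal p-values for the
#' family-wise error rate within families defined by `family_column`.
#'
#' @param table data.frame with columns `phenotype_id`, `p` (nominal
#'   p-value), optionally `a`,`b`,`c`,`d`, `or`, and a family column.
#' @param family_column column defining test families (default `"group"`;
#'   `NULL` treats the whole table as one family).
#' @param method FWER method, see [fwer_adjust()].
#' @param alpha confidence-interval level for [odds_ratio_ci()].
#' @param continuity passed to [odds_ratio_ci()].
#' @return the input with columns `or`, `ci_low`, `ci_high`, `p_adjusted`
#'   filled in.
#' @export
process_assoc_table <- function(table, family_column = "group",
                                method = "bonferroni", alpha = 0.05,
                                continuity = FALSE) {
  stopifnot(is.data.frame(table), "p" %in% names(table))
  out <- table
  if (!"or" %in% names(out)) out$or <- NA_real_
  out$ci_low <- NA_real_
  out$ci_high <- NA_real_
  has_counts <- all(c("a", "b", "c", "d") %in% names(out))
  if (has_counts) {
    for (i in seq_len(nrow(out))) {
      cts <- unlist(out[i, c("a", "b", "c", "d")])
      if (any(is.na(cts))) next
      ci <- odds_ratio_ci(cts[1], cts[2], cts[3], cts[4],
                          alpha = alpha, continuity = continuity)
      out$or[i] <- ci$or
      out$ci_low[i] <- ci$ci_low
      out$ci_high[i] <- ci$ci_high
    }
  }
  fam <- if (is.null(family_column)) rep("all", nrow(out)) else {
    if (!family_column %in% names(out)) {
      stop(sprintf("family column '%s' not found", family_column),
           call. = FALSE)
    }
    as.character(out[[family_column]])
  }
  out$p_adjusted <- NA_real_
  for (f in unique(fam)) {
    rows <- fam == f
    out$p_adjusted[rows] <- fwer_adjust(out$p[rows], method = method)
  }
  out
}
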