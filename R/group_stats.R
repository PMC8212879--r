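# Group-comparison protocol and crosslink normalization.
#
# One-way ANOVA followed by post hoc two-tailed two-sample Student's
# t-tests (pooled variance), implemented from sums of squares and the
# F/t distribution functions so every intermediate quantity is exposed
# and testable.  No multiple-testing correction is applied by default;
# Holm adjustment is available behind a flag.

#' Collagen content from hydroxyproline
#'
#' Converts a hydroxyproline amount to collagen using 300 hydroxyprolines
#' per triple helix (molar) and 300 kDa per triple helix (mass):
#' `collagen_nmol = hyp_nmol/300` and `collagen_ug = collagen_nmol * 300`
#' (1 nmol x 300 kDa = 300 ug).
#'
#' @param hyp_nmol hydroxyproline amount, nmol (>= 0).
#' @return A list with `collagen_nmol` and `collagen_ug`.
#' @export
collagen_from_hyp <- function(hyp_nmol) {
  if (any(hyp_nmol < 0)) stop("hydroxyproline amount must be nonnegative")
  nmol <- hyp_nmol / 300
  list(collagen_nmol = nmol, collagen_ug = nmol * 300)
}

#' Crosslink abundance per collagen molecule
#'
#' Mature pyridinium crosslinks (PYD + DPD) per collagen triple helix,
#' mol/mol, with collagen content derived from hydroxyproline via
#' [collagen_from_hyp()].
#'
#' @param pyd_dpd_nmol total PYD + DPD crosslinks, nmol (>= 0).
#' @param hyp_nmol hydroxyproline, nmol (> 0 for a defined ratio).
#' @return An object of class `"crosslink_quant"` with fields
#'   `pyd_dpd_nmol`, `hyp_nmol`, `collagen_nmol`, `collagen_ug` and
#'   `crosslinks_per_collagen` (`NA` with a warning when `hyp_nmol = 0`).
#' @export
crosslink_quant <- function(pyd_dpd_nmol, hyp_nmol) {
  if (any(pyd_dpd_nmol < 0) || any(hyp_nmol < 0))
    stop("crosslink and hydroxyproline amounts must be nonnegative")
  col <- collagen_from_hyp(hyp_nmol)
  ratio <- ifelse(col$collagen_nmol > 0,
                  pyd_dpd_nmol / col$collagen_nmol, NA_real_)
  if (anyNA(ratio))
    warning("hyp_nmol = 0: crosslinks per collagen is undefined")
  structure(list(pyd_dpd_nmol = pyd_dpd_nmol, hyp_nmol = hyp_nmol,
                 collagen_nmol = col$collagen_nmol,
                 collagen_ug = col$collagen_ug,
                 crosslinks_per_collagen = ratio),
            class = "crosslink_quant")
}

#' @export
#' @rdname crosslink_quant
#' @param q a `"crosslink_quant"`.
crosslink_density <- function(q) {
  stopifnot(inherits(q, "crosslink_quant"))
  q$crosslinks_per_collagen
}

#' @export
print.crosslink_quant <- function(x, ...) {
  cat(sprintf(
    "Crosslinks: %.4g nmol PYD+DPD, %.4g nmol Hyp -> %.4g nmol collagen",
    sum(x$pyd_dpd_nmol), sum(x$hyp_nmol), sum(x$collagen_nmol)),
    "\n")
  cat("crosslinks per collagen (mol/mol):",
      format(x$crosslinks_per_collagen, digits = 4), "\n")
  invisible(x)
}

#' Assemble and validate a group metric table
#'
#' Long-format table of per-sample metric values used by
#' [one_way_anova()] and [posthoc_ttests()].
#'
#' @param df data.frame with columns `sample_id`, `group`, `metric`,
#'   `value`.
#' @return The validated data.frame with class `"group_table"`.
#' @export
group_table <- function(df) {
  need <- c("sample_id", "group", "metric", "value")
  if (!all(need %in% names(df)))
    stop("group table needs columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(df$value)))
    stop("group table values must be finite")
  df$group <- as.character(df$group)
  df$metric <- as.character(df$metric)
  class(df) <- c("group_table", "data.frame")
  df
}

metric_groups <- function(table, metric) {
  df <- table[table$metric == metric, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for metric '", metric, "'")
  split(df$value, df$group)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA computed from sums of squares:
#' `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom,
#' with the p-value from the F distribution.
#'
#' @param table a [group_table()].
#' @param metric metric name to analyze.
#' @return An object of class `"shg_anova"`: `F`, `df1`, `df2`, `p`,
#'   `ss_between`, `ss_within`, `groups`, `n`.
#' @export
one_way_anova <- function(table, metric) {
  g <- metric_groups(table, metric)
  if (length(g) < 2) stop("ANOVA needs at least 2 groups")
  sizes <- lengths(g)
  if (any(sizes < 2))
    stop("every group needs at least 2 samples; offending: ",
         paste(names(g)[sizes < 2], collapse = ", "))
  all_v <- unlist(g, use.names = FALSE)
  grand <- mean(all_v)
  ss_b <- sum(sizes * (vapply(g, mean, numeric(1)) - grand)^2)
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(g) - 1
  df2 <- length(all_v) - length(g)
  ms_b <- ss_b / df1
  ms_w <- ss_w / df2
  f <- if (ms_w > 0) ms_b / ms_w else if (ms_b == 0) 0 else Inf
  p <- if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE) else 0
  structure(list(F = f, df1 = df1, df2 = df2, p = p, ss_between = ss_b,
                 ss_within = ss_w, metric = metric,
                 groups = names(g), n = sizes),
            class = "shg_anova")
}

#' @export
print.shg_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on '%s': F(%d, %d) = %.4g, p = %.4g\n",
              x$metric, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Significance stars for p-values
#'
#' @param p p-values.
#' @param thresholds named decreasing thresholds; defaults
#'   `* < 0.05`, `** < 0.01`, `*** < 0.001`, `**** < 0.0001`.
#' @return Character vector of star annotations (`""` = not significant).
#' @export
significance_stars <- function(p, thresholds = c(`*` = 0.05, `**` = 0.01,
                                                 `***` = 0.001,
                                                 `****` = 1e-4)) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  vapply(p, function(pp) {
    stars <- ""
    for (i in seq_along(thresholds))
      if (!is.na(pp) && pp < thresholds[i]) stars <- names(thresholds)[i]
    stars
  }, character(1))
}

#' Post hoc pairwise Student's t-tests
#'
#' Two-sample two-tailed t-tests for every group pair: pooled-variance
#' Student's t by default (Welch available), p from the t distribution,
#' flagged significant at `alpha`, with star annotations.  With zero
#' pooled variance and equal means the statistic is defined as t = 0,
#' p = 1; zero pooled variance with unequal means is flagged as an
#' infinite-t pair (p = 0).
#'
#' @param table a [group_table()].
#' @param metric metric name.
#' @param alpha significance level (default 0.05).
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @param adjust p-value adjustment passed to [stats::p.adjust()]
#'   (default `"none"`, matching the protocol; `"holm"` available).
#' @return A data.frame of class `"posthoc_ttests"` with columns
#'   `group1`, `group2`, `t`, `df`, `p`, `significant`, `stars`.
#' @export
posthoc_ttests <- function(table, metric, alpha = 0.05, welch = FALSE,
                           adjust = "none") {
  g <- metric_groups(table, metric)
  if (length(g) < 2) stop("need at least 2 groups")
  if (any(lengths(g) < 2))
    stop("every group needs at least 2 samples per pair")
  pairs <- utils::combn(names(g), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- g[[pairs[1, i]]]; y <- g[[pairs[2, i]]]
    r <- student_t2(x, y, welch)
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               t = r$t, df = r$df, p = r$p)
  })
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = adjust)
  out$significant <- !is.na(out$p) & out$p < alpha
  out$stars <- significance_stars(out$p)
  attr(out, "metric") <- metric
  attr(out, "alpha") <- alpha
  class(out) <- c("posthoc_ttests", "data.frame")
  out
}

# Two-sample t statistic from first principles.
student_t2 <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    se <- sqrt(se2)
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  }
  if (se == 0) {
    if (mx == my) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mx - my) * Inf, df = df, p = 0))
  }
  t <- (mx - my) / se
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' @export
print.posthoc_ttests <- function(x, ...) {
  cat(sprintf("Post hoc Student's t-tests on '%s' (alpha = %g)\n",
              attr(x, "metric"), attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
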