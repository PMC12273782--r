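#' Remove outliers beyond 1.5 times the interquartile range
#'
#' Values outside the closed interval `[Q1 - k*IQR, Q3 + k*IQR]` are dropped;
#' quartiles use linear interpolation (type 7) and boundary values are
#' retained. Fewer than 4 values are returned unchanged.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return The retained values.
#' @export
remove_outliers_iqr <- function(values, k = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) return(values)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition,
#' `F = MS_between / MS_within`, with the p value from the F distribution
#' (fitted via [stats::lm()]).
#'
#' @param groups Named list of numeric vectors, one per group; at least two
#'   groups with at least two observations each.
#' @return A list of class `anova_report`: `F`, `df_between`, `df_within`,
#'   `p`, `ms_within`, `group_means`, `group_ns`.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L))
    stop("each group needs at least 2 retained observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  if (length(unique(y)) == 1L)
    stop("degenerate data: all observations identical")
  means <- vapply(groups, mean, numeric(1))
  within_ss <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  if (within_ss == 0) {
    warning("zero within-group variance with unequal means; p reported as 0")
    return(structure(list(F = Inf, df_between = length(groups) - 1L,
                          df_within = length(y) - length(groups), p = 0,
                          ms_within = 0, group_means = means, group_ns = ns),
                     class = "anova_report"))
  }
  tab <- stats::anova(stats::lm(y ~ g))
  structure(list(
    F = tab$`F value`[1],
    df_between = tab$Df[1],
    df_within = tab$Df[2],
    p = tab$`Pr(>F)`[1],
    ms_within = tab$`Mean Sq`[2],
    group_means = means,
    group_ns = ns
  ), class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Fisher's least significant difference post hoc test
#'
#' Unadjusted pairwise comparisons using the ANOVA pooled within-group
#' variance: `t = (mean_i - mean_j) / sqrt(MS_within * (1/n_i + 1/n_j))` with
#' the within-group degrees of freedom and a two-tailed p value. No
#' multiplicity adjustment (LSD is unadjusted by definition).
#'
#' @param groups The same named list of numeric vectors passed to
#'   [oneway_anova()].
#' @param anova The `anova_report` computed on those groups.
#' @return data.frame with `group1`, `group2`, `mean_diff`, `t`, `p`.
#' @export
fisher_lsd <- function(groups, anova) {
  stopifnot(inherits(anova, "anova_report"))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  nm <- names(groups)
  out <- list()
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    ni <- length(groups[[i]])
    nj <- length(groups[[j]])
    if (ni < 1L || nj < 1L) {
      warning("skipping pair ", nm[i], " vs ", nm[j], ": empty group")
      next
    }
    diff <- mean(groups[[i]]) - mean(groups[[j]])
    se <- sqrt(anova$ms_within * (1 / ni + 1 / nj))
    tval <- if (se > 0) diff / se else ifelse(diff == 0, 0, Inf * sign(diff))
    p <- if (is.finite(tval)) {
      2 * stats::pt(-abs(tval), df = anova$df_within)
    } else 0
    out[[length(out) + 1L]] <- data.frame(
      group1 = nm[i], group2 = nm[j], mean_diff = diff, t = tval, p = p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' qPCR fold change by the 2^-ddCt method
#'
#' Per animal, `dCt = Ct_target - Ct_reference`; the group-mean difference
#' `ddCt = mean(dCt treated) - mean(dCt control)` gives the fold change
#' `2^-ddCt`. The group comparison is a two-tailed unpaired (pooled-variance)
#' t test on the per-animal dCt values.
#'
#' @param treated,control data.frames with numeric columns `ct_target` and
#'   `ct_reference`, one row per animal. Ct values must be positive.
#' @return A list: `fold_change`, `ddct`, `p`, `dct_treated`, `dct_control`.
#' @export
fold_change_ddct <- function(treated, control) {
  for (d in list(treated, control)) {
    if (nrow(d) == 0L) stop("empty qPCR group")
    stopifnot(all(c("ct_target", "ct_reference") %in% names(d)))
    if (any(d$ct_target <= 0 | d$ct_reference <= 0))
      stop("Ct values must be positive")
  }
  dct_t <- treated$ct_target - treated$ct_reference
  dct_c <- control$ct_target - control$ct_reference
  ddct <- mean(dct_t) - mean(dct_c)
  p <- if (length(dct_t) >= 2 && length(dct_c) >= 2 &&
           (stats::var(dct_t) + stats::var(dct_c)) > 0) {
    stats::t.test(dct_t, dct_c, var.equal = TRUE)$p.value
  } else NA_real_
  list(fold_change = 2^(-ddct), ddct = ddct, p = p,
       dct_treated = dct_t, dct_control = dct_c)
}

#' Fold-change table for a tidy qPCR Ct data set
#'
#' @param qpcr data.frame with columns `animal`, `group`, `side`, `gene`,
#'   `ct_target`, `ct_reference`.
#' @param control_group Name of the reference (sham) group.
#' @return Tidy data.frame with one row per gene, side, and non-control
#'   group: `gene`, `side`, `group`, `fold_change`, `ddct`, `p`.
#' @export
analyze_qpcr <- function(qpcr, control_group = "sham") {
  need <- c("animal", "group", "side", "gene", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(qpcr)))
  if (!control_group %in% qpcr$group)
    stop("control group '", control_group, "' not present")
  out <- list()
  for (gene in unique(qpcr$gene)) for (side in unique(qpcr$side)) {
    ctl <- qpcr[qpcr$gene == gene & qpcr$side == side &
                  qpcr$group == control_group, ]
    if (nrow(ctl) == 0L) next
    for (grp in setdiff(unique(qpcr$group), control_group)) {
      trt <- qpcr[qpcr$gene == gene & qpcr$side == side & qpcr$group == grp, ]
      if (nrow(trt) == 0L) next
      fc <- fold_change_ddct(trt, ctl)
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, side = side, group = grp,
        fold_change = fc$fold_change, ddct = fc$ddct, p = fc$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
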