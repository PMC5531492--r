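## Group-level comparison of per-pair expansion indices.

#' Welch two-sample t test
#'
#' Unequal-variance two-sample t test with Welch–Satterthwaite degrees of
#' freedom and a two-sided p value, as used to compare expansion indices
#' between subject groups. Thin wrapper over [stats::t.test()] that also
#' reports group means, SDs and sizes.
#'
#' @param a,b Numeric samples, each of size >= 2; at least one must have
#'   nonzero variance.
#' @return Object of class `welch_test`: `t`, `df`, `p`, `mean`, `sd`, `n`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2) stop("first sample has fewer than 2 observations")
  if (length(b) < 2) stop("second sample has fewer than 2 observations")
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) != mean(b))
      stop("both samples are degenerate (zero variance) with distinct means")
    ## identical constant samples: no evidence of a difference
    res <- list(t = 0, df = length(a) + length(b) - 2, p = 1)
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(c(res, list(mean = c(mean(a), mean(b)),
                        sd = c(stats::sd(a), stats::sd(b)),
                        n = c(length(a), length(b)))),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t test: t = %.4g, df = %.3f, p = %.4g\n",
              x$t, x$df, x$p))
  cat(sprintf("  group means %.4g (sd %.4g, n %d) vs %.4g (sd %.4g, n %d)\n",
              x$mean[1], x$sd[1], x$n[1], x$mean[2], x$sd[2], x$n[2]))
  invisible(x)
}

#' Per-group summary table with Welch comparisons to a reference group
#'
#' One row per group with mean (SD) of each expansion index and the Welch
#' two-sided p value against the reference group; significance flagged at
#' p < 0.05. Groups with fewer than 2 records are excluded with a warning.
#'
#' @param records Data frame of per-pair records (see [pair_record()]):
#'   columns `group`, `pct_hyper_at_50`, and optionally
#'   `pct_tissue_exp_at_50`.
#' @param reference_group Label of the group all others are compared to.
#' @param per_subject If `TRUE` and a `subject` column is present, records
#'   are averaged within subject first (sensitivity analysis; by default
#'   pairs are treated as independent records).
#' @return Data frame with one row per group: n, mean/sd/p of each index,
#'   and `sig_*` flags; the reference row carries `p = NA`.
#' @export
group_table <- function(records, reference_group,
                        per_subject = FALSE) {
  stopifnot(is.data.frame(records), "group" %in% names(records),
            "pct_hyper_at_50" %in% names(records))
  if (per_subject && "subject" %in% names(records)) {
    num <- intersect(c("pct_hyper_at_50", "pct_tissue_exp_at_50"),
                     names(records))
    records <- stats::aggregate(records[num],
                                by = records[c("subject", "group")], mean)
  }
  counts <- table(records$group)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning(sprintf("excluding group(s) with a single record: %s",
                    paste(small, collapse = ", ")))
    records <- records[!records$group %in% small, , drop = FALSE]
  }
  groups <- unique(records$group)
  if (!reference_group %in% groups)
    stop(sprintf("reference group '%s' not present (or too small)",
                 reference_group))
  if (length(groups) < 2) stop("need at least two groups")
  has_tis <- "pct_tissue_exp_at_50" %in% names(records)
  ref_h <- records$pct_hyper_at_50[records$group == reference_group]
  rows <- lapply(groups, function(gr) {
    x <- records[records$group == gr, , drop = FALSE]
    row <- data.frame(group = gr, n = nrow(x),
                      mean_hyper = mean(x$pct_hyper_at_50),
                      sd_hyper = stats::sd(x$pct_hyper_at_50),
                      p_hyper = NA_real_)
    if (gr != reference_group)
      row$p_hyper <- welch_t(x$pct_hyper_at_50, ref_h)$p
    if (has_tis) {
      row$mean_tissue <- mean(x$pct_tissue_exp_at_50)
      row$sd_tissue <- stats::sd(x$pct_tissue_exp_at_50)
      row$p_tissue <- if (gr == reference_group) NA_real_ else
        welch_t(x$pct_tissue_exp_at_50,
                records$pct_tissue_exp_at_50[records$group ==
                                               reference_group])$p
    }
    row
  })
  out <- do.call(rbind, rows)
  out$sig_hyper <- !is.na(out$p_hyper) & out$p_hyper < 0.05
  if (has_tis) out$sig_tissue <- !is.na(out$p_tissue) & out$p_tissue < 0.05
  out
}

#' Pair-level hyperinflation classification
#'
#' Flags each pair as hyperinflated when its `pct_hyper_at_50` (percent of
#' lung with Delta* >= 0.5) meets the lung-volume cutoff, and tabulates
#' flags against group labels when present.
#'
#' @param records Data frame with `pct_hyper_at_50` (and optionally
#'   `group`).
#' @param cutoff Percent-of-lung cutoff (e.g. 0.1, 0.5, 1 or 2).
#' @return List with `flags` (logical per record) and `contingency`
#'   (table of flag x group, or flag counts without groups).
#' @export
classify_pairs <- function(records, cutoff = 0.1) {
  stopifnot(is.data.frame(records), "pct_hyper_at_50" %in% names(records))
  flags <- records$pct_hyper_at_50 >= cutoff
  cont <- if ("group" %in% names(records))
    table(hyperinflated = flags, group = records$group)
  else table(hyperinflated = flags)
  list(flags = flags, contingency = cont, cutoff = cutoff)
}
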