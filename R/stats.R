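#' Distributional assumption checks for group comparisons
#'
#' Kolmogorov-Smirnov test of each group against a normal with that
#' group's fitted mean and SD, and Levene's test of variance homogeneity
#' across groups.
#'
#' @param values Numeric vector of per-subject scalars.
#' @param groups Group labels, same length.
#' @return List with `normality_p` (named per group; minimum is what
#'   matters for gating), `levene_p`, and `degenerate` (TRUE when a group
#'   is constant, in which case the tests are skipped and NA returned).
#' @export
assumption_checks <- function(values, groups) {
  groups <- as.factor(groups)
  split_v <- split(values, groups)
  if (any(vapply(split_v, length, integer(1)) < 3)) {
    stop("need at least 3 subjects per group", call. = FALSE)
  }
  if (any(vapply(split_v, stats::sd, numeric(1)) == 0)) {
    return(list(normality_p = stats::setNames(
      rep(NA_real_, nlevels(groups)), levels(groups)),
      levene_p = NA_real_, degenerate = TRUE))
  }
  norm_p <- vapply(split_v, function(v) {
    suppressWarnings(stats::ks.test(v, "pnorm", mean(v),
                                    stats::sd(v))$p.value)
  }, numeric(1))
  lev <- car::leveneTest(values ~ groups)
  list(normality_p = norm_p, levene_p = lev[["Pr(>F)"]][1],
       degenerate = FALSE)
}

#' Channel-wise one-way ANOVA with Bonferroni correction
#'
#' One F test per unit (channel, channel pair or region pair) and
#' interval; corrected p-values are `min(1, family * p)` with the declared
#' family size.  With two groups and equal variances assumed, F equals the
#' square of the pooled two-sample t statistic.
#'
#' @param data Long data frame with columns `unit`, `interval`, `value`,
#'   `group` (one row per subject x unit x interval).
#' @param family Correction family size; defaults to the number of units
#'   (correction within each interval, the package's declared family).
#' @param alpha Corrected significance threshold (default 0.05).
#' @param check_assumptions Also run [assumption_checks()] per cell?
#' @return Data frame of class `stat_result`: `unit`, `interval`, `F`,
#'   `p`, `p_corr`, `significant`, group means `mean_<level>`, `n1`, `n2`,
#'   and (optionally) `normality_p` (minimum over groups), `levene_p`.
#' @export
oneway_anova_table <- function(data, family = NULL, alpha = 0.05,
                               check_assumptions = FALSE) {
  stopifnot(all(c("unit", "interval", "value", "group") %in% names(data)))
  data$group <- as.factor(data$group)
  lv <- levels(data$group)
  if (length(lv) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(family)) family <- length(unique(data$unit))
  if (family < 1) stop("family size must be >= 1", call. = FALSE)
  key <- interaction(data$unit, data$interval, drop = TRUE, sep = "\r")
  chunks <- split(seq_len(nrow(data)), key)
  cells <- do.call(rbind, strsplit(names(chunks), "\r", fixed = TRUE))
  rows <- lapply(seq_along(chunks), function(i) {
    d <- data[chunks[[i]], ]
    ns <- table(d$group)
    if (any(ns < 2)) stop("fewer than 2 subjects in a group for unit ",
                          cells[i, 1], call. = FALSE)
    ft <- stats::oneway.test(value ~ group, data = d, var.equal = TRUE)
    p <- ft$p.value
    means <- tapply(d$value, d$group, mean)
    row <- data.frame(unit = cells[i, 1], interval = cells[i, 2],
                      F = unname(ft$statistic), p = p,
                      p_corr = min(1, family * p),
                      n1 = unname(ns[1]), n2 = unname(ns[2]),
                      stringsAsFactors = FALSE)
    for (g in lv) row[[paste0("mean_", g)]] <- unname(means[g])
    if (check_assumptions) {
      ac <- assumption_checks(d$value, d$group)
      row$normality_p <- min(ac$normality_p)
      row$levene_p <- ac$levene_p
    }
    row
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_corr < alpha
  class(out) <- c("stat_result", class(out))
  out
}

#' Signed significance map from an ANOVA table
#'
#' Per unit and interval: the sign of the between-group mean difference
#' (second group level minus first) times a significance tier -- 1, 2 or 3
#' for corrected p below 0.05, 0.01 and 0.001 -- and 0 where not
#' significant.
#'
#' @param stats A `stat_result` from [oneway_anova_table()] (group means
#'   retained).
#' @return Data frame `unit`, `interval`, `direction`, `tier`, `signed_tier`.
#' @export
contrast_maps <- function(stats) {
  mean_cols <- grep("^mean_", names(stats), value = TRUE)
  if (length(mean_cols) < 2) {
    stop("stat table lacks group means", call. = FALSE)
  }
  diffs <- stats[[mean_cols[2]]] - stats[[mean_cols[1]]]
  tier <- ifelse(stats$p_corr < 0.001, 3,
                 ifelse(stats$p_corr < 0.01, 2,
                        ifelse(stats$p_corr < 0.05, 1, 0)))
  data.frame(unit = stats$unit, interval = stats$interval,
             direction = sign(diffs), tier = tier,
             signed_tier = sign(diffs) * tier,
             stringsAsFactors = FALSE)
}
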