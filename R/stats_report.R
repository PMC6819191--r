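#' Pearson correlation with a two-sided t test
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite, each with
#'   non-zero variance.
#' @return An object of class `stat_result`: list with `statistic` (R),
#'   `p_value`, `n`, and `method`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: an input has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(statistic = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), method = "Pearson correlation"),
            class = "stat_result")
}

#' One-way analysis of variance
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (or coercible), >= 2 groups with >= 2
#'   observations each.
#' @return A `stat_result` with the F `statistic`, `p_value`, `groups`
#'   (labels), and `n` per group.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  n_per <- table(groups)
  if (any(n_per < 2L)) stop("every group needs at least 2 observations")
  if (any(!is.finite(values))) stop("non-finite values in input")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  structure(list(statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
                 groups = levels(groups), n = as.integer(n_per),
                 method = "one-way ANOVA"),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Condition-endpoint table of a cohort
#'
#' Extracts, for every replicate series, the ratcheting strain and (when
#' geometry is given) the compression stiffness at the endpoint cycle,
#' together with the loading-condition metadata.
#'
#' @param cohort A list of [stress_strain_series()], e.g. from
#'   [generate_cohort()].
#' @param endpoint_cycle Cycle at which endpoints are read (default 400).
#' @param geometry Optional [specimen_geometry()] for the stiffness column.
#' @return A data.frame with one row per replicate: `stress_variation`,
#'   `stress_rate`, `segment`, `replicate`, `ratcheting_strain`,
#'   `stiffness_N_per_mm`.
#' @export
endpoint_table <- function(cohort, endpoint_cycle = 400, geometry = NULL) {
  stopifnot(is.list(cohort), length(cohort) > 0L)
  rows <- lapply(cohort, function(s) {
    prot <- attr(s, "protocol")
    cs <- cycle_summaries(s, prot, geometry)
    if (endpoint_cycle > nrow(cs))
      stop("endpoint cycle ", endpoint_cycle, " beyond the ", nrow(cs),
           " complete cycles of a series")
    row <- cs[cs$cycle == endpoint_cycle, ]
    data.frame(stress_variation = prot$stress_variation,
               stress_rate = prot$stress_rate,
               segment = attr(s, "segment") %||% NA_character_,
               replicate = attr(s, "replicate") %||% NA_integer_,
               ratcheting_strain = row$ratcheting_strain,
               stiffness_N_per_mm = row$stiffness_N_per_mm)
  })
  out <- do.call(rbind, rows)
  if (any(!is.finite(out$ratcheting_strain)))
    stop("non-finite endpoint encountered")
  out
}

#' Directional effect report on an endpoint table
#'
#' Summarises the direction of each loading-condition effect on the endpoint
#' metrics: Pearson correlation of ratcheting strain and stiffness against
#' stress variation (among rows at the modal stress rate) and against stress
#' rate (among rows at the modal stress variation), plus a segment contrast
#' (one-way ANOVA of ratcheting strain between segment labels) when two or
#' more segments are present. Correlation magnitudes are data-dependent; the
#' report is about signs and significance directions.
#'
#' @param table An [endpoint_table()].
#' @return An object of class `effect_report`: a data.frame of effects with
#'   columns `effect`, `metric`, `statistic`, `p_value`, `direction`, plus a
#'   `segment_means` attribute when segments are compared.
#' @export
effect_direction_report <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  effects <- list()

  add_cor <- function(sub, xvar, metric, label) {
    if (length(unique(sub[[xvar]])) < 2L)
      stop("factor `", xvar, "` has a single level; cannot assess its effect")
    ok <- is.finite(sub[[metric]])
    r <- pearson_test(sub[[xvar]][ok], sub[[metric]][ok])
    data.frame(effect = label, metric = metric, statistic = r$statistic,
               p_value = r$p_value,
               direction = ifelse(r$statistic > 0, "increasing", "decreasing"))
  }

  mode_of <- function(v) as.numeric(names(sort(table(v), decreasing = TRUE))[1])

  # stress-variation effect at (modal) fixed rate
  if (length(unique(table$stress_variation)) >= 2L) {
    rate0 <- mode_of(table$stress_rate)
    sub <- table[table$stress_rate == rate0, ]
    if (length(unique(sub$stress_variation)) >= 2L) {
      effects <- c(effects, list(
        add_cor(sub, "stress_variation", "ratcheting_strain",
                "stress variation")))
      if (any(is.finite(sub$stiffness_N_per_mm)))
        effects <- c(effects, list(
          add_cor(sub, "stress_variation", "stiffness_N_per_mm",
                  "stress variation")))
    }
  }
  # stress-rate effect at (modal) fixed stress variation
  if (length(unique(table$stress_rate)) >= 2L) {
    dsig0 <- mode_of(table$stress_variation)
    sub <- table[table$stress_variation == dsig0, ]
    if (length(unique(sub$stress_rate)) >= 2L) {
      effects <- c(effects, list(
        add_cor(sub, "stress_rate", "ratcheting_strain", "stress rate")))
      if (any(is.finite(sub$stiffness_N_per_mm)))
        effects <- c(effects, list(
          add_cor(sub, "stress_rate", "stiffness_N_per_mm", "stress rate")))
    }
  }
  if (length(effects) == 0L)
    stop("endpoint table spans a single level of every factor")
  out <- do.call(rbind, effects)

  seg_means <- NULL
  segs <- unique(stats::na.omit(table$segment))
  if (length(segs) >= 2L) {
    sub <- table[!is.na(table$segment), ]
    a <- anova_oneway(sub$ratcheting_strain, sub$segment)
    seg_means <- tapply(sub$ratcheting_strain, sub$segment, mean)
    out <- rbind(out, data.frame(
      effect = "segment", metric = "ratcheting_strain",
      statistic = a$statistic, p_value = a$p_value,
      direction = paste(names(seg_means)[order(seg_means)],
                        collapse = " < ")))
  }
  structure(out, segment_means = seg_means,
            class = c("effect_report", "data.frame"))
}

#' @export
print.effect_report <- function(x, ...) {
  cat("Directional effect report (endpoint metrics; magnitudes are",
      "data-dependent):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s -> %s: %s (statistic = %.3f, p = %.3g)\n",
                x$effect[i], x$metric[i], x$direction[i],
                x$statistic[i], x$p_value[i]))
  }
  invisible(x)
}
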