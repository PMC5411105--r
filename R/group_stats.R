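#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] with explicit guards for
#' the sample-size limits and constant input.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return Named list with \code{W} and \code{p}.
#' @export
shapiro_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("Shapiro-Wilk needs n >= 3")
  if (length(values) > 5000L) stop("Shapiro-Wilk needs n <= 5000")
  if (sd(values) == 0)
    stop("Shapiro-Wilk is undefined for a constant vector")
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

.stack_groups <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  if (any(!lengths(groups))) stop("empty group")
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups)),
                            levels = names(groups)))
}

#' One-way fixed-effects ANOVA across groups
#'
#' @param groups named list of numeric vectors (one per group), e.g.
#'   the delta15N values of the four juvenile age groups plus the adult
#'   females.
#' @return List with \code{F}, \code{df_between}, \code{df_within},
#'   \code{p}, plus the fitted \code{aov} object (element \code{fit}).
#' @export
oneway_anova <- function(groups) {
  d <- .stack_groups(groups)
  fit <- aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  list(F = tab$`F value`[1], df_between = tab$Df[1], df_within = tab$Df[2],
       p = tab$`Pr(>F)`[1], fit = fit)
}

#' Tukey-Kramer pairwise comparisons
#'
#' All pairwise mean differences with family-wise 95\% simultaneous
#' intervals from the studentized-range distribution, using the Kramer
#' adjustment for unequal group sizes (as implemented by
#' [stats::TukeyHSD()]). Pairs are labelled \code{"B-A"} with
#' \code{diff = mean(B) - mean(A)}, i.e. the difference is the mean of
#' the first-named group minus the mean of the second-named group,
#' following the order of the input list.
#'
#' @inheritParams oneway_anova
#' @param conf.level family-wise coverage of the intervals.
#' @return Data frame with columns \code{pair}, \code{group_a},
#'   \code{group_b}, \code{diff}, \code{lower}, \code{upper},
#'   \code{p_adj}.
#' @export
tukey_kramer <- function(groups, conf.level = 0.95) {
  d <- .stack_groups(groups)
  hsd <- TukeyHSD(aov(value ~ group, data = d), conf.level = conf.level)
  m <- hsd$group
  pairs <- strsplit(rownames(m), "-", fixed = TRUE)
  data.frame(pair = rownames(m),
             group_a = vapply(pairs, `[[`, character(1), 1L),
             group_b = vapply(pairs, `[[`, character(1), 2L),
             diff = unname(m[, "diff"]), lower = unname(m[, "lwr"]),
             upper = unname(m[, "upr"]), p_adj = unname(m[, "p adj"]),
             row.names = NULL)
}

#' Group-comparison statistics for a collagen table
#'
#' Builds the five comparison groups (four juvenile age groups plus the
#' adult females) for each isotope and runs the normality checks, the
#' one-way ANOVA and the Tukey-Kramer comparisons. Normality is
#' reported for three poolings -- all individuals, juveniles only, and
#' the ANOVA residuals -- because published analyses are often ambiguous
#' about which set was tested.
#'
#' @param samples collagen table (see [read_collagen()]).
#' @return List of class \code{"isotope_group_stats"} with elements
#'   \code{anova} (per isotope), \code{tukey} (per isotope),
#'   \code{shapiro} (per isotope and pooling), and the grouped values.
#' @export
isotope_group_stats <- function(samples) {
  juv <- samples[samples$cohort == "juvenile", , drop = FALSE]
  fem <- samples[samples$cohort == "adult_female", , drop = FALSE]
  grp <- assign_age_group(juv$age_low_years, juv$age_high_years)
  make_groups <- function(col) {
    g <- split(juv[[col]], grp)
    g$Female <- fem[[col]]
    g
  }
  out <- list(groups = list(), anova = list(), tukey = list(),
              shapiro = list())
  for (iso in c("N", "C")) {
    col <- if (iso == "N") "d15N" else "d13C"
    g <- make_groups(col)
    an <- oneway_anova(g)
    out$groups[[iso]] <- g
    out$anova[[iso]] <- an[c("F", "df_between", "df_within", "p")]
    out$tukey[[iso]] <- tukey_kramer(g)
    out$shapiro[[iso]] <- list(
      pooled = shapiro_normality(c(juv[[col]], fem[[col]])),
      juveniles = shapiro_normality(juv[[col]]),
      residuals = shapiro_normality(residuals(an$fit)))
  }
  structure(out, class = "isotope_group_stats")
}

#' @export
print.isotope_group_stats <- function(x, ...) {
  for (iso in c("N", "C")) {
    an <- x$anova[[iso]]
    cat(sprintf("delta%s ANOVA: F = %.2f, df = (%d, %d), p = %.4g\n",
                if (iso == "N") "15N" else "13C", an$F, an$df_between,
                an$df_within, an$p))
    tk <- x$tukey[[iso]]
    tk$p_shown <- ifelse(tk$p_adj < 5e-4, "0.000",
                         formatC(tk$p_adj, digits = 3, format = "f"))
    print(tk[, c("pair", "diff", "lower", "upper", "p_shown")], digits = 4)
  }
  invisible(x)
}
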