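#' weanmix: weaning reconstruction from bone-collagen stable isotopes
#'
#' Tools for reconstructing breastfeeding and weaning practices from
#' delta15N and delta13C measurements of bone collagen in juvenile and
#' adult-female skeletal series: collagen quality screening and age
#' grouping, inference of the breast-milk isotope source from maternal
#' collagen via keratin-based offset chains, a concentration-dependent
#' Bayesian mixing model of dietary source proportions per age group,
#' an approximate Bayesian computation (ABC) model of weaning start and
#' end ages under age-dependent collagen turnover, group-comparison
#' statistics, and synthetic-cohort generators.
#'
#' @importFrom stats aov TukeyHSD shapiro.test density quantile rnorm runif
#'   dnorm sd setNames var approx residuals bw.nrd0 rbeta
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom MASS kde2d bandwidth.nrd
#' @name weanmix-package
#' @aliases weanmix
"_PACKAGE"

# columns every collagen table must carry
.collagen_columns <- c("sample_id", "cemetery", "cohort", "age_estimate",
                       "age_low_years", "age_high_years", "d13C", "d15N",
                       "pctC", "pctN", "cn_ratio", "collagen_yield")

.numeric_collagen_columns <- c("age_low_years", "age_high_years", "d13C",
                               "d15N", "pctC", "pctN", "cn_ratio",
                               "collagen_yield")

#' Parse a printed age-estimate string into an interval in years
#'
#' Age estimates in osteological tables are printed as ranges in months or
#' years (\code{"1.5-3 months"}, \code{"3-3.5 years"}), single values
#' (\code{"1 year"}), open ranges from birth (\code{"Birth-1.5 months"}),
#' or the label \code{"Perinatal"}. All are converted to decimal years;
#' \code{"Birth"} and \code{"Perinatal"} map to age 0, a single value maps
#' to a degenerate interval. Adult life-stage labels ("Young Adult",
#' "Full Adult", "Mature Adult", or anything containing "Adult") are not
#' ages and are rejected with a condition of class
#' \code{"weanmix_adult_age"} so callers can distinguish non-juvenile
#' input from a malformed string (class \code{"weanmix_parse_error"}).
#'
#' @param text character vector of printed age estimates.
#' @return A data frame with one row per element and numeric columns
#'   \code{low} and \code{high} (years, \code{0 <= low <= high}).
#' @examples
#' parse_age_estimate(c("3–3.5 years", "1.5–3 months", "Perinatal"))
#' @export
parse_age_estimate <- function(text) {
  out <- lapply(as.character(text), .parse_age_one)
  data.frame(low = vapply(out, `[[`, numeric(1), 1L),
             high = vapply(out, `[[`, numeric(1), 2L))
}

.parse_age_one <- function(s) {
  if (is.na(s) || !nzchar(trimws(s)))
    stop(.cond("weanmix_parse_error", "empty age estimate"))
  raw <- trimws(s)
  if (grepl("adult", raw, ignore.case = TRUE))
    stop(.cond("weanmix_adult_age",
               sprintf("'%s' is an adult life stage, not a juvenile age", raw)))
  if (grepl("^perinatal$", raw, ignore.case = TRUE)) return(c(0, 0))
  # normalise dashes (hyphen, en dash) to a single separator
  norm <- gsub("–|—", "-", raw)
  parts <- strsplit(norm, "-", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (length(parts) > 2L || any(!nzchar(parts)))
    stop(.cond("weanmix_parse_error", sprintf("cannot parse age '%s'", raw)))
  units <- vapply(parts, .age_unit, character(1))
  # a side without its own unit inherits the other side's ("1.5-3 months")
  if (length(parts) == 2L) {
    if (units[1] == "" && units[2] != "") units[1] <- units[2]
    if (units[2] == "" && units[1] != "") units[2] <- units[1]
  }
  vals <- mapply(.age_value_years, parts, units)
  if (anyNA(vals))
    stop(.cond("weanmix_parse_error", sprintf("cannot parse age '%s'", raw)))
  if (length(vals) == 1L) vals <- c(vals, vals)
  if (vals[1] > vals[2])
    stop(.cond("weanmix_parse_error",
               sprintf("age interval reversed in '%s'", raw)))
  unname(vals)
}

.age_unit <- function(part) {
  if (grepl("month", part, ignore.case = TRUE)) return("month")
  if (grepl("year", part, ignore.case = TRUE)) return("year")
  ""
}

.age_value_years <- function(part, unit) {
  if (grepl("^birth$", trimws(part), ignore.case = TRUE)) return(0)
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", part)))
  if (is.na(num)) return(NA_real_)
  if (unit == "month") num / 12 else num  # bare numbers default to years
}

#' Midpoint of an age interval
#'
#' @param low,high numeric vectors of interval bounds in years, or a data
#'   frame with columns \code{low} and \code{high} passed as the first
#'   argument (as returned by [parse_age_estimate()]).
#' @return Numeric vector of midpoints in years.
#' @export
age_midpoint <- function(low, high = NULL) {
  if (is.data.frame(low)) {
    high <- low$high
    low <- low$low
  }
  stopifnot(length(low) == length(high), all(low <= high, na.rm = TRUE))
  (low + high) / 2
}

#' Collagen quality screening
#'
#' Collagen is accepted when elemental concentrations meet the minimum
#' nitrogen and carbon thresholds (4.8\% N, 13\% C) and the atomic C/N
#' ratio lies in the 2.9--3.6 preservation window; all bounds inclusive.
#' Published skeletal series occasionally retain individuals just outside
#' the screen, so \code{qc_screen()} accepts an \code{override} vector of
#' sample ids that are flagged but kept.
#'
#' @param samples data frame of collagen measurements (see
#'   [read_collagen()]).
#' @param min_pctN,min_pctC minimum elemental concentrations (percent).
#' @param cn_range inclusive lower/upper bounds on the atomic C/N ratio.
#' @param override character vector of sample ids retained despite
#'   failing the screen.
#' @return \code{qc_pass()}: a logical scalar with attribute
#'   \code{"violations"} listing the violated rules. \code{qc_screen()}:
#'   the input with logical columns \code{qc_pass} and \code{qc_keep}
#'   and a character column \code{qc_violations}.
#' @export
qc_screen <- function(samples, min_pctN = 4.8, min_pctC = 13,
                      cn_range = c(2.9, 3.6), override = character()) {
  .check_collagen_fields(samples)
  viol <- lapply(seq_len(nrow(samples)), function(i)
    .qc_violations(samples$pctN[i], samples$pctC[i], samples$cn_ratio[i],
                   min_pctN, min_pctC, cn_range))
  samples$qc_pass <- lengths(viol) == 0L
  samples$qc_violations <- vapply(viol, paste, character(1), collapse = "; ")
  samples$qc_keep <- samples$qc_pass | samples$sample_id %in% override
  samples
}

#' @rdname qc_screen
#' @param sample a single-row data frame (or list) with fields
#'   \code{pctN}, \code{pctC}, \code{cn_ratio}.
#' @export
qc_pass <- function(sample, min_pctN = 4.8, min_pctC = 13,
                    cn_range = c(2.9, 3.6)) {
  need <- c("pctN", "pctC", "cn_ratio")
  vals <- lapply(need, function(f) sample[[f]])
  if (any(vapply(vals, function(v) is.null(v) || length(v) != 1L || is.na(v),
                 logical(1))))
    stop("qc_pass() needs scalar, non-missing pctN, pctC and cn_ratio")
  v <- .qc_violations(sample$pctN, sample$pctC, sample$cn_ratio,
                      min_pctN, min_pctC, cn_range)
  structure(length(v) == 0L, violations = v)
}

.qc_violations <- function(pctN, pctC, cn, min_pctN, min_pctC, cn_range) {
  v <- character()
  if (is.na(pctN) || is.na(pctC) || is.na(cn))
    stop("missing measurement fields in QC input")
  if (pctN < min_pctN)
    v <- c(v, sprintf("pctN %.2f below minimum %.1f", pctN, min_pctN))
  if (pctC < min_pctC)
    v <- c(v, sprintf("pctC %.2f below minimum %.1f", pctC, min_pctC))
  if (cn < cn_range[1] || cn > cn_range[2])
    v <- c(v, sprintf("C/N %.2f outside [%.1f, %.1f]", cn,
                      cn_range[1], cn_range[2]))
  v
}

#' Assign juveniles to age groups
#'
#' Juveniles are grouped by the midpoint of their age interval into the
#' four study bins 0--0.5, 0.5--1, 1--2 and 2--6 years. Bins are read as
#' left-open, right-closed intervals (with birth in the first group), so
#' an individual aged exactly 1 year belongs to the 0.5--1 year group:
#' this is the convention under which the published group memberships
#' reproduce, since printed bin labels share their boundary ages.
#'
#' @param low,high age interval in years (vectors, or a data frame with
#'   \code{low}/\code{high} as first argument). Alternatively pass
#'   midpoints directly via \code{midpoint}.
#' @param midpoint optional numeric vector of age midpoints, overriding
#'   \code{low}/\code{high}.
#' @return Factor with levels \code{G1, G2, G3, G4}.
#' @export
assign_age_group <- function(low, high = NULL, midpoint = NULL) {
  if (is.null(midpoint)) midpoint <- age_midpoint(low, high)
  if (any(is.na(midpoint))) stop("missing age midpoints")
  if (any(midpoint < 0)) stop("negative age midpoints")
  if (any(midpoint > 6))
    stop("age midpoint above 6 years: outside the study's grouping")
  cut(midpoint, breaks = c(-Inf, 0.5, 1, 2, 6),
      labels = c("G1", "G2", "G3", "G4"), right = TRUE)
}

#' Read a collagen-measurement table
#'
#' Reads a delimiter-separated table with the standard columns
#' \code{sample_id, cemetery, cohort, age_estimate, age_low_years,
#' age_high_years, d13C, d15N, pctC, pctN, cn_ratio, collagen_yield}.
#' Rows that violate the type invariants (non-numeric isotope fields,
#' reversed age intervals, concentrations outside 0--100, non-positive
#' C/N) are dropped with a warning that reports their row numbers; the
#' dropped row indices are attached as attribute \code{"bad_rows"}.
#' Juvenile rows with missing age bounds are filled by parsing
#' \code{age_estimate}.
#'
#' @param path file path.
#' @param delim field delimiter (default tab).
#' @return Data frame of validated samples.
#' @examples
#' tab1 <- read_collagen(weanmix_example("canimar_collagen.tsv"))
#' nrow(tab1)  # 49
#' @export
read_collagen <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("collagen table not found: ", path)
  d <- read.delim(path, sep = delim, check.names = FALSE,
                  stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(d) == 0L) {
    warning("empty collagen table: ", path)
    d <- as.data.frame(setNames(rep(list(character()),
                                    length(.collagen_columns)),
                                .collagen_columns))
  }
  missing_cols <- setdiff(.collagen_columns, names(d))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  d <- d[, .collagen_columns]
  for (cl in .numeric_collagen_columns)
    d[[cl]] <- suppressWarnings(as.numeric(d[[cl]]))
  # fill age bounds from the printed estimate where absent (juveniles only)
  need_age <- d$cohort == "juvenile" &
    (is.na(d$age_low_years) | is.na(d$age_high_years))
  if (any(need_age)) {
    iv <- parse_age_estimate(d$age_estimate[need_age])
    d$age_low_years[need_age] <- iv$low
    d$age_high_years[need_age] <- iv$high
  }
  bad <- .invalid_collagen_rows(d)
  if (any(bad)) {
    warning(sprintf("dropped %d invalid row(s): %s", sum(bad),
                    paste(which(bad), collapse = ", ")))
    d <- d[!bad, , drop = FALSE]
  }
  rownames(d) <- NULL
  attr(d, "bad_rows") <- which(bad)
  d
}

.invalid_collagen_rows <- function(d) {
  juv <- d$cohort == "juvenile"
  bad_meas <- is.na(d$d13C) | is.na(d$d15N) | is.na(d$pctC) | is.na(d$pctN) |
    is.na(d$cn_ratio)
  bad_pct <- (!is.na(d$pctC) & (d$pctC < 0 | d$pctC > 100)) |
    (!is.na(d$pctN) & (d$pctN < 0 | d$pctN > 100)) |
    (!is.na(d$collagen_yield) & (d$collagen_yield < 0 | d$collagen_yield > 100))
  bad_cn <- !is.na(d$cn_ratio) & d$cn_ratio <= 0
  bad_age <- juv & (is.na(d$age_low_years) | is.na(d$age_high_years) |
                      d$age_low_years < 0 |
                      d$age_low_years > d$age_high_years)
  bad_cohort <- !d$cohort %in% c("juvenile", "adult_female")
  bad_meas | bad_pct | bad_cn | bad_age | bad_cohort
}

.check_collagen_fields <- function(samples) {
  missing_cols <- setdiff(c("sample_id", "pctN", "pctC", "cn_ratio"),
                          names(samples))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  invisible(samples)
}

#' Summaries of isotope values per group
#'
#' \code{summarize_group()} computes n, mean, sample SD (n-1
#' denominator), min and max of the delta15N and delta13C values of one
#' set of individuals. \code{group_summary()} applies it to each juvenile
#' age group plus the adult females of a full collagen table. SD is
#' \code{NA} (flagged) for single-sample groups. Values are returned at
#' full precision; use [round_half_up()] with 2 digits to mirror printed
#' tables.
#'
#' @param samples data frame with \code{d15N} and \code{d13C} columns.
#' @param group_label label stored in the result.
#' @return One-row (or per-group) data frame with columns
#'   \code{group, n, mean_d15N, sd_d15N, min_d15N, max_d15N, mean_d13C,
#'   sd_d13C, min_d13C, max_d13C}.
#' @export
summarize_group <- function(samples, group_label = "group") {
  if (!nrow(samples)) stop("cannot summarize an empty group")
  one <- function(x) {
    c(mean = mean(x), sd = if (length(x) >= 2L) sd(x) else NA_real_,
      min = min(x), max = max(x))
  }
  sN <- one(samples$d15N)
  sC <- one(samples$d13C)
  data.frame(group = group_label, n = nrow(samples),
             mean_d15N = sN["mean"], sd_d15N = sN["sd"],
             min_d15N = sN["min"], max_d15N = sN["max"],
             mean_d13C = sC["mean"], sd_d13C = sC["sd"],
             min_d13C = sC["min"], max_d13C = sC["max"],
             row.names = NULL)
}

#' @rdname summarize_group
#' @export
group_summary <- function(samples) {
  juv <- samples[samples$cohort == "juvenile", , drop = FALSE]
  fem <- samples[samples$cohort == "adult_female", , drop = FALSE]
  grp <- assign_age_group(juv$age_low_years, juv$age_high_years)
  present <- levels(grp)[table(grp) > 0L]
  parts <- lapply(present, function(g)
    summarize_group(juv[grp == g, , drop = FALSE], g))
  if (nrow(fem)) parts <- c(parts, list(summarize_group(fem, "females")))
  do.call(rbind, parts)
}

#' Round half away from zero
#'
#' Printed tables in this field round halves away from zero (2.5 -> 3,
#' -2.5 -> -3), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Path to a bundled example data file
#'
#' @param file file name under the package's \code{extdata} directory;
#'   with no argument, lists the available files.
#' @export
weanmix_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "weanmix")))
  system.file("extdata", file, package = "weanmix", mustWork = TRUE)
}

.cond <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
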