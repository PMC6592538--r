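## Cohort-level descriptive and univariate statistics: the machinery used to
## summarize a per-patient table and relate perfusion parameters to clinical
## covariates. Continuous outcomes are compared with Student's t test (two
## groups) or one-way ANOVA (more); categorical pairs with the chi-square
## test when its validity conditions hold (all expected counts >= 5) and
## Fisher's exact test otherwise. Alpha = 0.05; comparisons are exploratory
## and no multiple-testing correction is applied.

.cohortRequired <- c("age_years", "overweight", "hypertension",
                     "dyslipidemia", "diabetes", "former_smoker",
                     "hormone_therapy", "radiotherapy", "chemotherapy",
                     "ingress_whole_apu", "ingress_rate_whole_apu_s",
                     "ingress_zone1_apu", "ingress_rate_zone1_apu_s")

.hormoneLevels <- c("none", "tamoxifen", "aromatase_inhibitor")

#' Required columns of a cohort table
#'
#' @return Character vector of the mandatory column names of a cohort table
#'   (clinical covariates plus the whole-flap and zone-I perfusion columns).
#' @export
requiredCohortColumns <- function() .cohortRequired

.validateCohort <- function(tab) {
    missing <- setdiff(.cohortRequired, names(tab))
    if (length(missing))
        stop("cohort table is missing mandatory column(s): ",
             paste(missing, collapse = ", "))
    if (any(tab$age_years <= 0, na.rm = TRUE))
        stop("'age_years' must be positive")
    if ("bmi" %in% names(tab) && any(tab$bmi <= 0, na.rm = TRUE))
        stop("'bmi' must be positive")
    bad <- setdiff(unique(stats::na.omit(tab$hormone_therapy)),
                   .hormoneLevels)
    if (length(bad))
        stop("unknown hormone_therapy level(s): ", paste(bad, collapse = ", "))
    for (cl in c("overweight", "hypertension", "dyslipidemia", "diabetes",
                 "former_smoker", "radiotherapy", "chemotherapy"))
        if (!is.logical(tab[[cl]]))
            stop("column '", cl, "' must be logical (TRUE/FALSE)")
    invisible(tab)
}

#' Read a per-patient cohort table from CSV
#'
#' The CSV is mapped onto the canonical column dictionary (see
#' [requiredCohortColumns()]) through the optional \code{dictionary}
#' argument, validated and typed. Columns that are in the file but not in the
#' dictionary are preserved untouched. Binary flags may be encoded as
#' logical, 0/1 or yes/no strings.
#'
#' @param path CSV file path.
#' @param dictionary optional named character vector mapping canonical names
#'   (names) to file column names (values), absorbing whatever naming the
#'   deposited file uses.
#' @return A validated data frame; derived flags \code{tamoxifen} and
#'   \code{age_over_60} are added when absent.
#' @export
readCohort <- function(path, dictionary = NULL) {
    if (!file.exists(path))
        stop("cohort file not found: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!is.null(dictionary)) {
        for (canonical in names(dictionary)) {
            src <- dictionary[[canonical]]
            if (!src %in% names(tab))
                stop("dictionary maps '", canonical,
                     "' to absent column '", src, "'")
            names(tab)[names(tab) == src] <- canonical
        }
    }
    toLogical <- function(x) {
        if (is.logical(x)) return(x)
        if (is.numeric(x)) return(x != 0)
        xl <- tolower(trimws(as.character(x)))
        out <- rep(NA, length(x))
        out[xl %in% c("true", "yes", "1", "y")] <- TRUE
        out[xl %in% c("false", "no", "0", "n")] <- FALSE
        if (any(is.na(out) & !is.na(x)))
            stop("cannot interpret values as logical: ",
                 paste(utils::head(unique(x[is.na(out)])), collapse = ", "))
        out
    }
    for (cl in c("overweight", "hypertension", "dyslipidemia", "diabetes",
                 "former_smoker", "radiotherapy", "chemotherapy"))
        if (cl %in% names(tab))
            tab[[cl]] <- toLogical(tab[[cl]])
    .validateCohort(tab)
    if (!"tamoxifen" %in% names(tab))
        tab$tamoxifen <- tab$hormone_therapy == "tamoxifen"
    if (!"age_over_60" %in% names(tab))
        tab$age_over_60 <- tab$age_years > 60
    tab
}

#' Write a cohort table to CSV
#'
#' @param table a cohort data frame.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeCohort <- function(table, path) {
    utils::write.csv(table, path, row.names = FALSE)
    invisible(path)
}

#' Summarize one cohort variable
#'
#' Continuous variables are summarized by median, interquartile range,
#' min-max, mean and sd; categorical (including logical) variables by counts
#' and percentages of non-missing values.
#'
#' @param table a cohort data frame.
#' @param variable column name.
#' @param kind \code{"auto"} (default), \code{"continuous"} or
#'   \code{"categorical"}.
#' @return For continuous variables a one-row data frame with columns
#'   \code{n}, \code{mean}, \code{sd}, \code{median}, \code{q1}, \code{q3},
#'   \code{min}, \code{max}; for categorical variables a data frame with one
#'   row per level and columns \code{level}, \code{n}, \code{pct}.
#' @export
summarizeCohort <- function(table, variable,
                            kind = c("auto", "continuous", "categorical")) {
    kind <- match.arg(kind)
    if (!variable %in% names(table))
        stop("no such column: ", variable)
    x <- table[[variable]]
    if (all(is.na(x)))
        stop("column '", variable, "' is all missing")
    if (kind == "auto")
        kind <- if (is.numeric(x) && length(unique(stats::na.omit(x))) > 5L)
            "continuous" else "categorical"
    x <- x[!is.na(x)]
    if (kind == "continuous") {
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(variable = variable, n = length(x), mean = mean(x),
                   sd = stats::sd(x), median = q[2L], q1 = q[1L], q3 = q[3L],
                   min = min(x), max = max(x), stringsAsFactors = FALSE)
    } else {
        counts <- table(factor(x))
        data.frame(variable = variable, level = names(counts),
                   n = as.integer(counts),
                   pct = 100 * as.integer(counts) / length(x),
                   stringsAsFactors = FALSE, row.names = NULL)
    }
}

.newComparison <- function(grouping, outcome, groups, test, statistic, df,
                           p.value) {
    structure(list(grouping = grouping, outcome = outcome, groups = groups,
                   test = test, statistic = statistic, df = df,
                   p.value = p.value, significant = p.value < 0.05),
              class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
    cat(sprintf("ComparisonResult: %s by %s\n", x$outcome, x$grouping))
    print(x$groups, row.names = FALSE)
    cat(sprintf("  %s: statistic = %.4g, p = %.4g%s\n", x$test, x$statistic,
                x$p.value, if (x$significant) " *" else ""))
    invisible(x)
}

#' Compare a continuous outcome between groups
#'
#' Two groups are compared with the two-sided Student t test
#' (pooled variance; Welch available via \code{method}), more than two with
#' one-way ANOVA. Complete cases per comparison; every group must contain at
#' least 2 observations.
#'
#' @param table a cohort data frame.
#' @param outcome name of the continuous outcome column.
#' @param group name of the grouping (categorical / logical) column.
#' @param method \code{"auto"} (Student for 2 groups, ANOVA otherwise),
#'   \code{"student"} or \code{"welch"}.
#' @return A \code{ComparisonResult}: per-group n / mean / sd, the test used,
#'   its statistic, degrees of freedom and two-sided p value, and the
#'   significance flag at alpha = 0.05.
#' @export
compareMeans <- function(table, outcome, group,
                         method = c("auto", "student", "welch")) {
    method <- match.arg(method)
    for (cl in c(outcome, group))
        if (!cl %in% names(table))
            stop("no such column: ", cl)
    keep <- !is.na(table[[outcome]]) & !is.na(table[[group]])
    y <- table[[outcome]][keep]
    g <- factor(table[[group]][keep])
    g <- droplevels(g)
    if (nlevels(g) < 2L)
        stop("grouping variable has fewer than 2 non-empty groups")
    sizes <- table(g)
    if (any(sizes < 2L))
        stop("degenerate group(s) with fewer than 2 observations: ",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
    groups <- data.frame(level = levels(g), n = as.integer(sizes),
                         mean = as.numeric(tapply(y, g, mean)),
                         sd = as.numeric(tapply(y, g, stats::sd)),
                         stringsAsFactors = FALSE)
    if (nlevels(g) == 2L) {
        tt <- stats::t.test(y ~ g, var.equal = method != "welch")
        .newComparison(group, outcome, groups,
                       if (method == "welch") "Welch t" else "Student t",
                       unname(tt$statistic), unname(tt$parameter),
                       tt$p.value)
    } else {
        fit <- stats::aov(y ~ g)
        an <- stats::anova(fit)
        .newComparison(group, outcome, groups, "ANOVA",
                       an[["F value"]][1L],
                       an[["Df"]][1L], an[["Pr(>F)"]][1L])
    }
}

#' Compare two categorical variables
#'
#' Builds the contingency table on complete cases and applies the chi-square
#' test (without continuity correction) when all expected counts are >= 5 —
#' the conventional validity condition — and Fisher's exact test otherwise.
#'
#' @param table a cohort data frame.
#' @param a,b names of two categorical (or logical) columns.
#' @return A \code{ComparisonResult}; \code{$test} records which test was
#'   used and \code{$groups} holds the contingency table as a data frame.
#' @export
compareCategorical <- function(table, a, b) {
    for (cl in c(a, b))
        if (!cl %in% names(table))
            stop("no such column: ", cl)
    keep <- !is.na(table[[a]]) & !is.na(table[[b]])
    fa <- droplevels(factor(table[[a]][keep]))
    fb <- droplevels(factor(table[[b]][keep]))
    if (nlevels(fa) < 2L || nlevels(fb) < 2L)
        stop("both variables need at least 2 observed levels")
    ct <- table(fa, fb)
    expected <- outer(rowSums(ct), colSums(ct)) / sum(ct)
    if (all(expected >= 5)) {
        ht <- stats::chisq.test(ct, correct = FALSE)
        test <- "chi-square"
        statistic <- unname(ht$statistic)
        df <- unname(ht$parameter)
    } else {
        ht <- stats::fisher.test(ct)
        test <- "Fisher exact"
        statistic <- NA_real_
        df <- NA_real_
    }
    .newComparison(a, b, as.data.frame.matrix(ct), test, statistic, df,
                   ht$p.value)
}

#' Univariate analysis of perfusion parameters against clinical covariates
#'
#' Runs [compareMeans()] for every outcome x covariate pair and assembles the
#' per-group means and p values in one long-format report, one row per
#' covariate level. No multiple-testing correction is applied (exploratory
#' analysis); interpret p values accordingly.
#'
#' @param table a cohort data frame.
#' @param outcomes character vector of perfusion column names; defaults to
#'   the four canonical perfusion columns.
#' @param covariates character vector of grouping columns; defaults to the
#'   standard clinical dichotomies.
#' @return A data frame with columns \code{covariate}, \code{level},
#'   \code{n}, then \code{mean_<outcome>} and \code{p_<outcome>} for each
#'   outcome (p repeated across the covariate's rows), with attribute
#'   \code{note} recording that no correction was applied. Covariates whose
#'   groups are degenerate in the table are dropped with a message.
#' @export
univariateTable <- function(table,
        outcomes = c("ingress_whole_apu", "ingress_rate_whole_apu_s",
                     "ingress_zone1_apu", "ingress_rate_zone1_apu_s"),
        covariates = c("age_over_60", "overweight", "former_smoker",
                       "hypertension", "dyslipidemia", "diabetes",
                       "tamoxifen", "radiotherapy", "chemotherapy")) {
    rows <- list()
    for (cov in covariates) {
        res <- tryCatch(
            lapply(outcomes, function(o) compareMeans(table, o, cov)),
            error = function(e) {
                message("skipping covariate '", cov, "': ",
                        conditionMessage(e))
                NULL
            })
        if (is.null(res))
            next
        block <- res[[1L]]$groups[, c("level", "n")]
        block <- data.frame(covariate = cov, block,
                            stringsAsFactors = FALSE)
        for (i in seq_along(outcomes)) {
            block[[paste0("mean_", outcomes[i])]] <- res[[i]]$groups$mean
            block[[paste0("p_", outcomes[i])]] <- res[[i]]$p.value
        }
        rows[[cov]] <- block
    }
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    attr(out, "note") <-
        "Exploratory univariate analysis; no multiple-testing correction."
    out
}
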