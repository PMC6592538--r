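test_that("cohort tables round-trip through CSV and schema errors are explicit", {
    tab <- simulateCohort(cohortEffectConfig(n = 25, seed = 61))
    f <- tempfile(fileext = ".csv")
    writeCohort(tab, f)
    back <- readCohort(f)
    expect_equal(back[names(tab)], tab, tolerance = 1e-12)

    broken <- tab[, setdiff(names(tab), "ingress_whole_apu")]
    f2 <- tempfile(fileext = ".csv")
    writeCohort(broken, f2)
    expect_error(readCohort(f2), "ingress_whole_apu")

    # a column dictionary absorbs foreign naming
    renamed <- tab
    names(renamed)[names(renamed) == "ingress_whole_apu"] <- "IngressWF"
    f3 <- tempfile(fileext = ".csv")
    writeCohort(renamed, f3)
    mapped <- readCohort(f3, dictionary = c(ingress_whole_apu = "IngressWF"))
    expect_equal(mapped$ingress_whole_apu, tab$ingress_whole_apu)
    expect_error(readCohort(f3, dictionary = c(ingress_whole_apu = "nope")),
                 "absent column")
})

test_that("summaries report medians, extremes and consistent percentages", {
    df <- data.frame(v = c(1, 2, 3, 4, 5))
    s <- summarizeCohort(df, "v", kind = "continuous")
    expect_equal(s$median, 3)
    expect_equal(c(s$min, s$max), c(1, 5))

    flag <- data.frame(f = rep(c(TRUE, FALSE), c(21, 19)))
    sc <- summarizeCohort(flag, "f")
    expect_equal(sc$n[sc$level == "TRUE"], 21)
    expect_equal(sc$pct[sc$level == "TRUE"], 52.5)
    expect_equal(sum(sc$pct), 100)
    expect_equal(sc$pct, 100 * sc$n / sum(sc$n))

    expect_error(summarizeCohort(df, "missing"), "no such column")
    expect_error(summarizeCohort(data.frame(x = NA_real_), "x"), "missing")
})

test_that("two-group comparison matches the textbook pooled-variance t formula", {
    df <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                     g = rep(c("a", "b"), each = 3))
    res <- compareMeans(df, "y", "g")
    # hand-computed pooled-variance oracle
    m1 <- 2; m2 <- 5; s2p <- 1  # both group variances are 1
    tOracle <- (m1 - m2) / sqrt(s2p * (1 / 3 + 1 / 3))
    pOracle <- 2 * pt(-abs(tOracle), df = 4)
    expect_equal(res$test, "Student t")
    expect_equal(abs(res$statistic), abs(tOracle), tolerance = 1e-12)
    expect_equal(res$p.value, pOracle, tolerance = 1e-12)
    expect_equal(res$groups$mean, c(2, 5))

    # identical groups: zero statistic, p in the 1 region
    df0 <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
    res0 <- compareMeans(df0, "y", "g")
    expect_equal(res0$statistic, 0)
    expect_gt(res0$p.value, 0.99)
    expect_false(res0$significant)

    # three groups switch to ANOVA
    df3 <- data.frame(y = rnorm(30), g = rep(letters[1:3], 10))
    expect_equal(compareMeans(df3, "y", "g")$test, "ANOVA")
    # degenerate group
    dfd <- data.frame(y = 1:5, g = c("a", "a", "a", "a", "b"))
    expect_error(compareMeans(dfd, "y", "g"), "degenerate")
})

test_that("test selection follows the expected-count validity rule", {
    bal <- cohortFromCounts(20, 20, 20, 20)
    res <- compareCategorical(bal, "x", "y")
    expect_equal(res$test, "chi-square")
    expect_equal(res$statistic, 0)
    expect_gt(res$p.value, 0.99)

    # [[1,9],[11,3]] has expected counts exactly {5,5,7,7}: the inclusive
    # validity rule (all expected >= 5) keeps the chi-square test
    boundary <- cohortFromCounts(1, 9, 11, 3)
    expect_equal(compareCategorical(boundary, "x", "y")$test, "chi-square")

    sparse <- cohortFromCounts(1, 9, 11, 2)  # min expected 4.78 < 5
    res2 <- compareCategorical(sparse, "x", "y")
    expect_equal(res2$test, "Fisher exact")
    expect_equal(res2$p.value, fisherEnumP(1, 9, 11, 2), tolerance = 1e-9)

    # tables straddling the threshold: expected counts all 5 -> chi-square;
    # drop one observation so one expected count dips below 5 -> Fisher
    edge <- cohortFromCounts(5, 5, 5, 5)
    expect_equal(compareCategorical(edge, "x", "y")$test, "chi-square")
    edge2 <- cohortFromCounts(5, 5, 5, 4)
    expect_equal(compareCategorical(edge2, "x", "y")$test, "Fisher exact")

    expect_error(compareCategorical(data.frame(x = rep(TRUE, 5),
                                               y = rep(c(TRUE, FALSE), c(2, 3))),
                                    "x", "y"), "at least 2")
})

test_that("univariate report has one row per covariate level and flags injected effects", {
    cfg <- cohortEffectConfig(n = 200,
        effects = list(diabetes = c(ingress_whole_apu = 0.35)), seed = 62)
    tab <- simulateCohort(cfg)
    rep <- univariateTable(tab)
    expect_true(all(c("covariate", "level", "n", "mean_ingress_whole_apu",
                      "p_ingress_whole_apu") %in% names(rep)))
    expect_equal(sum(rep$covariate == "diabetes"), 2)
    expect_equal(sum(rep$n[rep$covariate == "diabetes"]), 200)
    pDiab <- rep$p_ingress_whole_apu[rep$covariate == "diabetes"][1]
    expect_lt(pDiab, 0.05)
    # the injected direction: diabetic stratum mean is lower
    means <- rep[rep$covariate == "diabetes", ]
    expect_lt(means$mean_ingress_whole_apu[means$level == "TRUE"],
              means$mean_ingress_whole_apu[means$level == "FALSE"])
    expect_match(attr(rep, "note"), "no multiple-testing correction")
})

test_that("null cohorts show no systematic significance structure", {
    set.seed(63)
    flagged <- replicate(40, {
        tab <- simulateCohort(cohortEffectConfig(n = 40, effects = list()))
        r <- univariateTable(tab, outcomes = "ingress_whole_apu",
                             covariates = c("overweight", "radiotherapy",
                                            "chemotherapy"))
        mean(r$p_ingress_whole_apu[!duplicated(r$covariate)] < 0.05)
    })
    expect_lt(mean(flagged), 0.12)  # ~5% expected, generous bound at 120 cells
})
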