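test_that("simulated dataset has the configured shape and classes", {
    sim <- simulateCounterSet(simConfig(seed = 3))
    x <- sim$object
    expect_equal(dim(x), c(579L + 15L + 8L, 15L))
    expect_equal(sum(codeClass(x) == "Endogenous"), 579L)
    expect_equal(sum(codeClass(x) == "Negative"), 8L)
    expect_equal(as.vector(table(sampleGroups(x))[c("case", "control")]),
                 c(11L, 4L))
    expect_true(all(assay(x, "counts") >= 0))
})

test_that("same config and seed give bit-identical output", {
    cfg <- simConfig(n_endogenous = 80L, n_housekeeping = 5L, seed = 99L)
    a <- simulateCounterSet(cfg)
    b <- simulateCounterSet(cfg)
    expect_identical(assay(a$object, "counts"), assay(b$object, "counts"))
    expect_identical(a$truth, b$truth)
    c2 <- simulateCounterSet(simConfig(n_endogenous = 80L,
                                       n_housekeeping = 5L, seed = 100L))
    expect_false(identical(assay(a$object, "counts"),
                           assay(c2$object, "counts")))
})

test_that("null config plants no differential expression", {
    sim <- simulateCounterSet(simConfig(n_endogenous = 120L,
                                        de_fraction_up = 0,
                                        de_fraction_down = 0, seed = 5))
    expect_equal(sum(sim$truth$genes$is_de), 0L)
    expect_true(all(sim$truth$genes$true_log2fc == 0))
})

test_that("planted DE bookkeeping matches the configured fractions", {
    cfg <- simConfig(n_endogenous = 200L, de_fraction_up = 0.1,
                     de_fraction_down = 0.05, seed = 21)
    tt <- simulateCounterSet(cfg)$truth$genes
    expect_equal(sum(tt$is_de), round(0.15 * 200))
    expect_equal(sum(tt$direction == "up"), 20L)
    expect_equal(sum(tt$direction == "down"), 10L)
    expect_true(all(sign(tt$true_log2fc[tt$direction == "up"]) == 1))
    expect_true(all(sign(tt$true_log2fc[tt$direction == "down"]) == -1))
    expect_true(all(tt$true_log2fc[!tt$is_de] == 0))
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(de_fraction_up = 0.7, de_fraction_down = 0.5),
                 "sum to <= 1")
    expect_error(simConfig(de_fraction_up = 0.5, de_fraction_down = 0.4,
                           dropout_fraction = 0.3), "infeasible")
    expect_error(simConfig(fc_values = c(2, 0.5)), ">= 1")
    expect_error(simConfig(degradation_factor_range = c(0, 1)), "> 0")
    expect_error(simConfig(n_negative = 1), ">= 2 negative")
})

test_that("expected detection count is n_endogenous * (1 - dropout)", {
    expect_equal(expectedDetectionCount(simConfig(dropout_fraction = 0)), 579)
    expect_equal(expectedDetectionCount(simConfig()), 449)
    expect_equal(expectedDetectionCount(
        simConfig(n_endogenous = 100L, dropout_fraction = 0.5)), 50)
})

test_that("degradation scales endogenous means but not negative probes", {
    cfg <- simConfig(n_endogenous = 50L, seed = 13)
    tr <- simulateCounterSet(cfg)$truth
    mu <- expectedCounts(tr)
    s_hi <- which.max(tr$samples$degradation)
    s_lo <- which.min(tr$samples$degradation)
    bg <- tr$samples$background_mean
    # signal component (mean minus background) scales with degradation
    sig_hi <- mu[, s_hi] - bg[s_hi]
    sig_lo <- mu[, s_lo] - bg[s_lo]
    same_group <- tr$samples$group[s_hi] == tr$samples$group[s_lo]
    nullg <- !tr$genes$is_de
    ratio <- sig_hi[nullg] / sig_lo[nullg]
    expect_true(all(abs(ratio - tr$samples$degradation[s_hi] /
                            tr$samples$degradation[s_lo]) < 1e-9))
    expect_true(all(diff(range(ratio)) < 1e-9))
})

test_that("empirical counts match the model means (standardized residuals)", {
    # each seed redraws planted parameters, so Monte-Carlo convergence is
    # checked via the CLT on standardized residuals pooled over the
    # endogenous cells of 150 small datasets: their mean is ~N(0, 1/sqrt(n)).
    z <- unlist(lapply(1:150, function(i) {
        cfg <- simConfig(n_endogenous = 20L, n_housekeeping = 3L,
                         n_case = 3L, n_control = 3L, dropout_fraction = 0,
                         de_fraction_up = 0, de_fraction_down = 0,
                         seed = 5000L + i)
        sim <- simulateCounterSet(cfg)
        mu <- expectedCounts(sim$truth)
        v <- mu + cfg$dispersion * mu^2
        cnt <- assay(sim$object, "counts")[seq_len(20), ]
        (cnt - mu) / sqrt(v)
    }))
    expect_lt(abs(mean(z)), 4 / sqrt(length(z)))
})

test_that("housekeeping genes show no systematic case/control difference", {
    deltas <- vapply(1:40, function(i) {
        sim <- simulateCounterSet(simConfig(n_endogenous = 20L,
                                            n_housekeeping = 6L,
                                            seed = 300L + i))
        x <- sim$object
        lg <- log2(assay(x, "counts")[housekeepingNames(x), , drop = FALSE] + 1)
        gr <- sampleGroups(x)
        mean(rowMeans(lg[, gr == "case"]) - rowMeans(lg[, gr == "control"]))
    }, 0)
    expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)))
})
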