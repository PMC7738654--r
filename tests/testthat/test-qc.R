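test_that("background threshold is mean + 2 sample SD of negative counts", {
    # zero variance: theta equals the mean exactly
    x0 <- setWithNegatives(matrix(5L, 8, 2))
    expect_equal(unname(theta(estimateBackground(x0))), c(5, 5))
    # hand-computed case: counts 1..8 -> 4.5 + 2*sqrt(6)
    x1 <- setWithNegatives(matrix(1:8, 8, 1))
    expect_equal(unname(theta(estimateBackground(x1))), 4.5 + 2 * sqrt(6),
                 tolerance = 1e-12)
    expect_error(estimateBackground(setWithNegatives(matrix(3L, 1, 2))),
                 ">= 2 negative")
    expect_warning(bg0 <- estimateBackground(setWithNegatives(matrix(0L, 8, 1))),
                   "zero")
    expect_equal(unname(theta(bg0)), 0)
})

test_that("theta is permutation invariant and scale equivariant", {
    set.seed(42)
    for (i in 1:20) {
        neg <- matrix(rpois(8, 10), 8, 1)
        t1 <- theta(estimateBackground(setWithNegatives(neg)))
        t2 <- theta(estimateBackground(setWithNegatives(neg[sample(8), , drop = FALSE])))
        t3 <- theta(estimateBackground(setWithNegatives(neg * 3L)))
        expect_equal(unname(t1), unname(t2))
        expect_equal(unname(t3), 3 * unname(t1), tolerance = 1e-12)
    }
})

test_that("housekeeping screen flags genes close to background", {
    neg <- matrix(10L, 8, 4)                       # theta = 10 everywhere
    hk <- rbind(HK_HIGH = rep(100L, 4),            # 10x theta: passes
                HK_EDGE = c(100L, 100L, 30L, 100L),# equals 3*theta once: fails
                HK_LOW  = rep(9L, 4))              # below background: fails
    x <- setWithNegatives(neg, extra = hk, extraClass = rep("Housekeeping", 3))
    bg <- estimateBackground(x)
    a <- screenHousekeeping(x, bg, k = 3)
    expect_identical(passingHk(a), "HK_HIGH")
    expect_false(a@passesBackground[["HK_EDGE"]])  # strict > at the boundary
    # a permissive k rescues the edge gene
    expect_setequal(passingHk(screenHousekeeping(x, bg, k = 1)),
                    c("HK_HIGH", "HK_EDGE"))
    xNoHk <- setWithNegatives(neg)
    expect_error(screenHousekeeping(xNoHk, estimateBackground(xNoHk)),
                 "no Housekeeping")
})

test_that("geNorm M matches brute force on random instances", {
    set.seed(7)
    for (i in 1:100) {
        ng <- sample(3:6, 1); ns <- sample(4:8, 1)
        cnt <- matrix(rpois(ng * ns, lambda = 200) + 1L, ng, ns)
        rownames(cnt) <- sprintf("HK_%02d", seq_len(ng))
        colnames(cnt) <- paste0("s", seq_len(ns))
        x <- NCounterSet(cnt, rep("Housekeeping", ng))
        M <- genormStability(x)
        expect_equal(unname(M), bruteGenormM(cnt), tolerance = 1e-9)
    }
})

test_that("geNorm degenerate cases behave as defined", {
    ns <- 5
    base <- matrix(2L^(3:7), 1)[rep(1, 3), ] # identical rows
    rownames(base) <- paste0("HK_", 1:3); colnames(base) <- paste0("s", 1:ns)
    x <- NCounterSet(base, rep("Housekeeping", 3))
    expect_equal(unname(genormStability(x)), c(0, 0, 0))

    # exactly proportional pair: their pairwise SD term is 0, so each gets
    # M = mean(SD against the third gene only) and the third is the outlier
    set.seed(1)
    a <- rpois(ns, 500) + 1L
    cnt <- rbind(HK_1 = a, HK_2 = 4L * a,
                 HK_3 = rpois(ns, 500) + 1L)
    colnames(cnt) <- paste0("s", 1:ns)
    x2 <- NCounterSet(cnt, rep("Housekeeping", 3))
    M <- genormStability(x2)
    sd13 <- sd(log2(cnt[1, ]) - log2(cnt[3, ]))
    expect_equal(unname(M["HK_1"]), sd13 / 2, tolerance = 1e-9)
    expect_equal(unname(M["HK_1"]), unname(M["HK_2"]), tolerance = 1e-9)
    expect_gt(M[["HK_3"]], M[["HK_1"]])

    expect_error(genormStability(x2, genes = c("HK_1", "HK_2")), ">= 3")
})

test_that("geNorm ranking eliminates the least stable gene first", {
    set.seed(11)
    ns <- 6
    a <- rpois(ns, 800) + 1L
    cnt <- rbind(HK_1 = a, HK_2 = 2L * a, HK_3 = a + rpois(ns, 5),
                 HK_4 = rpois(ns, 800) + 1L)  # unrelated -> least stable
    colnames(cnt) <- paste0("s", 1:ns)
    x <- NCounterSet(cnt, rep("Housekeeping", 4))
    rk <- genormRank(x)
    expect_equal(rk$gene[1], "HK_4")
    expect_equal(rk$elimination_order[1], 1L)
    # final three carry NA order, sorted least->most stable overall
    expect_true(all(is.na(rk$elimination_order[-1])))
    expect_equal(tail(rk$gene, 2), c("HK_1", "HK_2")) # proportional pair most stable
})

test_that("panel selection maximizes the minimum pairwise correlation", {
    set.seed(23)
    ns <- 8
    base <- rnorm(ns, 9, 1)
    mk <- function(noise) as.integer(round(2^(base + rnorm(ns, 0, noise))))
    cnt <- rbind(HK_A = mk(0.05), HK_B = mk(0.05), HK_C = mk(0.05),
                 HK_D = mk(0.05), HK_E = as.integer(rpois(ns, 500)) + 1L)
    cnt <- cnt + 1L  # keep well above the zero background below
    colnames(cnt) <- paste0("s", 1:ns)
    neg <- matrix(2L, 8, ns)
    x <- setWithNegatives(neg, extra = cnt, extraClass = rep("Housekeeping", 5))
    bg <- estimateBackground(x)
    a <- assessHousekeeping(x, screenHousekeeping(x, bg))
    a <- selectHkPanel(x, a, minR = 0.8, panelSize = 4)
    # exhaustive oracle over all 4-subsets
    lg <- log2(assay(x, "counts")[rownames(cnt), ] + 1)
    r <- cor(t(lg))
    subs <- combn(rownames(cnt), 4, simplify = FALSE)
    minr <- vapply(subs, function(s) min(r[s, s][upper.tri(r[s, s])]), 0)
    expect_setequal(hkPanel(a), subs[[which.max(minr)]])
    expect_false("HK_E" %in% hkPanel(a))  # the uncorrelated gene is excluded
})

test_that("panel selection handles exact ties and infeasible requests", {
    ns <- 5
    a <- 2L^(5:9)
    cnt <- rbind(HK_1 = a, HK_2 = 2L * a, HK_3 = 4L * a, HK_4 = 8L * a)
    colnames(cnt) <- paste0("s", 1:ns)
    x <- setWithNegatives(matrix(1L, 8, ns), extra = cnt,
                          extraClass = rep("Housekeeping", 4))
    bg <- estimateBackground(x)
    ass <- assessHousekeeping(x, screenHousekeeping(x, bg, k = 1))
    sel <- selectHkPanel(x, ass, minR = 0.8, panelSize = 4)
    # proportional genes: r ~ 1 (up to the +1 pseudocount), panel is all four
    expect_setequal(hkPanel(sel), rownames(cnt))
    expect_error(selectHkPanel(x, ass, panelSize = 5), "cannot select")
    # an unreachable minR is reported with the best achievable value
    expect_error(selectHkPanel(x, ass, minR = 1), "no 4-gene panel")
})

test_that("a noisy housekeeping gene is excluded with growing noise", {
    excl <- vapply(1:15, function(i) {
        set.seed(400 + i)
        ns <- 8
        base <- rnorm(ns, 9, 1.2)
        mk <- function(noise) pmax(as.integer(round(2^(base + rnorm(ns, 0, noise)))), 2L)
        cnt <- rbind(HK_A = mk(0.08), HK_B = mk(0.08), HK_C = mk(0.08),
                     HK_D = mk(0.08), HK_N = mk(3))
        colnames(cnt) <- paste0("s", 1:ns)
        x <- setWithNegatives(matrix(1L, 8, ns), extra = cnt,
                              extraClass = rep("Housekeeping", 5))
        a <- assessHousekeeping(x, screenHousekeeping(x, estimateBackground(x), k = 0.5))
        !("HK_N" %in% hkPanel(selectHkPanel(x, a, minR = 0.5)))
    }, TRUE)
    expect_gte(mean(excl), 14 / 15)
})
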