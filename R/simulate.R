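#' Simulation configuration for degraded FFPE nCounter data
#'
#' Builds a validated configuration for [simulateCounterSet()]. The defaults
#' emulate a 579-gene immunology codeset with 8 negative-control probes and a
#' 15-gene housekeeping panel, profiled on 11 case and 4 control FFPE samples
#' whose RNA quality varies: each sample carries a multiplicative degradation
#' (hybridization-efficiency) factor and its own nonspecific background level.
#'
#' The count model for endogenous/housekeeping probe g in sample s is
#' negative binomial with mean
#' `degradation_s * baseline_g * 2^lfc_g(s) + background_s`,
#' where `lfc_g(s)` is the planted log2 fold change for case samples (0 for
#' controls, housekeeping and null genes); negative probes have mean
#' `background_s` only. A `dropout_fraction` of endogenous genes is given a
#' near-zero baseline so their expected signal-to-noise ratio is at most 1:
#' these emulate transcripts lost to degradation and should fail detection.
#'
#' @param n_endogenous,n_negative,n_housekeeping panel composition (defaults
#'   579 / 8 / 15).
#' @param n_case,n_control group sizes (defaults 11 / 4).
#' @param de_fraction_up,de_fraction_down fractions of endogenous genes
#'   planted as up-/down-regulated in cases (defaults 48/579 and 21/579).
#' @param fc_values linear fold changes (all >= 1) sampled uniformly for
#'   planted genes; default `c(1.5, 2, 2.5, 4, 6)`.
#' @param baseline_log2_mean,baseline_log2_sd log2-normal baseline expression
#'   of non-dropout endogenous genes (defaults 9 and 1.2).
#' @param hk_log2_mean,hk_log2_sd housekeeping baseline distribution
#'   (defaults 10 and 0.5): high and tight, as reference genes should be.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); default 0.02 (counting CV ~14%, in line with
#'   typical nCounter replicate variability).
#' @param background_mean_range per-sample background mean, drawn uniformly;
#'   default `c(5, 15)` counts.
#' @param degradation_factor_range per-sample efficiency multiplier, drawn
#'   uniformly; default `c(0.1, 1)` (archival FFPE blocks commonly span an
#'   order of magnitude in effective RNA quality).
#' @param dropout_fraction fraction of endogenous genes forced near
#'   background; default `130/579`, so that the expected detected count is
#'   449 of 579.
#' @param seed integer RNG seed; a single RNG stream keyed by this seed
#'   drives the whole dataset.
#'
#' @return a validated `simConfig` list.
#' @seealso [simulateCounterSet()], [expectedDetectionCount()]
#' @export
simConfig <- function(n_endogenous = 579L, n_negative = 8L,
                      n_housekeeping = 15L, n_case = 11L, n_control = 4L,
                      de_fraction_up = 48 / 579, de_fraction_down = 21 / 579,
                      fc_values = c(1.5, 2, 2.5, 4, 6),
                      baseline_log2_mean = 9, baseline_log2_sd = 1.2,
                      hk_log2_mean = 10, hk_log2_sd = 0.5,
                      dispersion = 0.02,
                      background_mean_range = c(5, 15),
                      degradation_factor_range = c(0.1, 1),
                      dropout_fraction = 130 / 579,
                      seed = 1L) {
    cfg <- list(n_endogenous = as.integer(n_endogenous),
                n_negative = as.integer(n_negative),
                n_housekeeping = as.integer(n_housekeeping),
                n_case = as.integer(n_case), n_control = as.integer(n_control),
                de_fraction_up = de_fraction_up,
                de_fraction_down = de_fraction_down,
                fc_values = fc_values,
                baseline_log2_mean = baseline_log2_mean,
                baseline_log2_sd = baseline_log2_sd,
                hk_log2_mean = hk_log2_mean, hk_log2_sd = hk_log2_sd,
                dispersion = dispersion,
                background_mean_range = background_mean_range,
                degradation_factor_range = degradation_factor_range,
                dropout_fraction = dropout_fraction,
                seed = as.integer(seed))
    with(cfg, {
        if (any(c(n_endogenous, n_negative, n_housekeeping, n_case,
                  n_control) < 1L))
            stop("all panel and group sizes must be >= 1")
        if (n_negative < 2L)
            stop("need >= 2 negative probes for background estimation")
        if (de_fraction_up < 0 || de_fraction_down < 0 ||
            de_fraction_up + de_fraction_down > 1)
            stop("de fractions must be in [0,1] and sum to <= 1")
        if (de_fraction_up + de_fraction_down + dropout_fraction > 1)
            stop("de fractions plus dropout_fraction exceed 1: infeasible")
        if (length(fc_values) && any(fc_values < 1))
            stop("fc_values must all be >= 1 (direction is separate)")
        if (dropout_fraction < 0 || dropout_fraction > 1)
            stop("dropout_fraction must be in [0,1]")
        if (dispersion < 0) stop("dispersion must be >= 0")
        if (any(degradation_factor_range <= 0))
            stop("degradation factors must be > 0")
        if (any(background_mean_range <= 0))
            stop("background means must be > 0")
    })
    class(cfg) <- c("simConfig", "list")
    cfg
}

#' Expected number of detected genes under a configuration
#'
#' Dropout genes are constructed to fail the signal-to-noise filter and all
#' other endogenous genes to pass it, so the expected detected count is
#' `n_endogenous * (1 - dropout_fraction)`. The default configuration gives
#' 579 * (1 - 130/579) = 449.
#'
#' @param config a [simConfig()].
#' @return expected detected-gene count (real; not rounded).
#' @export
expectedDetectionCount <- function(config) {
    config$n_endogenous * (1 - config$dropout_fraction)
}

.rnbinom2 <- function(n, mu, dispersion) {
    if (dispersion <= 0) return(stats::rpois(n, mu))
    rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a degraded-FFPE nCounter dataset with known ground truth
#'
#' Draws raw counts under the model described in [simConfig()] and returns
#' both the [NCounterSet-class] and a truth table recording, per endogenous
#' gene, the planted log2 fold change, DE flag and direction, and per sample
#' the true degradation factor and background mean. Identical configurations
#' (including seed) give bit-identical output.
#'
#' @param config a [simConfig()].
#' @return list with elements `object` (an [NCounterSet-class], groups
#'   attached) and `truth` (list of data.frames `genes` and `samples`).
#' @examples
#' sim <- simulateCounterSet(simConfig(n_endogenous = 50, n_housekeeping = 5,
#'                                     seed = 7))
#' sim$object
#' head(sim$truth$genes)
#' @export
simulateCounterSet <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    rng <- local({ set.seed(config$seed); .Random.seed })
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    assign(".Random.seed", rng, .GlobalEnv)

    nE <- config$n_endogenous; nH <- config$n_housekeeping
    nN <- config$n_negative
    nS <- config$n_case + config$n_control
    sampleIds <- c(sprintf("case_%02d", seq_len(config$n_case)),
                   sprintf("ctrl_%02d", seq_len(config$n_control)))
    groups <- setNames(rep(c("case", "control"),
                           c(config$n_case, config$n_control)), sampleIds)

    degradation <- runif(nS, config$degradation_factor_range[1],
                         config$degradation_factor_range[2])
    bg_mean <- runif(nS, config$background_mean_range[1],
                     config$background_mean_range[2])

    ## gene roles: dropout genes are drawn after DE genes so DE genes are
    ## always detectable (planted effects must survive the SNR filter)
    n_up <- round(config$de_fraction_up * nE)
    n_down <- round(config$de_fraction_down * nE)
    n_drop <- min(round(config$dropout_fraction * nE), nE - n_up - n_down)
    role <- rep("null", nE)
    idx <- sample.int(nE)
    role[idx[seq_len(n_up)]] <- "up"
    role[idx[n_up + seq_len(n_down)]] <- "down"
    role[idx[n_up + n_down + seq_len(n_drop)]] <- "dropout"

    lfc <- numeric(nE)
    if (length(config$fc_values)) {
        ## index explicitly: sample(x, ...) on a length-1 numeric would
        ## silently sample from 1:x
        fc_up <- config$fc_values[sample.int(length(config$fc_values),
                                             n_up, replace = TRUE)]
        fc_dn <- config$fc_values[sample.int(length(config$fc_values),
                                             n_down, replace = TRUE)]
        lfc[role == "up"] <- log2(fc_up)
        lfc[role == "down"] <- -log2(fc_dn)
    }

    baseline <- 2 ^ rnorm(nE, config$baseline_log2_mean,
                          config$baseline_log2_sd)
    ## dropout baseline: expected signal small relative to the background SD,
    ## so expected SNR = (deg*b + bg) / (bg + 2*sd_bg) <= 1 for every sample
    sd_bg_min <- sqrt(bg_mean + config$dispersion * bg_mean ^ 2)
    drop_cap <- min(2 * sd_bg_min) / max(degradation)
    baseline[role == "dropout"] <- runif(n_drop, 0.05, 0.5) * drop_cap
    hk_baseline <- 2 ^ rnorm(nH, config$hk_log2_mean, config$hk_log2_sd)

    geneNames <- sprintf("GENE_%04d", seq_len(nE))
    hkNames <- sprintf("HK_%02d", seq_len(nH))
    negNames <- sprintf("NEG_%s", LETTERS[seq_len(nN)])

    is_case <- groups == "case"
    counts <- matrix(0L, nE + nH + nN, nS,
                     dimnames = list(c(geneNames, hkNames, negNames),
                                     sampleIds))
    for (s in seq_len(nS)) {
        fc_mult <- if (is_case[s]) 2 ^ lfc else rep(1, nE)
        muE <- degradation[s] * baseline * fc_mult + bg_mean[s]
        muH <- degradation[s] * hk_baseline + bg_mean[s]
        muN <- rep(bg_mean[s], nN)
        counts[, s] <- as.integer(.rnbinom2(nE + nH + nN, c(muE, muH, muN),
                                            config$dispersion))
    }

    obj <- NCounterSet(counts,
                       rep(c("Endogenous", "Housekeeping", "Negative"),
                           c(nE, nH, nN)),
                       groups = groups)
    metadata(obj)$simConfig <- config
    truth <- list(
        genes = data.frame(gene = geneNames, role = role,
                           true_log2fc = lfc, is_de = role %in% c("up", "down"),
                           direction = ifelse(role == "up", "up",
                                       ifelse(role == "down", "down", "none")),
                           baseline = baseline, stringsAsFactors = FALSE),
        samples = data.frame(sample_id = sampleIds, group = unname(groups),
                             degradation = degradation,
                             background_mean = bg_mean,
                             stringsAsFactors = FALSE))
    list(object = obj, truth = truth)
}

#' Expected count matrix under a simulation's planted parameters
#'
#' Returns the model means (not a random draw) for a simulated dataset:
#' useful for Monte-Carlo convergence checks and monotonicity properties.
#'
#' @param truth the `truth` element returned by [simulateCounterSet()].
#' @param caseSamples logical vector, TRUE where the sample is a case.
#' @return matrix of expected endogenous counts (genes x samples).
#' @export
expectedCounts <- function(truth, caseSamples = truth$samples$group == "case") {
    g <- truth$genes; s <- truth$samples
    outer_sig <- outer(g$baseline, s$degradation)
    fc <- outer(2 ^ g$true_log2fc, rep(1, nrow(s)))
    fc[, !caseSamples] <- 1
    sweep(outer_sig * fc, 2, s$background_mean, `+`)
}
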