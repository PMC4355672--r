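## Independent, naively-looped reference implementations used as oracles.
## These deliberately share no code with the package internals: per-feature
## loops, tapply-style stratification, base mean()/sd().

naiveScores <- function(x, omegaVals, kValsPerPoint = NULL, epsilon = 0.005) {
    mat <- assay(x, "intensity")
    grp <- sampleGroup(x)
    tp <- timePoint(x)
    st <- samplingTime(x)
    out <- numeric(nrow(mat))
    for (f in seq_len(nrow(mat))) {
        D <- 0; S <- 0
        for (i in sort(unique(tp))) {
            sts <- sort(unique(st[tp == i]))
            kv <- if (is.null(kValsPerPoint)) rep(1 / length(sts), length(sts))
                  else kValsPerPoint[[i + 1L]]
            for (j in sts) {
                sel <- tp == i & st == j
                vc <- mat[f, sel & grp == "C"]
                vm <- mat[f, sel & grp == "M"]
                sdc <- if (length(vc) > 1) sd(vc) else 0
                sdm <- if (length(vm) > 1) sd(vm) else 0
                D <- D + omegaVals[i + 1L] * kv[j + 1L] *
                    abs(mean(vc) - mean(vm))
                S <- S + omegaVals[i + 1L] * kv[j + 1L] * (sdc + sdm)
            }
        }
        out[f] <- if (D == 0) 0 else D / (S + epsilon)
    }
    out
}

## Brute-force AUC: average pairwise concordance over all (positive,
## negative) pairs, ties counting one half.
naiveAuc <- function(labels, scores) {
    pos <- which(labels == 1)
    neg <- which(labels == 0)
    tot <- 0
    for (p in pos)
        for (q in neg)
            tot <- tot + (scores[p] > scores[q]) + 0.5 * (scores[p] == scores[q])
    tot / (length(pos) * length(neg))
}

## Small random dataset with arbitrary (possibly unbalanced) strata.
randomTimeCourse <- function(seed, F = NULL, N = NULL, pMax = 3,
                             nPerGroup = NULL) {
    set.seed(seed)
    if (is.null(F)) F <- sample(3:20, 1)
    if (is.null(N)) N <- sample(2:5, 1)
    p <- sample.int(pMax, N, replace = TRUE)
    grp <- character(0); tp <- integer(0); st <- integer(0)
    for (i in seq_len(N) - 1L)
        for (j in seq_len(p[i + 1L]) - 1L) {
            nC <- if (is.null(nPerGroup)) sample(2:4, 1) else nPerGroup
            nM <- if (is.null(nPerGroup)) sample(2:4, 1) else nPerGroup
            grp <- c(grp, rep("C", nC), rep("M", nM))
            tp <- c(tp, rep(i, nC + nM))
            st <- c(st, rep(j, nC + nM))
        }
    vals <- matrix(abs(rnorm(length(grp) * F, 100, 30)), length(grp), F)
    TimeCourseExperiment(vals, grp, tp, st,
                         featureIds = paste0("F", seq_len(F)))
}

## Random weight scheme over n indices.
randomScheme <- function(n) {
    fam <- sample(c("equal", "linear", "proportional", "exponential"), 1)
    if (fam == "equal") makeWeights("equal", n = n)
    else makeWeights(fam, q = runif(1, 0, 1.5), n = n)
}
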