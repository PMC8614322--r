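test_that("simulation is bit-reproducible per seed and validates input", {
    p <- penParam(nAnimals = 3, duration = 20, seed = 7)
    a <- simulatePen(p); b <- simulatePen(p)
    expect_identical(groundTruth(a), groundTruth(b))
    expect_identical(pathLengths(a), pathLengths(b))
    c0 <- simulatePen(penParam(nAnimals = 3, duration = 20, seed = 8))
    expect_false(identical(groundTruth(a), groundTruth(c0)))
    bad <- matrix(1, 3, 3)
    expect_error(penParam(transition = bad), "row-stochastic")
    expect_error(penParam(feeder = c(0, 0, 9999, 10)), "inside the arena")
})

test_that("an absorbing start stays in its posture forever", {
    sim <- simulatePen(penParam(nAnimals = 4, duration = 30,
                                transition = diag(3),
                                initPosture = "ll_pig", seed = 2))
    occ <- occupancy(sim)
    expect_equal(unname(occ[, "ll_pig"]), rep(1, 4))
    expect_equal(sum(occ[, c("standing_pig", "sl_pig")]), 0)
    expect_equal(pathLengths(sim), rep(0, 4))
})

test_that("occupancy fractions sum to one and match the ethogram table", {
    sim <- simulatePen(penParam(nAnimals = 5, duration = 60, seed = 5))
    occ <- occupancy(sim)
    expect_equal(unname(rowSums(occ)), rep(1, 5))
    st <- groundTruth(sim)
    tab <- prop.table(table(st$animal, st$posture), margin = 1)
    for (lab in colnames(occ))
        if (lab %in% colnames(tab))
            expect_equal(unname(occ[, lab]), unname(tab[, lab]))
})

test_that("long-run posture occupancy matches the stationary eigenvector", {
    P <- matrix(c(0.90, 0.08, 0.02,
                  0.05, 0.85, 0.10,
                  0.02, 0.08, 0.90), 3, byrow = TRUE)
    ## analytic stationary distribution: left eigenvector at eigenvalue 1
    e <- eigen(t(P))
    pi0 <- Re(e$vectors[, which.min(abs(e$values - 1))])
    pi0 <- pi0 / sum(pi0)
    nF <- 50000
    sim <- simulatePen(penParam(nAnimals = 1, fps = 5, duration = nF / 5,
                                transition = P, feeder = NULL, seed = 12))
    occ <- occupancy(sim)[1, ]
    ## 3 sd of the empirical fraction, inflated by the chain's mixing time
    for (k in 1:3) {
        se <- sqrt(pi0[k] * (1 - pi0[k]) / nF)
        expect_lt(abs(occ[k] - pi0[k]), max(3 * 5 * se, 0.01))
    }
})

test_that("zero-noise detections are bijective with visible ground truth", {
    sim <- simulatePen(penParam(nAnimals = 5, duration = 30, seed = 9))
    dets <- emitDetections(sim, noiseParam())
    vis <- groundTruth(sim)[groundTruth(sim)$visible, ]
    expect_equal(nrow(dets), nrow(vis))
    expect_equal(sort(dets$x_min), sort(vis$x_min))
    expect_true(all(dets$confidence == 1))
    ## miss everything
    none <- emitDetections(sim, noiseParam(missRate = 1))
    expect_equal(nrow(none), 0L)
})

test_that("miss-rate thinning matches the binomial oracle over seeds", {
    sim <- simulatePen(penParam(nAnimals = 5, duration = 60, feeder = NULL,
                                seed = 4))
    slots <- nrow(groundTruth(sim))          # all visible, 300 x 5
    miss <- 0.05
    total <- 0
    for (s in 1:20)
        total <- total + nrow(emitDetections(sim, noiseParam(
            missRate = miss, seed = 100 + s)))
    expected <- (1 - miss) * slots * 20
    sdev <- sqrt(slots * 20 * miss * (1 - miss))
    expect_lt(abs(total - expected), 3 * sdev)
})

test_that("false positives, jitter and label flips behave as configured", {
    sim <- simulatePen(penParam(nAnimals = 2, duration = 30, seed = 3))
    dets <- emitDetections(sim, noiseParam(fpRate = 2, seed = 6))
    vis <- sum(groundTruth(sim)$visible)
    expect_gt(nrow(dets), vis)               # extra spurious boxes
    jit <- emitDetections(sim, noiseParam(jitterSd = 2, seed = 6))
    expect_equal(nrow(jit), vis)
    expect_gt(max(abs(sort(jit$x_min) - sort(
        groundTruth(sim)$x_min[groundTruth(sim)$visible]))), 0)
    flip <- emitDetections(sim, noiseParam(labelFlipRate = 1, seed = 6))
    expect_true(all(flip$label %in% postureLabels()))
    sameFrameCounts <- identical(table(flip$frame),
                                 table(groundTruth(sim)$frame[
                                     groundTruth(sim)$visible]))
    expect_true(sameFrameCounts)
})

test_that("the feeder blind spot skews the visibility histogram", {
    sim <- simulatePen(penParam(nAnimals = 5, duration = 120, seed = 20))
    hist <- visibilityHistogram(sim)
    expect_equal(sum(hist), 600)
    ## mass concentrates near full visibility, with a feeder-induced tail
    expect_true(names(which.max(hist)) %in% c("4", "5"))
    expect_gt(sum(hist[c("4", "5")]), sum(hist[as.character(0:3)]))
    expect_gt(sum(hist[as.character(0:4)]), 0)  # the feeder does hide pigs
    ## no feeder: everything visible
    simFree <- simulatePen(penParam(nAnimals = 5, duration = 20,
                                    feeder = NULL, seed = 20))
    hv <- visibilityHistogram(simFree)
    expect_equal(unname(hv["5"]), 100L)
})

test_that("rendered frames chain into the hash pipeline as expected", {
    lying <- simulatePen(penParam(nAnimals = 3, duration = 4,
                                  transition = diag(3),
                                  initPosture = "ll_pig", seed = 8))
    h1 <- computePhash(renderFrame(lying, 1))
    h2 <- computePhash(renderFrame(lying, 2))
    expect_lte(hammingDistance(h1, h2), 1)   # dedup would drop frame 2
    ## teleport one pig 100 px: the hash must notice
    moved <- lying
    st <- groundTruth(moved)
    i <- st$frame == 2 & st$animal == 1
    moved@states[i, c("cx", "x_min", "x_max")] <-
        st[i, c("cx", "x_min", "x_max")] + 100
    h3 <- computePhash(renderFrame(moved, 2))
    expect_gt(hammingDistance(h1, h3), 1)
    ## empty pen renders constant -> all-ones hash
    empty <- simulatePen(penParam(nAnimals = 1, duration = 2,
                                  feeder = c(0, 0, 640, 640),
                                  initPosture = "ll_pig", seed = 1))
    expect_error(renderFrame(empty, 99), "out of range")
})

test_that("a fully covering feeder yields a constant dark frame", {
    empty <- simulatePen(penParam(nAnimals = 1, duration = 2,
                                  feeder = c(0, 0, 640, 640),
                                  initPosture = "ll_pig", seed = 1))
    img <- renderFrame(empty, 1)
    expect_equal(length(unique(as.vector(img))), 1L)
    expect_equal(sum(hashBits(computePhash(img))), 64)
})
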