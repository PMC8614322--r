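boxRow <- function(x, y, w = 60, h = 40, frame = 1L, id = NULL,
                   label = "sl_pig", conf = 1)
    boundingBoxes(x, y, x + w, y + h, label = label, confidence = conf,
                  frame = frame, id = id)

test_that("frame matching: identical sets, empty sets, brute-force optimum", {
    g <- rbind(boxRow(0, 0), boxRow(100, 0), boxRow(200, 0))
    m <- matchFrame(g, g)
    expect_equal(nrow(m$matches), 3L)
    expect_equal(m$matches$iou, rep(1, 3))

    m0 <- matchFrame(g[1:2, ], g[0, ])
    expect_equal(m0$unmatchedGt, 1:2)

    ## ambiguous 3x3 overlap: total matched IoU equals permutation maximum
    set.seed(83)
    for (trial in 1:20) {
        g3 <- boxRow(runif(3, 0, 80), runif(3, 0, 80), frame = 1L)
        h3 <- boxRow(runif(3, 0, 80), runif(3, 0, 80), frame = 1L)
        got <- matchFrame(g3, h3, iouThreshold = 0)$matches
        expect_equal(sum(got$iou), bruteMaxIouSum(iouMatrix(g3, h3)),
                     tolerance = 1e-9)
    }
})

test_that("MOTA reproduces closed-form accounting on constructed scenarios", {
    ## perfect tracking: 5 objects x 300 frames
    gt <- do.call(rbind, lapply(1:5, function(i)
        boxRow(120 * i, 50, frame = 1:300, id = i)))
    mm <- evaluateMot(gt, gt)
    expect_equal(mota(mm), 1)
    expect_equal(motp(mm), 1)

    ## GT 1500 with FN=30, FP=15, IDSW=3 -> MOTA = 1 - 48/1500
    hyp <- gt
    drop <- which(hyp$id == 2 & hyp$frame <= 30)          # 30 misses
    hyp <- hyp[-drop, ]
    fp <- boxRow(600, 600, frame = 1:15, id = 99)         # 15 false alarms
    hyp <- rbind(hyp, fp)
    sw <- hyp$id == 5 & hyp$frame %in% c(101, 201, 301)   # fresh ids
    ## a switch at frame f only counts once; switch to a new id each time
    hyp$id[hyp$id == 5 & hyp$frame >= 101 & hyp$frame <= 200] <- 51L
    hyp$id[hyp$id == 5 & hyp$frame >= 201 & hyp$frame <= 300] <- 52L
    hyp$id[hyp$id == 1 & hyp$frame >= 151] <- 53L
    mm2 <- evaluateMot(gt, hyp)
    cts <- motCounts(mm2)
    expect_equal(sum(cts$gt), 1500)
    expect_equal(sum(cts$fn), 30)
    expect_equal(sum(cts$fp), 15)
    expect_equal(sum(cts$idsw), 3)
    expect_equal(mota(mm2), 1 - 48 / 1500)

    ## single object, 10 frames, one id change -> MOTA 0.9
    g1 <- boxRow(0, 0, frame = 1:10, id = 1)
    h1 <- g1; h1$id <- c(rep(1L, 5), rep(2L, 5))
    mm3 <- evaluateMot(g1, h1)
    expect_equal(sum(motCounts(mm3)$idsw), 1)
    expect_equal(mota(mm3), 0.9)
})

test_that("MOTA can go negative under a false-positive flood", {
    gt <- boxRow(0, 0, frame = 1:10, id = 1)
    flood <- do.call(rbind, lapply(1:10, function(f)
        boxRow(seq(100, 400, by = 100), rep(300, 4), frame = f,
               id = 10 + 1:4)))
    mm <- evaluateMot(gt, rbind(gt, flood))
    expect_lt(mota(mm), 0)
    expect_lte(mota(mm), 1)
})

test_that("MOTP stays within [threshold, 1] and supports centre distance", {
    gt <- boxRow(c(0, 100), c(0, 0), frame = 1L, id = 1:2)
    hyp <- boxRow(c(5, 104), c(0, 2), frame = 1L, id = 1:2)
    mm <- evaluateMot(gt, hyp, iouThreshold = 0.5)
    expect_gte(motp(mm), 0.5)
    expect_lte(motp(mm), 1)
    mmc <- evaluateMot(gt, hyp, iouThreshold = 0.5, metric = "center")
    expect_equal(motp(mmc), mean(c(5, sqrt(16 + 4))))
    expect_error(evaluateMot(gt[0, ], hyp), "empty ground truth")
})

test_that("match persistence prevents spurious switches on jitter overlap", {
    ## two adjacent gt pigs; hypothesis boxes overlap both, but each keeps
    ## its original assignment while above threshold
    gt <- rbind(boxRow(0, 0, w = 100, frame = 1:20, id = 1),
                boxRow(60, 0, w = 100, frame = 1:20, id = 2))
    hyp <- rbind(boxRow(2, 0, w = 100, frame = 1:20, id = 7),
                 boxRow(62, 0, w = 100, frame = 1:20, id = 8))
    mm <- evaluateMot(gt, hyp, iouThreshold = 0.3)
    expect_equal(sum(motCounts(mm)$idsw), 0)
    expect_equal(mota(mm), 1)
})

test_that("AP: perfect detection 1.0, FP-before-TP 0.5, none 0", {
    gt <- boxRow(0, 0, frame = 1L, label = "ll_pig")
    perfect <- transform(gt, confidence = 0.9)
    expect_equal(averagePrecisionValue(
        averagePrecision(perfect, gt, "ll_pig")), 1)

    det <- rbind(boxRow(300, 300, frame = 1L, label = "ll_pig", conf = 0.9),
                 boxRow(0, 0, frame = 1L, label = "ll_pig", conf = 0.5))
    pr <- averagePrecision(det, gt, "ll_pig")
    expect_equal(pr@recall, c(0, 1))
    expect_equal(pr@precision, c(0, 0.5))
    expect_equal(averagePrecisionValue(pr), 0.5)

    none <- averagePrecision(det[0, ], gt, "ll_pig")
    expect_equal(averagePrecisionValue(none), 0)
})

test_that("duplicate hits on one ground-truth box count as false positives", {
    gt <- boxRow(0, 0, frame = 1L, label = "sl_pig")
    det <- rbind(boxRow(0, 0, frame = 1L, conf = 0.9),
                 boxRow(1, 1, frame = 1L, conf = 0.8))
    pr <- averagePrecision(det, gt, "sl_pig")
    expect_equal(pr@tp, c(TRUE, FALSE))
    expect_equal(averagePrecisionValue(pr), 1)
})

test_that("AP is invariant under strictly monotone confidence transforms", {
    set.seed(97)
    gt <- boxRow(seq(0, 500, by = 100), rep(0, 6), frame = 1L,
                 label = "standing_pig")
    det <- boxRow(seq(0, 500, by = 100) + runif(6, -30, 30), rep(0, 6),
                  frame = 1L, label = "standing_pig",
                  conf = runif(6, 0.2, 0.9))
    det <- rbind(det, boxRow(700, 300, frame = 1L, label = "standing_pig",
                             conf = 0.55))
    ap1 <- averagePrecisionValue(averagePrecision(det, gt, "standing_pig"))
    det2 <- det; det2$confidence <- det$confidence^3
    ap2 <- averagePrecisionValue(averagePrecision(det2, gt, "standing_pig"))
    det3 <- det; det3$confidence <- plogis(5 * det$confidence - 2)
    ap3 <- averagePrecisionValue(averagePrecision(det3, gt, "standing_pig"))
    expect_equal(ap1, ap2)
    expect_equal(ap1, ap3)
})

test_that("mAP is the unweighted class mean", {
    mk <- function(ap, label) new("PrCurve", label = label,
                                  confidence = 1, tp = TRUE, precision = 1,
                                  recall = 1, ap = ap, nGt = 1L)
    expect_equal(meanAveragePrecision(list(mk(1, "a"), mk(1, "b"),
                                           mk(1, "c"))), 1)
    expect_equal(meanAveragePrecision(list(mk(0.9, "a"), mk(0.8, "b"),
                                           mk(1.0, "c"))), 0.9)
    expect_equal(meanAveragePrecision(list(mk(0.7, "a"))), 0.7)
    expect_error(meanAveragePrecision(list()), "at least one")
})
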