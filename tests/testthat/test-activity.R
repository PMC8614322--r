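mkTrack <- function(cx, cy, labels, frames = seq_along(cx), id = 1L,
                    w = 80, h = 50) {
    data.frame(frame = as.integer(frames), track_id = id,
               x_min = cx - w / 2, y_min = cy - h / 2,
               x_max = cx + w / 2, y_max = cy + h / 2,
               label = labels, confidence = 1)
}

test_that("walking rule: supra-threshold displacement while standing", {
    r <- classifyWalking(c(10, 10), c(13, 14), "standing_pig",
                         "standing_pig")
    expect_true(r$walking); expect_equal(r$dd, 5)
    r2 <- classifyWalking(c(10, 10), c(12, 12), "standing_pig",
                          "standing_pig")
    expect_false(r2$walking); expect_equal(r2$dd, 2 * sqrt(2))
    r3 <- classifyWalking(c(10, 10), c(20, 20), "ll_pig", "ll_pig")
    expect_false(r3$walking); expect_equal(r3$dd, 10 * sqrt(2))
})

test_that("locomotion sums only walking pairs; speed uses walking time", {
    ## 100 walking pairs of exactly 5 px at 5 FPS
    cx <- 100 + 5 * (0:100)
    tr <- mkTrack(cx, rep(100, 101), "standing_pig")
    loco <- locomotionSummary(tr, activityParam(fps = 5))
    expect_equal(loco$total_distance, 500)
    expect_equal(loco$walking_pairs, 100L)
    expect_equal(loco$speed_walking, 25)       # 500 px / 20 s
    expect_equal(loco$speed_overall, 25)       # moving the whole span here
    ## stationary pig
    still <- mkTrack(rep(100, 50), rep(100, 50), "standing_pig")
    l2 <- locomotionSummary(still)
    expect_equal(l2$total_distance, 0)
    expect_equal(l2$speed_walking, 0)
    ## sub-threshold jitter is excluded from distance but kept in the raw sum
    jig <- mkTrack(100 + rep(c(0, 2), 25), rep(100, 50), "standing_pig")
    l3 <- locomotionSummary(jig)
    expect_equal(l3$total_distance, 0)
    expect_gt(l3$raw_displacement, 0)
})

test_that("lying pigs accrue no distance however far boxes jump", {
    tr <- mkTrack(c(100, 300, 500), rep(100, 3), "ll_pig")
    expect_equal(locomotionSummary(tr)$total_distance, 0)
})

test_that("total distance is invariant under joint translation", {
    set.seed(23)
    cx <- cumsum(c(200, runif(40, -8, 8)))
    cy <- cumsum(c(200, runif(40, -8, 8)))
    tr <- mkTrack(cx, cy, "standing_pig")
    shifted <- tr
    shifted[c("x_min", "x_max")] <- shifted[c("x_min", "x_max")] + 37
    shifted[c("y_min", "y_max")] <- shifted[c("y_min", "y_max")] - 11
    expect_equal(locomotionSummary(shifted)$total_distance,
                 locomotionSummary(tr)$total_distance)
})

test_that("individual scores are clip-frame fractions", {
    tr <- mkTrack(rep(100, 300), rep(100, 300), rep("ll_pig", 300))
    expect_equal(postureScoreIndividual(tr, "ll_pig", 300)$score, 1)
    tr2 <- mkTrack(rep(100, 300), rep(100, 300),
                   c(rep("standing_pig", 30), rep("sl_pig", 270)))
    expect_equal(postureScoreIndividual(tr2, "standing_pig", 300)$score, 0.1)
    ## posture scores partition the visible frames
    tot <- sum(vapply(postureLabels(), function(a)
        postureScoreIndividual(tr2, a, 300)$score, numeric(1)))
    expect_equal(tot, 1)
    ## missed frames depress the score rather than renormalising
    half <- tr[1:150, ]
    expect_equal(postureScoreIndividual(half, "ll_pig", 300)$score, 0.5)
})

test_that("group score is the mean per-frame count and sums individuals", {
    tracks <- do.call(rbind, lapply(1:5, function(i)
        mkTrack(rep(100 * i, 40), rep(100, 40), "ll_pig", id = i)))
    g <- postureScoreGroup(tracks, "ll_pig", 40)
    expect_equal(g$score, 5)
    ## frame 1: 3 lateral, frame 2: 1 lateral -> group score 2
    t2 <- rbind(mkTrack(c(100, 100), c(100, 100), c("ll_pig", "ll_pig"),
                        frames = 1:2, id = 1),
                mkTrack(100, 300, "ll_pig", frames = 1, id = 2),
                mkTrack(100, 500, "ll_pig", frames = 1, id = 3),
                mkTrack(300, 500, "sl_pig", frames = 2, id = 4))
    expect_equal(postureScoreGroup(t2, "ll_pig", 2)$score, 2)
    ind <- postureScoreIndividual(t2, "ll_pig", 2)
    expect_equal(sum(ind$score), 2)
})

test_that("walking score never exceeds standing score", {
    set.seed(29)
    for (i in 1:10) {
        n <- 60
        labels <- sample(postureLabels(), n, replace = TRUE,
                         prob = c(0.5, 0.3, 0.2))
        cx <- cumsum(c(300, runif(n - 1, -10, 10)))
        tr <- mkTrack(cx, rep(100, n), labels)
        walk <- postureScoreIndividual(tr, "walking", n)$score
        stand <- postureScoreIndividual(tr, "standing_pig", n)$score
        expect_lte(walk, stand)
    }
})

test_that("activityScores emits a tidy table with group rows", {
    tr <- mkTrack(rep(100, 10), rep(100, 10), "sl_pig")
    sc <- activityScores(tr, 10)
    expect_setequal(unique(sc$activity), c(postureLabels(), "walking"))
    expect_true(all(c("1", "group") %in% sc$subject))
    expect_equal(sc$score[sc$subject == "1" & sc$activity == "sl_pig"], 1)
})

test_that("phase aggregation: mean/sd across days, degenerate cells flagged", {
    h <- expand.grid(day = 1:3, session = "morning", phase = "before",
                     activity = "standing_pig",
                     stringsAsFactors = FALSE)
    h$score <- c(0.2, 0.4, 0.6)
    out <- phaseAggregate(h)
    expect_equal(out$mean, 0.4)
    expect_equal(out$sd, 0.2)
    expect_false(out$insufficient_replicates)
    ## identical replicates: sd 0
    h$score <- 0.3
    expect_equal(phaseAggregate(h)$sd, 0)
    ## single replicate: flagged, sd 0; absent cells simply missing
    h1 <- h[1, ]
    out1 <- phaseAggregate(h1)
    expect_true(out1$insufficient_replicates)
    expect_equal(out1$sd, 0)
    expect_equal(nrow(out1), 1L)
    expect_error(phaseAggregate(h1[, -1]), "needs columns")
})
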