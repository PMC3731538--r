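fake_products <- function(precursor, arms) {
    data.frame(name = sprintf("%s-m%d", precursor, seq_along(arms)),
               precursor_name = precursor,
               arm_start = vapply(arms, `[`, 0L, 1L),
               arm_end = vapply(arms, `[`, 0L, 2L),
               stringsAsFactors = FALSE)
}

two_arm_sample <- function(c5, c3, template) {
    stack_from_spans(data.frame(offset = c(110L, 145L), len = 22L,
                                count = c(c5, c3)),
                     template = template)$stack
}

test_that("tallies normalize to relative frequencies per sample", {
    set.seed(71)
    template <- rand_seq(300)
    st <- two_arm_sample(75L, 25L, template)
    products <- fake_products("hsa-mir-901",
                              list(c(110L, 132L), c(145L, 167L)))
    em <- tally_expression(list(s1 = list("hsa-mir-901" = st)), products)
    expect_equal(unname(em$freq[, "s1"]), c(0.75, 0.25))
    expect_equal(sum(em$freq[, "s1"]), 1)
})

test_that("zero counts hit the log floor and empty samples are flagged", {
    set.seed(72)
    template <- rand_seq(300)
    st <- stack_from_spans(data.frame(offset = 110L, len = 22L, count = 60L),
                           template = template)$stack
    products <- fake_products("hsa-mir-901",
                              list(c(110L, 132L), c(145L, 167L)))
    em <- tally_expression(list(s1 = list("hsa-mir-901" = st),
                                s2 = list()),
                           products)
    expect_equal(em$log2[2, "s1"], log2(1e-6))
    expect_identical(em$empty_samples, "s2")
    expect_true(all(em$freq[, "s2"] == 0))
})

test_that("multi-sample columns each sum to one", {
    set.seed(73)
    template <- rand_seq(300)
    stacks <- list(a = list("hsa-mir-901" = two_arm_sample(75L, 25L, template)),
                   b = list("hsa-mir-901" = two_arm_sample(10L, 90L, template)),
                   c = list("hsa-mir-901" = two_arm_sample(33L, 67L, template)))
    products <- fake_products("hsa-mir-901",
                              list(c(110L, 132L), c(145L, 167L)))
    em <- tally_expression(stacks, products)
    expect_equal(unname(colSums(em$freq)), rep(1, 3))
    expect_true(all(em$freq >= 0))
})

test_that("cluster collapse sums members and preserves column sums", {
    counts <- matrix(c(10L, 20L, 70L,
                       5L, 5L, 90L), ncol = 2,
                     dimnames = list(c("hsa-miR-1-1", "hsa-miR-133a-1",
                                       "hsa-miR-7"), c("s1", "s2")))
    em <- mircurate:::expression_matrix(counts)
    clusters <- data.frame(name = "cluster-hsa-mir-1-1(2)", size = 2L,
                           members = "hsa-mir-1-1,hsa-mir-133a-1",
                           stringsAsFactors = FALSE)
    map <- c("hsa-miR-1-1" = "hsa-mir-1-1",
             "hsa-miR-133a-1" = "hsa-mir-133a-1",
             "hsa-miR-7" = "hsa-mir-7")
    cm <- collapse_by_cluster(em, clusters, map)
    expect_identical(rownames(cm$freq),
                     c("cluster-hsa-mir-1-1(2)", "hsa-miR-7"))
    expect_equal(cm$freq["cluster-hsa-mir-1-1(2)", "s1"], 0.3)
    expect_equal(colSums(cm$freq), colSums(em$freq))

    # no clusters: the matrix passes through unchanged
    none <- collapse_by_cluster(em, clusters[0, ], map)
    expect_equal(none$freq, em$freq)
})

test_that("permuting samples permutes columns identically", {
    set.seed(74)
    counts <- matrix(sample(0:50, 12), nrow = 4,
                     dimnames = list(sprintf("m%d", 1:4),
                                     sprintf("s%d", 1:3)))
    em <- mircurate:::expression_matrix(counts)
    em_perm <- mircurate:::expression_matrix(counts[, c(3, 1, 2)])
    expect_equal(em_perm$freq, em$freq[, c(3, 1, 2)])
    expect_equal(em_perm$log2, em$log2[, c(3, 1, 2)])
})

test_that("simulated cistron members collapse to an additive profile", {
    set.seed(75)
    template <- rand_seq(300)
    template2 <- rand_seq(300)
    # two co-transcribed members with similar counts plus one outsider
    st1 <- stack_from_spans(data.frame(offset = 110L, len = 22L, count = 40L),
                            template = template)$stack
    st2 <- stack_from_spans(data.frame(offset = 110L, len = 22L, count = 42L),
                            template = template2)$stack
    st2$precursor_name <- "hsa-mir-902"
    st3 <- stack_from_spans(data.frame(offset = 110L, len = 22L, count = 120L),
                            template = rand_seq(300))$stack
    st3$precursor_name <- "hsa-mir-903"
    products <- data.frame(
        name = c("hsa-miR-901", "hsa-miR-902", "hsa-miR-903"),
        precursor_name = c("hsa-mir-901", "hsa-mir-902", "hsa-mir-903"),
        arm_start = 110L, arm_end = 132L, stringsAsFactors = FALSE)
    em <- tally_expression(list(s1 = list("hsa-mir-901" = st1,
                                          "hsa-mir-902" = st2,
                                          "hsa-mir-903" = st3)), products)
    clusters <- data.frame(name = "cluster-hsa-mir-901(2)", size = 2L,
                           members = "hsa-mir-901,hsa-mir-902",
                           stringsAsFactors = FALSE)
    map <- setNames(products$precursor_name, products$name)
    cm <- collapse_by_cluster(em, clusters, map)
    expect_equal(cm$freq["cluster-hsa-mir-901(2)", "s1"],
                 (40 + 42) / 202)
    expect_equal(sum(cm$freq[, "s1"]), 1)
})

test_that("profile_expression tallies multiple samples over accepted loci", {
    p <- sim_params(seed = 76)
    hp <- make_hairpin_locus(p)
    hp$candidate$est_evidence <- TRUE
    reads1 <- simulate_stack(hp$candidate, hp$truth, p)
    reads2 <- simulate_stack(hp$candidate, hp$truth, p)
    res <- curate_cohort(list(hp$candidate), reads1)
    em <- profile_expression(res, list(hp$candidate),
                             list(s1 = reads1, s2 = reads2))
    expect_identical(dim(em$freq), c(2L, 2L))
    expect_equal(unname(colSums(em$freq)), c(1, 1))
    # mature row dominates in both samples
    mature <- res$products$name[res$products$designation == "mature"]
    expect_true(all(em$freq[mature, ] > 0.5))
})
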