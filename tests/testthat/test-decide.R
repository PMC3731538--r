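# minimal stack stand-in: decide() only reads counts and (when present)
# alignment rows
fake_stack <- function(total, nonred) {
    structure(list(precursor_name = "x", alignments = mircurate:::empty_alignments(),
                   coverage = matrix(0, 3, 10), total_count = as.integer(total),
                   nonredundant_count = as.integer(nonred)),
              class = "read_stack")
}

good_arms <- function() arm_call_fixture(c(100L, 122L), c(135L, 157L),
                                         five_fraction = 0.9)

test_that("read-count and redundancy thresholds sit exactly at the constants", {
    cand <- as_candidate(rand_seq(80), est = TRUE)
    ok_arms <- good_arms(); ok_hp <- hairpin_ok_fixture()

    d <- decide(cand, fake_stack(49, 10), ok_arms, ok_hp)
    expect_identical(d$reason, "INSUFFICIENT_READS")
    d <- decide(cand, fake_stack(50, 10), ok_arms, ok_hp)
    expect_identical(d$reason, "ACCEPTED")

    d <- decide(cand, fake_stack(50, 4), ok_arms, ok_hp)
    expect_identical(d$reason, "LOW_NONREDUNDANT")
    d <- decide(cand, fake_stack(50, 5), ok_arms, ok_hp)
    expect_identical(d$reason, "ACCEPTED")
})

test_that("the genomic-location threshold respects cistron membership", {
    ok_arms <- good_arms(); ok_hp <- hairpin_ok_fixture()
    c31 <- as_candidate(rand_seq(80), copies = 31L, est = TRUE)
    expect_identical(decide(c31, fake_stack(100, 10), ok_arms, ok_hp)$reason,
                     "EXCESS_MULTIMAP")
    c30 <- as_candidate(rand_seq(80), copies = 30L, est = TRUE)
    expect_identical(decide(c30, fake_stack(100, 10), ok_arms, ok_hp)$reason,
                     "ACCEPTED")
    # a cistron member is exempt even above the threshold
    c31c <- as_candidate(rand_seq(80), copies = 31L, est = TRUE,
                         cistron_id = "cluster-x(2)")
    expect_identical(decide(c31c, fake_stack(100, 10), ok_arms, ok_hp)$reason,
                     "ACCEPTED")
})

test_that("ncRNA overlap requires half the precursor on the same strand", {
    cand <- as_candidate(rand_seq(80), chrom = "chr1", start = 1000L,
                         est = TRUE)  # locus [1000, 1080)
    track <- function(s, e, class = "tRNA", strand = "+") {
        structure(data.frame(chrom = "chr1", start = s, end = e,
                             class = class, strand = strand,
                             stringsAsFactors = FALSE),
                  class = c("annotation_track", "data.frame"))
    }
    expect_identical(check_ncrna_overlap(cand, track(990L, 1090L)), "tRNA")
    expect_identical(check_ncrna_overlap(cand, NULL), NA_character_)
    # 30% overlap is not enough; 50% exactly is
    expect_identical(check_ncrna_overlap(cand, track(1056L, 1200L, "rRNA")),
                     NA_character_)
    expect_identical(check_ncrna_overlap(cand, track(1040L, 1200L, "rRNA")),
                     "rRNA")
    # opposite strand does not count
    expect_identical(check_ncrna_overlap(cand, track(990L, 1090L,
                                                     strand = "-")),
                     NA_character_)
    # decision integration
    ok_arms <- good_arms(); ok_hp <- hairpin_ok_fixture()
    d <- decide(cand, fake_stack(100, 10), ok_arms, ok_hp,
                track = track(990L, 1090L))
    expect_identical(d$reason, "NCRNA_OVERLAP")
    # a miRNA-class annotation is not a rejection
    d <- decide(cand, fake_stack(100, 10), ok_arms, ok_hp,
                track = track(990L, 1090L, "miRNA"))
    expect_identical(d$reason, "ACCEPTED")
})

test_that("reverse complements of accepted matures are artifacts", {
    set.seed(51)
    accepted <- replicate(5, rand_seq(22))
    rc <- dna_revcomp_t(accepted[3])
    expect_true(check_complement_artifact(rc, accepted))
    mut <- rc
    substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "G" else "A"
    expect_true(check_complement_artifact(mut, accepted))  # within 2 edits
    expect_false(check_complement_artifact(rc, character()))
    for (rep in 1:10) {
        r <- rand_seq(22)
        d <- min(adist(dna_revcomp_t(r), accepted))
        expect_identical(check_complement_artifact(r, accepted), d <= 2)
    }
})

test_that("pattern and expression-evidence rules close the tree", {
    ok_hp <- hairpin_ok_fixture()
    bad_arms <- arm_call_fixture(c(100L, 122L), NULL, bimodal = FALSE)
    cand <- as_candidate(rand_seq(80), est = TRUE)
    expect_identical(decide(cand, fake_stack(100, 10), bad_arms, NULL)$reason,
                     "NO_PATTERN_OR_FOLDBACK")
    expect_identical(decide(cand, fake_stack(100, 10), good_arms(),
                            hairpin_ok_fixture(FALSE))$reason,
                     "NO_PATTERN_OR_FOLDBACK")
    lonely <- as_candidate(rand_seq(80), est = FALSE)
    expect_identical(decide(lonely, fake_stack(100, 10), good_arms(),
                            ok_hp)$reason,
                     "NO_EXPRESSION_EVIDENCE")
    in_cistron <- as_candidate(rand_seq(80), est = FALSE,
                               cistron_id = "cluster-y(2)")
    expect_identical(decide(in_cistron, fake_stack(100, 10), good_arms(),
                            ok_hp)$reason, "ACCEPTED")
})

test_that("early rejections short-circuit later inputs", {
    # a candidate rejected on counts is invariant to downstream perturbations
    cand <- as_candidate(rand_seq(80), est = FALSE, copies = 40L)
    variants <- list(
        list(arms = good_arms(), hp = hairpin_ok_fixture(TRUE)),
        list(arms = arm_call_fixture(c(1L, 23L), NULL, bimodal = FALSE),
             hp = NULL),
        list(arms = good_arms(), hp = hairpin_ok_fixture(FALSE)))
    reasons <- vapply(variants, function(v) {
        decide(cand, fake_stack(10, 2), v$arms, v$hp)$reason
    }, character(1))
    expect_true(all(reasons == "INSUFFICIENT_READS"))
})

test_that("a bimodal candidate without a structure check is an internal error", {
    cand <- as_candidate(rand_seq(80), est = TRUE)
    expect_error(decide(cand, fake_stack(100, 10), good_arms(), NULL),
                 "internal error")
    expect_error(decide(cand, fake_stack(100, 10), NULL, NULL),
                 "internal error")
})

test_that("decision reasons partition any simulated cohort", {
    co <- make_cohort(sim_params(seed = 52,
                                 decoy_mix = c(prototypical = 5, trna_like = 3,
                                               low_depth = 2, repeat_like = 2)))
    res <- curate_cohort(co$candidates, co$reads, co$annotation, co$est)
    expect_identical(sum(res$tally), nrow(res$decisions))
    expect_identical(nrow(res$decisions), 12L)
    expect_true(all(res$decisions$reason %in% decision_reasons()))
    expect_identical(res$decisions$status == "accepted",
                     res$decisions$reason == "ACCEPTED")
})
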