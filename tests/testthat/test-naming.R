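test_that("mature names follow the gene-to-transcript conventions", {
    expect_identical(format_mature_name("hsa-mir-125b-1", "5p", "mature"),
                     "hsa-miR-125b-1")
    expect_identical(format_mature_name("hsa-mir-125b-1", "3p", "star"),
                     "hsa-miR-125b-1*")
    expect_identical(format_mature_name("hsa-mir-9-1", "5p", "5p"),
                     "hsa-miR-9-1-5p")
    expect_identical(format_mature_name("hsa-mir-9-1", "3p", "3p"),
                     "hsa-miR-9-1-3p")
    expect_identical(format_mature_name("hsa-let-7a", "5p", "mature"),
                     "hsa-let-7a")
    expect_error(format_mature_name("weird-name", "5p", "mature"), "weird")
})

test_that("arm dominance is a strict 80% boundary", {
    arms <- function(f) arm_call_fixture(c(0L, 22L), c(35L, 57L),
                                         five_fraction = f)
    expect_identical(unname(assign_designations(arms(0.994))),
                     c("mature", "star"))
    expect_identical(unname(assign_designations(arms(0.006))),
                     c("star", "mature"))
    expect_identical(unname(assign_designations(arms(0.5))), c("5p", "3p"))
    expect_identical(unname(assign_designations(arms(0.80))), c("5p", "3p"))
    expect_identical(unname(assign_designations(arms(0.81))),
                     c("mature", "star"))
    single <- arm_call_fixture(c(0L, 22L), NULL, five_fraction = 1)
    expect_identical(unname(assign_designations(single)), c("mature", "star"))
})

test_that("family compatibility implements the one-allowance rule", {
    a <- "TGAGGTAGTAGGTTGTATAGTT"
    expect_true(family_compatible(a, a))
    # one substitution inside the 5' seed region
    b <- a; substr(b, 5, 5) <- "C"
    expect_true(family_compatible(a, b))
    # two substitutions there are too many
    c2 <- b; substr(c2, 7, 7) <- "C"
    expect_false(family_compatible(a, c2))
    # a pure 1-nt 5' offset is allowed
    d <- paste0("A", substr(a, 1, 21))
    expect_true(family_compatible(a, d))
    # offset plus mismatch is rejected under the strict single allowance
    e <- d; substr(e, 6, 6) <- "C"
    expect_false(family_compatible(a, e))
    cfg <- curation_config(family_strict = FALSE)
    expect_true(family_compatible(a, e, cfg))
    # known paralogs sharing a seed but diverging 3' of it stay compatible
    fam <- fixture_mir1_family()
    expect_true(family_compatible(fam[["hsa-miR-1-1"]],
                                  fam[["hsa-miR-206"]]))
})

test_that("family compatibility is symmetric", {
    set.seed(61)
    for (rep in 1:300) {
        a <- rand_seq(sample(20:23, 1))
        b <- if (rep %% 2 == 0) {
            x <- a
            idx <- sample(8, sample(0:2, 1))
            for (q in idx) substr(x, q, q) <- sample(c("A", "C", "G", "T"), 1)
            x
        } else rand_seq(sample(20:23, 1))
        expect_identical(family_compatible(a, b), family_compatible(b, a))
    }
})

test_that("the known miR-1 family groups and is named canonically", {
    fam <- build_families(fixture_mir1_family())
    expect_identical(nrow(fam$families), 1L)
    expect_identical(fam$families$name, "sf-hsa-miR-1-1(3)")
    expect_identical(fam$families$size, 3L)
    expect_identical(fam$families$members,
                     "hsa-miR-1-1,hsa-miR-1-2,hsa-miR-206")
})

test_that("families equal the brute-force transitive closure", {
    set.seed(62)
    seqs <- setNames(replicate(40, rand_seq(22)),
                     sprintf("hsa-miR-%d", 1:40))
    # plant related groups so components are non-trivial
    seqs[2] <- seqs[1]
    seqs[3] <- { x <- seqs[1]; substr(x, 4, 4) <- "T"; x }
    seqs[10] <- paste0("G", substr(seqs[9], 1, 21))
    fam <- build_families(seqs)
    truth <- oracle_components(unname(seqs))
    sizes_truth <- sort(as.integer(table(truth)[table(truth) >= 2]))
    expect_identical(sort(fam$families$size), sizes_truth)
    expect_identical(length(fam$singletons), sum(table(truth) == 1))
    # partition: every mature lands in exactly one family or the singleton list
    all_members <- c(unlist(strsplit(fam$families$members, ",")),
                     fam$singletons)
    expect_identical(sort(all_members), sort(names(seqs)))
})

test_that("natural ordering ranks numeric name parts numerically", {
    x <- c("hsa-mir-125", "hsa-mir-9", "hsa-mir-21")
    expect_identical(x[natural_order(x)],
                     c("hsa-mir-9", "hsa-mir-21", "hsa-mir-125"))
})

test_that("cistron chaining honors the 5 kb gap exactly", {
    mk <- function(name, start, end, chrom = "chr1") {
        precursor_candidate(name, genomic_interval(chrom, start, end),
                            strrep("A", end - start), 0L)
    }
    # gap of exactly 5000 merges
    cl <- build_clusters(list(mk("hsa-mir-1-1", 1000L, 1100L),
                              mk("hsa-mir-2-1", 6100L, 6200L)))
    expect_identical(nrow(cl), 1L)
    expect_identical(cl$size, 2L)
    # gap of 5001 splits
    cl <- build_clusters(list(mk("hsa-mir-1-1", 1000L, 1100L),
                              mk("hsa-mir-2-1", 6101L, 6201L)))
    expect_identical(nrow(cl), 0L)
    # 2.8 kb apart forms one cistron
    cl <- build_clusters(list(mk("hsa-mir-1-2", 10000L, 10085L, "chr18"),
                              mk("hsa-mir-133a-1", 12885L, 12973L, "chr18")))
    expect_identical(cl$members, "hsa-mir-1-2,hsa-mir-133a-1")
})

test_that("multi-copy matures merge cistrons across chromosomes", {
    mk <- function(name, start, end, chrom) {
        precursor_candidate(name, genomic_interval(chrom, start, end),
                            strrep("A", end - start), 0L)
    }
    prec <- list(mk("hsa-mir-1-2", 10000L, 10085L, "chr18"),
                 mk("hsa-mir-133a-1", 12885L, 12973L, "chr18"),
                 mk("hsa-mir-1-1", 50000L, 50071L, "chr20"),
                 mk("hsa-mir-133a-2", 52500L, 52602L, "chr20"))
    m1 <- "TGGAATGTAAAGAAGTATGTAT"
    m133 <- "TTTGGTCCCCTTCAACCAGCTG"
    seqs <- c("hsa-mir-1-1" = m1, "hsa-mir-1-2" = m1,
              "hsa-mir-133a-1" = m133, "hsa-mir-133a-2" = m133)
    cl <- build_clusters(prec, mature_seqs = seqs)
    expect_identical(nrow(cl), 1L)
    expect_identical(cl$name, "cluster-hsa-mir-1-1(4)")
    expect_identical(cl$members,
                     "hsa-mir-1-1,hsa-mir-1-2,hsa-mir-133a-1,hsa-mir-133a-2")
    # without the mature mapping the two chromosomes stay apart
    cl <- build_clusters(prec)
    expect_identical(nrow(cl), 2L)
    # unrelated 6 kb neighbours remain singletons (not reported)
    cl <- build_clusters(list(mk("hsa-mir-7-1", 1000L, 1100L, "chr9"),
                              mk("hsa-mir-8-1", 7100L, 7200L, "chr9")))
    expect_identical(nrow(cl), 0L)
})
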