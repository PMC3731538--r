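test_that("exact substrings align with zero errors at their offset", {
    set.seed(21)
    cand <- as_candidate(rand_seq(120), flank = 40)
    read <- substr(cand$extended_sequence, 61, 82)
    aln <- align_read(read, cand)
    expect_identical(nrow(aln), 1L)
    expect_identical(aln$offset, 60L)
    expect_identical(aln$end, 82L)
    expect_identical(aln$errors, 0L)
    expect_identical(aln$edits, "")
})

test_that("a 3' non-templated A is reported as one terminal insertion", {
    set.seed(22)
    # template free of A in the tail neighbourhood so the addition cannot
    # be re-templated
    template <- paste0(rand_seq(60), strrep("G", 6), rand_seq(60))
    cand <- as_candidate(template, flank = 0)
    base <- substr(template, 40, 61)
    read <- paste0(base, "A")
    stopifnot(regexpr(read, cand$extended_sequence, fixed = TRUE) < 0)
    aln <- align_read(read, cand)
    expect_identical(aln$errors, 1L)
    edits <- parse_edits(aln$edits)
    expect_identical(edits$op, "insertion")
    expect_identical(edits$pos, nchar(read))
    expect_identical(edits$base, "A")
})

test_that("reads absent within the error budget return no alignment", {
    set.seed(23)
    for (rep in 1:20) {
        cand <- as_candidate(rand_seq(150), flank = 0)
        read <- rand_seq(22)
        oracle <- oracle_align(read, cand$extended_sequence)
        aln <- align_read(read, cand)
        if (is.null(oracle)) {
            expect_identical(nrow(aln), 0L)
        } else {
            expect_identical(aln$errors, oracle$dmin)
        }
    }
})

test_that("alignment agrees with the brute-force window-scan oracle", {
    set.seed(24)
    cfg <- curation_config()
    for (rep in 1:150) {
        n <- sample(60:300, 1)
        m <- sample(16:30, 1)
        text <- rand_seq(n)
        read <- if (rep %% 3 == 0) {
            rand_seq(m)  # mostly absent
        } else {
            # plant a mutated window so hits are frequent
            s <- sample(n - m, 1)
            r <- substr(text, s, s + m - 1)
            p <- sample(m, sample(0:3, 1))
            for (q in p) substr(r, q, q) <- sample(c("A", "C", "G", "T"), 1)
            r
        }
        cand <- as_candidate(text, flank = 0, name = "hsa-mir-999")
        aln <- align_read(read, cand, cfg)
        oracle <- oracle_align(read, text, cfg$max_errors)
        if (is.null(oracle)) {
            expect_identical(nrow(aln), 0L)
        } else {
            expect_identical(aln$errors, oracle$dmin)
            expect_identical(aln$offset, oracle$offset)
            expect_identical(aln$end, oracle$end)
        }
    }
})

test_that("multi-mapping reads keep only their lowest-error placements", {
    set.seed(25)
    body <- rand_seq(80)
    c1 <- as_candidate(body, name = "hsa-mir-801", flank = 10)
    body2 <- body
    substr(body2, 40, 40) <- if (substr(body2, 40, 40) == "A") "C" else "A"
    c2 <- as_candidate(body2, name = "hsa-mir-802", flank = 10)

    read <- substr(body, 30, 51)  # exact on c1, 1 error on c2
    aln <- resolve_multimap(align_reads(collapse_reads(
        data.frame(sequence = read, count = 4L)), list(c1, c2)))
    expect_identical(aln$precursor, "hsa-mir-801")
    expect_false(aln$multimapped)

    # identical copies: kept at both, flagged, full count at each
    c3 <- as_candidate(body, name = "hsa-mir-803", flank = 10)
    aln <- resolve_multimap(align_reads(collapse_reads(
        data.frame(sequence = read, count = 4L)), list(c1, c3)))
    expect_identical(sort(aln$precursor), c("hsa-mir-801", "hsa-mir-803"))
    expect_true(all(aln$multimapped))
    expect_identical(aln$count, c(4L, 4L))

    # single-precursor universe: the identity assignment
    aln1 <- align_reads(collapse_reads(data.frame(sequence = read, count = 4L)),
                        list(c1))
    expect_identical(resolve_multimap(aln1)[, names(aln1)], aln1)
})

test_that("stack coverage matches brute-force accumulation and is conserved", {
    set.seed(26)
    spans <- data.frame(offset = sample(0:250, 30, replace = TRUE),
                        len = sample(18:26, 30, replace = TRUE),
                        count = sample(1:40, 30, replace = TRUE))
    sf <- stack_from_spans(spans)
    st <- sf$stack
    combined <- st$coverage[nrow(st$coverage), ]
    expect_equal(combined,
                 oracle_coverage(st$alignments, ncol(st$coverage)))
    # conservation: total coverage mass equals sum of count x aligned length
    expect_equal(sum(combined),
                 sum(st$alignments$count *
                     (st$alignments$end - st$alignments$offset)))
    # a single 5-copy read spanning [10,32)
    sf <- stack_from_spans(data.frame(offset = 10L, len = 22L, count = 5L))
    cov <- sf$stack$coverage[3, ]
    expect_true(all(cov[11:32] == 5))
    expect_true(all(cov[-(11:32)] == 0))
})

test_that("error tiers are positionwise monotone and empty stacks are zero", {
    set.seed(27)
    p <- sim_params(seed = 27, depth = 300)
    hp <- make_hairpin_locus(p)
    reads <- simulate_stack(hp$candidate, hp$truth, p)
    aln <- resolve_multimap(align_reads(reads, list(hp$candidate)))
    st <- build_stack(hp$candidate, aln)
    expect_true(all(st$coverage["e0", ] <= st$coverage["e1", ]))
    expect_true(all(st$coverage["e1", ] <= st$coverage["e2", ]))
    expect_true(st$nonredundant_count <= nrow(st$alignments))
    expect_true(st$total_count >= st$nonredundant_count)

    empty <- build_stack(hp$candidate, mircurate:::empty_alignments())
    expect_identical(empty$total_count, 0L)
    expect_true(all(empty$coverage == 0))
})

test_that("alignments outside the sequence are an internal error", {
    cand <- as_candidate(rand_seq(50), flank = 0)
    bad <- data.frame(sequence = "ACGTACGTACGTACGTACGT", count = 1L,
                      precursor = cand$name, offset = 40L, end = 62L,
                      errors = 0L, edits = "")
    expect_error(build_stack(cand, bad), "consistency")
})

test_that("SAM export writes a header and one record per alignment", {
    set.seed(28)
    sf <- stack_from_spans(data.frame(offset = c(50L, 90L), len = 22L,
                                      count = c(8L, 3L)))
    path <- withr::local_tempfile(fileext = ".sam")
    write_stack_sam(sf$stack, sf$candidate, path)
    lines <- readLines(path)
    expect_match(lines[1], "^@HD")
    expect_match(lines[2], "^@SQ\tSN:hsa-mir-901\tLN:300")
    expect_length(lines, 2L + nrow(sf$stack$alignments))
    expect_match(lines[3], "NM:i:0$")
})
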