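#' Parameters for the synthetic read-stack simulator
#'
#' The generator emulates the canonical biogenesis geometry: a duplex of
#' `duplex_len` (18--26 nt) with `overhang`-nt 3' overhangs around a loop of
#' `loop_size` nt, a strong 5' U/A bias on the mature strand, read depth
#' split between arms by `arm_ratio`, rarer 5'-end than 3'-end jitter,
#' occasional non-templated 3' A/U additions, and internal G-to-A changes
#' mimicking dsRNA deamination. Decoy classes cover the main rejection
#' modes: tRNA-like unimodal stacks with a non-templated CCA terminus,
#' under-sequenced loci, and repeat-derived high-copy loci.
#'
#' @param seed integer RNG seed; all outputs are pure functions of
#'   (params, seed).
#' @param depth reads drawn per precursor.
#' @param arm_ratio fraction of reads on the mature arm.
#' @param jitter5_max,jitter5_prob maximal 5'-end shift (nt) and its
#'   per-read probability; kept rarer than 3' jitter.
#' @param jitter3_max,jitter3_prob maximal 3'-end shift and probability.
#' @param addition_prob probability of one non-templated 3' A/U.
#' @param edit_prob probability of one internal G-to-A change.
#' @param loop_size hairpin loop length (nt).
#' @param duplex_len mature/star length (nt).
#' @param overhang designed 3' overhang (nt).
#' @param five_prime_bias probability that the mature 5' nucleotide is U/A.
#' @param mature_arm which arm carries the mature product (`"five"` or
#'   `"three"`).
#' @param decoy_mix named counts per cohort class
#'   (`prototypical, trna_like, low_depth, repeat_like`).
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(seed = 1L, depth = 500L, arm_ratio = 0.9,
                       jitter5_max = 1L, jitter5_prob = 0.05,
                       jitter3_max = 2L, jitter3_prob = 0.3,
                       addition_prob = 0.1, edit_prob = 0.02,
                       loop_size = 13L, duplex_len = 22L, overhang = 2L,
                       five_prime_bias = 0.8, mature_arm = "five",
                       decoy_mix = c(prototypical = 100L, trna_like = 50L,
                                     low_depth = 25L, repeat_like = 25L)) {
    p <- list(seed = as.integer(seed), depth = as.integer(depth),
              arm_ratio = arm_ratio, jitter5_max = as.integer(jitter5_max),
              jitter5_prob = jitter5_prob,
              jitter3_max = as.integer(jitter3_max),
              jitter3_prob = jitter3_prob, addition_prob = addition_prob,
              edit_prob = edit_prob, loop_size = as.integer(loop_size),
              duplex_len = as.integer(duplex_len),
              overhang = as.integer(overhang),
              five_prime_bias = five_prime_bias,
              mature_arm = match.arg(mature_arm, c("five", "three")),
              decoy_mix = decoy_mix)
    probs <- c(p$arm_ratio, p$jitter5_prob, p$jitter3_prob, p$addition_prob,
               p$edit_prob, p$five_prime_bias)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                         call. = FALSE)
    if (p$depth < 1L) stop("depth must be >= 1", call. = FALSE)
    if (p$duplex_len < 18L || p$duplex_len > 26L) {
        stop("duplex_len must lie in [18, 26]", call. = FALSE)
    }
    class(p) <- "sim_params"
    p
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulate one prototypical hairpin locus
#'
#' Draws a random mature of `duplex_len` nt with the configured 5' U/A
#' bias, builds the star arm as the staggered reverse complement producing
#' the designed 3' overhangs, joins the arms with an unpaired loop, and
#' embeds the hairpin in random flanking sequence. Uses the current RNG
#' state (seed the stream upstream, e.g. in [make_cohort()]).
#'
#' @param params a [sim_params()] object.
#' @param name precursor name.
#' @param chrom,locus_start genomic placement of the hairpin.
#' @param flank_nt flanking context to embed on each side.
#' @return List with the [precursor_candidate()] (`candidate`) and a
#'   `truth` record (exact arm intervals in extended coordinates, mature
#'   arm, designed spacing).
#' @export
make_hairpin_locus <- function(params, name = "sim-mir-1", chrom = "chrSim",
                               locus_start = 1000L, flank_nt = 100L) {
    L <- params$duplex_len
    oh <- params$overhang
    core_len <- L - oh

    # 5' arm: random core; loop-adjacent overhang bases avoid pairing with
    # the all-A loop (no T) so the designed overhang survives folding
    first <- if (stats::runif(1) < params$five_prime_bias) {
        sample(c("T", "A"), 1)
    } else sample(c("C", "G"), 1)
    arm5 <- paste0(first, rand_dna(core_len - 1L),
                   rand_dna(oh, alphabet = c("A", "C", "G")))
    # 3' arm: reverse complement of the paired core, plus an outer overhang
    arm3 <- paste0(dna_revcomp(substr(arm5, 1L, core_len)), rand_dna(oh))
    if (params$mature_arm == "three") {
        # bias the 3'-arm 5' nucleotide instead: it complements core base
        # core_len of the 5' arm, so rewrite that base
        want <- if (stats::runif(1) < params$five_prime_bias) {
            sample(c("T", "A"), 1)
        } else sample(c("C", "G"), 1)
        substr(arm5, core_len, core_len) <- dna_revcomp(want)
        arm3 <- paste0(dna_revcomp(substr(arm5, 1L, core_len)), rand_dna(oh))
    }
    loop <- strrep("A", params$loop_size)
    hairpin <- paste0(arm5, loop, arm3)

    extended <- paste0(rand_dna(flank_nt), hairpin, rand_dna(flank_nt))
    locus <- genomic_interval(chrom, locus_start,
                              locus_start + nchar(hairpin))
    candidate <- precursor_candidate(name, locus, extended,
                                     extension_offset = flank_nt)
    five_iv <- c(flank_nt, flank_nt + L)
    three_iv <- c(flank_nt + L + params$loop_size,
                  flank_nt + L + params$loop_size + L)
    truth <- list(name = name,
                  five_arm = five_iv, three_arm = three_iv,
                  mature_arm = params$mature_arm,
                  spacing = params$loop_size,
                  hairpin = hairpin)
    list(candidate = candidate, truth = truth)
}

#' Simulate a collapsed read stack for a hairpin locus
#'
#' Draws `depth` reads: the arm by Bernoulli(`arm_ratio`), 5'/3' end
#' jitter (5' strictly rarer than 3' under the defaults), a non-templated
#' 3' A/U with `addition_prob`, and an internal G-to-A change with
#' `edit_prob`; reads are then collapsed with summed counts.
#'
#' @param candidate a [precursor_candidate()] from [make_hairpin_locus()].
#' @param truth its truth record.
#' @param params a [sim_params()] object.
#' @return A `collapsed_reads` data.frame.
#' @export
simulate_stack <- function(candidate, truth, params) {
    ext <- candidate$extended_sequence
    mature_iv <- if (truth$mature_arm == "five") truth$five_arm else truth$three_arm
    star_iv <- if (truth$mature_arm == "five") truth$three_arm else truth$five_arm

    draw_shift <- function(maxs, prob) {
        if (maxs < 1L || stats::runif(1) >= prob) return(0L)
        sample(c(seq(-maxs, -1L), seq_len(maxs)), 1L)
    }
    seqs <- character(params$depth)
    for (i in seq_len(params$depth)) {
        iv <- if (stats::runif(1) < params$arm_ratio) mature_iv else star_iv
        s <- iv[1] + draw_shift(params$jitter5_max, params$jitter5_prob)
        e <- iv[2] + draw_shift(params$jitter3_max, params$jitter3_prob)
        s <- max(0L, s); e <- min(nchar(ext), e)
        rd <- substr(ext, s + 1L, e)
        if (stats::runif(1) < params$addition_prob) {
            rd <- paste0(rd, sample(c("A", "T"), 1L))
        }
        if (stats::runif(1) < params$edit_prob) {
            gpos <- gregexpr("G", rd, fixed = TRUE)[[1]]
            if (gpos[1] > 0L) {
                p <- if (length(gpos) == 1L) gpos else sample(gpos, 1L)
                substr(rd, p, p) <- "A"
            }
        }
        seqs[i] <- rd
    }
    collapse_reads(data.frame(sequence = seqs, count = 1L,
                              stringsAsFactors = FALSE))
}

#' Simulate a tRNA-like decoy locus
#'
#' A ~73-nt transcript whose reads tile it with uniform starts (unimodal
#' coverage) and whose most frequent read ends at the transcript 3'
#' terminus with the tRNA aminoacyl-acceptor CCA, partially non-templated
#' so it still aligns within the error budget. Returns the matching
#' annotation interval labeled `tRNA`.
#'
#' @param params a [sim_params()] object.
#' @param name,chrom,locus_start placement as in [make_hairpin_locus()].
#' @param flank_nt embedded flanking context per side.
#' @return List with `candidate`, `reads` (collapsed), `annotation` (one
#'   BED-like row), and `truth`.
#' @export
make_trna_decoy <- function(params, name = "sim-mir-t1", chrom = "chrSim",
                            locus_start = 1000L, flank_nt = 100L) {
    tlen <- 73L
    # genomic template ends in C: mature tRNA appends the remaining CA
    body <- paste0(rand_dna(tlen - 1L), "C")
    extended <- paste0(rand_dna(flank_nt), body, rand_dna(flank_nt))
    locus <- genomic_interval(chrom, locus_start, locus_start + tlen)
    candidate <- precursor_candidate(name, locus, extended,
                                     extension_offset = flank_nt)

    rlen <- 22L
    top <- paste0(substr(body, tlen - rlen + 3L, tlen), "CA")
    n_top <- max(1L, as.integer(round(params$depth * 0.25)))
    n_rest <- max(0L, params$depth - n_top)
    starts <- sample.int(tlen - rlen + 1L, n_rest, replace = TRUE) - 1L
    seqs <- substring(body, starts + 1L, starts + rlen)
    reads <- collapse_reads(data.frame(
        sequence = c(rep(top, n_top), seqs), count = 1L,
        stringsAsFactors = FALSE))
    annotation <- data.frame(chrom = chrom, start = locus_start,
                             end = locus_start + tlen, class = "tRNA",
                             strand = "+", stringsAsFactors = FALSE)
    truth <- list(name = name, class = "trna_like",
                  expected_reason = "NCRNA_OVERLAP")
    list(candidate = candidate, reads = reads, annotation = annotation,
         truth = truth)
}

#' Generate a fully labeled synthetic cohort
#'
#' Builds `decoy_mix` candidates (prototypical miRNAs plus tRNA-like,
#' low-depth and repeat-derived decoys) on a synthetic chromosome, pools
#' and collapses their reads, and labels every candidate with its expected
#' decision-tree reason code. Some prototypical precursors are placed in
#' cistron pairs (within the 5 kb chaining distance) with EST evidence
#' randomized; isolated prototypical precursors always carry EST evidence.
#' Deterministic: identical `params` (including `seed`) give byte-identical
#' outputs via [write_cohort()].
#'
#' @param params a [sim_params()] object.
#' @param config a [curation_config()] (supplies the flank width).
#' @return A cohort bundle: list with `candidates`, `genome`
#'   (`DNAStringSet`), `bed` (data.frame), `reads`, `annotation`, `est`
#'   (named logical), `truth` (data.frame with `name, class,
#'   expected_reason, arm coordinates`), and `params`.
#' @export
make_cohort <- function(params = sim_params(), config = curation_config()) {
    set.seed(params$seed)
    mix <- params$decoy_mix
    classes <- rep(names(mix), times = as.integer(mix))
    n <- length(classes)
    # shuffle so cistron pairing below is class-blind only within prototypical
    classes <- sample(classes)

    flank <- config$flank_nt
    chrom <- "chrSim"
    pieces <- character(0)
    cursor <- 0L

    candidates <- list()
    truth_rows <- list()
    reads_all <- list()
    annot_rows <- list()
    est <- logical(0)

    proto_idx <- which(classes == "prototypical")
    # every other prototypical is paired with its successor inside 5 kb
    paired_with_next <- rep(FALSE, n)
    if (length(proto_idx) >= 2) {
        firsts <- proto_idx[seq(1, length(proto_idx) - 1, by = 2)]
        nexts <- proto_idx[seq(2, length(proto_idx), by = 2)]
        adjacent <- nexts == firsts + 1L
        paired_with_next[firsts[adjacent]] <- TRUE
    }

    prev_paired <- FALSE
    for (i in seq_len(n)) {
        cls <- classes[i]
        name <- sprintf("sim-mir-%d", i)
        gap <- if (prev_paired) {
            sample(500:3000, 1L)            # inside the cistron distance
        } else {
            sample(8000:12000, 1L)          # safely outside it
        }
        spacer <- rand_dna(gap)
        locus_start <- cursor + gap + flank

        depth <- params$depth
        copies <- 1L
        if (cls == "low_depth") depth <- sample(15:45, 1L)
        if (cls == "repeat_like") copies <- sample(31:60, 1L)

        if (cls == "trna_like") {
            d <- make_trna_decoy(params, name, chrom, locus_start, flank)
            annot_rows[[length(annot_rows) + 1L]] <- d$annotation
            reads <- d$reads
            cand <- d$candidate
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
                name = name, class = cls, expected_reason = "NCRNA_OVERLAP",
                five_start = NA_integer_, five_end = NA_integer_,
                three_start = NA_integer_, three_end = NA_integer_,
                mature_arm = NA_character_, stringsAsFactors = FALSE)
            locus_body <- substr(cand$extended_sequence, flank + 1L,
                                 flank + interval_width(cand$locus))
        } else {
            p_i <- params
            p_i$depth <- depth
            hp <- make_hairpin_locus(p_i, name, chrom, locus_start, flank)
            reads <- simulate_stack(hp$candidate, hp$truth, p_i)
            cand <- hp$candidate
            expected <- switch(cls,
                               prototypical = "ACCEPTED",
                               low_depth = "INSUFFICIENT_READS",
                               repeat_like = "EXCESS_MULTIMAP")
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
                name = name, class = cls, expected_reason = expected,
                five_start = hp$truth$five_arm[1], five_end = hp$truth$five_arm[2],
                three_start = hp$truth$three_arm[1],
                three_end = hp$truth$three_arm[2],
                mature_arm = hp$truth$mature_arm, stringsAsFactors = FALSE)
            locus_body <- hp$truth$hairpin
        }
        cand$genomic_location_count <- copies
        cand$locus <- genomic_interval(chrom, locus_start,
                                       locus_start + nchar(locus_body))
        # rebuild the candidate's flanks from the chromosome context later;
        # the embedded extended sequence is what the pipeline aligns against
        candidates[[name]] <- cand
        reads_all[[name]] <- reads
        est[name] <- if (cls == "prototypical") {
            if (paired_with_next[i] || prev_paired) stats::runif(1) < 0.5 else TRUE
        } else FALSE

        # chromosome assembly: spacer + left flank + locus + right flank is
        # exactly the candidate's extended sequence minus the overlap we
        # re-embed; we simply append spacer + extended and advance
        pieces <- c(pieces, spacer, cand$extended_sequence)
        cursor <- cursor + gap + nchar(cand$extended_sequence)
        # record true genomic placement of the locus within the chromosome
        cand$locus <- genomic_interval(chrom, locus_start,
                                       locus_start + nchar(locus_body))
        candidates[[name]] <- cand

        prev_paired <- paired_with_next[i]
    }

    genome <- Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""),
                                                chrom))
    bed <- do.call(rbind, lapply(candidates, function(p) {
        data.frame(chrom = p$locus$chrom, start = p$locus$start,
                   end = p$locus$end, name = p$name,
                   score = ifelse(p$genomic_location_count > 1L,
                                  p$genomic_location_count, 0L),
                   strand = p$locus$strand, stringsAsFactors = FALSE)
    }))
    rownames(bed) <- NULL

    pooled <- collapse_reads(do.call(rbind, reads_all))
    annotation <- if (length(annot_rows)) {
        a <- do.call(rbind, annot_rows)
        a <- a[order(a$chrom, a$start), , drop = FALSE]
        rownames(a) <- NULL
        class(a) <- c("annotation_track", "data.frame")
        a
    } else NULL

    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL

    structure(list(candidates = candidates, genome = genome, bed = bed,
                   reads = pooled, annotation = annotation, est = est,
                   truth = truth, params = params),
              class = "sim_cohort")
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits exactly the formats the readers consume: precursor FASTA
#' (annotated loci), genome FASTA, BED6 loci (score column = genomic copy
#' count), collapsed reads TSV, ncRNA annotation BED6, EST flag TSV, and
#' the truth table TSV.
#'
#' @param cohort a [make_cohort()] bundle.
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(precursors = file.path(dir, "precursors.fa"),
               genome = file.path(dir, "genome.fa"),
               bed = file.path(dir, "loci.bed"),
               reads = file.path(dir, "reads.tsv"),
               annotation = file.path(dir, "annotation.bed"),
               est = file.path(dir, "est.tsv"),
               truth = file.path(dir, "truth.tsv"))

    loci_seqs <- Biostrings::DNAStringSet(vapply(cohort$candidates, function(p) {
        substr(p$extended_sequence, p$extension_offset + 1L,
               p$extension_offset + interval_width(p$locus))
    }, ""))
    Biostrings::writeXStringSet(loci_seqs, paths["precursors"])
    Biostrings::writeXStringSet(cohort$genome, paths["genome"])

    write.table(cohort$bed, paths["bed"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write_collapsed_reads(cohort$reads, paths["reads"])
    if (!is.null(cohort$annotation)) {
        a <- cohort$annotation
        write.table(data.frame(a$chrom, a$start, a$end, a$class, 0L, a$strand),
                    paths["annotation"], sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    } else {
        file.create(paths["annotation"])
    }
    write.table(data.frame(names(cohort$est), as.integer(cohort$est)),
                paths["est"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(paths)
}
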