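# Fixtures built in code: designed duplexes with controlled overhangs, a
# candidate wrapper, and stacks assembled from explicit read spans.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A designed hairpin whose only pairable letters sit in the G/C duplex
# core: overhang tails and the loop are all-A, so base-pair maximization
# recovers exactly the designed register and the measured overhangs are
# exact by construction.
designed_duplex <- function(core_len = 20L, overhang = 2L, loop = 13L,
                            arm_len = core_len + overhang) {
    core <- rand_seq(core_len, alphabet = c("G", "C"))
    arm5 <- paste0(core, strrep("A", overhang))
    arm3 <- paste0(dna_revcomp_t(core), strrep("A", overhang))
    seq <- paste0(arm5, strrep("A", loop), arm3)
    list(seq = seq,
         five = c(0L, nchar(arm5)),
         three = c(nchar(arm5) + loop, nchar(arm5) + loop + nchar(arm3)))
}

dna_revcomp_t <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# wrap a bare sequence (plus inert all-A flanks) into a candidate
as_candidate <- function(seq, name = "hsa-mir-900", flank = 30L,
                         chrom = "chrT", start = 1000L, strand = "+",
                         copies = 1L, cistron_id = NA_character_,
                         est = FALSE) {
    ext <- paste0(strrep("A", flank), seq, strrep("A", flank))
    precursor_candidate(name,
                        genomic_interval(chrom, start, start + nchar(seq),
                                         strand),
                        ext, extension_offset = flank,
                        genomic_location_count = copies,
                        cistron_id = cistron_id, est_evidence = est)
}

arm_call_fixture <- function(five, three, spacing = NULL,
                             five_fraction = 0.5, bimodal = TRUE) {
    structure(list(five_arm = five, three_arm = three,
                   spacing = if (is.null(spacing) && !is.null(three)) {
                       three[1] - five[2]
                   } else spacing,
                   five_fraction = five_fraction,
                   three_fraction = 1 - five_fraction,
                   bimodal = bimodal, five_end_mode_share = 1,
                   outside_fraction = 0, diagnostics = character()),
              class = "arm_call")
}

hairpin_ok_fixture <- function(ok = TRUE) {
    structure(list(hairpin_ok = ok, diagnostics = character()),
              class = "hairpin_check")
}

# a stack built from explicit (offset, length, count) spans over a random
# template; spans become exact-substring reads so alignment is trivial
stack_from_spans <- function(spans, template_len = 300L, template = NULL,
                             candidate = NULL, config = curation_config()) {
    if (is.null(template)) {
        template <- rand_seq(template_len)
    }
    if (is.null(candidate)) {
        candidate <- precursor_candidate(
            "hsa-mir-901", genomic_interval("chrT", 0L, nchar(template)),
            template, extension_offset = 0L)
    }
    reads <- data.frame(
        sequence = substring(candidate$extended_sequence,
                             spans$offset + 1L,
                             spans$offset + spans$len),
        count = spans$count, stringsAsFactors = FALSE)
    reads <- collapse_reads(reads)
    aln <- resolve_multimap(align_reads(reads, list(candidate), config))
    list(candidate = candidate,
         stack = build_stack(candidate, aln, config))
}

# known mature sequences of a real seed family: identical multi-copy
# members plus a paralog differing only 3' of the seed region
fixture_mir1_family <- function() {
    c("hsa-miR-1-1" = "TGGAATGTAAAGAAGTATGTAT",
      "hsa-miR-1-2" = "TGGAATGTAAAGAAGTATGTAT",
      "hsa-miR-206" = "TGGAATGTAAGGAAGTGTGTGG")
}
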