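#' Genomic interval
#'
#' Coordinates are 0-based half-open (BED-native) throughout the package;
#' 1-based closed coordinates appear only in rendered human-readable views.
#'
#' @param chrom chromosome/contig identifier.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A `genomic_interval` object.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
    start <- as.integer(start); end <- as.integer(end)
    if (is.na(start) || is.na(end) || start < 0L || start >= end) {
        stop("invalid interval: need 0 <= start < end", call. = FALSE)
    }
    if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
    structure(list(chrom = as.character(chrom), start = start, end = end,
                   strand = strand),
              class = "genomic_interval")
}

interval_width <- function(x) x$end - x$start

#' Candidate precursor hairpin locus
#'
#' Carries the flank-extended sequence used for read alignment and secondary
#' structure, plus the bookkeeping the decision tree consumes: genomic copy
#' count, cistron membership, and EST expression evidence.
#'
#' @param name precursor identifier, e.g. `"hsa-mir-125b-1"`.
#' @param locus [genomic_interval()] of the annotated precursor.
#' @param extended_sequence DNA string covering the locus plus up to
#'   `flank_nt` of context each side (truncated at contig edges). `U` is
#'   accepted on input and canonicalized to `T`.
#' @param extension_offset 0-based position of the locus start within
#'   `extended_sequence`.
#' @param genomic_location_count number of genomic copies of the precursor.
#' @param cistron_id cluster membership identifier or `NA`.
#' @param est_evidence logical EST expression-evidence flag.
#' @return A `precursor_candidate` object.
#' @export
precursor_candidate <- function(name, locus, extended_sequence,
                                extension_offset = 0L,
                                genomic_location_count = 1L,
                                cistron_id = NA_character_,
                                est_evidence = FALSE) {
    seq <- canonical_dna(extended_sequence)
    extension_offset <- as.integer(extension_offset)
    if (extension_offset < 0L || extension_offset >= nchar(seq)) {
        stop("extension_offset outside extended_sequence for ", name, call. = FALSE)
    }
    if (grepl("[^ACGTN]", seq)) {
        stop("extended_sequence of ", name, " contains non-ACGTN characters",
             call. = FALSE)
    }
    structure(list(name = as.character(name), locus = locus,
                   extended_sequence = seq,
                   extension_offset = extension_offset,
                   genomic_location_count = as.integer(genomic_location_count),
                   cistron_id = as.character(cistron_id),
                   est_evidence = isTRUE(est_evidence)),
              class = "precursor_candidate")
}

#' @export
print.precursor_candidate <- function(x, ...) {
    cat(sprintf("<precursor_candidate %s %s:%d-%d(%s) ext=%dnt offset=%d copies=%d>\n",
                x$name, x$locus$chrom, x$locus$start, x$locus$end,
                x$locus$strand, nchar(x$extended_sequence),
                x$extension_offset, x$genomic_location_count))
    invisible(x)
}

# uppercase DNA with U -> T; the reverse conversion happens only at folding
canonical_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

dna_revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Natural (alphanumeric-aware) ordering of identifiers
#'
#' Digit runs compare numerically so that `mir-9 < mir-21 < mir-125`, as the
#' "lowest alpha-numeric member" naming rule requires.
#'
#' @param x character vector of identifiers.
#' @return An integer permutation ordering `x`.
#' @export
natural_order <- function(x) {
    padded <- x
    m <- gregexpr("[0-9]+", padded)
    regmatches(padded, m) <- lapply(regmatches(padded, m), function(v) {
        if (!length(v)) return(v)
        sprintf("%012d", as.numeric(v))
    })
    order(padded, x)
}

ncrna_classes <- function() {
    c("tRNA", "rRNA", "snoRNA", "snRNA", "other_ncRNA", "miRNA")
}
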