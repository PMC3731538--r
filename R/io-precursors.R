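#' Read candidate precursors from FASTA + BED6
#'
#' FASTA record names must match the BED name column one-to-one. When a
#' genome FASTA is supplied, each precursor sequence is re-extracted from the
#' genome together with `flank_nt` nucleotides of context on each side
#' (truncated at contig edges, with `extension_offset` adjusted); minus-strand
#' loci are reverse-complemented so the extended sequence always reads
#' 5' to 3'. Without a genome the FASTA sequence is used as-is with
#' `extension_offset = 0`. The BED score column, when positive, is read as
#' the genomic copy count of the precursor (absent or 0 means a single
#' location).
#'
#' @param fasta_path precursor FASTA.
#' @param bed_path BED6 of precursor loci (name column matches FASTA).
#' @param genome_path optional genome FASTA for flank extraction.
#' @param config a [curation_config()].
#' @return A named list of [precursor_candidate()] objects, in BED order.
#' @export
read_precursor_fasta <- function(fasta_path, bed_path, genome_path = NULL,
                                 config = curation_config()) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    bed <- read_bed6(bed_path)

    orphans_bed <- setdiff(bed$name, names(seqs))
    orphans_fa <- setdiff(names(seqs), bed$name)
    if (length(orphans_bed) || length(orphans_fa)) {
        stop("FASTA/BED name mismatch; missing from FASTA: [",
             paste(orphans_bed, collapse = ", "), "]; missing from BED: [",
             paste(orphans_fa, collapse = ", "), "]", call. = FALSE)
    }
    if (anyDuplicated(bed$name)) {
        stop("duplicated precursor names in BED: ",
             paste(unique(bed$name[duplicated(bed$name)]), collapse = ", "),
             call. = FALSE)
    }

    genome <- NULL
    if (!is.null(genome_path)) {
        genome <- Biostrings::readDNAStringSet(genome_path)
        names(genome) <- sub("\\s.*$", "", names(genome))
    }

    out <- vector("list", nrow(bed))
    for (i in seq_len(nrow(bed))) {
        rec <- bed[i, ]
        locus <- genomic_interval(rec$chrom, rec$start, rec$end, rec$strand)
        count <- if (!is.na(rec$score) && rec$score > 0) rec$score else 1L
        if (is.null(genome)) {
            out[[i]] <- precursor_candidate(
                rec$name, locus,
                as.character(seqs[[rec$name]]),
                extension_offset = 0L,
                genomic_location_count = count)
        } else {
            if (!rec$chrom %in% names(genome)) {
                stop("BED contig not in genome: ", rec$chrom, call. = FALSE)
            }
            clen <- Biostrings::width(genome[rec$chrom])
            if (rec$end > clen) {
                stop("BED interval off contig for ", rec$name, call. = FALSE)
            }
            ext_start <- max(0L, rec$start - config$flank_nt)
            ext_end <- min(clen, rec$end + config$flank_nt)
            ext <- as.character(Biostrings::subseq(genome[[rec$chrom]],
                                                   ext_start + 1L, ext_end))
            if (rec$strand == "-") {
                ext <- dna_revcomp(ext)
                offset <- ext_end - rec$end
            } else {
                offset <- rec$start - ext_start
            }
            out[[i]] <- precursor_candidate(
                rec$name, locus, ext,
                extension_offset = offset,
                genomic_location_count = count)
        }
    }
    names(out) <- bed$name
    out
}

# BED6 via rtracklayer; returns a 0-based half-open data.frame
read_bed6 <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    score <- if ("score" %in% names(S4Vectors::mcols(gr))) {
        as.integer(S4Vectors::mcols(gr)$score)
    } else rep(NA_integer_, length(gr))
    data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = BiocGenerics::start(gr) - 1L,
        end = BiocGenerics::end(gr),
        name = as.character(S4Vectors::mcols(gr)$name),
        score = score,
        strand = strand,
        stringsAsFactors = FALSE)
}

#' Read an ncRNA annotation track (BED6, class label in the name column)
#'
#' Interval class labels must come from the closed vocabulary
#' `tRNA, rRNA, snoRNA, snRNA, other_ncRNA, miRNA`. Intervals are returned
#' sorted by chromosome and start.
#'
#' @param path BED6 file; the name column carries the ncRNA class.
#' @return An `annotation_track` data.frame with columns
#'   `chrom,start,end,class,strand` (0-based half-open).
#' @export
read_annotation_track <- function(path) {
    bed <- read_bed6(path)
    bad <- setdiff(unique(bed$name), ncrna_classes())
    if (length(bad)) {
        stop("unknown ncRNA class label(s): ", paste(bad, collapse = ", "),
             "; expected one of ", paste(ncrna_classes(), collapse = ", "),
             call. = FALSE)
    }
    track <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                        class = bed$name, strand = bed$strand,
                        stringsAsFactors = FALSE)
    track <- track[order(track$chrom, track$start, track$end), , drop = FALSE]
    rownames(track) <- NULL
    class(track) <- c("annotation_track", "data.frame")
    track
}

#' Read per-precursor EST expression-evidence flags
#'
#' @param path TSV with two columns: precursor name and 0/1 flag.
#' @return A named logical vector.
#' @export
read_est_flags <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("name", "flag"),
                     colClasses = c("character", "integer"))
    if (any(!df$flag %in% c(0L, 1L))) {
        stop("EST flags must be 0 or 1", call. = FALSE)
    }
    setNames(df$flag == 1L, df$name)
}
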