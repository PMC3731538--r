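#' Read collapsed small RNA reads
#'
#' Accepts either a two-column TSV (`sequence<TAB>count`) or a FASTA whose
#' headers end in `_x<COUNT>` (e.g. `>r1_x7`). Duplicate sequences are merged
#' with counts summed, and records are returned in deterministic order:
#' descending count, then lexicographic sequence. Re-reading the output of
#' [write_collapsed_reads()] reproduces identical records.
#'
#' @param path input file.
#' @return A `collapsed_reads` data.frame with columns `sequence`, `count`.
#' @export
read_collapsed_reads <- function(path) {
    first <- readLines(path, n = 1L)
    if (length(first) && startsWith(first, ">")) {
        # BStringSet: RNA-alphabet reads (U) are canonicalized below
        seqs <- Biostrings::readBStringSet(path)
        headers <- names(seqs)
        m <- regmatches(headers, regexpr("_x([0-9]+)$", headers))
        if (length(m) != length(headers)) {
            bad <- which(!grepl("_x[0-9]+$", headers))[1]
            stop("FASTA read header lacks _x<count> suffix (record ", bad, "): ",
                 headers[bad], call. = FALSE)
        }
        counts <- as.integer(sub("_x", "", m))
        df <- data.frame(sequence = as.character(seqs), count = counts,
                         stringsAsFactors = FALSE)
        lineno <- seq_len(nrow(df))
    } else {
        df <- read.table(path, sep = "\t", header = FALSE,
                         col.names = c("sequence", "count"),
                         colClasses = c("character", "integer"),
                         comment.char = "#")
        lineno <- seq_len(nrow(df))
    }
    if (any(is.na(df$count) | df$count < 1L)) {
        bad <- which(is.na(df$count) | df$count < 1L)[1]
        stop("nonpositive read count at record ", lineno[bad], call. = FALSE)
    }
    df$sequence <- canonical_dna(df$sequence)
    if (any(!nzchar(df$sequence)) || any(grepl("[^ACGTN]", df$sequence))) {
        stop("read sequences must be non-empty over the A,C,G,T/U,N alphabet",
             call. = FALSE)
    }
    collapse_reads(df)
}

#' Collapse a sequence/count table into canonical collapsed reads
#'
#' Merges duplicate sequences (counts summed) and orders records by
#' descending count then sequence.
#'
#' @param df data.frame with `sequence` and `count` columns.
#' @return A `collapsed_reads` data.frame.
#' @export
collapse_reads <- function(df) {
    agg <- aggregate(count ~ sequence, data = df, FUN = sum)
    agg <- agg[order(-agg$count, agg$sequence), , drop = FALSE]
    rownames(agg) <- NULL
    agg <- agg[, c("sequence", "count")]
    agg$count <- as.integer(agg$count)
    class(agg) <- c("collapsed_reads", "data.frame")
    agg
}

#' Write collapsed reads as sequence/count TSV
#'
#' @param reads a `collapsed_reads` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_collapsed_reads <- function(reads, path) {
    write.table(reads[, c("sequence", "count")], path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}
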