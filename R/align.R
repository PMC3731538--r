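#' Align one collapsed read to a candidate precursor
#'
#' Semi-global alignment of the read within the candidate's extended
#' sequence, allowing up to `max_errors` unit-cost edits (mismatches,
#' insertions, deletions) in total -- the error budget that accommodates 3'
#' non-templated A/U additions and G-to-A changes from dsRNA deamination.
#' Only the forward strand is searched (directional libraries). Among all
#' placements the minimal achievable error count wins; ties within one
#' precursor are resolved to the leftmost start, then the shortest reference
#' span, so output is deterministic.
#'
#' @param read a single-row `collapsed_reads` entry, or a read sequence
#'   string (count taken as 1).
#' @param candidate a [precursor_candidate()].
#' @param config a [curation_config()].
#' @return A data.frame of alignments with columns `sequence, count,
#'   precursor, offset, end, errors, edits` (0-based half-open coordinates;
#'   `edits` is a comma-joined `pos:op:base` string in read coordinates).
#'   Zero rows when the read does not map within the error budget.
#' @export
align_read <- function(read, candidate, config = curation_config()) {
    if (is.character(read)) read <- data.frame(sequence = read, count = 1L)
    seq <- canonical_dna(read$sequence[1])
    if (nchar(seq) < 16L) {
        stop("reads shorter than 16 nt are not aligned (read: ", seq, ")",
             call. = FALSE)
    }
    hit <- align_one(seq, candidate$extended_sequence, config$max_errors)
    if (is.null(hit)) return(empty_alignments())
    data.frame(sequence = seq, count = as.integer(read$count[1]),
               precursor = candidate$name,
               offset = hit$offset, end = hit$end, errors = hit$errors,
               edits = hit$edits, stringsAsFactors = FALSE)
}

empty_alignments <- function() {
    data.frame(sequence = character(), count = integer(),
               precursor = character(), offset = integer(), end = integer(),
               errors = integer(), edits = character(),
               stringsAsFactors = FALSE)
}

# exact placement via fixed-string search, else the C-level edit DP
align_one <- function(seq, text, max_errors) {
    p <- regexpr(seq, text, fixed = TRUE)
    if (p > 0L) {
        return(list(offset = as.integer(p) - 1L,
                    end = as.integer(p) - 1L + nchar(seq),
                    errors = 0L, edits = ""))
    }
    res <- cpp_align_read(seq, text, as.integer(max_errors))
    if (is.null(res)) return(NULL)
    ops <- c("mismatch", "insertion", "deletion")[res$edit_op]
    edits <- paste(res$edit_pos, ops, res$edit_base, sep = ":", collapse = ",")
    list(offset = as.integer(res$offset), end = as.integer(res$end),
         errors = as.integer(res$errors), edits = edits)
}

#' Parse an alignment edit string into a table
#'
#' Alignment rows carry their edit operations as a compact comma-joined
#' `pos:op:base` string in read coordinates; this expands it.
#'
#' @param edits the `edits` field of one alignment row.
#' @return data.frame with columns `pos`, `op` (`mismatch`, `insertion`,
#'   `deletion`), `base`.
#' @export
parse_edits <- function(edits) {
    if (!nzchar(edits)) {
        return(data.frame(pos = integer(), op = character(),
                          base = character(), stringsAsFactors = FALSE))
    }
    parts <- strsplit(strsplit(edits, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(pos = as.integer(vapply(parts, `[`, "", 1)),
               op = vapply(parts, `[`, "", 2),
               base = vapply(parts, `[`, "", 3),
               stringsAsFactors = FALSE)
}

#' Align a set of collapsed reads against all candidate precursors
#'
#' The workhorse behind the cohort pipeline. Exact placements are found by
#' fixed-string search; reads without an exact hit on a given precursor are
#' screened with a pigeonhole filter (a read within `max_errors` edits of a
#' window must share one of `max_errors + 1` exact chunks with it) before the
#' edit-distance alignment runs.
#'
#' @param reads a `collapsed_reads` data.frame.
#' @param candidates list of [precursor_candidate()] objects.
#' @param config a [curation_config()].
#' @return Alignment data.frame as in [align_read()], all reads x all
#'   precursors, unresolved for multi-mapping (see [resolve_multimap()]).
#' @export
align_reads <- function(reads, candidates, config = curation_config()) {
    texts <- vapply(candidates, `[[`, "", "extended_sequence")
    cnames <- vapply(candidates, `[[`, "", "name")
    nerr <- config$max_errors
    rows <- vector("list", nrow(reads) * 2L)
    nrow_out <- 0L

    for (i in seq_len(nrow(reads))) {
        seq <- reads$sequence[i]
        if (nchar(seq) < 16L) next
        cnt <- reads$count[i]

        exact <- regexpr(seq, texts, fixed = TRUE)
        hit_exact <- which(exact > 0L)
        for (ci in hit_exact) {
            nrow_out <- nrow_out + 1L
            rows[[nrow_out]] <- list(seq, cnt, cnames[ci],
                                     as.integer(exact[ci]) - 1L,
                                     as.integer(exact[ci]) - 1L + nchar(seq),
                                     0L, "")
        }

        # pigeonhole screen for inexact placements
        rest <- setdiff(seq_along(texts), hit_exact)
        if (length(rest) && nerr > 0L) {
            k <- nchar(seq) %/% (nerr + 1L)
            chunk_hits <- logical(length(texts))
            for (c_i in seq_len(nerr + 1L)) {
                chunk <- substr(seq, (c_i - 1L) * k + 1L, c_i * k)
                chunk_hits <- chunk_hits | (regexpr(chunk, texts, fixed = TRUE) > 0L)
            }
            for (ci in intersect(rest, which(chunk_hits))) {
                hit <- align_one(seq, texts[ci], nerr)
                if (is.null(hit)) next
                nrow_out <- nrow_out + 1L
                rows[[nrow_out]] <- list(seq, cnt, cnames[ci], hit$offset,
                                         hit$end, hit$errors, hit$edits)
            }
        }
    }

    if (nrow_out == 0L) return(empty_alignments())
    out <- do.call(rbind, lapply(rows[seq_len(nrow_out)], function(r) {
        data.frame(sequence = r[[1]], count = r[[2]], precursor = r[[3]],
                   offset = r[[4]], end = r[[5]], errors = r[[6]],
                   edits = r[[7]], stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Resolve multi-mapping reads to their lowest-error placements
#'
#' Each read is retained only at the precursors achieving its global minimum
#' error count; the full read count is credited at every tied best location,
#' and surviving multi-location reads are flagged `multimapped`.
#'
#' @param alignments alignment data.frame from [align_reads()].
#' @return The filtered data.frame with an added logical `multimapped`
#'   column.
#' @export
resolve_multimap <- function(alignments) {
    if (!nrow(alignments)) {
        out <- empty_alignments()
        out$multimapped <- logical()
        return(out)
    }
    best <- tapply(alignments$errors, alignments$sequence, min)
    keep <- alignments$errors == best[alignments$sequence]
    out <- alignments[keep, , drop = FALSE]
    nloc <- table(out$sequence)
    out$multimapped <- as.vector(nloc[out$sequence] > 1L)
    rownames(out) <- NULL
    out
}

#' Build the per-precursor read stack
#'
#' Collects the alignments assigned to one candidate into a stack with
#' error-tier-resolved positional coverage. Coverage row `t` (`e0`, `e1`,
#' `e2`, ...) accumulates the counts of reads aligned with at most `t`
#' errors, so the last row is the combined coverage and rows are positionwise
#' monotone.
#'
#' @param candidate a [precursor_candidate()].
#' @param alignments alignment rows assigned to this candidate.
#' @param config a [curation_config()].
#' @return A `read_stack`: list with `precursor_name`, `alignments` (sorted
#'   by errors, then descending count, then offset), `coverage` (matrix,
#'   tiers x positions), `total_count`, `nonredundant_count`.
#' @export
build_stack <- function(candidate, alignments, config = curation_config()) {
    L <- nchar(candidate$extended_sequence)
    if (nrow(alignments)) {
        alignments <- alignments[alignments$precursor == candidate$name, ,
                                 drop = FALSE]
    }
    if (nrow(alignments) &&
        (any(alignments$offset < 0L) || any(alignments$end > L) ||
         any(alignments$offset >= alignments$end))) {
        stop("internal consistency error: alignment outside ", candidate$name,
             call. = FALSE)
    }
    ntier <- config$max_errors + 1L
    cov <- matrix(0, nrow = ntier, ncol = L,
                  dimnames = list(paste0("e", seq_len(ntier) - 1L), NULL))
    if (nrow(alignments)) {
        ord <- order(alignments$errors, -alignments$count, alignments$offset,
                     alignments$sequence)
        alignments <- alignments[ord, , drop = FALSE]
        rownames(alignments) <- NULL
        for (i in seq_len(nrow(alignments))) {
            tiers <- (alignments$errors[i] + 1L):ntier
            span <- (alignments$offset[i] + 1L):alignments$end[i]
            cov[tiers, span] <- cov[tiers, span] + alignments$count[i]
        }
    }
    structure(list(precursor_name = candidate$name,
                   alignments = alignments,
                   coverage = cov,
                   total_count = as.integer(sum(alignments$count)),
                   nonredundant_count = length(unique(alignments$sequence))),
              class = "read_stack")
}

#' @export
print.read_stack <- function(x, ...) {
    cat(sprintf("<read_stack %s: %d alignments, %d reads (%d distinct)>\n",
                x$precursor_name, nrow(x$alignments), x$total_count,
                x$nonredundant_count))
    invisible(x)
}

#' Export assigned alignments as SAM text
#'
#' Minimal single-reference SAM (flag 0, `NM` tag carrying the error count)
#' for inspection in standard viewers. Not load-bearing for curation.
#'
#' @param stack a `read_stack`.
#' @param candidate the matching [precursor_candidate()].
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_stack_sam <- function(stack, candidate, path) {
    L <- nchar(candidate$extended_sequence)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", candidate$name, L)), con)
    aln <- stack$alignments
    for (i in seq_len(nrow(aln))) {
        # cigar spelled as a plain match span; edits are carried by NM
        writeLines(sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                           sprintf("read%05d_x%d", i, aln$count[i]),
                           candidate$name, aln$offset[i] + 1L,
                           nchar(aln$sequence[i]), aln$sequence[i],
                           aln$errors[i]), con)
    }
    invisible(path)
}
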