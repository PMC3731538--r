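#' Render a monospace read-alignment view of a precursor
#'
#' The classic curation display: the extended precursor sequence, a
#' coverage histogram on a log4 scale, and beneath it the top five reads
#' per arm at their alignment offsets, grouped by error tier. The mature
#' arm is tagged `[mature]`/`[5p]` and the star arm `[star]`/`[3p]` when an
#' arm call is supplied.
#'
#' Histogram quantization: the relative read frequency `f` at a position
#' (combined coverage over total read count) maps to glyph level
#' `ceil(4 + log4(f))` clamped to 1..4 for `f > 0`, so any covered position
#' shows at least one level and `f >= 1/4` shows the tallest glyph. Levels
#' render as `. : | #`.
#'
#' @param stack a `read_stack` belonging to `candidate`.
#' @param candidate the [precursor_candidate()].
#' @param arms optional `arm_call` used to tag arms.
#' @param config a [curation_config()].
#' @return A single string (lines joined with newlines); also works with
#'   `cat()`.
#' @export
render_alignment_view <- function(stack, candidate, arms = NULL,
                                  config = curation_config()) {
    seq <- candidate$extended_sequence
    L <- nchar(seq)
    lines <- c(sprintf(">%s %s:%d-%d(%s) reads=%d distinct=%d",
                       candidate$name, candidate$locus$chrom,
                       candidate$locus$start, candidate$locus$end,
                       candidate$locus$strand, stack$total_count,
                       stack$nonredundant_count),
               seq)

    if (stack$total_count > 0) {
        cov <- stack$coverage[nrow(stack$coverage), ]
        f <- cov / stack$total_count
        lvl <- integer(L)
        pos <- f > 0
        lvl[pos] <- pmin(4L, pmax(1L, ceiling(4 + log(f[pos], base = 4))))
        glyphs <- c(" ", ".", ":", "|", "#")[lvl + 1L]
        lines <- c(lines, paste(glyphs, collapse = ""))
    }

    aln <- stack$alignments
    if (!is.null(aln) && nrow(aln)) {
        tag_of <- function(offsets) {
            if (is.null(arms)) return(rep("", length(offsets)))
            des <- assign_designations(arms, config)
            lab <- c(five = switch(des[["five"]], mature = "[mature]",
                                   star = "[star]", "5p" = "[5p]"),
                     three = switch(des[["three"]], mature = "[mature]",
                                    star = "[star]", "3p" = "[3p]"))
            out <- rep("", length(offsets))
            sel5 <- arm_assigned(data.frame(offset = offsets), arms$five_arm)
            out[sel5] <- lab[["five"]]
            if (!is.null(arms$three_arm)) {
                sel3 <- arm_assigned(data.frame(offset = offsets), arms$three_arm)
                out[sel3 & !sel5] <- lab[["three"]]
            }
            out
        }
        for (tier in sort(unique(aln$errors))) {
            at <- aln[aln$errors == tier, , drop = FALSE]
            lines <- c(lines, sprintf("# errors: %d", tier))
            shown <- top_per_arm(at, arms)
            tags <- tag_of(shown$offset)
            for (i in seq_len(nrow(shown))) {
                lines <- c(lines, sprintf("%s%s x%d %s",
                                          strrep(" ", shown$offset[i]),
                                          shown$sequence[i], shown$count[i],
                                          tags[i]))
            }
        }
    }
    paste(lines, collapse = "\n")
}

# top five reads per arm by count (all reads in one group without arms)
top_per_arm <- function(aln, arms) {
    aln <- aln[order(-aln$count, aln$offset, aln$sequence), , drop = FALSE]
    if (is.null(arms) || is.null(arms$three_arm)) {
        return(head(aln, 5L))
    }
    in5 <- arm_assigned(aln, arms$five_arm)
    in3 <- arm_assigned(aln, arms$three_arm) & !in5
    out <- rbind(head(aln[in5, , drop = FALSE], 5L),
                 head(aln[in3, , drop = FALSE], 5L),
                 head(aln[!in5 & !in3, , drop = FALSE], 5L))
    out[order(out$offset, -out$count), , drop = FALSE]
}

#' Write the curation decision report
#'
#' One TSV row per precursor (name, status, reason, key metrics) plus a
#' footer tally per reason code as `# tally` comment lines. Tally values
#' always sum to the number of input precursors, mirroring the structure of
#' a curation summary table.
#'
#' @param decisions list of `curation_decision` objects (or a
#'   [decisions_table()] data.frame).
#' @param path output TSV path.
#' @return The named tally vector (one entry per reason code observed, plus
#'   `accepted`), invisibly.
#' @export
write_decision_report <- function(decisions, path) {
    tab <- if (is.data.frame(decisions)) decisions else decisions_table(decisions)
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write report to ", path,
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    on.exit(close(con))
    if (is.null(tab)) {
        tab <- decisions_table(list())
    }
    if (!is.null(tab) && nrow(tab)) {
        write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
        tally <- c(accepted = sum(tab$status == "accepted"))
        rej <- table(tab$reason[tab$status == "rejected"])
        tally <- c(tally, setNames(as.integer(rej), names(rej)))
    } else {
        writeLines(paste(c("name", "status", "reason"), collapse = "\t"), con)
        tally <- c(accepted = 0L)
    }
    for (k in names(tally)) {
        writeLines(sprintf("# tally\t%s\t%d", k, tally[[k]]), con)
    }
    invisible(tally)
}
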