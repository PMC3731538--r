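#' Detect the bimodal Drosha/Dicer read signature on a stack
#'
#' Canonical processing leaves two sharp read peaks of ~22 nt spaced
#' 10--20 nt apart, one per duplex arm. Peaks are defined by modal 5' start
#' (count-weighted; miRNA 5' ends are more homogeneous than 3' ends, so
#' modes are sharper than coverage maxima), with ties broken toward the
#' smaller position. The first peak is the global modal start; the second is
#' the modal start among reads overlapping the first peak by at most 50% of
#' their aligned length. Each peak spans from its modal start over the
#' count-weighted modal read length of the reads starting there.
#'
#' The verdict is geometric: `bimodal` requires both peak widths within
#' `peak_width_nt +/- peak_width_tol_nt` and the inter-peak spacing within
#' `[peak_spacing_min_nt, peak_spacing_max_nt]`. Failures are listed in
#' `diagnostics`: `UNIMODAL` (no second disjoint peak, or the two candidate
#' peaks overlap, as under uniform tRNA-like tiling), `NO_CLEARANCE`
#' (spacing below the minimum needed to accommodate a loop),
#' `SPACING_OUT_OF_RANGE` (spacing beyond the maximum), `PEAK_TOO_WIDE`
#' (width outside the accepted window). A `FUZZY_FIVE_END` note is appended
#' when fewer than half of the 5'-arm reads share the modal start; it is
#' advisory and never blocks acceptance.
#'
#' @param stack a `read_stack` with `total_count > 0`.
#' @param config a [curation_config()].
#' @return An `arm_call`: list with `five_arm`/`three_arm` intervals
#'   (`c(start, end)`, 0-based half-open in extended coordinates; the 3' arm
#'   may be `NULL`), `spacing`, `five_fraction`, `three_fraction`,
#'   `bimodal`, `five_end_mode_share`, `outside_fraction`, `diagnostics`.
#' @export
call_arms <- function(stack, config = curation_config()) {
    if (stack$total_count <= 0L) {
        stop("call_arms requires a non-empty read stack", call. = FALSE)
    }
    aln <- stack$alignments

    peak1 <- modal_peak(aln)
    ov <- pmax(0L, pmin(aln$end, peak1[2]) - pmax(aln$offset, peak1[1]))
    disjoint <- ov <= 0.5 * (aln$end - aln$offset)
    peak2 <- if (any(disjoint)) modal_peak(aln[disjoint, , drop = FALSE]) else NULL

    if (is.null(peak2) || peak1[1] <= peak2[1]) {
        five <- peak1; three <- peak2
    } else {
        five <- peak2; three <- peak1
    }

    diagnostics <- character()
    spacing <- NA_integer_
    wmin <- config$peak_width_nt - config$peak_width_tol_nt
    wmax <- config$peak_width_nt + config$peak_width_tol_nt

    if (is.null(three)) {
        diagnostics <- c(diagnostics, "UNIMODAL")
    } else {
        spacing <- three[1] - five[2]
        if (spacing < 0L) {
            # overlapping candidate peaks: one smeared mode, not two arms
            diagnostics <- c(diagnostics, "UNIMODAL")
        } else if (spacing < config$peak_spacing_min_nt) {
            diagnostics <- c(diagnostics, "NO_CLEARANCE")
        } else if (spacing > config$peak_spacing_max_nt) {
            diagnostics <- c(diagnostics, "SPACING_OUT_OF_RANGE")
        }
        widths <- c(five[2] - five[1], three[2] - three[1])
        if (any(widths < wmin | widths > wmax)) {
            diagnostics <- c(diagnostics, "PEAK_TOO_WIDE")
        }
    }
    bimodal <- length(diagnostics) == 0L

    in5 <- arm_assigned(aln, five)
    in3 <- if (!is.null(three)) arm_assigned(aln, three) & !in5 else rep(FALSE, nrow(aln))
    c5 <- sum(aln$count[in5]); c3 <- sum(aln$count[in3])
    five_fraction <- if (c5 + c3 > 0) c5 / (c5 + c3) else NA_real_
    three_fraction <- if (c5 + c3 > 0) c3 / (c5 + c3) else NA_real_
    outside_fraction <- 1 - (c5 + c3) / stack$total_count

    five_end_mode_share <- NA_real_
    if (any(in5)) {
        s <- tapply(aln$count[in5], aln$offset[in5], sum)
        five_end_mode_share <- max(s) / sum(s)
        if (five_end_mode_share < 0.5) {
            diagnostics <- c(diagnostics, "FUZZY_FIVE_END")
        }
    }

    structure(list(five_arm = five, three_arm = three, spacing = spacing,
                   five_fraction = five_fraction,
                   three_fraction = three_fraction,
                   bimodal = bimodal,
                   five_end_mode_share = five_end_mode_share,
                   outside_fraction = outside_fraction,
                   diagnostics = diagnostics),
              class = "arm_call")
}

# count-weighted modal 5' start, then count-weighted modal length among the
# reads at that start; ties toward the smaller value
modal_peak <- function(aln) {
    by_start <- tapply(aln$count, aln$offset, sum)
    starts <- as.integer(names(by_start))
    s <- starts[order(-by_start, starts)][1]
    at <- aln[aln$offset == s, , drop = FALSE]
    by_len <- tapply(at$count, at$end - at$offset, sum)
    lens <- as.integer(names(by_len))
    len <- lens[order(-by_len, lens)][1]
    c(s, s + len)
}

# a read belongs to an arm when its 5' start lies within the arm interval
# extended by 2 nt on each side
arm_assigned <- function(aln, arm, slack = 2L) {
    aln$offset >= arm[1] - slack & aln$offset < arm[2] + slack
}

#' @export
print.arm_call <- function(x, ...) {
    fmt <- function(a) if (is.null(a)) "-" else sprintf("[%d,%d)", a[1], a[2])
    cat(sprintf("<arm_call 5p=%s 3p=%s spacing=%s bimodal=%s fractions=%.3f/%.3f>\n",
                fmt(x$five_arm), fmt(x$three_arm),
                ifelse(is.na(x$spacing), "-", x$spacing), x$bimodal,
                x$five_fraction, x$three_fraction))
    if (length(x$diagnostics)) cat("  diagnostics:",
                                   paste(x$diagnostics, collapse = ", "), "\n")
    invisible(x)
}

#' Diagnose a tRNA turnover signature on a read stack
#'
#' tRNAs carry a post-transcriptionally added 3' CCA (the aminoacyl acceptor
#' end) that is absent from the genomic template, so abundant reads ending
#' in a non-templated CCA mark tRNA turnover products misread as miRNAs.
#' The check inspects the single most frequent read: `TRUE` when it ends in
#' CCA and that CCA is not templated at its alignment position (it shows up
#' as 3' edits or extends past the aligned reference span).
#'
#' @param stack a non-empty `read_stack`.
#' @param candidate the matching [precursor_candidate()].
#' @return Logical with an `evidence` attribute describing the call.
#' @export
trna_signature <- function(stack, candidate) {
    aln <- stack$alignments
    if (!nrow(aln)) stop("trna_signature requires a non-empty stack", call. = FALSE)
    top <- aln[order(-aln$count, aln$sequence), , drop = FALSE][1, ]
    seq <- top$sequence
    if (substr(seq, nchar(seq) - 2L, nchar(seq)) != "CCA") {
        return(structure(FALSE, evidence = "top read does not end in CCA"))
    }
    templ <- substr(candidate$extended_sequence, top$end - 2L, top$end)
    if (templ == "CCA") {
        return(structure(FALSE,
                         evidence = "terminal CCA is genome-templated at the alignment position"))
    }
    structure(TRUE, evidence = sprintf(
        "top read (x%d) ends in CCA; template 3' trinucleotide at [%d,%d) is %s",
        top$count, top$end - 3L, top$end, templ))
}

#' Measure 5' and 3' end homogeneity of the called arms
#'
#' For each arm, the count-weighted fraction of its reads sharing the modal
#' 5' start (respectively modal 3' end); arms are then combined by read
#' count. Canonical miRNA processing leaves 5' ends much more homogeneous
#' than 3' ends, so these shares separate miRNAs from turnover ladders.
#' Diagnostic metrics only -- never a hard filter.
#'
#' @param stack a `read_stack`.
#' @param arms an `arm_call` with at least one arm.
#' @return Named numeric vector `c(five_share, three_share)`.
#' @export
end_heterogeneity <- function(stack, arms) {
    aln <- stack$alignments
    arm_list <- Filter(Negate(is.null), list(arms$five_arm, arms$three_arm))
    shares5 <- c(); shares3 <- c(); weights <- c()
    taken <- rep(FALSE, nrow(aln))
    for (arm in arm_list) {
        sel <- arm_assigned(aln, arm) & !taken
        taken <- taken | sel
        if (!any(sel)) next
        a <- aln[sel, , drop = FALSE]
        s5 <- tapply(a$count, a$offset, sum)
        s3 <- tapply(a$count, a$end, sum)
        shares5 <- c(shares5, max(s5) / sum(s5))
        shares3 <- c(shares3, max(s3) / sum(s3))
        weights <- c(weights, sum(a$count))
    }
    if (!length(weights)) return(c(five_share = NA_real_, three_share = NA_real_))
    c(five_share = sum(shares5 * weights) / sum(weights),
      three_share = sum(shares3 * weights) / sum(weights))
}
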