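#' Reason-code vocabulary of the curation decision tree
#'
#' Stable strings, part of the public contract: one code per candidate, with
#' `ACCEPTED` reserved for accepted precursors.
#'
#' @return Character vector of reason codes in rule order.
#' @export
decision_reasons <- function() {
    c("INSUFFICIENT_READS", "LOW_NONREDUNDANT", "EXCESS_MULTIMAP",
      "NCRNA_OVERLAP", "COMPLEMENT_ARTIFACT", "NO_PATTERN_OR_FOLDBACK",
      "NO_EXPRESSION_EVIDENCE", "ACCEPTED")
}

#' Check a candidate locus against an ncRNA annotation track
#'
#' Returns the class of the first annotation interval (in chromosome/start
#' order) that overlaps the precursor locus by at least 50% of the precursor
#' length on the same strand, or `NA` when none does. Candidates sitting on
#' tRNA/snoRNA/rRNA annotation are turnover products, not miRNAs.
#'
#' @param candidate a [precursor_candidate()].
#' @param track an `annotation_track` (see [read_annotation_track()]), or
#'   `NULL`.
#' @return A class label from the track vocabulary, or `NA_character_`.
#' @export
check_ncrna_overlap <- function(candidate, track) {
    if (is.null(track) || !nrow(track)) return(NA_character_)
    loc <- candidate$locus
    same <- track$chrom == loc$chrom & track$strand == loc$strand
    if (!any(same)) return(NA_character_)
    t <- track[same, , drop = FALSE]
    ov <- pmin(t$end, loc$end) - pmax(t$start, loc$start)
    hit <- which(ov >= 0.5 * interval_width(loc))
    if (!length(hit)) return(NA_character_)
    t$class[hit[1]]
}

#' Flag reverse-complement artifacts of already accepted miRNAs
#'
#' Sequencing errors on nearly palindromic miRNA/miRNA* reads can generate
#' spurious calls whose dominant read is the reverse complement of a known
#' mature. `TRUE` when the reverse complement of the candidate's dominant
#' read lies within `max_errors` edits of any accepted mature sequence.
#'
#' @param mature_seq dominant read sequence of the candidate.
#' @param accepted_matures character vector of accepted mature sequences
#'   (empty set returns `FALSE`).
#' @param config a [curation_config()].
#' @return Logical.
#' @export
check_complement_artifact <- function(mature_seq, accepted_matures,
                                      config = curation_config()) {
    if (!length(accepted_matures)) return(FALSE)
    rc <- dna_revcomp(canonical_dna(mature_seq))
    d <- adist(rc, canonical_dna(accepted_matures))
    any(d <= config$max_errors)
}

#' Apply the miRNA acceptance decision tree
#'
#' Rules are applied in a fixed order and the first failure wins, so every
#' candidate carries exactly one reason code:
#' \enumerate{
#'   \item pooled read count below `min_read_count` -> `INSUFFICIENT_READS`
#'   \item distinct read sequences below `min_nonredundant` ->
#'     `LOW_NONREDUNDANT`
#'   \item more than `max_genomic_locations` genomic copies and no cistron
#'     membership -> `EXCESS_MULTIMAP`
#'   \item overlap with a non-miRNA ncRNA annotation, or a tRNA CCA
#'     signature -> `NCRNA_OVERLAP`
#'   \item reverse-complement artifact of an accepted mature ->
#'     `COMPLEMENT_ARTIFACT`
#'   \item missing bimodal read pattern or failed hairpin/overhang check ->
#'     `NO_PATTERN_OR_FOLDBACK`
#'   \item neither cistron membership nor EST evidence ->
#'     `NO_EXPRESSION_EVIDENCE`
#'   \item otherwise `ACCEPTED`.
#' }
#' Cheap count filters run first and expression evidence last; the order is
#' part of the contract because any single-reason tally depends on it.
#'
#' @param candidate a [precursor_candidate()] (with `cistron_id` and
#'   `est_evidence` filled in).
#' @param stack the candidate's `read_stack` (may be `NULL` when no reads
#'   aligned).
#' @param arms the `arm_call`, or `NULL` if the stack was empty.
#' @param structure the completed `hairpin_check`, or `NULL` when no
#'   bimodal pattern was found.
#' @param track optional `annotation_track`.
#' @param config a [curation_config()].
#' @param accepted_matures mature sequences accepted so far (for the
#'   complement-artifact rule).
#' @return A `curation_decision`: list with `precursor_name`, `status`,
#'   `reason`, and a `metrics` snapshot.
#' @export
decide <- function(candidate, stack, arms = NULL, structure = NULL,
                   track = NULL, config = curation_config(),
                   accepted_matures = character()) {
    total <- if (is.null(stack)) 0L else stack$total_count
    nonred <- if (is.null(stack)) 0L else stack$nonredundant_count

    trna <- FALSE
    dominant <- NA_character_
    if (!is.null(stack) && nrow(stack$alignments)) {
        trna <- isTRUE(as.logical(trna_signature(stack, candidate)))
        top <- stack$alignments[order(-stack$alignments$count,
                                      stack$alignments$sequence), , drop = FALSE]
        dominant <- top$sequence[1]
    }
    overlap_class <- check_ncrna_overlap(candidate, track)
    bimodal <- !is.null(arms) && isTRUE(arms$bimodal)
    hairpin_ok <- !is.null(structure) && isTRUE(structure$hairpin_ok)

    reason <- if (total < config$min_read_count) {
        "INSUFFICIENT_READS"
    } else if (nonred < config$min_nonredundant) {
        "LOW_NONREDUNDANT"
    } else if (candidate$genomic_location_count > config$max_genomic_locations &&
               is.na(candidate$cistron_id)) {
        "EXCESS_MULTIMAP"
    } else if ((!is.na(overlap_class) && overlap_class != "miRNA") || trna) {
        "NCRNA_OVERLAP"
    } else if (!is.na(dominant) &&
               check_complement_artifact(dominant, accepted_matures, config)) {
        "COMPLEMENT_ARTIFACT"
    } else {
        if (is.null(arms)) {
            stop("internal error: candidate ", candidate$name,
                 " passed the count filters without an arm call", call. = FALSE)
        }
        if (isTRUE(arms$bimodal) && is.null(structure)) {
            stop("internal error: candidate ", candidate$name,
                 " is bimodal but has no structure check", call. = FALSE)
        }
        if (!(bimodal && hairpin_ok)) {
            "NO_PATTERN_OR_FOLDBACK"
        } else if (is.na(candidate$cistron_id) && !candidate$est_evidence) {
            "NO_EXPRESSION_EVIDENCE"
        } else {
            "ACCEPTED"
        }
    }

    structure(list(
        precursor_name = candidate$name,
        status = if (reason == "ACCEPTED") "accepted" else "rejected",
        reason = reason,
        metrics = list(
            total_count = total,
            nonredundant_count = nonred,
            genomic_location_count = candidate$genomic_location_count,
            bimodal = bimodal,
            hairpin_ok = hairpin_ok,
            five_fraction = if (is.null(arms)) NA_real_ else arms$five_fraction,
            three_fraction = if (is.null(arms)) NA_real_ else arms$three_fraction,
            trna_signature = trna,
            ncrna_class = overlap_class,
            dominant_read = dominant,
            cistron_id = candidate$cistron_id,
            est_evidence = candidate$est_evidence)),
        class = "curation_decision")
}

#' @export
print.curation_decision <- function(x, ...) {
    cat(sprintf("<curation_decision %s: %s (%s)>\n", x$precursor_name,
                x$status, x$reason))
    invisible(x)
}

#' Collect curation decisions into a data.frame
#'
#' @param decisions list of `curation_decision` objects.
#' @return One row per precursor: name, status, reason and key metrics.
#' @export
decisions_table <- function(decisions) {
    if (inherits(decisions, "curation_decision")) decisions <- list(decisions)
    do.call(rbind, lapply(decisions, function(d) {
        m <- d$metrics
        data.frame(name = d$precursor_name, status = d$status,
                   reason = d$reason, total_count = m$total_count,
                   nonredundant_count = m$nonredundant_count,
                   genomic_location_count = m$genomic_location_count,
                   bimodal = m$bimodal, hairpin_ok = m$hairpin_ok,
                   five_fraction = m$five_fraction,
                   three_fraction = m$three_fraction,
                   trna_signature = m$trna_signature,
                   cistron_id = m$cistron_id,
                   est_evidence = m$est_evidence,
                   stringsAsFactors = FALSE)
    }))
}
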