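#' Run the full curation workflow over a candidate cohort
#'
#' Ties the modules together: locus cistron assignment, read alignment with
#' lowest-error multi-map resolution, per-precursor stacks, arm calls,
#' hairpin checks, the decision tree (candidates processed in descending
#' read support so complement artifacts are screened against already
#' accepted matures), and finally mature product naming, sequence families,
#' and genomic clusters for the accepted set.
#'
#' @param candidates named list of [precursor_candidate()] objects.
#' @param reads a `collapsed_reads` data.frame (pooled library).
#' @param track optional `annotation_track`.
#' @param est optional named logical vector of EST evidence flags.
#' @param config a [curation_config()].
#' @param engine folding backend passed to [fold_hairpin()].
#' @return A `curation_result`: list with `decisions` (data.frame),
#'   `stacks`, `arms`, `structures` (named lists), `products` (data.frame
#'   of mature products), `families`, `clusters`, `tally`.
#' @export
curate_cohort <- function(candidates, reads, track = NULL, est = NULL,
                          config = curation_config(),
                          engine = c("auto", "nussinov", "rnafold")) {
    engine <- resolve_fold_engine(match.arg(engine))
    if (is.null(names(candidates))) {
        names(candidates) <- vapply(candidates, `[[`, "", "name")
    }

    # cistron membership from the input loci: any candidate chained within
    # cluster_distance_nt of another belongs to a locus cluster
    locus_clusters <- build_clusters(candidates, config)
    for (i in seq_len(nrow(locus_clusters))) {
        for (m in strsplit(locus_clusters$members[i], ",", fixed = TRUE)[[1]]) {
            candidates[[m]]$cistron_id <- locus_clusters$name[i]
        }
    }
    if (!is.null(est)) {
        for (m in intersect(names(est), names(candidates))) {
            candidates[[m]]$est_evidence <- isTRUE(est[[m]])
        }
    }

    aln <- resolve_multimap(align_reads(reads, candidates, config))
    stacks <- lapply(candidates, function(cand) {
        build_stack(cand, aln[aln$precursor == cand$name, , drop = FALSE],
                    config)
    })

    totals <- vapply(stacks, `[[`, 0L, "total_count")
    order_names <- names(candidates)[order(-totals, names(candidates))]

    arms <- list(); structures <- list(); decisions <- list()
    accepted_matures <- character(0)
    for (nm in order_names) {
        cand <- candidates[[nm]]
        st <- stacks[[nm]]
        ac <- NULL; hc <- NULL
        if (st$total_count > 0L) {
            ac <- call_arms(st, config)
            if (isTRUE(ac$bimodal)) {
                hc <- check_duplex(fold_hairpin(cand, ac, config, engine),
                                   ac, config, cand)
            }
        }
        d <- decide(cand, st, ac, hc, track, config, accepted_matures)
        if (d$status == "accepted") {
            accepted_matures <- c(accepted_matures, d$metrics$dominant_read)
        }
        arms[[nm]] <- ac
        structures[[nm]] <- hc
        decisions[[nm]] <- d
    }

    dec_tab <- decisions_table(decisions[names(candidates)])
    products <- build_products(candidates, stacks, arms, dec_tab, config)

    families <- build_families(products[, c("name", "sequence")], config)
    accepted <- candidates[dec_tab$name[dec_tab$status == "accepted"]]
    mature_seqs <- setNames(
        products$sequence[products$designation %in% c("mature", "5p")],
        products$precursor_name[products$designation %in% c("mature", "5p")])
    clusters <- build_clusters(accepted, config, mature_seqs)

    tally <- c(accepted = sum(dec_tab$status == "accepted"))
    rej <- table(dec_tab$reason[dec_tab$status == "rejected"])
    tally <- c(tally, setNames(as.integer(rej), names(rej)))

    structure(list(decisions = dec_tab, stacks = stacks, arms = arms,
                   structures = structures, products = products,
                   families = families, clusters = clusters, tally = tally),
              class = "curation_result")
}

# mature product rows (both arms) for every accepted precursor
build_products <- function(candidates, stacks, arms, dec_tab, config) {
    rows <- list()
    for (nm in dec_tab$name[dec_tab$status == "accepted"]) {
        ac <- arms[[nm]]
        st <- stacks[[nm]]
        des <- assign_designations(ac, config)
        ivs <- list(five = ac$five_arm, three = ac$three_arm)
        for (side in c("five", "three")) {
            iv <- ivs[[side]]
            if (is.null(iv)) next
            sel <- arm_assigned(st$alignments, iv)
            if (side == "three") {
                sel <- sel & !arm_assigned(st$alignments, ivs$five)
            }
            if (any(sel)) {
                a <- st$alignments[sel, , drop = FALSE]
                a <- a[order(-a$count, a$sequence), , drop = FALSE]
                seq <- a$sequence[1]
                count <- sum(a$count)
            } else {
                cand <- candidates[[nm]]
                seq <- substr(cand$extended_sequence, iv[1] + 1L, iv[2])
                count <- 0L
            }
            arm_lab <- if (side == "five") "5p" else "3p"
            rows[[length(rows) + 1L]] <- data.frame(
                name = try_mature_name(nm, arm_lab, des[[side]]),
                precursor_name = nm, arm = arm_lab,
                designation = des[[side]], sequence = seq,
                read_count = count,
                seed = substr(seq, config$seed_start, config$seed_end),
                arm_start = iv[1], arm_end = iv[2],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) {
        return(data.frame(name = character(), precursor_name = character(),
                          arm = character(), designation = character(),
                          sequence = character(), read_count = integer(),
                          seed = character(), arm_start = integer(),
                          arm_end = integer(), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# fall back to a raw suffix for precursor names outside the miRNA pattern
try_mature_name <- function(precursor_name, arm, designation) {
    tryCatch(format_mature_name(precursor_name, arm, designation),
             error = function(e) paste0(precursor_name, "-", arm))
}

#' @export
print.curation_result <- function(x, ...) {
    cat(sprintf("<curation_result: %d candidates, %d accepted>\n",
                nrow(x$decisions), sum(x$decisions$status == "accepted")))
    print(x$tally)
    invisible(x)
}

#' Per-sample expression profile of a curated cohort
#'
#' Convenience wrapper: aligns each sample's reads against the accepted
#' precursors and tallies mature/star expression with [tally_expression()].
#'
#' @param result a `curation_result`.
#' @param candidates the candidate list given to [curate_cohort()].
#' @param sample_reads named list of `collapsed_reads`, one per sample.
#' @param config a [curation_config()].
#' @return An `expression_matrix`.
#' @export
profile_expression <- function(result, candidates, sample_reads,
                               config = curation_config()) {
    if (is.null(names(candidates))) {
        names(candidates) <- vapply(candidates, `[[`, "", "name")
    }
    accepted <- candidates[result$decisions$name[result$decisions$status ==
                                                 "accepted"]]
    sample_stacks <- lapply(sample_reads, function(rds) {
        aln <- resolve_multimap(align_reads(rds, accepted, config))
        lapply(accepted, function(cand) {
            build_stack(cand, aln[aln$precursor == cand$name, , drop = FALSE],
                        config)
        })
    })
    tally_expression(sample_stacks, result$products)
}
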