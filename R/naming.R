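#' Assign mature/star or 5p/3p designations to the two arms
#'
#' When the coverage of one arm exceeds `arm_dominance` (strictly; default
#' 80%) relative to the other, the dominant arm is the mature product and
#' the minor arm the miRNA*; otherwise both arms are biologically relevant
#' and are named 5p/3p by position. A single-arm stack makes the observed
#' arm mature with a zero-count star partner.
#'
#' @param arms an `arm_call` with arm fractions.
#' @param config a [curation_config()].
#' @return Named character vector `c(five = ..., three = ...)` with values
#'   in `mature`, `star`, `5p`, `3p`.
#' @export
assign_designations <- function(arms, config = curation_config()) {
    if (is.null(arms$three_arm) || is.na(arms$three_fraction)) {
        return(c(five = "mature", three = "star"))
    }
    f5 <- arms$five_fraction
    if (f5 > config$arm_dominance) {
        c(five = "mature", three = "star")
    } else if (1 - f5 > config$arm_dominance) {
        c(five = "star", three = "mature")
    } else {
        c(five = "5p", three = "3p")
    }
}

#' Format a mature miRNA name from its precursor name
#'
#' Gene-to-transcript conventions: lower-case `mir` becomes `miR`; the major
#' product of a dominated duplex keeps the bare name while the minor product
#' gains a trailing `*`; roughly equally expressed arms are suffixed `-5p`
#' and `-3p` by position.
#'
#' @param precursor_name e.g. `"hsa-mir-125b-1"` or `"hsa-let-7a"`.
#' @param arm `"5p"` or `"3p"` (which physical arm the product sits on).
#' @param designation one of `mature`, `star`, `5p`, `3p`.
#' @return The mature product name.
#' @examples
#' format_mature_name("hsa-mir-125b-1", "5p", "mature")  # hsa-miR-125b-1
#' format_mature_name("hsa-mir-125b-1", "3p", "star")    # hsa-miR-125b-1*
#' format_mature_name("hsa-mir-9-1", "5p", "5p")         # hsa-miR-9-1-5p
#' @export
format_mature_name <- function(precursor_name, arm, designation) {
    if (!grepl("^[a-z]{3}-(mir|let)-", precursor_name)) {
        stop("cannot derive a mature name from precursor '", precursor_name,
             "' (expected <sp>-mir-<id> or <sp>-let-<id>)", call. = FALSE)
    }
    base <- sub("^([a-z]{3})-mir-", "\\1-miR-", precursor_name)
    switch(designation,
           mature = base,
           star = paste0(base, "*"),
           "5p" = paste0(base, "-5p"),
           "3p" = paste0(base, "-3p"),
           stop("unknown designation: ", designation, call. = FALSE))
}

#' Test whether two mature sequences belong to the same seed family
#'
#' Family membership reflects shared mRNA targeting, which is nucleated by
#' the seed, so compatibility is evaluated over the 5' region through the
#' seed end (positions 1..`seed_end`). One deviation is permitted: a single
#' mismatch (a wobble-equivalent substitution counts the same) OR a single
#' 1-nt offset of the 5' alignment -- not both (`family_strict = TRUE`,
#' the default). With `family_strict = FALSE` the offset and the mismatch
#' budget may combine.
#'
#' @param a,b mature sequences (16--28 nt).
#' @param config a [curation_config()].
#' @return Logical; symmetric in its arguments.
#' @export
family_compatible <- function(a, b, config = curation_config()) {
    a <- canonical_dna(a); b <- canonical_dna(b)
    region_len <- config$seed_end
    offs <- seq(-config$family_max_5p_offset, config$family_max_5p_offset)
    for (o in offs) {
        # compare a[i] against b[i + o] over the 5' region
        ia <- seq_len(region_len)
        ib <- ia + o
        ok <- ia <= nchar(a) & ib >= 1L & ib <= nchar(b)
        if (!any(ok)) next
        mm <- sum(substring(a, ia[ok], ia[ok]) != substring(b, ib[ok], ib[ok]))
        budget <- if (config$family_strict && o != 0L) 0L else config$family_max_mismatch
        if (mm <= budget) return(TRUE)
    }
    FALSE
}

#' Group mature products into sequence families
#'
#' Families are the connected components (single linkage) of the
#' [family_compatible()] graph; components of size >= 2 are named
#' `sf-<lowest member>(<n>)` with the lowest member under natural
#' alphanumeric order, and singletons are reported separately.
#'
#' @param matures data.frame with columns `name` (unique) and `sequence`,
#'   or a named character vector of sequences.
#' @param config a [curation_config()].
#' @return List with `families` (data.frame: `name`, `size`, `members`
#'   comma-joined in natural order) and `singletons` (character vector).
#' @export
build_families <- function(matures, config = curation_config()) {
    if (is.character(matures)) {
        matures <- data.frame(name = names(matures), sequence = unname(matures),
                              stringsAsFactors = FALSE)
    }
    stopifnot(!anyDuplicated(matures$name))
    n <- nrow(matures)
    edges <- integer(0)
    if (n > 1) {
        for (i in seq_len(n - 1)) {
            for (j in seq((i + 1), n)) {
                if (family_compatible(matures$sequence[i], matures$sequence[j],
                                      config)) {
                    edges <- c(edges, i, j)
                }
            }
        }
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership

    fam_rows <- list()
    singles <- character(0)
    for (cid in sort(unique(comp))) {
        members <- matures$name[comp == cid]
        if (length(members) < 2) {
            singles <- c(singles, members)
            next
        }
        members <- members[natural_order(members)]
        fam_rows[[length(fam_rows) + 1L]] <- data.frame(
            name = sprintf("sf-%s(%d)", members[1], length(members)),
            size = length(members),
            members = paste(members, collapse = ","),
            stringsAsFactors = FALSE)
    }
    families <- if (length(fam_rows)) do.call(rbind, fam_rows) else
        data.frame(name = character(), size = integer(), members = character(),
                   stringsAsFactors = FALSE)
    families <- families[natural_order(families$name), , drop = FALSE]
    rownames(families) <- NULL
    list(families = families, singletons = singles)
}

#' Group precursors into genomic cistrons
#'
#' Cistronic miRNAs are co-transcribed precursors typically within
#' `cluster_distance_nt` (5 kb) of each other. Precursors on one
#' chromosome+strand are chained by single linkage whenever the gap between
#' nearest edges is at most `cluster_distance_nt`; cistrons sharing a
#' multi-copy miRNA (an identical mature sequence, which makes the copies
#' indistinguishable) are then merged, possibly across chromosomes.
#' Clusters are named `cluster-<lowest member>(<n>)`; for a merged cluster
#' the reported span is that of the component holding the lowest member.
#'
#' @param precursors list of [precursor_candidate()] objects (or any list
#'   of objects with `name` and `locus`).
#' @param config a [curation_config()].
#' @param mature_seqs optional named character vector (precursor name ->
#'   mature sequence) enabling multi-copy merging.
#' @return Data.frame with columns `name, size, members, chrom, start, end,
#'   strand`; one row per cistron of size >= 2 (singletons are omitted).
#' @export
build_clusters <- function(precursors, config = curation_config(),
                           mature_seqs = NULL) {
    if (!length(precursors)) {
        return(data.frame(name = character(), size = integer(),
                          members = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), stringsAsFactors = FALSE))
    }
    names_ <- vapply(precursors, `[[`, "", "name")
    gr <- GenomicRanges::GRanges(
        seqnames = vapply(precursors, function(p) p$locus$chrom, ""),
        ranges = IRanges::IRanges(
            start = vapply(precursors, function(p) p$locus$start, 0L) + 1L,
            end = vapply(precursors, function(p) p$locus$end, 0L)),
        strand = vapply(precursors, function(p) p$locus$strand, ""))
    merged <- GenomicRanges::reduce(
        gr, min.gapwidth = config$cluster_distance_nt + 1L,
        ignore.strand = FALSE)
    hits <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = FALSE)
    membership <- integer(length(gr))
    membership[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

    # merge cistrons that contain copies of the same multi-copy miRNA
    if (!is.null(mature_seqs)) {
        parent <- seq_len(max(membership))
        find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
        seqs <- mature_seqs[names_]
        for (s in unique(seqs[!is.na(seqs)])) {
            cls <- unique(membership[!is.na(seqs) & seqs == s])
            if (length(cls) > 1) {
                roots <- vapply(cls, find, 0L)
                for (r in roots[-1]) parent[find(r)] <- find(roots[1])
            }
        }
        membership <- vapply(membership, find, 0L)
    }

    rows <- list()
    for (cid in unique(membership)) {
        idx <- which(membership == cid)
        if (length(idx) < 2) next
        members <- names_[idx][natural_order(names_[idx])]
        lowest_i <- idx[natural_order(names_[idx])][1]
        span_chrom <- precursors[[lowest_i]]$locus$chrom
        span_strand <- precursors[[lowest_i]]$locus$strand
        on_span <- idx[vapply(precursors[idx], function(p) {
            p$locus$chrom == span_chrom && p$locus$strand == span_strand
        }, logical(1))]
        rows[[length(rows) + 1L]] <- data.frame(
            name = sprintf("cluster-%s(%d)", members[1], length(members)),
            size = length(members),
            members = paste(members, collapse = ","),
            chrom = span_chrom,
            start = min(vapply(precursors[on_span], function(p) p$locus$start, 0L)),
            end = max(vapply(precursors[on_span], function(p) p$locus$end, 0L)),
            strand = span_strand,
            stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(name = character(), size = integer(), members = character(),
                   chrom = character(), start = integer(), end = integer(),
                   strand = character(), stringsAsFactors = FALSE)
    out <- out[natural_order(out$name), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write cluster spans as BED6
#'
#' @param clusters output of [build_clusters()].
#' @param path BED output path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
    if (!nrow(clusters)) {
        file.create(path)
        return(invisible(path))
    }
    gr <- GenomicRanges::GRanges(
        seqnames = clusters$chrom,
        ranges = IRanges::IRanges(start = clusters$start + 1L,
                                  end = clusters$end),
        strand = clusters$strand,
        name = clusters$name,
        score = clusters$size)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
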