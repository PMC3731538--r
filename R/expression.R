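#' Tally per-sample expression of accepted mature products
#'
#' All reads mapping to each mature/miRNA* arm are tallied per sample and
#' normalized to relative frequencies (count over column total). A read
#' belongs to the arm whose interval contains its 5' start within 2 nt. The
#' log2 layer substitutes a pseudofrequency floor of `1e-6` for zeros so
#' profiles remain heatmap-ready.
#'
#' @param sample_stacks named list (one element per sample) of lists of
#'   `read_stack` objects keyed by precursor name; restrict to accepted
#'   precursors upstream.
#' @param products data.frame of mature products with columns `name`,
#'   `precursor_name`, `arm_start`, `arm_end` (extended coordinates).
#' @return An `expression_matrix`: list with `counts`, `freq`, `log2`
#'   (products x samples matrices) and `empty_samples` (samples with zero
#'   assigned reads, flagged).
#' @export
tally_expression <- function(sample_stacks, products) {
    samples <- names(sample_stacks)
    if (is.null(samples)) stop("sample_stacks must be a named list", call. = FALSE)
    counts <- matrix(0L, nrow = nrow(products), ncol = length(samples),
                     dimnames = list(products$name, samples))
    for (s in samples) {
        stacks <- sample_stacks[[s]]
        for (i in seq_len(nrow(products))) {
            st <- stacks[[products$precursor_name[i]]]
            if (is.null(st) || !nrow(st$alignments)) next
            sel <- arm_assigned(st$alignments,
                                c(products$arm_start[i], products$arm_end[i]))
            counts[i, s] <- sum(st$alignments$count[sel])
        }
    }
    expression_matrix(counts)
}

expression_matrix <- function(counts, floor = 1e-6) {
    totals <- colSums(counts)
    freq <- sweep(counts, 2, pmax(totals, 1L), "/")
    lg <- log2(pmax(freq, floor))
    structure(list(counts = counts, freq = freq, log2 = lg,
                   empty_samples = colnames(counts)[totals == 0]),
              class = "expression_matrix")
}

#' Collapse an expression matrix by genomic cluster
#'
#' Cistronic miRNAs are co-transcribed, so summing member frequencies per
#' cluster yields the profile that best reflects transcriptional
#' regulation. Cluster rows replace their member rows; rows outside any
#' cluster pass through unchanged. Column sums are preserved.
#'
#' @param matrix an `expression_matrix`.
#' @param clusters output of [build_clusters()].
#' @param row_to_precursor named character vector mapping matrix row names
#'   to precursor names; defaults to stripping mature-name decorations is
#'   not attempted -- supply the mapping explicitly (the cohort pipeline
#'   does).
#' @return A collapsed `expression_matrix`.
#' @export
collapse_by_cluster <- function(matrix, clusters, row_to_precursor) {
    rows <- rownames(matrix$counts)
    prec <- row_to_precursor[rows]
    cluster_of <- rep(NA_character_, length(rows))
    for (i in seq_len(nrow(clusters))) {
        members <- strsplit(clusters$members[i], ",", fixed = TRUE)[[1]]
        hit <- !is.na(prec) & prec %in% members
        if (any(!is.na(cluster_of[hit]))) {
            stop("row mapped to two clusters: ",
                 paste(rows[hit & !is.na(cluster_of)], collapse = ", "),
                 call. = FALSE)
        }
        cluster_of[hit] <- clusters$name[i]
    }
    group <- ifelse(is.na(cluster_of), rows, cluster_of)
    keys <- unique(group)
    counts <- matrix(0L, nrow = length(keys), ncol = ncol(matrix$counts),
                     dimnames = list(keys, colnames(matrix$counts)))
    for (k in keys) {
        counts[k, ] <- colSums(matrix$counts[group == k, , drop = FALSE])
    }
    expression_matrix(counts)
}

#' @export
print.expression_matrix <- function(x, ...) {
    cat(sprintf("<expression_matrix %d rows x %d samples>\n",
                nrow(x$counts), ncol(x$counts)))
    if (length(x$empty_samples)) {
        cat("  empty samples:", paste(x$empty_samples, collapse = ", "), "\n")
    }
    invisible(x)
}

#' Write an expression matrix as TSV
#'
#' Emits the relative-frequency layer and the log2 layer, separated by a
#' comment line, rows x samples.
#'
#' @param matrix an `expression_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# relative frequency", con)
    write.table(format(matrix$freq, digits = 8, trim = TRUE), con, sep = "\t",
                quote = FALSE, col.names = NA)
    writeLines("# log2 relative frequency (floor 1e-6)", con)
    write.table(format(matrix$log2, digits = 8, trim = TRUE), con, sep = "\t",
                quote = FALSE, col.names = NA)
    invisible(path)
}
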