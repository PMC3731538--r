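# Independent oracles used to pin down the package's core algorithms.
# They deliberately take the dumb road: exhaustive window scans via
# utils::adist, a memoized top-down recursion for maximal pairing, and a
# boolean-closure component finder.

# brute-force best placement of `read` in `text` at edit distance <=
# max_errors: scan every window of every plausible length with adist and
# keep the leftmost start (then shortest window) at the minimal distance
oracle_align <- function(read, text, max_errors = 2L) {
    m <- nchar(read); n <- nchar(text)
    best <- NULL
    for (L in seq(max(1L, m - max_errors), m + max_errors)) {
        if (L > n) next
        starts <- seq_len(n - L + 1L)
        wins <- substring(text, starts, starts + L - 1L)
        d <- as.integer(adist(read, wins))
        hit <- which(d <= max_errors)
        for (h in hit) {
            cand <- list(dmin = d[h], offset = starts[h] - 1L,
                         end = starts[h] - 1L + L)
            if (is.null(best) ||
                cand$dmin < best$dmin ||
                (cand$dmin == best$dmin && cand$offset < best$offset) ||
                (cand$dmin == best$dmin && cand$offset == best$offset &&
                 cand$end < best$end)) {
                best <- cand
            }
        }
    }
    best
}

# maximal number of nested base pairs (AU/GC/GU, min_loop unpaired between
# a pair) by memoized top-down recursion over the interval
oracle_pair_count <- function(rna, min_loop = 3L) {
    bases <- strsplit(rna, "")[[1]]
    n <- length(bases)
    pairs_ok <- function(a, b) {
        paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    }
    memo <- matrix(NA_integer_, n, n)
    rec <- function(i, j) {
        if (j - i < min_loop + 1L) return(0L)
        if (!is.na(memo[i, j])) return(memo[i, j])
        best <- rec(i + 1L, j)
        for (k in seq(i + min_loop + 1L, j)) {
            if (!pairs_ok(bases[i], bases[k])) next
            left <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
            right <- if (k + 1L <= j) rec(k + 1L, j) else 0L
            best <- max(best, 1L + left + right)
        }
        memo[i, j] <<- best
        best
    }
    if (n < 2L) return(0L)
    rec(1L, n)
}

# connected components of the family-compatibility graph by repeated
# boolean closure of the adjacency matrix
oracle_components <- function(seqs, config = curation_config()) {
    n <- length(seqs)
    adj <- diag(TRUE, n)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i != j && family_compatible(seqs[i], seqs[j], config)) {
                adj[i, j] <- TRUE
            }
        }
    }
    repeat {
        nxt <- (adj %*% adj) > 0
        if (identical(nxt, adj > 0)) break
        adj <- nxt
    }
    apply(adj, 1, function(r) min(which(r)))
}

# per-position coverage by direct accumulation
oracle_coverage <- function(alignments, L) {
    cov <- numeric(L)
    for (i in seq_len(nrow(alignments))) {
        span <- (alignments$offset[i] + 1L):alignments$end[i]
        cov[span] <- cov[span] + alignments$count[i]
    }
    cov
}
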