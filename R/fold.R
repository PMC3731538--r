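#' Fold the hairpin window around the called arms
#'
#' The window spans the called peaks plus `fold_pad_nt` nucleotides each
#' side, clipped to the extended sequence, and is folded into a nested
#' secondary structure. Two interchangeable backends sit behind the same
#' adapter: the built-in base-pair-maximization folder (Nussinov-style
#' interval dynamic program over AU/GC/GU pairs, minimum loop
#' `min_loop_nt`, deterministic tie-breaking toward the lowest 5' partner)
#' and, when installed, ViennaRNA's `RNAfold` minimum-free-energy engine.
#' Downstream code consumes only the returned structure, so the backends are
#' interchangeable.
#'
#' @param candidate a [precursor_candidate()].
#' @param arms an `arm_call` defining at least one peak.
#' @param config a [curation_config()].
#' @param engine `"auto"` (RNAfold when its executable is on the PATH,
#'   otherwise the built-in maximizer), `"nussinov"`, or `"rnafold"`.
#'   Thermodynamic folding resolves near-tied pairing registers that pure
#'   pair-count maximization cannot, so it is preferred when available.
#' @return A partial `hairpin_check`: list with `dotbracket`, `pair_table`
#'   (1-based partner per window position, 0 = unpaired), `fold_window`
#'   (`c(start, end)` in extended coordinates), `loop_size`, `engine`.
#'   Complete the verdict with [check_duplex()].
#' @export
fold_hairpin <- function(candidate, arms, config = curation_config(),
                         engine = c("auto", "nussinov", "rnafold")) {
    engine <- resolve_fold_engine(match.arg(engine))
    if (is.null(arms$five_arm)) {
        stop("fold_hairpin needs at least one called peak", call. = FALSE)
    }
    L <- nchar(candidate$extended_sequence)
    last <- if (is.null(arms$three_arm)) arms$five_arm[2] else arms$three_arm[2]
    win <- c(max(0L, arms$five_arm[1] - config$fold_pad_nt),
             min(L, last + config$fold_pad_nt))
    if (win[2] - win[1] < 40L) {
        stop("TOO_SHORT: fold window of ", win[2] - win[1],
             " nt (< 40 nt) for ", candidate$name, call. = FALSE)
    }
    rna <- chartr("T", "U", substr(candidate$extended_sequence,
                                   win[1] + 1L, win[2]))
    pt <- switch(engine,
                 nussinov = cpp_nussinov(rna, as.integer(config$min_loop_nt)),
                 rnafold = rnafold_pair_table(rna))
    structure(list(dotbracket = pair_table_to_dotbracket(pt),
                   pair_table = pt,
                   fold_window = win,
                   loop_size = loop_size_from_pairs(pt),
                   engine = engine),
              class = "hairpin_check")
}

resolve_fold_engine <- function(engine) {
    if (engine != "auto") return(engine)
    if (Sys.which("RNAfold") != "") "rnafold" else "nussinov"
}

# external thermodynamic backend (adapter around the RNAfold executable)
rnafold_pair_table <- function(rna) {
    if (Sys.which("RNAfold") == "") {
        stop("RNAfold executable not found on PATH; use engine = 'nussinov'",
             call. = FALSE)
    }
    out <- system2("RNAfold", args = c("--noPS"), input = rna, stdout = TRUE)
    db <- sub("\\s.*$", "", out[2])
    dotbracket_to_pair_table(db)
}

pair_table_to_dotbracket <- function(pt) {
    db <- rep(".", length(pt))
    db[pt > seq_along(pt)] <- "("
    db[pt > 0 & pt < seq_along(pt)] <- ")"
    paste(db, collapse = "")
}

dotbracket_to_pair_table <- function(db) {
    chars <- strsplit(db, "")[[1]]
    pt <- integer(length(chars))
    stack <- integer(0)
    for (i in seq_along(chars)) {
        if (chars[i] == "(") {
            stack <- c(stack, i)
        } else if (chars[i] == ")") {
            if (!length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pt[i] <- j; pt[j] <- i
        }
    }
    if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
    pt
}

# nt between the innermost stem pair (smallest enclosed span)
loop_size_from_pairs <- function(pt) {
    i <- which(pt > seq_along(pt))
    if (!length(i)) return(NA_integer_)
    as.integer(min(pt[i] - i) - 1L)
}

#' Verify duplex pairing, loop clearance and 3' overhangs
#'
#' Completes a [fold_hairpin()] structure into a hairpin verdict. The 3'
#' overhang of each arm is the number of consecutive positions, counted
#' inward from the arm's 3' terminus, that are unpaired or paired outside
#' the partner arm -- i.e. whose partner would fall beyond the partner arm's
#' 5' terminus. RNase-III processing leaves both overhangs at
#' `overhang_nt` (checked within `overhang_tol_nt`). G-U wobbles are
#' legitimate duplex pairs and are counted in `gu_pairs`.
#'
#' Diagnostics: `ARMS_NOT_PAIRED` when fewer than `duplex_min_paired` of the
#' 5'-arm positions pair into the 3' arm, `NO_LOOP` when no stem encloses at
#' least `min_loop_nt` unpaired nucleotides, `BAD_OVERHANG` when either
#' overhang leaves the tolerated window. `hairpin_ok` is true exactly when
#' no diagnostic fires.
#'
#' @param structure a `hairpin_check` from [fold_hairpin()].
#' @param arms the `arm_call` used to define the fold window.
#' @param config a [curation_config()].
#' @param candidate optional [precursor_candidate()] (used to count G-U
#'   pairs from sequence; omit to skip).
#' @return The completed `hairpin_check` with `arms_paired_fraction`,
#'   `five_overhang_3p`, `three_overhang_3p`, `gu_pairs`, `hairpin_ok`,
#'   `diagnostics`.
#' @export
check_duplex <- function(structure, arms, config = curation_config(),
                         candidate = NULL) {
    pt <- structure$pair_table
    win <- structure$fold_window
    if (is.null(arms$three_arm)) {
        structure$arms_paired_fraction <- 0
        structure$five_overhang_3p <- NA_integer_
        structure$three_overhang_3p <- NA_integer_
        structure$gu_pairs <- 0L
        structure$diagnostics <- "ARMS_NOT_PAIRED"
        structure$hairpin_ok <- FALSE
        return(structure)
    }
    # arm intervals in 1-based window coordinates
    a <- c(arms$five_arm[1] - win[1] + 1L, arms$five_arm[2] - win[1])
    b <- c(arms$three_arm[1] - win[1] + 1L, arms$three_arm[2] - win[1])
    n <- length(pt)
    a <- pmin(pmax(a, 1L), n); b <- pmin(pmax(b, 1L), n)

    in_arm <- function(p, arm) p >= arm[1] & p <= arm[2]
    five_pos <- a[1]:a[2]
    paired_into_3p <- pt[five_pos] > 0 & in_arm(pt[five_pos], b)
    arms_paired_fraction <- mean(paired_into_3p)

    # loop between the innermost pair of the inter-arm duplex; spurious
    # mini-hairpins in the flanks must not masquerade as the loop
    duplex5 <- five_pos[paired_into_3p]
    structure$loop_size <- if (length(duplex5)) {
        as.integer(min(pt[duplex5] - duplex5) - 1L)
    } else NA_integer_

    overhang <- function(arm, partner) {
        count <- 0L
        for (p in seq(arm[2], arm[1])) {
            if (pt[p] > 0 && in_arm(pt[p], partner)) break
            count <- count + 1L
        }
        count
    }
    five_oh <- overhang(a, b)
    three_oh <- overhang(b, a)

    gu <- 0L
    if (!is.null(candidate)) {
        rna <- chartr("T", "U", substr(candidate$extended_sequence,
                                       win[1] + 1L, win[2]))
        bases <- strsplit(rna, "")[[1]]
        p5 <- five_pos[paired_into_3p]
        gu <- sum(paste0(bases[p5], bases[pt[p5]]) %in% c("GU", "UG"))
    }

    diagnostics <- character()
    if (arms_paired_fraction < config$duplex_min_paired) {
        diagnostics <- c(diagnostics, "ARMS_NOT_PAIRED")
    }
    if (is.na(structure$loop_size) || structure$loop_size < config$min_loop_nt) {
        diagnostics <- c(diagnostics, "NO_LOOP")
    }
    lo <- config$overhang_nt - config$overhang_tol_nt
    hi <- config$overhang_nt + config$overhang_tol_nt
    if (five_oh < lo || five_oh > hi || three_oh < lo || three_oh > hi) {
        diagnostics <- c(diagnostics, "BAD_OVERHANG")
    }

    structure$arms_paired_fraction <- arms_paired_fraction
    structure$five_overhang_3p <- five_oh
    structure$three_overhang_3p <- three_oh
    structure$gu_pairs <- gu
    structure$diagnostics <- diagnostics
    structure$hairpin_ok <- length(diagnostics) == 0L
    structure
}

#' @export
print.hairpin_check <- function(x, ...) {
    cat(sprintf("<hairpin_check window=[%d,%d) engine=%s>\n",
                x$fold_window[1], x$fold_window[2], x$engine))
    cat(" ", x$dotbracket, "\n")
    if (!is.null(x$hairpin_ok)) {
        cat(sprintf("  paired=%.2f loop=%s overhangs=%s/%s ok=%s\n",
                    x$arms_paired_fraction, x$loop_size,
                    x$five_overhang_3p, x$three_overhang_3p, x$hairpin_ok))
        if (length(x$diagnostics)) cat("  diagnostics:",
                                       paste(x$diagnostics, collapse = ", "), "\n")
    }
    invisible(x)
}
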