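#' Curation threshold configuration
#'
#' Every numeric constant of the curation workflow lives in this one object,
#' so no other function hard-codes a threshold. The defaults encode the
#' standard desk-curation constants for mammalian small RNA libraries: up to
#' 2 alignment errors per read, 100 nt of genomic flank around each annotated
#' precursor, a minimum of 50 pooled reads and 5 distinct read sequences per
#' candidate, at most 30 genomic copies for loci outside known cistrons, two
#' ~22-nt read peaks spaced 10--20 nt with 2-nt 3' overhangs, an 80% arm
#' dominance cut for mature/star naming, 5 kb cistron chaining, a
#' one-deviation budget for seed families, and the seed at mature positions
#' 2--8.
#'
#' @param ... named overrides of individual fields. Unknown names are an
#'   error.
#'
#' @return An object of class `curation_config`: a named list of validated
#'   thresholds.
#'
#' @details Fields beyond the headline constants operationalize qualitative
#' criteria: `peak_width_tol_nt` turns "~22 nt" into the accepted width
#' window `[peak_width_nt - tol, peak_width_nt + tol]` (default 18--26 nt,
#' matching the 19--24 nt library size selection with a margin);
#' `overhang_tol_nt` relaxes the 2-nt overhang by one nucleotide either way;
#' `duplex_min_paired` is the minimum fraction of 5'-arm positions paired
#' into the 3' arm for a fold to count as a foldback; `min_loop_nt` is the
#' minimum hairpin loop; `fold_pad_nt` is how far the fold window extends
#' beyond the called peaks; `family_strict` selects the single-allowance
#' reading of the family rule (one mismatch OR one wobble OR one 1-nt 5'
#' offset).
#'
#' @examples
#' cfg <- curation_config()
#' cfg$min_read_count
#' curation_config(min_read_count = 10)$min_read_count
#' @export
curation_config <- function(...) {
    cfg <- list(
        max_errors = 2L,
        flank_nt = 100L,
        min_read_count = 50L,
        min_nonredundant = 5L,
        max_genomic_locations = 30L,
        peak_width_nt = 22L,
        peak_width_tol_nt = 4L,
        peak_spacing_min_nt = 10L,
        peak_spacing_max_nt = 20L,
        overhang_nt = 2L,
        overhang_tol_nt = 1L,
        arm_dominance = 0.80,
        cluster_distance_nt = 5000L,
        family_max_mismatch = 1L,
        family_max_5p_offset = 1L,
        family_strict = TRUE,
        seed_start = 2L,
        seed_end = 8L,
        duplex_min_paired = 0.6,
        min_loop_nt = 3L,
        fold_pad_nt = 10L
    )
    overrides <- list(...)
    if (length(overrides)) {
        bad <- setdiff(names(overrides), names(cfg))
        if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
            stop("unknown configuration key(s): ",
                 paste(bad, collapse = ", "), call. = FALSE)
        }
        for (k in names(overrides)) cfg[[k]] <- coerce_config_value(k, overrides[[k]])
    }
    class(cfg) <- "curation_config"
    validate_config(cfg)
    cfg
}

config_field_types <- function() {
    c(max_errors = "int", flank_nt = "int", min_read_count = "int",
      min_nonredundant = "int", max_genomic_locations = "int",
      peak_width_nt = "int", peak_width_tol_nt = "int",
      peak_spacing_min_nt = "int", peak_spacing_max_nt = "int",
      overhang_nt = "int", overhang_tol_nt = "int",
      arm_dominance = "num", cluster_distance_nt = "int",
      family_max_mismatch = "int", family_max_5p_offset = "int",
      family_strict = "bool", seed_start = "int", seed_end = "int",
      duplex_min_paired = "num", min_loop_nt = "int", fold_pad_nt = "int")
}

coerce_config_value <- function(key, value) {
    type <- config_field_types()[[key]]
    if (is.null(type)) stop("unknown configuration key: ", key, call. = FALSE)
    if (type == "bool") {
        if (is.character(value)) value <- tolower(value) %in% c("true", "1", "yes")
        return(isTRUE(as.logical(value)))
    }
    value <- suppressWarnings(as.numeric(value))
    if (is.na(value)) stop("configuration key '", key, "' is not numeric", call. = FALSE)
    if (type == "int") {
        if (value != round(value)) {
            stop("configuration key '", key, "' must be an integer", call. = FALSE)
        }
        return(as.integer(value))
    }
    value
}

validate_config <- function(cfg) {
    ints <- names(config_field_types())[config_field_types() == "int"]
    for (k in ints) {
        if (cfg[[k]] < 0L) stop("configuration key '", k, "' must be nonnegative",
                                call. = FALSE)
    }
    if (cfg$peak_spacing_min_nt > cfg$peak_spacing_max_nt) {
        stop("configuration: peak_spacing_min_nt exceeds peak_spacing_max_nt",
             call. = FALSE)
    }
    if (cfg$arm_dominance <= 0.5 || cfg$arm_dominance > 1) {
        stop("configuration key 'arm_dominance' must lie in (0.5, 1]", call. = FALSE)
    }
    if (cfg$duplex_min_paired < 0 || cfg$duplex_min_paired > 1) {
        stop("configuration key 'duplex_min_paired' must lie in [0, 1]", call. = FALSE)
    }
    if (cfg$seed_start < 1L || cfg$seed_end < cfg$seed_start) {
        stop("configuration: seed_start..seed_end is not a valid 1-based range",
             call. = FALSE)
    }
    invisible(cfg)
}

#' Load a curation configuration from a key=value file
#'
#' The file format is flat UTF-8 `key=value` text; blank lines and lines
#' starting with `#` are ignored. Keys must match [curation_config()] field
#' names exactly; unknown keys and invariant violations are errors naming the
#' offending key.
#'
#' @param path path to a config file, or `NULL` for all defaults.
#' @return A validated `curation_config` object.
#' @seealso [write_config()]
#' @export
load_config <- function(path = NULL) {
    if (is.null(path)) return(curation_config())
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    overrides <- list()
    for (ln in lines) {
        if (!grepl("=", ln, fixed = TRUE)) {
            stop("malformed config line (expected key=value): '", ln, "'",
                 call. = FALSE)
        }
        key <- trimws(sub("=.*$", "", ln))
        val <- trimws(sub("^[^=]*=", "", ln))
        overrides[[key]] <- val
    }
    do.call(curation_config, overrides)
}

#' Write a curation configuration as key=value text
#'
#' Round-trips with [load_config()]: loading the written file reproduces an
#' identical configuration object.
#'
#' @param config a `curation_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
    stopifnot(inherits(config, "curation_config"))
    fmt <- vapply(names(config), function(k) {
        v <- config[[k]]
        if (is.logical(v)) paste0(k, "=", tolower(as.character(v)))
        else paste0(k, "=", format(v, scientific = FALSE))
    }, character(1))
    writeLines(fmt, path)
    invisible(path)
}

#' @export
print.curation_config <- function(x, ...) {
    cat("curation_config with", length(x), "thresholds:\n")
    for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
    invisible(x)
}
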