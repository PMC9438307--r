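#' Default run configuration
#'
#' All pipeline tunables with their defaults. Defaults reproduce the standard
#' settings of the mining and reconciliation chain: E-value threshold 1e-10
#' for the translated search, 5000 bp flank extension around hit regions,
#' 30 bp contig-border distance for "edge" calls, bootstrap-collapse threshold
#' 90, and exclusion of species-tree branches shorter than 2 My from rate
#' estimation.
#'
#' @param ... overrides for individual fields.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    e_value_threshold = 1e-10,
    flank = 5000L,             # bp added on each side of a translated-search hit
    edge_distance = 30L,       # bp: "edge" status requires border distance < this
    support_collapse = 90,     # % bootstrap: nodes below are collapsed
    min_branch_my = 2,         # My: shorter species-tree branches excluded from rates
    completeness_fraction = 0.8,  # reference coverage needed for "complete"
    margin_bits = 5,           # bit-score margin below which family calls are ambiguous
    gap_open = 11L,            # affine gap open (BLOSUM62 convention)
    gap_extend = 1L,
    karlin_lambda = 0.267,     # gapped BLOSUM62 Karlin-Altschul constants
    karlin_k = 0.041,
    fs_penalty = -20L,         # spliced-aligner frameshift unit
    gap_res_penalty = -12L,    # spliced-aligner reference-residue skip
    gap_dna_penalty = -12L,    # spliced-aligner in-frame codon insertion
    intron_penalty = -15L,     # spliced-aligner intron open (GT..AG)
    stop_penalty = -25L,       # spliced-aligner in-frame stop readthrough
    min_intron = 30L,          # bp: minimum intron length
    search_window = 12000L,    # bp: translated-search window length
    search_step = 6000L,       # bp: translated-search window step
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Write a run configuration as plain-text `key: value` lines
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    paste0(k, ": ", format(cfg[[k]], scientific = TRUE, digits = 15)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration written by [write_config()]
#'
#' @param path path to a config file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 2))
  vals <- trimws(vapply(kv, `[`, "", 3))
  defaults <- run_config()
  out <- as.list(defaults)
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(out)) stop("unknown config field: ", k)
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) stop("non-numeric config value for ", k, ": ", vals[i])
    out[[k]] <- if (is.integer(defaults[[k]])) as.integer(v) else v
  }
  structure(out, class = "run_config")
}
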