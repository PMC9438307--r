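#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a plain named
#' character vector (names are the full header lines, sequences upper-cased).
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; zero-length for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

#' Write sequences to a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (length(records) > 0 && (is.null(names(records)) || any(names(records) == "")))
    stop("all records must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    if (nchar(s) == 0) writeLines("", con)
    else writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# --- internal sequence helpers ---------------------------------------------

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), ""))
}

# encode a protein string as 0-based indices into the BLOSUM62 rows (-1 unknown)
encode_protein <- function(p) {
  if (is.null(the$aa_lut)) {
    lut <- rep(-1L, 128)
    chars <- strsplit(the$aa_alphabet, "", fixed = TRUE)[[1]]
    lut[utf8ToInt(paste(chars, collapse = "")) + 1L] <- seq_along(chars) - 1L
    lut[utf8ToInt(paste(tolower(chars), collapse = "")) + 1L] <- seq_along(chars) - 1L
    the$aa_lut <- lut
  }
  v <- utf8ToInt(p); v[v > 127L] <- 63L
  the$aa_lut[v + 1L]
}

# encode DNA as A=0 C=1 G=2 T=3, -1 otherwise
encode_dna <- function(d) {
  if (is.null(the$dna_lut)) {
    lut <- rep(-1L, 128)
    lut[utf8ToInt("ACGTacgt") + 1L] <- c(0:3, 0:3)
    the$dna_lut <- lut
  }
  v <- utf8ToInt(d); v[v > 127L] <- 63L
  the$dna_lut[v + 1L]
}

# codon index (16*b1+4*b2+b3, 0-based) -> BLOSUM62 row index of the amino acid
codon_aa_table <- function() {
  if (!is.null(the$codon_aa)) return(the$codon_aa)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  tab <- integer(64)
  aa_alpha <- strsplit(the$aa_alphabet, "", fixed = TRUE)[[1]]
  for (b1 in 0:3) for (b2 in 0:3) for (b3 in 0:3) {
    codon <- paste0(bases[b1 + 1], bases[b2 + 1], bases[b3 + 1])
    aa <- unname(gc[codon])
    tab[16 * b1 + 4 * b2 + b3 + 1] <- match(aa, aa_alpha) - 1L
  }
  the$codon_aa <- tab
  tab
}

stop_aa_index <- function() {
  match("*", strsplit(the$aa_alphabet, "", fixed = TRUE)[[1]]) - 1L
}

# translate a DNA string in frame 1 (no ambiguity handling; stops as '*')
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3
  if (n == 0) return("")
  enc <- encode_dna(cds)
  tab <- codon_aa_table()
  aa_alpha <- strsplit(the$aa_alphabet, "", fixed = TRUE)[[1]]
  out <- character(n)
  for (k in seq_len(n)) {
    b <- enc[(3 * k - 2):(3 * k)]
    out[k] <- if (any(b < 0)) "X" else aa_alpha[tab[16 * b[1] + 4 * b[2] + b[3] + 1] + 1]
  }
  paste(out, collapse = "")
}

is_stop_codon <- function(codon) {
  toupper(codon) %in% c("TAA", "TAG", "TGA")
}
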