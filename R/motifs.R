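AA20 <- "ACDEFGHIKLMNPQRSTVWY"

#' Diagnostic Elovl motif patterns
#'
#' The conserved motifs characteristic of Elovl condensing enzymes: the
#' histidine box `HXXHH` and the additional conserved regions `KXXEXXDT`,
#' `QXXFLHXXHH`, `NXXXHXXMYXYY` and `TXXQXXQ`. `X` matches any residue.
#' The C-terminal ER retrieval signal `RXKXX` is handled separately by
#' [check_er_signal()] because it is anchored to the carboxyl terminus.
#'
#' @return A named character vector of motif patterns.
#' @export
elovl_motifs <- function() {
  c(
    histidine_box = "HXXHH",
    motif_KxxExxDT = "KXXEXXDT",
    motif_QxxFLHxxHH = "QXXFLHXXHH",
    motif_NxxxHxxMYxYY = "NXXXHXXMYXYY",
    motif_TxxQxxQ = "TXXQXXQ"
  )
}

#' Translate an open reading frame
#'
#' Standard-code translation of a complete ORF: the sequence must have
#' triplet length, start with `ATG`, end with a stop codon and contain no
#' internal stop; the terminal stop is not translated, so the protein length
#' is `length/3 - 1`. Codons containing `N` translate to `X` with a warning
#' (sequencing ambiguity is tolerated without altering the protein length).
#'
#' @param seq Character vector of nucleotide sequences (case-insensitive,
#'   alphabet A/C/G/T/N); names are carried over to the result.
#' @return Character vector of amino-acid sequences.
#' @examples
#' translate_orf("ATGAAATAA")  # "MK"
#' @export
translate_orf <- function(seq) {
  if (!is.character(seq) || length(seq) == 0 || any(is.na(seq)) ||
      any(nchar(seq) == 0)) {
    abort("`seq` must be one or more non-empty nucleotide sequences.")
  }
  out <- vapply(seq, translate_orf_one, character(1), USE.NAMES = FALSE)
  names(out) <- names(seq)
  out
}

translate_orf_one <- function(seq) {
  s <- toupper(seq)
  if (stringr::str_detect(s, "[^ACGTN]")) {
    abort("Nucleotide sequence contains characters outside A/C/G/T/N.")
  }
  n <- nchar(s)
  if (n %% 3L != 0L) {
    abort(sprintf("ORF length (%d) is not a multiple of 3.", n))
  }
  codons <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  if (codons[1] != "ATG") {
    abort("ORF does not start with an ATG initiation codon.")
  }
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  fuzzy <- is.na(aa)
  if (any(fuzzy)) {
    warn(sprintf("%d codon(s) contain N and were translated as X.", sum(fuzzy)))
    aa[fuzzy] <- "X"
  }
  if (aa[length(aa)] != "*") {
    abort("ORF does not end with a stop codon.")
  }
  if (any(aa[-length(aa)] == "*")) {
    abort("ORF contains an internal stop codon.")
  }
  paste(aa[-length(aa)], collapse = "")
}

#' Find the longest ORF in a nucleotide sequence
#'
#' Convenience search used before [translate_orf()] when a full-length cDNA
#' (with UTRs) is supplied: scans all three forward frames for the longest
#' ATG-to-stop span (stop included).
#'
#' @param seq A single nucleotide sequence.
#' @return A tibble with `start`, `end` (1-based, inclusive, stop codon
#'   included), `width` and `orf` (the subsequence); zero rows when no
#'   complete ORF exists.
#' @export
find_orf <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort("`seq` must be a single nucleotide sequence.")
  }
  s <- toupper(seq)
  best <- NULL
  for (frame in 0:2) {
    n_codons <- (nchar(s) - frame) %/% 3L
    if (n_codons < 2L) next
    starts <- frame + seq(1L, by = 3L, length.out = n_codons)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    open_from <- NA_integer_  # earliest un-terminated ATG codon index
    for (i in seq_len(n_codons)) {
      if (is_stop[i]) {
        if (!is.na(open_from)) {
          cand <- c(starts[open_from], starts[i] + 2L)
          if (is.null(best) || diff(cand) > diff(best)) best <- cand
          open_from <- NA_integer_
        }
      } else if (codons[i] == "ATG" && is.na(open_from)) {
        open_from <- i
      }
    }
  }
  if (is.null(best)) {
    return(tibble(start = integer(), end = integer(), width = integer(),
                  orf = character()))
  }
  tibble(
    start = best[1], end = best[2], width = best[2] - best[1] + 1L,
    orf = substring(s, best[1], best[2])
  )
}

#' Scan proteins for X-wildcard motifs
#'
#' Reports every (possibly overlapping) occurrence of each pattern, in
#' ascending position order. Patterns are written over the 20 amino-acid
#' letters plus the wildcard `X`, which matches any residue.
#'
#' @param proteins Character vector of amino-acid sequences; names become
#'   `seq_id` (unnamed input is numbered).
#' @param patterns Named character vector of patterns
#'   (default [elovl_motifs()]).
#' @return A tibble with `seq_id`, `motif`, `pattern`, `start`, `end`
#'   (1-based, inclusive) and `match` (the matched substring).
#' @examples
#' scan_motifs(c(p1 = "AHQVHHL"), c(histidine_box = "HXXHH"))
#' @export
scan_motifs <- function(proteins, patterns = elovl_motifs()) {
  if (!is.character(proteins) || length(proteins) == 0 ||
      any(is.na(proteins)) || any(nchar(proteins) == 0)) {
    abort("`proteins` must be one or more non-empty amino-acid sequences.")
  }
  check_patterns(patterns)
  ids <- names(proteins) %||% paste0("seq", seq_along(proteins))
  proteins <- toupper(proteins)

  hits <- purrr::map2_dfr(proteins, ids, function(p, id) {
    purrr::imap_dfr(patterns, function(pat, motif_name) {
      m <- nchar(pat)
      if (m > nchar(p)) return(NULL)
      rx <- paste0("(?=", gsub("X", ".", pat, fixed = TRUE), ")")
      hits <- gregexpr(rx, p, perl = TRUE)[[1]]
      if (hits[1] == -1) return(NULL)
      starts <- as.integer(hits)
      tibble(
        seq_id = id, motif = motif_name, pattern = pat,
        start = starts, end = starts + m - 1L,
        match = substring(p, starts, starts + m - 1L)
      )
    })
  })
  if (nrow(hits) == 0) {
    return(tibble(seq_id = character(), motif = character(),
                  pattern = character(), start = integer(), end = integer(),
                  match = character()))
  }
  dplyr::arrange(hits, .data$seq_id, .data$motif, .data$start)
}

check_patterns <- function(patterns) {
  if (!is.character(patterns) || length(patterns) == 0) {
    abort("`patterns` must be a character vector of motif patterns.")
  }
  bad <- stringr::str_detect(patterns, paste0("[^", AA20, "X]")) |
    nchar(patterns) < 3L
  if (any(bad)) {
    abort(paste0(
      "Invalid motif pattern(s) (20 amino-acid letters plus X, length >= 3): ",
      paste0("\"", patterns[bad], "\"", collapse = ", "), "."
    ))
  }
  invisible(patterns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test for the C-terminal ER retrieval signal
#'
#' Checks whether a protein ends in the di-basic ER retrieval signal
#' `RXKXX` — an arginine at the fifth-last position and a lysine at the
#' third-last — which retains Elovl enzymes in the endoplasmic reticulum.
#'
#' @param proteins Character vector of amino-acid sequences, each at least 5
#'   residues long; names become `seq_id`.
#' @return A tibble with `seq_id`, `has_er_signal` and `start` (1-based
#'   position of the terminal 5-residue window; `NA` when absent).
#' @examples
#' check_er_signal(c(a = "MLRSKAA"))
#' @export
check_er_signal <- function(proteins) {
  if (!is.character(proteins) || length(proteins) == 0 ||
      any(is.na(proteins))) {
    abort("`proteins` must be one or more amino-acid sequences.")
  }
  if (any(nchar(proteins) < 5L)) {
    abort("ER-signal check requires proteins of at least 5 residues.")
  }
  ids <- names(proteins) %||% paste0("seq", seq_along(proteins))
  p <- toupper(proteins)
  tail5 <- substring(p, nchar(p) - 4L, nchar(p))
  hit <- stringr::str_detect(tail5, "^R.K..$")
  tibble(
    seq_id = ids,
    has_er_signal = hit,
    start = ifelse(hit, nchar(p) - 4L, NA_integer_)
  )
}
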