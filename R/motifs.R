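#' Read a multiple sequence alignment
#'
#' Imports an alignment computed externally (e.g. by Clustal Omega) in
#' aligned-FASTA or Clustal format.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return Named character vector of aligned sequences (equal widths,
#'   gaps as `-`), of length >= 2.
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  as_msa(seqs)
}

#' Validate aligned sequences as an MSA
#'
#' @param seqs Named character vector of aligned sequences.
#' @return The validated vector.
#' @export
as_msa <- function(seqs) {
  if (length(seqs) < 2) stop("MSA needs at least 2 records")
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must have equal length")
  }
  if (is.null(names(seqs))) stop("MSA records must be named")
  seqs
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
}

#' Map alignment columns to reference residue numbers
#'
#' Column i maps to the number of non-gap reference characters in columns
#' up to and including i when the reference is non-gap at i, and to NA
#' (gap) otherwise. The mapping is a bijection between non-gap reference
#' columns and 1..L where L is the ungapped reference length.
#'
#' @param msa MSA (see [as_msa()]).
#' @param reference_id Name of the reference record (e.g. the
#'   Synechococcus 7942 KaiC sequence the alignments are projected onto).
#' @return Integer vector of length `width(msa)`; NA at reference-gap
#'   columns.
#' @export
map_to_reference <- function(msa, reference_id) {
  msa <- as_msa(msa)
  if (!reference_id %in% names(msa)) {
    stop("reference '", reference_id, "' absent from alignment")
  }
  ref <- strsplit(msa[[reference_id]], "", fixed = TRUE)[[1]]
  nongap <- ref != "-"
  out <- rep(NA_integer_, length(ref))
  out[nongap] <- seq_len(sum(nongap))
  out
}

#' A motif window in reference coordinates
#'
#' @param name Window name (e.g. `"Walker A CII"`, `"phosphosites"`).
#' @param positions Reference residue numbers covered by the window.
#' @return List of class `motif_window`.
#' @export
motif_window <- function(name, positions) {
  stopifnot(is.character(name), length(positions) >= 1,
            all(positions >= 1))
  structure(list(name = name, positions = as.integer(positions)),
            class = "motif_window")
}

#' Locate a wildcard pattern in an ungapped reference sequence
#'
#' `X` in the pattern matches any residue. Used to anchor windows whose
#' identity is given by a consensus (such as the Walker A motif GXXXXGKT)
#' rather than by explicit coordinates.
#'
#' @param reference Ungapped amino-acid sequence.
#' @param pattern Pattern over the amino-acid alphabet plus `X`.
#' @return Integer vector of reference positions of the first match, or
#'   NULL if absent.
#' @export
locate_pattern <- function(reference, pattern) {
  rx <- gsub("X", ".", pattern, fixed = TRUE)
  m <- regexpr(rx, reference)
  if (m < 0) return(NULL)
  seq(as.integer(m), length.out = nchar(pattern))
}

#' Position frequency matrix for a motif window
#'
#' Per reference position of the window, the relative frequency of each of
#' the 20 amino acids plus the gap character over the alignment records.
#' Gaps are counted as a 21st symbol so the frequencies always sum to 1.
#'
#' @param msa MSA (see [as_msa()]).
#' @param mapping Column-to-reference mapping from [map_to_reference()].
#' @param window A [motif_window()].
#' @param include_reference Count the reference record itself
#'   (default TRUE).
#' @param reference_id Reference record name, required when
#'   `include_reference = FALSE`.
#' @return Data frame `motif`, `refpos`, `residue`, `frequency` (long
#'   form), with attribute `dominant`: a data frame of the dominant residue
#'   and its frequency per position.
#' @export
column_frequencies <- function(msa, mapping, window,
                               include_reference = TRUE,
                               reference_id = NULL) {
  msa <- as_msa(msa)
  cols <- match(window$positions, mapping)
  if (anyNA(cols)) {
    stop("window '", window$name, "' has positions outside the reference")
  }
  if (!include_reference) {
    if (is.null(reference_id)) stop("reference_id required")
    msa <- msa[names(msa) != reference_id]
  }
  m <- msa_matrix(msa)
  symbols <- c(AA_STANDARD, "X", "-")
  out <- do.call(rbind, lapply(seq_along(cols), function(k) {
    col <- m[, cols[[k]]]
    col[!col %in% symbols] <- "X"
    tab <- table(factor(col, levels = symbols))
    data.frame(motif = window$name, refpos = window$positions[[k]],
               residue = symbols, frequency = as.numeric(tab / length(col)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  dom <- do.call(rbind, lapply(split(out, out$refpos), function(d) {
    i <- which.max(d$frequency)
    data.frame(refpos = d$refpos[[i]], residue = d$residue[[i]],
               frequency = d$frequency[[i]], stringsAsFactors = FALSE)
  }))
  dom <- dom[order(dom$refpos), ]
  rownames(dom) <- NULL
  attr(out, "dominant") <- dom
  out
}

#' Motif match summary across alignment records
#'
#' For each motif window with a consensus pattern, reports the fraction of
#' sequences whose window residues match the pattern (`X` matches any
#' amino acid; gap columns never match) together with the consensus string
#' formed from the dominant residue per position.
#'
#' @param msa MSA (see [as_msa()]).
#' @param mapping Column-to-reference mapping from [map_to_reference()].
#' @param windows List of [motif_window()]s.
#' @param patterns Named character vector of consensus patterns, one per
#'   window name; pattern length must equal the window length.
#' @return Data frame `motif`, `pattern`, `consensus`, `match_fraction`,
#'   `n_records`.
#' @export
motif_report <- function(msa, mapping, windows, patterns) {
  msa <- as_msa(msa)
  m <- msa_matrix(msa)
  do.call(rbind, lapply(windows, function(w) {
    pat <- patterns[[w$name]]
    if (is.null(pat) || is.na(pat)) {
      stop("no pattern for window '", w$name, "'")
    }
    if (nchar(pat) != length(w$positions)) {
      stop("pattern/window length mismatch for '", w$name, "'")
    }
    cols <- match(w$positions, mapping)
    if (anyNA(cols)) stop("window '", w$name, "' outside the reference")
    pc <- strsplit(pat, "", fixed = TRUE)[[1]]
    sub <- m[, cols, drop = FALSE]
    ok <- apply(sub, 1, function(row) {
      all(ifelse(pc == "X", row %in% AA_STANDARD, row == pc))
    })
    pfm <- column_frequencies(msa, mapping, w)
    dom <- attr(pfm, "dominant")
    data.frame(motif = w$name, pattern = pat,
               consensus = paste(dom$residue, collapse = ""),
               match_fraction = mean(ok), n_records = nrow(m),
               stringsAsFactors = FALSE)
  }))
}

#' Default KaiC motif windows
#'
#' The shipped window set covers only the anchors with established
#' KaiC-7942 coordinates: the dominant CII phosphorylation sites S431/T432,
#' the dephosphorylation-critical T426, and the CII ATP-binding Walker A
#' motif (P-loop), located in the reference by its GXXXXGKT consensus.
#' Further functional elements (R-finger, catalytic glutamates, the 422 and
#' 438-444 loops, the A-loop span, KaiA-binding residues) have no complete
#' published coordinate set and are deliberately left to user configuration
#' via [motif_window()] rather than hard-coded.
#'
#' @param reference Ungapped reference (KaiC-7942-like) sequence, used to
#'   locate the CII Walker A motif; windows that cannot be located are
#'   omitted with a warning.
#' @return Named list of [motif_window()]s, plus attribute `patterns` with
#'   the consensus patterns for [motif_report()].
#' @export
kaic_motif_windows <- function(reference) {
  windows <- list()
  patterns <- character()
  L <- nchar(reference)
  if (L >= 432) {
    windows$phosphosites <- motif_window("phosphosites", c(431, 432))
    patterns["phosphosites"] <- "ST"
  }
  if (L >= 426) {
    windows$T426 <- motif_window("T426", 426)
    patterns["T426"] <- "T"
  }
  wa <- locate_pattern(reference, "GXXXXGKT")
  if (!is.null(wa)) {
    windows$walker_a <- motif_window("walker_a", wa)
    patterns["walker_a"] <- "GXXXXGKT"
  } else {
    warning("kaic_motif_windows: Walker A consensus not found in reference")
  }
  attr(windows, "patterns") <- patterns
  windows
}
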