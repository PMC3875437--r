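#' Reference-numbered alignment
#'
#' A `ref_alignment` couples an aligned sequence set with a designated
#' reference sequence whose ungapped residue numbering (offset by
#' `reference_offset`) defines the position labels used throughout the
#' package (e.g. LacI linker numbering 45-62). The column map is built once
#' by walking the reference sequence and is kept positional thereafter, so
#' subsets of the alignment remain comparable column-for-column.
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of aligned (gapped) sequences, equal length.
#' @param reference_id Identifier of the reference sequence.
#' @param reference_offset Integer label given to the first non-gap residue
#'   of the reference sequence.
#' @param column_map Optional precomputed column map (tibble with `position`
#'   and `column`); used when subsetting to preserve the original mapping.
#' @return An object of class `ref_alignment`: a list with `sequences`
#'   (tibble `id`, `seq`), `reference_id`, `reference_offset`, `column_map`
#'   (tibble `position` character, `column` 1-based integer).
#' @export
ref_alignment <- function(ids, seqs, reference_id, reference_offset = 1L,
                          column_map = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (anyDuplicated(ids)) abort("Duplicate sequence identifiers")
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1) {
    abort("Ragged alignment: sequences have unequal lengths")
  }
  if (!reference_id %in% ids) {
    abort(sprintf("Reference sequence '%s' not found in alignment",
                  reference_id))
  }
  if (is.null(column_map)) {
    ref <- strsplit(seqs[match(reference_id, ids)], "")[[1]]
    non_gap <- which(ref != "-" & ref != ".")
    column_map <- tibble(
      position = as.character(seq_along(non_gap) + reference_offset - 1L),
      column = as.integer(non_gap)
    )
  }
  structure(
    list(
      sequences = tibble(id = ids, seq = seqs),
      reference_id = reference_id,
      reference_offset = as.integer(reference_offset),
      column_map = column_map
    ),
    class = "ref_alignment"
  )
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat(sprintf(
    "<ref_alignment> %d sequences x %d columns; reference '%s', positions %s..%s\n",
    nrow(x$sequences), nchar(x$sequences$seq[1]), x$reference_id,
    x$column_map$position[1],
    x$column_map$position[nrow(x$column_map)]
  ))
  invisible(x)
}

#' Read an aligned FASTA with reference numbering
#'
#' @param path Path to an aligned FASTA file.
#' @inheritParams ref_alignment
#' @return A [ref_alignment()] object.
#' @export
read_alignment <- function(path, reference_id, reference_offset = 1L) {
  aln <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aln))
  ref_alignment(ids, as.character(aln), reference_id, reference_offset)
}

#' Write a reference alignment as aligned FASTA
#'
#' @param aln A [ref_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  x <- Biostrings::AAStringSet(stats::setNames(aln$sequences$seq,
                                               aln$sequences$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

aln_column <- function(aln, position) {
  idx <- match(as.character(position), aln$column_map$position)
  if (anyNA(idx)) {
    abort(sprintf("Position(s) not in column map: %s",
                  paste(position[is.na(idx)], collapse = ", ")))
  }
  aln$column_map$column[idx]
}

aln_letters <- function(aln, position) {
  col <- aln_column(aln, position)
  substring(aln$sequences$seq, col, col)
}

#' Per-column symbol frequencies
#'
#' Relative frequencies of the 21-symbol alphabet (20 amino acids + gap) in
#' the alignment column(s) mapped to the given reference position(s).
#' Ambiguity codes (B, Z, X, ...) and any other non-canonical letters are
#' counted as gap, with a warning.
#'
#' @param aln A [ref_alignment()].
#' @param positions Position label(s); default all mapped positions.
#' @return A tibble with columns `position`, `symbol`, `freq`,
#'   `n_sequences`, one row per (position, symbol); frequencies sum to 1
#'   within each position.
#' @export
#' @examples
#' aln <- ref_alignment(c("r", "a", "b"), c("MKV", "MK-", "MQV"), "r")
#' column_frequencies(aln, "2")
column_frequencies <- function(aln, positions = NULL) {
  if (is.null(positions)) positions <- aln$column_map$position
  alphabet <- alignment_alphabet()
  n <- nrow(aln$sequences)
  purrr::map_dfr(as.character(positions), function(pos) {
    letters <- toupper(aln_letters(aln, pos))
    letters[letters == "."] <- "-"
    odd <- !(letters %in% alphabet)
    if (any(odd)) {
      warn(sprintf(
        "Position %s: %d non-canonical letter(s) (%s) counted as gap",
        pos, sum(odd), paste(unique(letters[odd]), collapse = ", ")
      ))
      letters[odd] <- "-"
    }
    counts <- table(factor(letters, levels = alphabet))
    tibble(position = pos, symbol = alphabet,
           freq = as.numeric(counts) / n, n_sequences = n)
  })
}

#' Gap-inclusive Shannon sequence entropy
#'
#' Computes `-sum(f_i * ln(f_i))` over the 21-symbol frequencies of one
#' alignment column, in nats, with `0 * ln(0)` defined as 0. Zero
#' corresponds to perfect conservation; equal frequency of all 21 symbols
#' gives `ln(21)` (3.04 to two decimals).
#'
#' @param freqs A numeric vector of relative frequencies (any length; they
#'   should sum to 1), or a tibble from [column_frequencies()] with a
#'   `freq` column (single position).
#' @return Entropy in nats.
#' @export
#' @examples
#' sequence_entropy(c(1, rep(0, 20)))
#' sequence_entropy(rep(1 / 21, 21))
sequence_entropy <- function(freqs) {
  if (is.data.frame(freqs)) {
    if ("position" %in% names(freqs) &&
        length(unique(freqs$position)) > 1) {
      abort("Multiple positions supplied; use entropy_table()")
    }
    freqs <- freqs$freq
  }
  if (any(freqs < 0)) abort("Frequencies must be non-negative")
  f <- freqs[freqs > 0]
  # the `+ 0` normalizes IEEE negative zero for perfectly conserved columns
  -sum(f * log(f)) + 0
}

#' Entropy profile of an alignment
#'
#' Sequence entropy at each mapped reference position of an alignment (or a
#' chosen subset of positions).
#'
#' @inheritParams column_frequencies
#' @param set_name Label recorded in the output (e.g. `"all_seqs"`,
#'   `"ypal_seqs"`).
#' @return A tibble with columns `set_name`, `position`, `entropy` (nats),
#'   `n_sequences`.
#' @export
entropy_table <- function(aln, positions = NULL, set_name = "all_seqs") {
  column_frequencies(aln, positions) %>%
    dplyr::group_by(.data$position) %>%
    dplyr::summarise(
      entropy = sequence_entropy(.data$freq),
      n_sequences = .data$n_sequences[1],
      .groups = "drop"
    ) %>%
    dplyr::mutate(set_name = set_name, .before = 1) %>%
    dplyr::arrange(match(.data$position,
                         if (is.null(positions)) aln$column_map$position
                         else as.character(positions)))
}

#' Restrict an alignment to sequences carrying a motif
#'
#' Keeps exactly the sequences whose letters at the motif positions equal
#' the required amino acids (exact match, case-insensitive; a gap at a motif
#' position is a mismatch). The column map is kept from the parent
#' alignment — columns are positional, not content-dependent — so entropies
#' of nested sequence sets stay comparable even if the reference sequence
#' itself fails the motif and is dropped.
#'
#' @param aln A [ref_alignment()].
#' @param motif Named character vector: position label -> required amino
#'   acid, e.g. [ypal_motif()].
#' @return A [ref_alignment()] containing the matching sequences. An empty
#'   result is returned with a warning, not an error.
#' @export
subset_by_motif <- function(aln, motif) {
  if (length(motif) == 0) abort("Motif must contain at least one constraint")
  keep <- rep(TRUE, nrow(aln$sequences))
  for (pos in names(motif)) {
    keep <- keep &
      toupper(aln_letters(aln, pos)) == toupper(motif[[pos]])
  }
  if (!any(keep)) warn("No sequences match the motif; returning empty set")
  out <- aln
  out$sequences <- aln$sequences[keep, , drop = FALSE]
  out
}

#' Two-tier toggle/rheostat separation by sequence entropy
#'
#' Labels each position from its motif-subset entropy: `toggle_candidate`
#' when entropy is below `toggle_cut`, `rheostat_candidate` when at or above
#' `rheostat_cut`, otherwise `intermediate`. The default cuts (0.1 and 0.6
#' nats) reproduce the separation observed for the LacI/GalR linker, where
#' the YPAL motif positions score below 0.1 in the motif subset and all
#' mutagenized rheostat positions score at or above 0.6.
#'
#' @param entropies A tibble with columns `position` and `entropy` (e.g.
#'   from [entropy_table()], or [linker_entropies()] after renaming).
#' @param toggle_cut Entropy below which a position is a toggle candidate.
#' @param rheostat_cut Entropy at or above which a position is a rheostat
#'   candidate (a value exactly at the cut qualifies).
#' @return The input with an added `tier` column.
#' @export
#' @examples
#' linker_entropies() |>
#'   dplyr::transmute(position, entropy = ypal_seqs) |>
#'   tier_separation()
tier_separation <- function(entropies, toggle_cut = 0.1,
                            rheostat_cut = 0.6) {
  entropies %>%
    dplyr::mutate(tier = dplyr::case_when(
      .data$entropy < toggle_cut ~ "toggle_candidate",
      .data$entropy >= rheostat_cut ~ "rheostat_candidate",
      TRUE ~ "intermediate"
    ))
}
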