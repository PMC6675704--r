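AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

validate_protein <- function(sequence, id = "protein") {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop_ps("protein sequence must be a single character string")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop_ps("protein '%s' has an empty sequence", id)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop_ps("protein '%s' contains non-amino-acid character(s): %s",
            id, paste(bad, collapse = ", "))
  }
  sequence
}

#' Tile a protein into overlapping peptides
#'
#' Decomposes an antigen sequence into overlapping peptides of fixed length
#' on a fixed start offset, the standard design for linear-epitope serology
#' arrays (e.g. 20-mers with a 10-residue offset, so consecutive peptides
#' overlap by 10 residues). The first tile starts at position 1 and tile i
#' starts at `1 + (i - 1) * offset`. The final tile is truncated to end
#' exactly at the protein's last residue; it is never extended past the
#' protein nor back-shifted onto the grid, so the printed panel layout of a
#' truncated terminal peptide is reproduced.
#'
#' @param sequence amino-acid string (standard 20-letter alphabet).
#' @param id antigen identifier used to name tiles as
#'   `"{id}-{ordinal:02d}"`.
#' @param tile_length peptide length in residues (default 20).
#' @param offset start-to-start distance between consecutive tiles
#'   (default 10). Must satisfy `1 <= offset <= tile_length`.
#' @return a `data.frame` with columns `name`, `index`, `start`, `end`,
#'   `sequence`; coordinates are 1-based inclusive.
#' @examples
#' tiles <- tile_protein(strrep("ACDEFGHIKL", 4), id = "demo")
#' nrow(tiles)  # ceil((40 - 20) / 10) + 1 = 3
#' @export
tile_protein <- function(sequence, id = "antigen", tile_length = 20L,
                         offset = 10L) {
  sequence <- validate_protein(sequence, id)
  tile_length <- as.integer(tile_length)
  offset <- as.integer(offset)
  if (is.na(tile_length) || tile_length < 1L) stop_ps("tile_length must be >= 1")
  if (is.na(offset) || offset < 1L) stop_ps("offset must be >= 1")
  if (offset > tile_length) {
    stop_ps("offset (%d) must not exceed tile_length (%d): tiles would leave gaps",
            offset, tile_length)
  }
  L <- nchar(sequence)
  if (L < tile_length) {
    stop_ps("protein '%s' (length %d) is shorter than tile_length %d",
            id, L, tile_length)
  }
  n <- as.integer(ceiling((L - tile_length) / offset)) + 1L
  start <- 1L + (seq_len(n) - 1L) * offset
  end <- pmin(start + tile_length - 1L, L)
  # the truncation rule only ever shortens the final tile
  stopifnot(all(end[-n] == start[-n] + tile_length - 1L), end[n] == L)
  data.frame(
    name = sprintf("%s-%02d", id, seq_len(n)),
    index = seq_len(n),
    start = start,
    end = end,
    sequence = substring(sequence, start, end),
    stringsAsFactors = FALSE
  )
}

#' Reassemble a protein from overlapping tiles
#'
#' Reconstructs the antigen sequence from a table of peptides with known
#' 1-based start positions (the inverse of [tile_protein()], also usable on
#' a published peptide panel table). Consecutive tiles must overlap or abut
#' with residue-level agreement in every overlap.
#'
#' @param tiles a `data.frame` with columns `start` and `sequence`
#'   (additional columns are ignored; `end` is derived from the sequence
#'   length, which guards against typographical end coordinates).
#' @return a single amino-acid string covering positions 1..L.
#' @export
assemble_from_tiles <- function(tiles) {
  check_columns(tiles, c("start", "sequence"), "tile table")
  if (nrow(tiles) < 1L) stop_ps("no tiles to assemble")
  tiles <- tiles[order(tiles$start), , drop = FALSE]
  start <- as.integer(tiles$start)
  seqs <- toupper(as.character(tiles$sequence))
  end <- start + nchar(seqs) - 1L
  if (start[1] != 1L) stop_ps("assembly must start at position 1, got %d", start[1])
  L <- max(end)
  residues <- character(L)
  for (i in seq_along(start)) {
    pos <- start[i]:end[i]
    chars <- strsplit(seqs[i], "")[[1]]
    placed <- residues[pos]
    clash <- placed != "" & placed != chars
    if (any(clash)) {
      at <- pos[which(clash)[1]]
      stop_ps("conflicting residues in overlap at position %d ('%s' vs '%s')",
              at, residues[at], chars[which(clash)[1]])
    }
    residues[pos] <- chars
  }
  gaps <- which(residues == "")
  if (length(gaps) > 0L) {
    stop_ps("gap between consecutive tiles: position %d is uncovered", gaps[1])
  }
  validate_protein(paste(residues, collapse = ""))
}

#' Read an antigen sequence from a FASTA file
#'
#' @param path FASTA file (single or multi record).
#' @param id optional record identifier to select; defaults to the first
#'   record. Matching is on the first whitespace-delimited token of the
#'   FASTA header.
#' @return a list with elements `id` and `sequence`.
#' @export
read_antigen_fasta <- function(path, id = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop_ps("no records in FASTA file '%s'", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (is.null(id)) {
    pick <- 1L
  } else {
    pick <- match(id, ids)
    if (is.na(pick)) stop_ps("record '%s' not found in '%s'", id, path)
  }
  list(id = ids[pick], sequence = validate_protein(as.character(set[[pick]]), ids[pick]))
}

#' Write a peptide tile table as TSV
#'
#' Columns `name`, `start`, `end`, `sequence` (panel-table schema).
#'
#' @param tiles tile `data.frame` from [tile_protein()].
#' @param path output file.
#' @export
write_tiles <- function(tiles, path) {
  check_columns(tiles, c("name", "start", "end", "sequence"), "tile table")
  utils::write.table(tiles[, c("name", "start", "end", "sequence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peptide tile table (TSV)
#'
#' @param path TSV with columns `name`, `start`, `end`, `sequence`.
#' @return tile `data.frame`.
#' @export
read_tiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("name", "start", "end", "sequence"), path)
  df
}

#' The published MGMT 20-peptide panel
#'
#' The 20 overlapping MGMT peptides (20-mers, 10-residue offset, final
#' peptide truncated) used throughout the examples and the synthetic
#' presets, as a tile table. The printed end coordinates are retained
#' verbatim; [assemble_from_tiles()] derives ends from sequence lengths and
#' is therefore robust to the two typographical irregularities in the
#' printed spans.
#'
#' @return tile `data.frame` with columns `name`, `start`, `end`, `sequence`.
#' @export
mgmt_peptide_table <- function() {
  read_tiles(system.file("extdata", "mgmt_peptides.tsv", package = "pepscreen",
                         mustWork = TRUE))
}
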