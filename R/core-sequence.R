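## Antigen sequence handling and tiling-library construction.

#' Load a mature protein monomer sequence
#'
#' Reads a single-record amino-acid FASTA file, or returns a builtin
#' antigen by name. The builtin `"CRP"` is the 206-residue mature human
#' C-reactive protein monomer (the chain obtained after cleaving the signal
#' peptide), the antigen printed on the epitope-mapping array. Its identity
#' is enforced by [validateAnchors()] against eleven known epitope motifs
#' rather than by any network fetch.
#'
#' @param source path to a FASTA file, or the builtin name `"CRP"`.
#' @return an [Biostrings::AAString] with a `proteinId` attribute.
#' @examples
#' crp <- loadMatureSequence("CRP")
#' length(crp)  # 206
#' @export
loadMatureSequence <- function(source = "CRP") {
  stopifnot(is.character(source), length(source) == 1L)
  if (identical(source, "CRP"))
    source <- system.file("extdata", "crp_mature.fasta", package = "epitiler",
                          mustWork = TRUE)
  if (!file.exists(source))
    stop("no such FASTA file or builtin antigen: ", source)
  set <- tryCatch(readAAStringSet(source),
                  error = function(e) stop("malformed FASTA: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) != 1L)
    stop("expected exactly one FASTA record, found ", length(set))
  seq <- toupper(as.character(set[[1L]]))
  if (!grepl(sprintf("^[%s]+$", paste(AA_ALPHABET1, collapse = "")), seq))
    stop("sequence contains non-amino-acid characters")
  out <- AAString(seq)
  attr(out, "proteinId") <- sub("\\s.*$", "", names(set)[1L])
  out
}

#' The eleven mapped CRP epitope anchors
#'
#' Motifs and 1-based inclusive coordinates on the mature CRP monomer of the
#' eleven linear epitopes recognized by patient IgG in the mapped cohort.
#' They double as a sequence fingerprint: the bundled fixture must pass all
#' eleven in [validateAnchors()].
#'
#' @return data.frame with columns `motif`, `start`, `end`.
#' @export
crpAnchors <- function() {
  data.frame(
    motif = c("CLH", "EILIF", "SEIL", "SWE", "VRKSLKK", "ILGQ",
              "SFGGNFEGSQSL", "DIGN", "PDE", "YEVQG", "QLWP"),
    start = c(36L, 62L, 80L, 99L, 117L, 134L, 141L, 155L, 168L, 192L, 203L),
    end   = c(38L, 66L, 83L, 101L, 123L, 137L, 152L, 158L, 170L, 196L, 206L)
  )
}

#' Validate motif anchors against a sequence
#'
#' Checks, for each anchor, that the sequence between `start` and `end`
#' (1-based, inclusive) equals the stated motif. Used as a standing
#' regression test on the bundled CRP fixture.
#'
#' @param seq an [Biostrings::AAString] or single character string.
#' @param anchors data.frame with `motif`, `start`, `end` (default:
#'   [crpAnchors()]).
#' @return data.frame `motif`, `start`, `end`, `found`, `pass`.
#' @export
validateAnchors <- function(seq, anchors = crpAnchors()) {
  seq <- as.character(seq)
  stopifnot(nrow(anchors) > 0L)
  if (any(nchar(anchors$motif) != anchors$end - anchors$start + 1L))
    stop("anchor motif length must equal end - start + 1")
  if (any(anchors$start < 1L) || any(anchors$end > nchar(seq)) ||
      any(anchors$start > anchors$end))
    stop("anchor coordinates out of sequence bounds")
  found <- substring(seq, anchors$start, anchors$end)
  cbind(anchors, found = found, pass = found == anchors$motif)
}

#' Locate exact occurrences of a motif
#'
#' @param seq an [Biostrings::AAString] or single character string.
#' @param motif non-empty amino-acid string.
#' @return integer vector of all 1-based start positions, ascending
#'   (possibly empty).
#' @examples
#' locateMotif(loadMatureSequence("CRP"), "SEIL")  # 80
#' @export
locateMotif <- function(seq, motif) {
  stopifnot(nchar(motif) > 0L)
  if (nchar(motif) > nchar(as.character(seq))) return(integer())
  m <- matchPattern(motif, AAString(as.character(seq)))
  as.integer(Biostrings::start(m))
}

#' Build the overlapping-peptide tiling library
#'
#' Elongates the mature sequence with a neutral flank on both sides and
#' slides a window of `tileLength` residues with `tileLength - overlap`
#' step across the flanked sequence, exactly as the physical array is
#' printed. With the defaults (15-mers, 14-residue overlap, 7-residue GS
#' flank) a 206-residue monomer yields 206 tiles. Each tile records its
#' span on the flanked sequence and its clipped span on the mature
#' sequence; tiles lying wholly within a flank get `NA` mature spans.
#'
#' A warning is issued if the flank creates a spurious match of any supplied
#' anchor motif outside its mature position.
#'
#' @param seq an [Biostrings::AAString] or character string (mature monomer).
#' @param tileLength peptide length in residues (default 15).
#' @param overlap shared residues between consecutive tiles (default 14).
#' @param flank flank sequence used on both sides (default `"GSGSGSG"`, a
#'   7-residue neutral GS linker; `""` for none).
#' @param proteinId label stored in the result.
#' @param checkMotifs optional character vector of motifs checked against
#'   spurious flank-boundary matches (warning only).
#' @return a [PeptideTiling].
#' @examples
#' tl <- tileSequence(loadMatureSequence("CRP"))
#' length(tl)  # 206
#' @export
tileSequence <- function(seq, tileLength = 15L, overlap = 14L,
                         flank = "GSGSGSG",
                         proteinId = attr(seq, "proteinId"),
                         checkMotifs = NULL) {
  protein <- as.character(seq)
  tileLength <- as.integer(tileLength)
  overlap <- as.integer(overlap)
  if (is.null(proteinId)) proteinId <- "protein"
  stopifnot(overlap >= 0L, overlap < tileLength)
  fl <- nchar(flank)
  flanked <- paste0(flank, protein, flank)
  if (tileLength > nchar(flanked))
    stop("tileLength exceeds the flanked sequence length")
  step <- tileLength - overlap
  starts <- seq.int(1L, nchar(flanked) - tileLength + 1L, by = step)
  L <- nchar(protein)
  mStart <- pmax(starts - fl, 1L)
  mEnd <- pmin(starts + tileLength - 1L - fl, L)
  flankOnly <- (starts + tileLength - 1L) <= fl | starts > fl + L
  mStart[flankOnly] <- NA_integer_
  mEnd[flankOnly] <- NA_integer_
  if (!is.null(checkMotifs) && fl > 0L) {
    for (m in checkMotifs) {
      hits <- length(locateMotif(flanked, m)) - length(locateMotif(protein, m))
      if (hits > 0L)
        warning("flank creates ", hits, " spurious match(es) of motif ", m)
    }
  }
  new("PeptideTiling", proteinId = proteinId, protein = protein,
      flank = flank, tileLength = tileLength, overlap = overlap,
      flankedStart = as.integer(starts),
      matureStart = as.integer(mStart), matureEnd = as.integer(mEnd))
}

#' Tabular view of a tiling library
#'
#' @param tiling a [PeptideTiling].
#' @return data.frame with `tile_index` (1-based), `flanked_start`,
#'   `mature_start`, `mature_end` and `sequence` (the printed peptide).
#' @export
tilingTable <- function(tiling) {
  stopifnot(is(tiling, "PeptideTiling"))
  flanked <- paste0(tiling@flank, tiling@protein, tiling@flank)
  data.frame(
    tile_index = seq_along(tiling@flankedStart),
    flanked_start = tiling@flankedStart,
    mature_start = tiling@matureStart,
    mature_end = tiling@matureEnd,
    sequence = substring(flanked, tiling@flankedStart,
                         tiling@flankedStart + tiling@tileLength - 1L)
  )
}

#' Printed peptide sequences of a tiling library
#'
#' @param tiling a [PeptideTiling].
#' @return an [Biostrings::AAStringSet], one entry per tile.
#' @export
tileSequences <- function(tiling) {
  tab <- tilingTable(tiling)
  setNames(AAStringSet(tab$sequence), sprintf("tile%03d", tab$tile_index))
}

#' Write / read a tiling library as tab-separated text
#'
#' The writer stores the antigen, flank and geometry in `#`-prefixed header
#' lines so the reader can reconstruct the full [PeptideTiling] object.
#'
#' @param tiling a [PeptideTiling].
#' @param path file path.
#' @return `writeTilingTable()` returns `path` invisibly;
#'   `readTilingTable()` returns a [PeptideTiling].
#' @export
writeTilingTable <- function(tiling, path) {
  stopifnot(is(tiling, "PeptideTiling"))
  hdr <- c(
    sprintf("# proteinId: %s", tiling@proteinId),
    sprintf("# protein: %s", tiling@protein),
    sprintf("# flank: %s", tiling@flank),
    sprintf("# tileLength: %d", tiling@tileLength),
    sprintf("# overlap: %d", tiling@overlap))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(tilingTable(tiling), con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @rdname writeTilingTable
#' @export
readTilingTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  val <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) stop("tiling table header missing field: ", key)
    sub(sprintf("^# %s:\\s*", key), "", ln[1L])
  }
  tiling <- tileSequence(val("protein"),
                         tileLength = as.integer(val("tileLength")),
                         overlap = as.integer(val("overlap")),
                         flank = val("flank"), proteinId = val("proteinId"))
  tab <- read.delim(textConnection(lines[!grepl("^#", lines)]))
  ref <- tilingTable(tiling)
  if (!identical(tab$sequence, ref$sequence) ||
      nrow(tab) != nrow(ref))
    stop("tiling table rows are inconsistent with its header geometry")
  tiling
}
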