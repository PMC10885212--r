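#' Parse a construct specification string
#'
#' A construct specification describes how to find the random barcode inside
#' a read: the barcode length, an optional fixed spacer between the barcode
#' and the transposon/construct end sequence, and the end sequence itself,
#' which is used as the anchor. The grammar is \code{B<int>[N<int>]<DNA>},
#' e.g. \code{"B17GTGTATAAGAGACAG"} for a Tn5 construct with a 17-bp barcode
#' directly abutting the mosaic end, or \code{"B17N13GTGTATAAGAGACAG"} when
#' 13 fixed bases separate barcode and anchor.
#'
#' @param text Specification string matching \code{B<int>[N<int>]<DNA>}.
#' @param max_anchor_mismatches Maximum number of substitutions tolerated
#'   when locating the anchor in a read (no indels). Default 2.
#' @return An object of class \code{construct_spec} with elements
#'   \code{barcode_length}, \code{spacer_length}, \code{end_sequence} and
#'   \code{max_anchor_mismatches}.
#' @examples
#' parse_construct_spec("B17GTGTATAAGAGACAG")
#' parse_construct_spec("B4N2GTGTATAAGA")
#' @export
parse_construct_spec <- function(text, max_anchor_mismatches = 2L) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  m <- regmatches(text, regexec("^B([0-9]+)(N([0-9]+))?([A-Za-z]+)$", text))[[1]]
  if (length(m) == 0L) {
    stop("malformed construct specification '", text,
         "': expected B<int>[N<int>]<DNA>, e.g. 'B17GTGTATAAGAGACAG'",
         call. = FALSE)
  }
  barcode_length <- as.integer(m[2])
  spacer_length <- if (nzchar(m[4])) as.integer(m[4]) else 0L
  end_sequence <- toupper(m[5])
  construct_spec(barcode_length, end_sequence,
                 spacer_length = spacer_length,
                 max_anchor_mismatches = as.integer(max_anchor_mismatches))
}

#' Construct-specification constructor
#'
#' @param barcode_length Barcode length in bp (>= 1); default 17 (Tn5-style
#'   libraries).
#' @param end_sequence Construct/transposon end sequence over A, C, G, T used
#'   as the anchor; must be at least 10 bp.
#' @param spacer_length Fixed bases between the barcode and the anchor.
#' @param max_anchor_mismatches Substitution budget for anchor matching; must
#'   stay below a third of the anchor length.
#' @return A \code{construct_spec} object.
#' @export
construct_spec <- function(barcode_length = 17L,
                           end_sequence = "GTGTATAAGAGACAG",
                           spacer_length = 0L,
                           max_anchor_mismatches = 2L) {
  barcode_length <- as.integer(barcode_length)
  spacer_length <- as.integer(spacer_length)
  max_anchor_mismatches <- as.integer(max_anchor_mismatches)
  if (is.na(barcode_length) || barcode_length < 1L)
    stop("barcode_length must be >= 1", call. = FALSE)
  if (grepl("[^ACGT]", end_sequence))
    stop("end_sequence must contain only A, C, G, T; got '", end_sequence, "'",
         call. = FALSE)
  if (nchar(end_sequence) < 10L)
    stop("end_sequence must be at least 10 bp long", call. = FALSE)
  if (spacer_length < 0L) stop("spacer_length must be >= 0", call. = FALSE)
  if (max_anchor_mismatches < 0L ||
      max_anchor_mismatches >= nchar(end_sequence) / 3)
    stop("max_anchor_mismatches must be non-negative and below a third of ",
         "the anchor length", call. = FALSE)
  structure(
    list(barcode_length = barcode_length,
         spacer_length = spacer_length,
         end_sequence = end_sequence,
         max_anchor_mismatches = max_anchor_mismatches),
    class = "construct_spec")
}

#' @export
print.construct_spec <- function(x, ...) {
  cat(sprintf(
    "construct_spec: barcode %d bp | spacer %d bp | anchor %s (<=%d mismatches)\n",
    x$barcode_length, x$spacer_length, x$end_sequence,
    x$max_anchor_mismatches))
  invisible(x)
}

## Leftmost anchor offset (1-based start) per read, substitutions only.
## Returns NA where no match within budget.
.anchor_starts <- function(reads, spec) {
  hits <- Biostrings::vmatchPattern(spec$end_sequence, reads,
                                    max.mismatch = spec$max_anchor_mismatches,
                                    with.indels = FALSE, fixed = TRUE)
  starts <- rep(NA_integer_, length(reads))
  n <- S4Vectors::elementNROWS(hits)
  idx <- which(n > 0L)
  if (length(idx)) {
    all_starts <- IRanges::start(unlist(hits, use.names = FALSE))
    first_of <- cumsum(c(1L, n[-length(n)]))  # match starts are ascending
    starts[idx] <- all_starts[first_of[idx]]
  }
  starts
}

#' Extract barcodes (and host junctions) from reads
#'
#' Locates the leftmost occurrence of the construct end sequence in each read,
#' tolerating up to \code{spec$max_anchor_mismatches} substitutions (no
#' indels). The barcode is the \code{barcode_length} bases ending
#' \code{spacer_length + 1} bases before the anchor start; in mapping mode
#' (\code{want_host = TRUE}) the host sequence is everything after the anchor.
#' Reads whose forward orientation carries no anchor are re-searched as their
#' reverse complement. A missing barcode (no anchor, or too few bases before
#' it) is a valid outcome, reported as \code{NA}.
#'
#' @param reads A \code{\link[Biostrings]{DNAStringSet}} (names used as read
#'   ids) or a character vector of sequences.
#' @param spec A \code{\link{construct_spec}}.
#' @param want_host Also report the host sequence downstream of the anchor.
#' @return A data.frame with columns \code{read_id}, \code{barcode} (NA when
#'   absent), \code{host} (empty unless a barcode was found and
#'   \code{want_host}), and \code{anchor_start} (1-based offset of the anchor
#'   in the searched orientation, NA when not found).
#' @export
extract_barcodes <- function(reads, spec, want_host = FALSE) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  n <- length(reads)
  if (n == 0L) {
    return(data.frame(read_id = character(), barcode = character(),
                      host = character(), anchor_start = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- .anchor_starts(reads, spec)
  miss <- which(is.na(starts))
  if (length(miss)) {
    rc <- Biostrings::reverseComplement(reads[miss])
    rc_starts <- .anchor_starts(rc, spec)
    found <- which(!is.na(rc_starts))
    if (length(found)) {
      reads[miss[found]] <- rc[found]
      starts[miss[found]] <- rc_starts[found]
    }
  }
  widths <- Biostrings::width(reads)
  bc_end <- starts - spec$spacer_length - 1L
  bc_start <- bc_end - spec$barcode_length + 1L
  ok <- !is.na(starts) & bc_start >= 1L
  barcode <- rep(NA_character_, n)
  host <- character(n)
  if (any(ok)) {
    barcode[ok] <- as.character(Biostrings::subseq(
      reads[ok], start = bc_start[ok], end = bc_end[ok]))
    if (want_host) {
      h_start <- starts[ok] + nchar(spec$end_sequence)
      w <- widths[ok]
      has_host <- h_start <= w
      if (any(has_host)) {
        hidx <- which(ok)[has_host]
        host[hidx] <- as.character(Biostrings::subseq(
          reads[hidx], start = h_start[has_host], end = w[has_host]))
      }
    }
  }
  data.frame(read_id = ids, barcode = barcode, host = host,
             anchor_start = ifelse(ok, starts, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' Thin wrapper over \code{\link[Biostrings]{readDNAStringSet}} accepting
#' plain or gzip-compressed 4-line FASTQ.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A \code{DNAStringSet} of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L ||
      (grepl("\\.gz$", path) && length(readLines(path, n = 1L)) == 0L))
    return(Biostrings::DNAStringSet())
  Biostrings::readDNAStringSet(path, format = "fastq")
}
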