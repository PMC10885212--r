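#' Count barcodes in a sample
#'
#' Extracts the barcode from every read using the construct anchor and
#' tallies occurrences. Reads without a recognizable barcode (or with an
#' ambiguous N base in the barcode) only contribute to the run statistics.
#'
#' @param reads FASTQ path or \code{DNAStringSet}.
#' @param spec A \code{\link{construct_spec}}.
#' @param sample_id Sample label carried into downstream tables; defaults to
#'   the FASTQ file name stem.
#' @return list with \code{counts} (data.frame \code{barcode},
#'   \code{barcode_count}, sorted by decreasing count), \code{sample_id} and
#'   \code{stats} (reads scanned / with barcode / without barcode).
#' @export
count_reads <- function(reads, spec, sample_id = NULL) {
  if (is.character(reads)) {
    if (is.null(sample_id))
      sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(reads))
    reads <- read_fastq(reads)
  }
  if (is.null(sample_id)) sample_id <- "sample"
  ex <- extract_barcodes(reads, spec, want_host = FALSE)
  bc <- ex$barcode[!is.na(ex$barcode)]
  bc <- bc[!grepl("N", bc, fixed = TRUE)]
  tab <- table(bc)
  counts <- data.frame(barcode = names(tab),
                       barcode_count = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$barcode_count, counts$barcode), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, sample_id = sample_id,
       stats = list(reads_scanned = nrow(ex),
                    reads_with_barcode = length(bc),
                    reads_without_barcode = nrow(ex) - length(bc)))
}

#' Merge near-identical barcodes in a count table
#'
#' Collapses sequencing/PCR variants of the same barcode. With a library map,
#' a counted barcode within Levenshtein distance < \code{max_edit_distance}
#' of exactly one mapped barcode is absorbed into that mapped barcode (the
#' mapped sequence is assumed correct); a counted barcode within range of
#' several mapped barcodes is ambiguous and left untouched. Without a map,
#' merging is greedy by descending abundance (ties broken lexicographically),
#' the more abundant barcode absorbing the rarer one. Total counts are
#' conserved either way.
#'
#' @param counts data.frame with columns \code{barcode},
#'   \code{barcode_count} (as produced by \code{\link{count_reads}}).
#' @param library_map Optional library map data.frame (needs a
#'   \code{barcode} column).
#' @param max_edit_distance Exclusive distance bound; 0 disables merging.
#' @return data.frame \code{barcode}, \code{barcode_count}, sorted by
#'   decreasing count.
#' @export
merge_similar <- function(counts, library_map = NULL,
                          max_edit_distance = 2L) {
  stopifnot(max_edit_distance >= 0L)
  if (max_edit_distance == 0L || nrow(counts) == 0L) return(counts)
  if (is.null(library_map) && nrow(counts) < 2L) return(counts)
  cnt <- stats::setNames(counts$barcode_count, counts$barcode)
  if (!is.null(library_map)) {
    mapped <- unique(library_map$barcode)
    unmapped <- setdiff(names(cnt), mapped)
    if (length(unmapped) && length(mapped)) {
      d <- utils::adist(unmapped, mapped)
      for (i in seq_along(unmapped)) {
        tgt <- which(d[i, ] < max_edit_distance)
        if (length(tgt) == 1L) {
          m <- mapped[tgt]
          cnt[m] <- sum(cnt[m], cnt[unmapped[i]], na.rm = TRUE)
          cnt <- cnt[names(cnt) != unmapped[i]]
        } else if (length(tgt) > 1L) {
          message("barcode ", unmapped[i], " is within distance ",
                  max_edit_distance - 1L, " of ", length(tgt),
                  " mapped barcodes; left unmerged")
        }
      }
    }
  } else {
    ord <- order(-cnt, names(cnt))
    bcs <- names(cnt)[ord]
    vals <- unname(cnt[ord])
    absorbed <- logical(length(bcs))
    for (i in seq_along(bcs)) {
      if (absorbed[i]) next
      rest <- which(!absorbed & seq_along(bcs) > i)
      if (!length(rest)) next
      d <- utils::adist(bcs[i], bcs[rest])[1, ]
      hit <- rest[d < max_edit_distance]
      if (length(hit)) {
        vals[i] <- vals[i] + sum(vals[hit])
        absorbed[hit] <- TRUE
      }
    }
    cnt <- stats::setNames(vals[!absorbed], bcs[!absorbed])
  }
  out <- data.frame(barcode = names(cnt), barcode_count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$barcode_count, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-sample count tables into a count matrix
#'
#' Full outer join of per-sample barcode counts; barcodes absent from a
#' sample get 0. When a library map is supplied, the requested annotation
#' column is carried over per barcode (unmapped barcodes keep an empty
#' annotation and are retained).
#'
#' @param tables Named list of count data.frames (\code{barcode},
#'   \code{barcode_count}); names are the sample ids. Elements produced by
#'   \code{\link{count_reads}} (lists with \code{counts}/\code{sample_id})
#'   are also accepted.
#' @param library_map Optional library map.
#' @param annotation_column Name of the library-map column to carry over
#'   (e.g. \code{"locus_tag"}); \code{NULL} for none.
#' @return data.frame with columns \code{barcode}, optionally the annotation
#'   column, then one integer column per sample.
#' @export
merge_samples <- function(tables, library_map = NULL,
                          annotation_column = NULL) {
  stopifnot(length(tables) >= 1L)
  tabs <- lapply(tables, function(t)
    if (is.list(t) && !is.data.frame(t) && !is.null(t$counts)) t$counts else t)
  ids <- names(tabs)
  if (is.null(ids))
    ids <- vapply(tables, function(t)
      if (is.list(t) && !is.null(t$sample_id)) t$sample_id else NA_character_,
      character(1))
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("every count table must carry a sample id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  barcodes <- sort(unique(unlist(lapply(tabs, `[[`, "barcode"))))
  mat <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  for (i in seq_along(tabs)) {
    v <- stats::setNames(tabs[[i]]$barcode_count, tabs[[i]]$barcode)[barcodes]
    v[is.na(v)] <- 0L
    mat[[ids[i]]] <- as.integer(v)
  }
  if (!is.null(library_map) && !is.null(annotation_column)) {
    if (!annotation_column %in% names(library_map))
      stop("annotation column '", annotation_column,
           "' not found in the library map", call. = FALSE)
    ann <- stats::setNames(as.character(library_map[[annotation_column]]),
                           library_map$barcode)[barcodes]
    ann[is.na(ann)] <- ""
    mat <- cbind(mat[1], stats::setNames(data.frame(ann,
                                                    stringsAsFactors = FALSE),
                                         annotation_column),
                 mat[-1])
    rownames(mat) <- NULL
  }
  mat
}

#' Per-sample barcode relative frequencies
#'
#' Divides each sample column of the count matrix by its total, yielding
#' lineage frequencies suitable for tracking strain abundance over time.
#'
#' @param matrix Count matrix data.frame from \code{\link{merge_samples}}
#'   (columns \code{barcode}, optional annotation, then samples).
#' @return data.frame of the same shape with counts replaced by frequencies;
#'   every sample column sums to 1.
#' @export
barcode_frequencies <- function(matrix) {
  num <- vapply(matrix, is.numeric, logical(1))
  for (j in names(matrix)[num]) {
    s <- sum(matrix[[j]])
    if (s <= 0)
      stop("sample '", j, "' has zero total counts; cannot compute ",
           "frequencies", call. = FALSE)
    matrix[[j]] <- matrix[[j]] / s
  }
  matrix
}
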