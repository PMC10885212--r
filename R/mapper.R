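#' Collect host sequences for library mapping
#'
#' Keeps extractions that carry a barcode and a host junction sequence of at
#' least \code{min_host_len} bases (shorter junctions cannot be placed
#' confidently on the genome), and collapses identical (barcode, host) pairs
#' into one row with a multiplicity.
#'
#' @param extractions data.frame from \code{\link{extract_barcodes}} run with
#'   \code{want_host = TRUE}.
#' @param min_host_len Minimum host length in bp (inclusive); default 20.
#' @return data.frame with columns \code{barcode}, \code{host},
#'   \code{read_count}.
#' @export
collect_host_sequences <- function(extractions, min_host_len = 20L) {
  keep <- !is.na(extractions$barcode) &
    !grepl("N", extractions$barcode, fixed = TRUE) &
    nchar(extractions$host) >= min_host_len
  df <- extractions[keep, c("barcode", "host"), drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no reads with a barcode and a host sequence of >= ",
            min_host_len, " bp; the library map will be empty")
    return(data.frame(barcode = character(), host = character(),
                      read_count = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(read_count = rep(1L, nrow(df))),
                          by = df[c("barcode", "host")], FUN = sum)
  agg <- agg[order(agg$barcode, agg$host), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

## Exact seed-and-verify matcher: place every host on the genome (both
## strands) requiring a full-length exact match. Seeds on the first
## `seed_len` bases via PDict, then verifies the remainder.
.align_exact <- function(hosts, genome, seed_len = 20L) {
  seqs <- as.character(genome)
  chroms <- names(genome)
  uhost <- unique(hosts$host)
  seed_len <- min(seed_len, min(nchar(uhost)))
  seeds <- Biostrings::DNAStringSet(substr(uhost, 1L, seed_len))
  pd <- Biostrings::PDict(seeds)
  out <- vector("list", length(seqs) * 2L)
  k <- 0L
  for (ci in seq_along(seqs)) {
    subject <- genome[[ci]]
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") subject else
        Biostrings::reverseComplement(subject)
      mi <- Biostrings::matchPDict(pd, subj)
      n <- S4Vectors::elementNROWS(mi)
      hit_host <- rep(seq_along(uhost), n)
      st <- IRanges::start(unlist(mi, use.names = FALSE))
      if (!length(st)) next
      ## verify the full host beyond the seed
      full <- nchar(uhost)[hit_host]
      subj_chr <- as.character(subj)
      ok <- st + full - 1L <= Biostrings::nchar(subj) &
        substr(rep(subj_chr, length(st)), st, st + full - 1L) ==
          uhost[hit_host]
      st <- st[ok]; hit_host <- hit_host[ok]; full <- full[ok]
      if (!length(st)) next
      ## junction = reference coordinate of the first host base
      len <- Biostrings::nchar(subject)
      pos <- if (strand == "+") st else len - st + 1L
      k <- k + 1L
      out[[k]] <- data.frame(host = uhost[hit_host], chrom = chroms[ci],
                             position = pos, strand = strand,
                             bitscore = 2 * full,
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(host = character(), chrom = character(),
                      position = integer(), strand = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}

## blastn-based matcher; emits the same columns as .align_exact.
.align_blast <- function(hosts, genome, word_size = 11L) {
  blastn <- Sys.which("blastn")
  makedb <- Sys.which("makeblastdb")
  if (!nzchar(blastn) || !nzchar(makedb))
    stop("external search executables 'blastn'/'makeblastdb' not found on ",
         "PATH; use aligner = \"exact\" or install BLAST+", call. = FALSE)
  tmp <- tempfile("tnbarseq_blast_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  db <- file.path(tmp, "genome.fna")
  qf <- file.path(tmp, "hosts.fna")
  Biostrings::writeXStringSet(genome, db)
  uhost <- unique(hosts$host)
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::DNAStringSet(uhost),
                    paste0("h", seq_along(uhost))), qf)
  system2(makedb, c("-in", db, "-dbtype", "nucl"), stdout = FALSE)
  res <- system2(blastn, c("-query", qf, "-db", db, "-task", "blastn-short",
                           "-word_size", word_size, "-dust", "no",
                           "-outfmt", shQuote("6 qseqid sseqid pident length qstart qend sstart send bitscore")),
                 stdout = TRUE)
  if (!length(res))
    return(data.frame(host = character(), chrom = character(),
                      position = integer(), strand = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  tab <- utils::read.table(text = res, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("qseqid", "sseqid", "pident",
                                         "length", "qstart", "qend",
                                         "sstart", "send", "bitscore"))
  qi <- as.integer(sub("^h", "", tab$qseqid))
  fwd <- tab$sstart <= tab$send
  ## junction: reference coordinate matching the first host base, projected
  ## back through any 5' clipping of the alignment
  pos <- ifelse(fwd, tab$sstart - (tab$qstart - 1L),
                tab$sstart + (tab$qstart - 1L))
  data.frame(host = uhost[qi], chrom = tab$sseqid,
             position = as.integer(pos),
             strand = ifelse(fwd, "+", "-"),
             bitscore = tab$bitscore, stringsAsFactors = FALSE)
}

#' Align host sequences to a reference genome
#'
#' Places each unique host junction sequence on the genome and keeps, per
#' host, only the hit(s) sharing the maximal bitscore. Hits are reported as
#' junction coordinates: the 1-based reference position of the first host
#' base adjacent to the construct (for minus-strand placements this is the
#' rightmost reference coordinate of the alignment). A host surviving at more
#' than one location is flagged ambiguous.
#'
#' @param hosts data.frame from \code{\link{collect_host_sequences}}.
#' @param genome A named \code{DNAStringSet}, or a path to a FASTA file.
#' @param aligner \code{"exact"} (built-in full-length exact matcher),
#'   \code{"blast"} (external blastn, tabular output), or \code{"auto"}
#'   (blastn when available, else exact).
#' @return data.frame with one row per (barcode, host, location):
#'   \code{barcode}, \code{host}, \code{chrom}, \code{position},
#'   \code{strand}, \code{bitscore}, \code{read_count}, \code{n_best}
#'   (number of tied best locations for that host; > 1 means ambiguous).
#' @export
align_hosts <- function(hosts, genome, aligner = c("auto", "exact", "blast")) {
  aligner <- match.arg(aligner)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  empty <- data.frame(barcode = character(), host = character(),
                      chrom = character(), position = integer(),
                      strand = character(), bitscore = numeric(),
                      read_count = integer(), n_best = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hosts) == 0L) return(empty)
  if (aligner == "auto")
    aligner <- if (nzchar(Sys.which("blastn"))) "blast" else "exact"
  hits <- switch(aligner,
                 exact = .align_exact(hosts, genome),
                 blast = .align_blast(hosts, genome))
  if (nrow(hits) == 0L) return(empty)
  ## best-bitscore filter per host
  best <- tapply(hits$bitscore, hits$host, max)
  hits <- hits[hits$bitscore >= best[hits$host] - 1e-9, , drop = FALSE]
  nb <- table(hits$host)
  hits$n_best <- as.integer(nb[hits$host])
  merged <- merge(hosts, hits, by = "host")
  merged <- merged[order(merged$barcode, merged$host, merged$chrom,
                         merged$position), , drop = FALSE]
  rownames(merged) <- NULL
  merged[c("barcode", "host", "chrom", "position", "strand", "bitscore",
           "read_count", "n_best")]
}

## Collapse candidate sites of one barcode: sites within `tol` bp of a
## more-supported site (same chrom/strand) inherit its position.
.collapse_sites <- function(df, tol) {
  df <- df[order(-df$reads, df$chrom, df$position, df$strand), , drop = FALSE]
  n <- nrow(df)
  anchor <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(anchor[i])) next
    anchor[i] <- i
    cand <- which(is.na(anchor) & df$chrom == df$chrom[i] &
                    df$strand == df$strand[i] &
                    abs(df$position - df$position[i]) <= tol)
    anchor[cand] <- i
  }
  agg <- stats::aggregate(df$reads, by = list(anchor = anchor), FUN = sum)
  data.frame(chrom = df$chrom[agg$anchor], position = df$position[agg$anchor],
             strand = df$strand[agg$anchor], reads = agg$x,
             stringsAsFactors = FALSE)
}

#' Resolve each barcode to a primary insertion site
#'
#' Groups alignment hits by barcode, collapses candidate sites within
#' \code{position_tolerance} bp (same chrom and strand) onto the
#' most-supported position, and designates the site with maximal read support
#' as primary. Reads from ambiguous hosts (tied best-score locations) count
#' only toward the denominator. Barcodes whose primary site carries less than
#' \code{min_primary_fraction} of their reads are multimapped artifacts
#' (insertions in repeated regions) and are removed.
#'
#' @param hits data.frame from \code{\link{align_hosts}}.
#' @param min_primary_fraction Minimum fraction of reads at the primary site
#'   for a barcode to be kept (boundary inclusive); default 0.75.
#' @param position_tolerance Collapse radius in bp; default 5.
#' @return data.frame with columns \code{barcode}, \code{chrom},
#'   \code{position}, \code{strand}, \code{total_reads},
#'   \code{primary_fraction}, \code{status} (\code{"kept"} or
#'   \code{"removed_multimapped"}).
#' @export
resolve_locations <- function(hits, min_primary_fraction = 0.75,
                              position_tolerance = 5L) {
  if (nrow(hits) == 0L)
    return(data.frame(barcode = character(), chrom = character(),
                      position = integer(), strand = character(),
                      total_reads = integer(), primary_fraction = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  out <- lapply(split(hits, hits$barcode), function(bh) {
    per_host <- bh[!duplicated(bh$host), c("host", "read_count"), drop = FALSE]
    total <- sum(per_host$read_count)
    unambig <- bh[bh$n_best == 1L, , drop = FALSE]
    if (nrow(unambig) == 0L) {
      return(data.frame(barcode = bh$barcode[1], chrom = NA_character_,
                        position = NA_integer_, strand = NA_character_,
                        total_reads = total, primary_fraction = 0,
                        status = "removed_multimapped",
                        stringsAsFactors = FALSE))
    }
    sites <- stats::aggregate(
      list(reads = unambig$read_count),
      by = unambig[c("chrom", "position", "strand")], FUN = sum)
    sites <- .collapse_sites(sites, position_tolerance)
    top <- which.max(sites$reads)
    pf <- sites$reads[top] / total
    data.frame(barcode = bh$barcode[1], chrom = sites$chrom[top],
               position = sites$position[top], strand = sites$strand[top],
               total_reads = total, primary_fraction = pf,
               status = if (pf >= min_primary_fraction) "kept" else
                 "removed_multimapped",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge near-identical barcodes mapped to the same position
#'
#' Barcodes that map to the same (collapsed) insertion site and differ by a
#' Levenshtein distance strictly below \code{max_edit_distance} are PCR or
#' sequencing artifacts of one true barcode; the more abundant barcode is
#' assumed correct and absorbs the reads of the others. Merging proceeds in
#' descending read abundance (ties broken lexicographically by barcode
#' sequence) so the outcome is deterministic.
#'
#' @param locations data.frame from \code{\link{resolve_locations}}; only
#'   \code{status == "kept"} rows participate.
#' @param max_edit_distance Exclusive edit-distance bound; default 2 (so
#'   distances 0 and 1 merge).
#' @return \code{locations} with merged rows re-labelled
#'   \code{status = "merged_into:<barcode>"} and their reads added to the
#'   absorbing barcode's \code{total_reads}.
#' @export
merge_nearby_barcodes <- function(locations, max_edit_distance = 2L) {
  if (max_edit_distance <= 0L || nrow(locations) == 0L) return(locations)
  kept <- which(locations$status == "kept")
  if (length(kept) < 2L) return(locations)
  key <- paste(locations$chrom[kept], locations$position[kept],
               locations$strand[kept])
  for (grp in split(kept, key)) {
    if (length(grp) < 2L) next
    ord <- grp[order(-locations$total_reads[grp], locations$barcode[grp])]
    absorbed <- logical(length(ord))
    for (i in seq_along(ord)) {
      if (absorbed[i]) next
      rest <- which(!absorbed & seq_along(ord) > i)
      if (!length(rest)) next
      d <- utils::adist(locations$barcode[ord[i]],
                        locations$barcode[ord[rest]])[1, ]
      hit <- rest[d < max_edit_distance]
      if (length(hit)) {
        locations$total_reads[ord[i]] <- locations$total_reads[ord[i]] +
          sum(locations$total_reads[ord[hit]])
        locations$status[ord[hit]] <-
          paste0("merged_into:", locations$barcode[ord[i]])
        absorbed[hit] <- TRUE
      }
    }
  }
  locations
}

#' Annotate insertion sites against a GFF3 file
#'
#' For every kept barcode, reports the overlapping feature of
#' \code{feature_type} or, failing that, the nearest one, with a signed
#' distance (negative when the insertion lies 5' of the feature start in
#' genome coordinates, 0 when inside). For insertions inside a feature the
#' insertion percentile locates the site within the gene, measured from the
#' feature's own 5' end: \code{100 * (site - start + 1) / length} on the plus
#' strand and \code{100 * (end - site + 1) / length} on the minus strand.
#'
#' @param locations data.frame from \code{\link{resolve_locations}} /
#'   \code{\link{merge_nearby_barcodes}}.
#' @param annotation Path to a GFF3 file, or a \code{GRanges}.
#' @param feature_type GFF3 type to annotate against (default
#'   \code{"gene"}).
#' @param attributes GFF3 attribute keys to carry into the map (default
#'   \code{"ID"}). Unknown keys yield empty strings with a warning.
#' @return data.frame (library map) with columns \code{barcode},
#'   \code{number_of_reads}, \code{insertion_site}, \code{chr},
#'   \code{strand}, \code{distance_to_feature}, \code{percentile}, and one
#'   column per requested attribute.
#' @export
annotate_insertions <- function(locations, annotation,
                                feature_type = "gene",
                                attributes = "ID") {
  kept <- locations[locations$status == "kept", , drop = FALSE]
  map <- data.frame(barcode = kept$barcode,
                    number_of_reads = kept$total_reads,
                    insertion_site = kept$position,
                    chr = kept$chrom, strand = kept$strand,
                    distance_to_feature = rep(NA_integer_, nrow(kept)),
                    percentile = rep(NA_real_, nrow(kept)),
                    stringsAsFactors = FALSE)
  for (a in attributes) map[[a]] <- rep("", nrow(kept))
  if (nrow(map) == 0L) return(map)
  gr <- if (methods::is(annotation, "GRanges")) annotation else
    rtracklayer::import(annotation, format = "gff3")
  feats <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
  if (length(feats) == 0L) {
    warning("no features of type '", feature_type,
            "' in the annotation; all insertions reported intergenic")
    return(map)
  }
  missing_attr <- setdiff(attributes, names(S4Vectors::mcols(feats)))
  if (length(missing_attr))
    warning("attribute key(s) not present in the annotation: ",
            paste(missing_attr, collapse = ", "))
  sites <- GenomicRanges::GRanges(map$chr,
                                  IRanges::IRanges(map$insertion_site,
                                                   width = 1L))
  nn <- GenomicRanges::nearest(sites, feats, ignore.strand = TRUE)
  for (i in seq_len(nrow(map))) {
    j <- nn[i]
    if (is.na(j)) next
    fs <- GenomicRanges::start(feats)[j]
    fe <- GenomicRanges::end(feats)[j]
    fstrand <- as.character(GenomicRanges::strand(feats))[j]
    site <- map$insertion_site[i]
    if (site < fs) {
      map$distance_to_feature[i] <- site - fs
    } else if (site > fe) {
      map$distance_to_feature[i] <- site - fe
    } else {
      map$distance_to_feature[i] <- 0L
      flen <- fe - fs + 1L
      map$percentile[i] <- if (fstrand == "-")
        100 * (fe - site + 1) / flen else 100 * (site - fs + 1) / flen
    }
    for (a in setdiff(attributes, missing_attr)) {
      v <- S4Vectors::mcols(feats)[[a]][j]
      if (methods::is(v, "List") || is.list(v))
        v <- paste(unlist(v), collapse = ";")
      map[[a]][i] <- if (is.na(v)) "" else as.character(v)
    }
  }
  map
}

#' Map a barcoded insertion library
#'
#' End-to-end library mapping: extract barcode + host junction from each
#' read, align hosts of at least \code{min_host_len} bp to the genome, keep
#' best-bitscore placements, resolve each barcode to a primary site (removing
#' multimapped barcodes), merge near-identical barcodes at the same site, and
#' annotate against the GFF3 file.
#'
#' @param reads FASTQ path or \code{DNAStringSet}.
#' @param genome FASTA path or named \code{DNAStringSet}.
#' @param annotation GFF3 path or \code{GRanges}; \code{NULL} to skip
#'   annotation.
#' @param spec A \code{\link{construct_spec}}.
#' @param min_host_len Minimum host junction length (default 20).
#' @param min_primary_fraction Primary-location filter threshold (default
#'   0.75).
#' @param max_edit_distance Exclusive barcode-merge distance (default 2).
#' @param feature_type,attributes Passed to
#'   \code{\link{annotate_insertions}}.
#' @param aligner Passed to \code{\link{align_hosts}}.
#' @return list with \code{map} (the annotated library map) and \code{stats}
#'   (named list of run statistics).
#' @export
map_library <- function(reads, genome, annotation, spec,
                        min_host_len = 20L, min_primary_fraction = 0.75,
                        max_edit_distance = 2L, feature_type = "gene",
                        attributes = "ID", aligner = "auto") {
  if (is.character(reads)) reads <- read_fastq(reads)
  ex <- extract_barcodes(reads, spec, want_host = TRUE)
  stats <- list(reads_scanned = nrow(ex),
                reads_with_barcode = sum(!is.na(ex$barcode)))
  hosts <- if (stats$reads_with_barcode > 0L)
    collect_host_sequences(ex, min_host_len) else
      data.frame(barcode = character(), host = character(),
                 read_count = integer(), stringsAsFactors = FALSE)
  stats$reads_with_host <- sum(hosts$read_count)
  hits <- align_hosts(hosts, genome, aligner = aligner)
  locs <- resolve_locations(hits, min_primary_fraction)
  stats$barcodes_aligned <- nrow(locs)
  stats$barcodes_multimapped <- sum(locs$status == "removed_multimapped")
  locs <- merge_nearby_barcodes(locs, max_edit_distance)
  stats$barcodes_merged <- sum(startsWith(locs$status, "merged_into"))
  stats$barcodes_kept <- sum(locs$status == "kept")
  map <- if (is.null(annotation)) {
    kept <- locs[locs$status == "kept", , drop = FALSE]
    data.frame(barcode = kept$barcode, number_of_reads = kept$total_reads,
               insertion_site = kept$position, chr = kept$chrom,
               strand = kept$strand,
               distance_to_feature = rep(NA_integer_, nrow(kept)),
               percentile = rep(NA_real_, nrow(kept)),
               stringsAsFactors = FALSE)
  } else {
    annotate_insertions(locs, annotation, feature_type, attributes)
  }
  stats$unique_insertion_sites <-
    length(unique(paste(map$chr, map$insertion_site)))
  if (!is.null(annotation) && length(attributes) &&
      attributes[1] %in% names(map)) {
    in_gene <- !is.na(map$percentile)
    stats$genes_hit <- length(unique(map[[attributes[1]]][in_gene]))
    core <- in_gene & map$percentile >= 5 & map$percentile <= 95
    stats$genes_hit_5_95 <- length(unique(map[[attributes[1]]][core]))
  } else {
    stats$genes_hit <- 0L
    stats$genes_hit_5_95 <- 0L
  }
  list(map = map, stats = stats)
}
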