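#' Simulate a genome with gene annotation
#'
#' Generates a random DNA sequence and packs non-overlapping gene features
#' onto it (random strands, lengths uniform between
#' \code{gene_length_range}), each carrying \code{ID}, \code{Name} and
#' \code{locus_tag} attributes. Optionally a segment is duplicated verbatim
#' elsewhere on the chromosome to create an exact repeat for multimapping
#' tests. Fully deterministic under a fixed seed.
#'
#' @param length_bp Genome length.
#' @param n_genes Number of gene features.
#' @param seed RNG seed.
#' @param gene_length_range Min/max gene length; default c(600, 1200).
#' @param repeat_copies Number of copies of an identical
#'   \code{repeat_length}-bp segment to embed (0 or >= 2).
#' @param repeat_length Length of the repeated segment; default 1000.
#' @return list with \code{genome} (named \code{DNAStringSet}, one
#'   chromosome \code{"chr1"}), \code{annotation} (\code{GRanges} of gene
#'   features) and \code{repeats} (start positions of repeat copies).
#' @export
sim_genome <- function(length_bp, n_genes, seed = 1L,
                       gene_length_range = c(600L, 1200L),
                       repeat_copies = 0L, repeat_length = 1000L) {
  set.seed(seed)
  mean_len <- mean(gene_length_range)
  if (n_genes * mean_len >= length_bp)
    stop("cannot pack ", n_genes, " genes of mean length ", mean_len,
         " into ", length_bp, " bp", call. = FALSE)
  seq <- paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
               collapse = "")
  starts <- integer(0); ends <- integer(0); strands <- character(0)
  if (n_genes > 0L) {
    lens <- sample(seq(gene_length_range[1], gene_length_range[2]),
                   n_genes, replace = TRUE)
    slack <- length_bp - sum(lens)
    gaps <- slack * as.vector(stats::rmultinom(1, 1000L,
                                               rep(1, n_genes + 1L))) / 1000L
    starts <- cumsum(gaps[seq_len(n_genes)] + c(0, lens[-n_genes]))
    starts <- pmax(1L, as.integer(floor(starts)) + 1L)
    ends <- starts + lens - 1L
    if (any(ends > length_bp) || any(diff(starts) <= 0))
      stop("infeasible gene packing", call. = FALSE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  }
  rep_starts <- integer(0)
  if (repeat_copies >= 2L) {
    if (repeat_copies * repeat_length > length_bp)
      stop("repeat copies do not fit in the genome", call. = FALSE)
    rep_starts <- as.integer(floor(
      seq(1L, length_bp - repeat_length + 1L, length.out = repeat_copies)))
    segment <- substr(seq, rep_starts[1], rep_starts[1] + repeat_length - 1L)
    for (s in rep_starts[-1])
      substr(seq, s, s + repeat_length - 1L) <- segment
  }
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chr1"
  ann <- GenomicRanges::GRanges(
    seqnames = rep("chr1", n_genes),
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands)
  if (n_genes > 0L) {
    ids <- sprintf("gene_%04d", seq_len(n_genes))
    ann$type <- "gene"
    ann$ID <- ids
    ann$Name <- sprintf("gn%04d", seq_len(n_genes))
    ann$locus_tag <- sprintf("TB_%04d", seq_len(n_genes))
  } else {
    ann$type <- character(0)
  }
  list(genome = genome, annotation = ann, repeats = rep_starts)
}

#' Write simulated genome and annotation to FASTA/GFF3
#'
#' @param sim Output of \code{\link{sim_genome}}.
#' @param fasta,gff3 Output paths.
#' @return Invisible list of the two paths.
#' @export
write_sim_genome <- function(sim, fasta, gff3) {
  Biostrings::writeXStringSet(sim$genome, fasta)
  rtracklayer::export(sim$annotation, gff3, format = "gff3")
  invisible(list(fasta = fasta, gff3 = gff3))
}

#' Generate random barcodes
#'
#' Draws unique random barcodes over A/C/G/T, rejecting candidates within
#' Levenshtein distance < \code{min_distance} of an accepted barcode, so the
#' default library has no spurious merge partners.
#'
#' @param n Number of barcodes.
#' @param barcode_length Length in bp; default 17.
#' @param min_distance Minimum pairwise edit distance; default 3.
#' @return Character vector of barcodes.
#' @export
random_barcodes <- function(n, barcode_length = 17L, min_distance = 3L) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need * 2L), function(i)
      paste(sample(c("A", "C", "G", "T"), barcode_length, replace = TRUE),
            collapse = ""), character(1))
    cand <- unique(cand)
    for (b in cand) {
      if (length(out) >= n) break
      if (!length(out) || min(utils::adist(b, out)) >= min_distance)
        out <- c(out, b)
    }
  }
  out
}

#' Simulate a barcoded insertion library
#'
#' Draws uniform random insertion sites and strands on the simulated genome
#' and assigns each a unique random barcode (pairwise edit distance >= 3
#' unless \code{collision_pairs} near-duplicate barcodes are requested, which
#' are planted at distance 1 from an existing barcode at the same site to
#' exercise downstream merging). Each insertion is annotated with the gene
#' it falls in, if any.
#'
#' @param sim Output of \code{\link{sim_genome}}.
#' @param n_insertions Number of insertions.
#' @param barcode_length Barcode length; default 17.
#' @param seed RNG seed.
#' @param collision_pairs Number of planted distance-1 barcode pairs.
#' @return data.frame truth table: \code{barcode}, \code{chrom},
#'   \code{position}, \code{strand}, \code{gene} (ID attribute or "" when
#'   intergenic).
#' @export
sim_library <- function(sim, n_insertions, barcode_length = 17L, seed = 1L,
                        collision_pairs = 0L) {
  set.seed(seed)
  len <- Biostrings::width(sim$genome)[1]
  pos <- sample.int(len, n_insertions, replace = FALSE)
  strand <- sample(c("+", "-"), n_insertions, replace = TRUE)
  bcs <- random_barcodes(n_insertions, barcode_length)
  truth <- data.frame(barcode = bcs, chrom = "chr1", position = pos,
                      strand = strand, stringsAsFactors = FALSE)
  if (collision_pairs > 0L) {
    for (i in seq_len(collision_pairs)) {
      src <- truth[i, ]
      bc <- src$barcode
      p <- sample.int(nchar(bc), 1L)
      repl <- sample(setdiff(c("A", "C", "G", "T"),
                             substr(bc, p, p)), 1L)
      substr(bc, p, p) <- repl
      truth <- rbind(truth, data.frame(barcode = bc, chrom = src$chrom,
                                       position = src$position,
                                       strand = src$strand,
                                       stringsAsFactors = FALSE))
    }
  }
  sites <- GenomicRanges::GRanges(truth$chrom,
                                  IRanges::IRanges(truth$position,
                                                   width = 1L))
  ov <- GenomicRanges::findOverlaps(sites, sim$annotation,
                                    ignore.strand = TRUE)
  truth$gene <- ""
  if (length(ov))
    truth$gene[S4Vectors::queryHits(ov)] <-
      sim$annotation$ID[S4Vectors::subjectHits(ov)]
  truth
}

.mutate_seq <- function(x, error_rate) {
  if (error_rate <= 0) return(x)
  chars <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(chars)) < error_rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Simulate library-mapping reads
#'
#' Emits reads of the construct-primed mapping protocol:
#' barcode + spacer + construct end sequence + host junction, where the host
#' is the genomic flank starting at the insertion site (strand-aware).
#' Substitution errors are applied at \code{error_rate} per base and each
#' read is emitted in a random orientation.
#'
#' @param truth Insertion table from \code{\link{sim_library}}.
#' @param sim Output of \code{\link{sim_genome}}.
#' @param spec A \code{\link{construct_spec}}.
#' @param depth_per_barcode Reads per insertion.
#' @param read_len Read length; must exceed barcode + spacer + anchor by at
#'   least 20 bp of host.
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param fastq Optional path; when given, reads are written as FASTQ
#'   (constant quality) and the path is returned.
#' @return \code{DNAStringSet} of reads (or the FASTQ path).
#' @export
sim_mapping_reads <- function(truth, sim, spec, depth_per_barcode = 50L,
                              read_len = 100L, error_rate = 0,
                              seed = 1L, fastq = NULL) {
  set.seed(seed)
  prefix_len <- spec$barcode_length + spec$spacer_length +
    nchar(spec$end_sequence)
  if (read_len <= prefix_len + 20L)
    stop("read_len must exceed barcode + spacer + anchor by > 20 bp",
         call. = FALSE)
  host_len <- read_len - prefix_len
  chrom_seq <- as.character(sim$genome[[1]])
  len <- nchar(chrom_seq)
  spacer <- if (spec$spacer_length > 0L)
    paste(rep("T", spec$spacer_length), collapse = "") else ""
  reads <- character(0)
  if (depth_per_barcode > 0L && nrow(truth) > 0L) {
    hosts <- vapply(seq_len(nrow(truth)), function(i) {
      p <- truth$position[i]
      if (truth$strand[i] == "+") {
        substr(chrom_seq, p, min(len, p + host_len - 1L))
      } else {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(
          substr(chrom_seq, max(1L, p - host_len + 1L), p))))
      }
    }, character(1))
    base <- paste0(truth$barcode, spacer, spec$end_sequence, hosts)
    reads <- rep(base, each = depth_per_barcode)
    if (error_rate > 0)
      reads <- vapply(reads, .mutate_seq, character(1), error_rate,
                      USE.NAMES = FALSE)
    flip <- stats::runif(length(reads)) < 0.5
    if (any(flip))
      reads[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[flip])))
  }
  ds <- Biostrings::DNAStringSet(reads)
  names(ds) <- sprintf("simread_%06d", seq_along(ds))
  if (!is.null(fastq)) {
    write_fastq(ds, fastq)
    return(fastq)
  }
  ds
}

#' Write a DNAStringSet as FASTQ with constant quality
#'
#' @param reads Named \code{DNAStringSet}.
#' @param path Output path (gzip when ending in .gz).
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    qual <- vapply(Biostrings::width(reads), function(w)
      paste(rep("I", w), collapse = ""), character(1))
    writeLines(paste0("@", names(reads), "\n", as.character(reads), "\n+\n",
                      qual), con)
  }
  invisible(path)
}

#' Simulate a selection screen count matrix
#'
#' Emulates a barcode-abundance screen with known ground truth. Baseline
#' lineage abundances are Dirichlet(1)-distributed; in treatment samples
#' each barcode's abundance is scaled by 2^LFC, where the barcode LFC is its
#' gene's true LFC plus Normal(0, \code{barcode_jitter_sd}) jitter (drawn
#' once per barcode). An optional multinomial bottleneck of
#' \code{bottleneck_size} cells is applied per treatment sample before
#' sequencing. Counts are negative binomial with
#' sigma^2 = mu + dispersion * mu^2 at sequencing depth \code{depth}.
#' Wild-type control barcodes can be spiked at fixed relative
#' concentrations.
#'
#' @param n_genes Number of genes.
#' @param barcodes_per_gene Insertions per gene; default 3.
#' @param gene_lfc Named numeric vector of true LFCs per gene id
#'   (\code{sprintf("gene_\%04d", i)}); unnamed genes default to 0.
#' @param n_control,n_treatment Replicates per condition; default 3 each.
#' @param depth Expected total reads per sample; default 1e6.
#' @param dispersion NB dispersion phi; default 0.1.
#' @param bottleneck_size Optional number of cells surviving a bottleneck in
#'   treatment samples.
#' @param controls Optional data.frame (\code{genotype},
#'   \code{concentration}); one wild-type control barcode is spiked per row,
#'   with abundance proportional to its concentration.
#' @param barcode_jitter_sd Per-barcode LFC jitter (log2); default 0.2.
#' @param barcode_length Barcode length; default 17.
#' @param seed RNG seed.
#' @return list with \code{matrix} (count matrix data.frame:
#'   \code{barcode}, \code{gene}, sample columns), \code{design},
#'   \code{controls} (spiked control table with barcodes, or NULL), and
#'   \code{truth} (per-barcode true LFC table).
#' @export
sim_screen <- function(n_genes, barcodes_per_gene = 3L, gene_lfc = NULL,
                       n_control = 3L, n_treatment = 3L, depth = 1e6,
                       dispersion = 0.1, bottleneck_size = NULL,
                       controls = NULL, barcode_jitter_sd = 0.2,
                       barcode_length = 17L, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  lfc <- stats::setNames(rep(0, n_genes), genes)
  if (!is.null(gene_lfc)) lfc[names(gene_lfc)] <- gene_lfc
  n_bc <- n_genes * barcodes_per_gene
  gene_of <- rep(genes, each = barcodes_per_gene)
  bc_lfc <- lfc[gene_of] + stats::rnorm(n_bc, 0, barcode_jitter_sd)
  n_ctrl_bc <- if (is.null(controls)) 0L else nrow(controls)
  bcs <- random_barcodes(n_bc + n_ctrl_bc, barcode_length)
  base <- stats::rexp(n_bc)
  base <- base / sum(base)
  ctrl_tab <- NULL
  if (n_ctrl_bc > 0L) {
    ctrl_tab <- data.frame(barcode = bcs[n_bc + seq_len(n_ctrl_bc)],
                           genotype = controls$genotype,
                           concentration = controls$concentration,
                           stringsAsFactors = FALSE)
    ## controls take a fixed 5% of the population, split by concentration
    spike <- 0.05 * controls$concentration / sum(controls$concentration)
    base <- c(base * 0.95, spike)
    bc_lfc <- c(bc_lfc, rep(0, n_ctrl_bc))
    gene_of <- c(gene_of, rep("", n_ctrl_bc))
  }
  samples <- c(paste0("control_", seq_len(n_control)),
               paste0("treatment_", seq_len(n_treatment)))
  cond <- rep(c("control", "treatment"), c(n_control, n_treatment))
  trt_ab <- base * 2^bc_lfc
  trt_ab <- trt_ab / sum(trt_ab)
  counts <- matrix(0L, nrow = length(base), ncol = length(samples),
                   dimnames = list(bcs, samples))
  size <- 1 / dispersion
  for (j in seq_along(samples)) {
    ab <- if (cond[j] == "control") base else trt_ab
    if (cond[j] == "treatment" && !is.null(bottleneck_size)) {
      surv <- stats::rmultinom(1, bottleneck_size, ab)[, 1]
      ab <- surv / sum(surv)
    }
    mu <- ab * depth
    counts[, j] <- stats::rnbinom(length(mu), mu = mu, size = size)
  }
  mat <- data.frame(barcode = bcs, gene = gene_of, stringsAsFactors = FALSE)
  for (j in seq_along(samples)) mat[[samples[j]]] <- counts[, j]
  list(matrix = mat,
       design = data.frame(sample_id = samples, condition = cond,
                           stringsAsFactors = FALSE),
       controls = ctrl_tab,
       truth = data.frame(barcode = bcs, gene = gene_of, true_lfc = bc_lfc,
                          stringsAsFactors = FALSE))
}
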