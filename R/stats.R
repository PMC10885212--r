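#' Dilution-series quality control with wild-type control barcodes
#'
#' In vivo screens can pass through severe population bottlenecks that
#' scramble barcode abundances. Spiking wild-type control strains at known
#' relative concentrations lets each sample be checked: counts of the
#' wild-type controls should scale with their spiked concentrations. Per
#' sample, an ordinary least-squares regression of log10(count + 1) on
#' log10(concentration) over the wild-type control barcodes is fit on raw
#' counts; samples with r-squared at or below 0.8 are flagged for removal.
#' At least 4 wild-type control barcodes are required; with fewer, QC is
#' skipped (all samples retained) with a warning.
#'
#' @param matrix Count matrix data.frame (columns \code{barcode}, optional
#'   annotation, then samples).
#' @param controls data.frame with columns \code{barcode}, \code{genotype},
#'   \code{concentration}; rows with genotype \code{"wt"} (case-insensitive)
#'   form the dilution series.
#' @param r_squared_min Retention threshold (exclusive); default 0.8.
#' @return data.frame with columns \code{sample_id}, \code{r_squared},
#'   \code{retained}.
#' @export
qc_controls <- function(matrix, controls, r_squared_min = 0.8) {
  samples <- names(matrix)[vapply(matrix, is.numeric, logical(1))]
  wt <- controls[tolower(controls$genotype) %in% c("wt", "wildtype",
                                                   "wild-type"), ,
                 drop = FALSE]
  wt <- wt[!duplicated(wt$barcode), , drop = FALSE]
  present <- wt$barcode %in% matrix$barcode
  if (sum(present) < 4L) {
    warning("fewer than 4 wild-type control barcodes found in the count ",
            "matrix; QC skipped, all samples retained")
    return(data.frame(sample_id = samples, r_squared = NA_real_,
                      retained = TRUE, stringsAsFactors = FALSE))
  }
  wt <- wt[present, , drop = FALSE]
  idx <- match(wt$barcode, matrix$barcode)
  x <- log10(wt$concentration)
  res <- lapply(samples, function(s) {
    y <- log10(matrix[[s]][idx] + 1)
    r2 <- if (stats::var(y) == 0) 0 else
      summary(stats::lm(y ~ x))$r.squared
    data.frame(sample_id = s, r_squared = r2,
               retained = r2 > r_squared_min, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-sample size factors
#'
#' Median-of-ratios normalization: a reference pseudo-sample is built as the
#' per-barcode geometric mean across samples (barcodes with a zero anywhere
#' are excluded from the reference), and each sample's size factor is the
#' median ratio of its counts to the reference. With
#' \code{method = "control"} the median is taken over the wild-type control
#' barcodes only, which anchors normalization to strains of known neutral
#' fitness and is robust to genuine global abundance shifts (e.g.
#' bottlenecked in vivo samples). Factors are rescaled to geometric mean 1 so
#' normalization is idempotent.
#'
#' @param matrix Count matrix data.frame.
#' @param method \code{"median"} (all eligible barcodes) or
#'   \code{"control"}.
#' @param controls Control table (needed for \code{method = "control"}).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(matrix, method = c("median", "control"),
                         controls = NULL) {
  method <- match.arg(method)
  samples <- names(matrix)[vapply(matrix, is.numeric, logical(1))]
  m <- as.matrix(matrix[samples])
  rownames(m) <- matrix$barcode
  if (method == "control") {
    if (is.null(controls)) stop("method = \"control\" requires a control ",
                                "table", call. = FALSE)
    keep <- rownames(m) %in% controls$barcode
    if (!any(keep)) stop("no control barcodes found in the count matrix",
                         call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  pos <- rowSums(m == 0) == 0
  if (!any(pos))
    stop("no barcode has positive counts in every sample; median-of-ratios ",
         "is undefined - consider control normalization", call. = FALSE)
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE] / ref, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, samples)
}

#' Normalize a count matrix by size factors
#'
#' @param matrix Count matrix data.frame.
#' @param sf Named size factors from \code{\link{size_factors}}.
#' @return The matrix with each sample column divided by its size factor.
#' @export
normalize_counts <- function(matrix, sf) {
  for (s in names(sf)) matrix[[s]] <- matrix[[s]] / sf[[s]]
  matrix
}

#' Fit the mean-variance relation of replicate counts
#'
#' Replicated barcode counts are overdispersed relative to Poisson. The
#' relation sigma^2(mu) = mu + exp(b) * mu^k is fitted by least squares of
#' log(v - mu) on log(mu) over barcodes whose empirical variance exceeds
#' their mean. The model falls back to Poisson (sigma^2 = mu) when a fit is
#' not warranted: with a single replicate, with fewer than
#' \code{min_barcodes} overdispersed barcodes, or when a pooled chi-square
#' dispersion test finds no significant overdispersion (for Poisson
#' replicates roughly half of all barcodes show v > mu by chance, so the
#' existence of such barcodes alone is not evidence of overdispersion).
#'
#' @param counts Numeric matrix or data.frame of normalized counts, barcodes
#'   in rows, replicate samples in columns.
#' @param min_barcodes Minimum number of overdispersed barcodes for a fit;
#'   default 10.
#' @param dispersion_test_p Significance level of the pooled chi-square
#'   dispersion test (statistic sum over barcodes of (r - 1) v / mu with
#'   r replicates, referred to its Poisson null); default 0.05.
#' @return list of class \code{mean_variance_model} with elements \code{k},
#'   \code{b}, \code{fallback_poisson}.
#' @export
fit_mean_variance <- function(counts, min_barcodes = 10L,
                              dispersion_test_p = 0.05) {
  m <- as.matrix(counts)
  model <- list(k = NA_real_, b = NA_real_, fallback_poisson = TRUE)
  class(model) <- "mean_variance_model"
  if (ncol(m) < 2L) return(model)
  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var)
  use <- mu > 0 & v > mu
  if (sum(use) < min_barcodes) return(model)
  r <- ncol(m)
  pos <- mu > 0
  x2 <- sum((r - 1) * v[pos] / mu[pos])
  df <- sum(pos) * (r - 1)
  if (stats::pchisq(x2, df, lower.tail = FALSE) > dispersion_test_p)
    return(model)
  fit <- stats::lm(log(v[use] - mu[use]) ~ log(mu[use]))
  model$b <- unname(stats::coef(fit)[1])
  model$k <- unname(stats::coef(fit)[2])
  model$fallback_poisson <- FALSE
  model
}

#' Modeled count variance at a given mean
#'
#' @param model A \code{mean_variance_model}.
#' @param mu Mean normalized count(s).
#' @return sigma^2(mu) = mu + exp(b) * mu^k, or mu under the Poisson
#'   fallback.
#' @export
model_variance <- function(model, mu) {
  if (model$fallback_poisson) return(mu)
  mu + exp(model$b) * mu^model$k
}

#' Per-barcode selection test
#'
#' For each barcode, the mean normalized control count mu and the
#' model variance sigma^2(mu) parameterize a negative-binomial null
#' (Poisson when sigma^2 <= mu). One-sided tail p-values are computed for
#' the observed mean normalized treatment count T: p_neg = P(X <= T)
#' (depletion) and p_pos = P(X >= T) (enrichment). The log2 fold change uses
#' a pseudocount of 1: lfc = log2((T + 1) / (mu + 1)). Percentile ranks
#' u = rank / n (ascending p, average ties) over all tested barcodes feed
#' the gene-level rank aggregation.
#'
#' @param matrix Count matrix data.frame (raw counts).
#' @param design data.frame with columns \code{sample_id},
#'   \code{condition}.
#' @param sf Size factors.
#' @param model \code{mean_variance_model}.
#' @param treatment,control Condition labels in \code{design}.
#' @param gene_column Optional annotation column naming each barcode's gene.
#' @return data.frame with one row per tested barcode: \code{barcode},
#'   \code{gene}, \code{control_mean}, \code{treatment_mean}, \code{lfc},
#'   \code{p_neg}, \code{p_pos}, \code{rank_neg}, \code{rank_pos}. Barcodes
#'   with zero mean in both conditions are excluded.
#' @export
barcode_test <- function(matrix, design, sf, model,
                         treatment = "treatment", control = "control",
                         gene_column = NULL) {
  ctrl_samples <- design$sample_id[design$condition == control]
  trt_samples <- design$sample_id[design$condition == treatment]
  stopifnot(length(ctrl_samples) >= 1L, length(trt_samples) >= 1L)
  norm <- normalize_counts(matrix, sf)
  mu <- rowMeans(as.matrix(norm[ctrl_samples]))
  trt <- rowMeans(as.matrix(norm[trt_samples]))
  keep <- mu > 0 | trt > 0
  mu <- mu[keep]; trt <- trt[keep]
  gene <- if (!is.null(gene_column) && gene_column %in% names(matrix))
    as.character(matrix[[gene_column]])[keep] else rep(NA_character_,
                                                       sum(keep))
  v <- model_variance(model, mu)
  p_neg <- p_pos <- numeric(length(mu))
  nb <- v > mu & mu > 0
  if (any(nb)) {
    size <- mu[nb]^2 / (v[nb] - mu[nb])
    p_neg[nb] <- stats::pnbinom(floor(trt[nb]), mu = mu[nb], size = size)
    p_pos[nb] <- 1 - stats::pnbinom(ceiling(trt[nb]) - 1, mu = mu[nb],
                                    size = size)
  }
  if (any(!nb)) {
    p_neg[!nb] <- stats::ppois(floor(trt[!nb]), lambda = mu[!nb])
    p_pos[!nb] <- 1 - stats::ppois(ceiling(trt[!nb]) - 1,
                                   lambda = mu[!nb])
  }
  n <- length(mu)
  data.frame(barcode = matrix$barcode[keep], gene = gene,
             control_mean = mu, treatment_mean = trt,
             lfc = log2((trt + 1) / (mu + 1)),
             p_neg = p_neg, p_pos = p_pos,
             rank_neg = rank(p_neg, ties.method = "average") / n,
             rank_pos = rank(p_pos, ties.method = "average") / n,
             stringsAsFactors = FALSE)
}

## alpha-RRA score for one gene: sorted member percentile ranks u (length m)
## with logical `good`; rho = min over good k of P(Beta(k, m-k+1) <= u_(k)).
.rra_rho <- function(u, good) {
  ord <- order(u)
  u <- u[ord]; good <- good[ord]
  if (!any(good)) return(1)
  m <- length(u)
  k <- which(good)
  min(stats::pbeta(u[k], k, m - k + 1))
}

## Vectorized null rho: `uM`/`goodM` are n_perm x m matrices of sampled
## barcode ranks and good flags.
.rra_rho_matrix <- function(uM, goodM) {
  m <- ncol(uM)
  ord <- t(apply(uM, 1, order))
  rows <- rep(seq_len(nrow(uM)), m)
  idx <- cbind(rows, as.vector(ord))
  uS <- matrix(uM[idx], ncol = m)
  gS <- matrix(goodM[idx], ncol = m)
  beta <- vapply(seq_len(m), function(k)
    stats::pbeta(uS[, k], k, m - k + 1), numeric(nrow(uM)))
  beta <- matrix(beta, ncol = m)
  beta[!gS] <- Inf
  rho <- do.call(pmin, as.data.frame(beta))
  rho[is.infinite(rho)] <- 1
  rho
}

#' Robust rank aggregation of barcode ranks into gene scores
#'
#' Aggregates per-barcode percentile ranks into a per-gene, per-direction
#' score rho using the alpha-thresholded robust rank aggregation of the
#' MAGeCK framework: with the gene's m member ranks sorted
#' u_(1) <= ... <= u_(m), rho = min over "good" k (barcodes whose
#' direction p-value is below \code{alpha}) of P(Beta(k, m-k+1) <= u_(k)).
#' Genes with no good barcode score rho = 1. Significance is assessed by
#' permutation: for each gene size, \code{n_perm} random reassignments of
#' barcode ranks build the null distribution of rho, and
#' p = (1 + #\{rho_null <= rho_obs\}) / (1 + n_perm), adjusted per direction
#' by Benjamini-Hochberg. The gene log2 fold change is the median of its
#' member barcode LFCs.
#'
#' @param stats data.frame from \code{\link{barcode_test}}; rows without a
#'   gene assignment are ignored.
#' @param alpha Good-barcode p-value threshold; default 0.05.
#' @param n_perm Permutations per gene size; default 1000 (values below 100
#'   give unstable p-values and trigger a warning).
#' @param seed Optional RNG seed for the permutation null.
#' @return data.frame with one row per gene: \code{gene},
#'   \code{num_barcodes}, \code{lfc}, \code{rho_neg}, \code{p_neg},
#'   \code{fdr_neg}, \code{rho_pos}, \code{p_pos}, \code{fdr_pos}, sorted by
#'   \code{p_neg}.
#' @export
rra_gene_rank <- function(stats, alpha = 0.05, n_perm = 1000L,
                          seed = NULL) {
  if (n_perm < 100L) warning("n_perm < 100 gives unstable permutation ",
                             "p-values")
  if (!is.null(seed)) set.seed(seed)
  st <- stats[!is.na(stats$gene) & nzchar(stats$gene), , drop = FALSE]
  if (nrow(st) == 0L)
    return(data.frame(gene = character(), num_barcodes = integer(),
                      lfc = numeric(), rho_neg = numeric(),
                      p_neg = numeric(), fdr_neg = numeric(),
                      rho_pos = numeric(), p_pos = numeric(),
                      fdr_pos = numeric(), stringsAsFactors = FALSE))
  genes <- split(seq_len(nrow(st)), st$gene)
  sizes <- vapply(genes, length, integer(1))
  n_bc <- nrow(st)
  dir_cols <- list(neg = c("rank_neg", "p_neg"),
                   pos = c("rank_pos", "p_pos"))
  res <- data.frame(gene = names(genes), num_barcodes = unname(sizes),
                    lfc = vapply(genes, function(i)
                      stats::median(st$lfc[i]), numeric(1)),
                    stringsAsFactors = FALSE)
  for (dir in names(dir_cols)) {
    u_all <- st[[dir_cols[[dir]][1]]]
    good_all <- st[[dir_cols[[dir]][2]]] < alpha
    rho <- vapply(genes, function(i) .rra_rho(u_all[i], good_all[i]),
                  numeric(1))
    pvals <- numeric(length(genes))
    for (m in sort(unique(sizes))) {
      pick <- matrix(sample.int(n_bc, n_perm * m, replace = TRUE),
                     nrow = n_perm)
      null_rho <- if (m == 1L) {
        b <- stats::pbeta(u_all[pick[, 1]], 1, 1)
        ifelse(good_all[pick[, 1]], b, 1)
      } else {
        .rra_rho_matrix(matrix(u_all[pick], ncol = m),
                        matrix(good_all[pick], ncol = m))
      }
      null_sorted <- sort(null_rho)
      of_size <- which(sizes == m)
      pvals[of_size] <- (1 + findInterval(rho[of_size], null_sorted)) /
        (1 + n_perm)
    }
    res[[paste0("rho_", dir)]] <- unname(rho)
    res[[paste0("p_", dir)]] <- pvals
    res[[paste0("fdr_", dir)]] <- stats::p.adjust(pvals, method = "BH")
  }
  res <- res[order(res$p_neg, res$rho_neg, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene-level selection analysis of a barcode count matrix
#'
#' Runs the full four-step analysis: (1) optional wild-type control-barcode
#' QC (samples with dilution-series r-squared <= 0.8 are dropped), (2) size
#' factors (control normalization when a control table is given, otherwise
#' median-of-ratios), (3) mean-variance modeling on the control-condition
#' replicates, (4) per-barcode negative-binomial tests and robust rank
#' aggregation into per-gene negative- and positive-selection scores with
#' permutation p-values and BH FDR.
#'
#' @param matrix Count matrix data.frame (\code{barcode}, optional
#'   annotation column, samples).
#' @param design data.frame with columns \code{sample_id},
#'   \code{condition}.
#' @param controls Optional control table (\code{barcode}, \code{genotype},
#'   \code{concentration}); enables QC and control normalization.
#' @param treatment,control Condition labels; defaults \code{"treatment"} /
#'   \code{"control"}.
#' @param gene_column Annotation column assigning barcodes to genes;
#'   defaults to the first non-numeric column after \code{barcode} if
#'   present.
#' @param alpha,n_perm,seed Passed to \code{\link{rra_gene_rank}}.
#' @param run_qc Set \code{FALSE} to skip QC even when controls are given.
#' @return list with \code{gene_stats}, \code{barcode_stats}, \code{qc},
#'   \code{size_factors}, \code{model}.
#' @export
analyze_screen <- function(matrix, design, controls = NULL,
                           treatment = "treatment", control = "control",
                           gene_column = NULL, alpha = 0.05,
                           n_perm = 1000L, seed = NULL, run_qc = TRUE) {
  design <- design[design$condition %in% c(treatment, control), ,
                   drop = FALSE]
  missing_s <- setdiff(design$sample_id, names(matrix))
  if (length(missing_s))
    stop("design sample(s) absent from the count matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  if (is.null(gene_column)) {
    cand <- setdiff(names(matrix)[!vapply(matrix, is.numeric, logical(1))],
                    "barcode")
    if (length(cand)) gene_column <- cand[1]
  }
  qc <- NULL
  if (!is.null(controls) && run_qc) {
    qc <- qc_controls(matrix[c("barcode", design$sample_id)], controls)
    dropped <- qc$sample_id[!qc$retained]
    if (length(dropped)) {
      design <- design[!design$sample_id %in% dropped, , drop = FALSE]
      if (!any(design$condition == treatment))
        stop("all treatment samples failed control-barcode QC", call. = FALSE)
      if (!any(design$condition == control))
        stop("all control samples failed control-barcode QC", call. = FALSE)
    }
  }
  keep_cols <- c("barcode", intersect(gene_column, names(matrix)),
                 design$sample_id)
  sub <- matrix[keep_cols]
  sf <- size_factors(sub,
                     method = if (is.null(controls)) "median" else "control",
                     controls = controls)
  ctrl_samples <- design$sample_id[design$condition == control]
  norm_ctrl <- normalize_counts(sub, sf)[ctrl_samples]
  model <- fit_mean_variance(norm_ctrl)
  bstats <- barcode_test(sub, design, sf, model, treatment = treatment,
                         control = control, gene_column = gene_column)
  gstats <- rra_gene_rank(bstats, alpha = alpha, n_perm = n_perm,
                          seed = seed)
  list(gene_stats = gstats, barcode_stats = bstats, qc = qc,
       size_factors = sf, model = model)
}

#' Write the gene-level results table
#'
#' @param results List from \code{\link{analyze_screen}}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  g <- results$gene_stats
  out <- data.frame(gene = g$gene, num_barcodes = g$num_barcodes,
                    LFC = g$lfc,
                    neg_selection_pval = g$p_neg,
                    neg_selection_fdr = g$fdr_neg,
                    pos_selection_pval = g$p_pos,
                    pos_selection_fdr = g$fdr_pos,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
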