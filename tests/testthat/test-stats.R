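make_ctrl_matrix <- function(counts_per_sample, concentrations) {
  n <- length(concentrations)
  df <- data.frame(barcode = sprintf("wt%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (s in names(counts_per_sample)) df[[s]] <- counts_per_sample[[s]]
  list(matrix = df,
       controls = data.frame(barcode = df$barcode, genotype = "wt",
                             concentration = concentrations,
                             stringsAsFactors = FALSE))
}

test_that("dilution-series QC retains proportional samples and removes
           flat or shuffled ones", {
  conc <- c(1, 0.1, 0.01, 0.001)
  x <- make_ctrl_matrix(list(good = as.integer(1e6 * conc),
                             flat = rep(500L, 4),
                             shuffled = as.integer(1e6 * conc[c(2, 4, 1, 3)])),
                        conc)
  qc <- qc_controls(x$matrix, x$controls)
  expect_equal(qc$r_squared[qc$sample_id == "good"], 1, tolerance = 1e-6)
  expect_true(qc$retained[qc$sample_id == "good"])
  expect_equal(qc$r_squared[qc$sample_id == "flat"], 0)
  expect_false(qc$retained[qc$sample_id == "flat"])
  expect_false(qc$retained[qc$sample_id == "shuffled"])
})

test_that("QC is skipped with a warning below 4 control barcodes", {
  conc <- c(1, 0.1, 0.01)
  x <- make_ctrl_matrix(list(s1 = c(1000L, 100L, 10L)), conc)
  expect_warning(qc <- qc_controls(x$matrix, x$controls), "fewer than 4")
  expect_true(all(qc$retained))
  expect_true(all(is.na(qc$r_squared)))
})

test_that("median-of-ratios size factors match the arithmetic oracle", {
  m <- data.frame(barcode = c("b1", "b2", "b3"),
                  A = c(100L, 200L, 300L), B = c(200L, 400L, 600L),
                  stringsAsFactors = FALSE)
  sf <- size_factors(m)
  # oracle: ref_i = sqrt(A_i * B_i); s_j = median_i(count_ij / ref_i)
  ref <- sqrt(m$A * m$B)
  expect_equal(unname(sf),
               c(median(m$A / ref), median(m$B / ref)), tolerance = 1e-12)
  expect_equal(unname(sf), c(0.7071068, 1.4142136), tolerance = 1e-6)

  ident <- data.frame(barcode = c("b1", "b2"), A = c(10L, 20L),
                      B = c(10L, 20L), stringsAsFactors = FALSE)
  expect_equal(unname(size_factors(ident)), c(1, 1))
})

test_that("normalization is idempotent: re-derived factors are 1", {
  set.seed(3)
  m <- data.frame(barcode = sprintf("b%03d", 1:200), stringsAsFactors = FALSE)
  for (s in c("s1", "s2", "s3", "s4"))
    m[[s]] <- rnbinom(200, mu = runif(200, 50, 500), size = 5) + 1L
  sf <- size_factors(m)
  renorm <- size_factors(normalize_counts(m, sf))
  expect_equal(unname(renorm), rep(1, 4), tolerance = 1e-6)
})

test_that("control-barcode size factors use control rows only and equalize
           identical controls", {
  m <- data.frame(barcode = c("wt1", "wt2", "wt3", "wt4", "x1"),
                  A = c(100L, 200L, 300L, 400L, 10L),
                  B = c(100L, 200L, 300L, 400L, 900L),
                  stringsAsFactors = FALSE)
  ctrl <- data.frame(barcode = paste0("wt", 1:4), genotype = "wt",
                     concentration = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  sf <- size_factors(m, method = "control", controls = ctrl)
  expect_equal(unname(sf), c(1, 1))  # controls identical across samples
})

test_that("control normalization recenters bottlenecked data where global
           median normalization is biased", {
  set.seed(77)
  scr <- sim_screen(150, gene_lfc = setNames(rep(-3, 90),
                                             sprintf("gene_%04d", 1:90)),
                    depth = 3e5, dispersion = 0.02,
                    controls = data.frame(genotype = "wt",
                                          concentration = rep(1, 8)),
                    seed = 77)
  sf <- size_factors(scr$matrix, method = "control",
                     controls = scr$controls)
  norm <- normalize_counts(scr$matrix, sf)
  ctrl_rows <- norm$barcode %in% scr$controls$barcode
  ctrl_mean <- rowMeans(as.matrix(norm[ctrl_rows,
                                       paste0("control_", 1:3)]))
  trt_mean <- rowMeans(as.matrix(norm[ctrl_rows,
                                      paste0("treatment_", 1:3)]))
  lfc <- log2((trt_mean + 1) / (ctrl_mean + 1))
  expect_lt(abs(median(lfc)), 0.1)
})

test_that("mean-variance fit recovers simulated quadratic overdispersion and
           falls back to Poisson when warranted", {
  set.seed(21)
  n <- 5000
  mu <- exp(runif(n, log(20), log(2000)))
  m <- matrix(rnbinom(n * 50, mu = rep(mu, 50), size = 10), nrow = n)
  fit <- fit_mean_variance(m)
  expect_false(fit$fallback_poisson)
  expect_equal(fit$k, 2, tolerance = 0.1)
  expect_equal(exp(fit$b), 0.1, tolerance = 0.1)
  expect_true(all(model_variance(fit, mu) >= mu))

  pois <- matrix(rpois(2000 * 20, rep(mu[1:2000], 20)), nrow = 2000)
  pfit <- fit_mean_variance(pois)
  expect_true(pfit$fallback_poisson || exp(pfit$b) < 0.01)

  single <- fit_mean_variance(matrix(rpois(100, 50), ncol = 1))
  expect_true(single$fallback_poisson)
})

test_that("barcode test matches Poisson tail oracles and pseudocounted
           LFC arithmetic", {
  mat <- data.frame(barcode = c("b1", "b2", "b3"),
                    c1 = c(100L, 100L, 7L), c2 = c(100L, 100L, 7L),
                    t1 = c(100L, 0L, 31L), t2 = c(100L, 0L, 31L),
                    stringsAsFactors = FALSE)
  design <- data.frame(sample_id = c("c1", "c2", "t1", "t2"),
                       condition = c("control", "control",
                                     "treatment", "treatment"),
                       stringsAsFactors = FALSE)
  sf <- setNames(rep(1, 4), design$sample_id)
  model <- structure(list(k = NA, b = NA, fallback_poisson = TRUE),
                     class = "mean_variance_model")
  st <- barcode_test(mat, design, sf, model)
  # frozen Poisson CDF oracle: ppois(100, 100) = 0.5265622
  expect_equal(st$p_neg[st$barcode == "b1"], 0.5265622, tolerance = 1e-6)
  expect_equal(st$p_neg[st$barcode == "b2"], exp(-100), tolerance = 1e-10)
  expect_equal(st$lfc[st$barcode == "b3"], 2)  # log2(32/8)
  expect_true(all(st$p_neg + st$p_pos >= 1))
  expect_true(all(st$rank_neg > 0 & st$rank_neg <= 1))
})

test_that("RRA score matches the Beta order-statistic closed form and is
           monotone in member ranks", {
  # m = 2, u = (0.01, 0.02), both good:
  # min(1 - (1 - 0.01)^2, 0.02^2) = min(0.0199, 0.0004) = 0.0004
  expect_equal(tnbarseq:::.rra_rho(c(0.01, 0.02), c(TRUE, TRUE)), 4e-04)
  expect_equal(tnbarseq:::.rra_rho(c(0.5, 0.9), c(FALSE, FALSE)), 1)
  # monotone: worsening any member rank cannot decrease rho. Goodness is
  # tied to the rank itself (p < alpha <=> small u), as in the pipeline,
  # so the good members always occupy a prefix of the sorted ranks.
  set.seed(5)
  for (i in 1:50) {
    m <- sample(2:6, 1)
    thr <- runif(1, 0.05, 0.5)
    u <- sort(runif(m))
    rho <- tnbarseq:::.rra_rho(u, u < thr)
    j <- sample(m, 1)
    u2 <- u
    u2[j] <- min(1, u2[j] + runif(1, 0, 1 - u2[j]))
    expect_gte(tnbarseq:::.rra_rho(u2, u2 < thr), rho - 1e-12)
    expect_true(rho > 0 && rho <= 1)
  }
})

test_that("vectorized permutation-null rho agrees with the scalar scorer", {
  set.seed(6)
  m <- 4
  uM <- matrix(runif(40), ncol = m)
  gM <- matrix(runif(40) < 0.6, ncol = m)
  got <- tnbarseq:::.rra_rho_matrix(uM, gM)
  want <- vapply(seq_len(nrow(uM)), function(i)
    tnbarseq:::.rra_rho(uM[i, ], gM[i, ]), numeric(1))
  expect_equal(got, want)
})

test_that("genes with no good barcode score rho 1 and large p", {
  st <- data.frame(barcode = c("a", "b", "c"),
                   gene = c("g1", "g1", "g1"),
                   lfc = c(0, 0, 0),
                   p_neg = c(0.5, 0.6, 0.9), p_pos = c(0.5, 0.4, 0.1),
                   rank_neg = c(0.4, 0.6, 0.9), rank_pos = c(0.6, 0.4, 0.1),
                   stringsAsFactors = FALSE)
  g <- rra_gene_rank(st, n_perm = 200, seed = 1)
  expect_equal(g$rho_neg, 1)
  expect_gt(g$p_neg, 0.5)
})

test_that("permutation p-values are calibrated under a global null: valid
           (super-uniform) everywhere and uniform on their continuous
           part", {
  scr <- sim_screen(400, barcodes_per_gene = 3, seed = 901)
  res <- analyze_screen(scr$matrix, scr$design, n_perm = 2000, seed = 902)
  g <- res$gene_stats
  # validity: P(p <= t) <= t (within binomial noise) at several t
  for (t in c(0.01, 0.05, 0.1))
    expect_lte(mean(g$p_neg <= t), t + 2 * sqrt(t * (1 - t) / nrow(g)))
  # genes with no good barcode carry the atom at p ~ 1 by construction;
  # the remaining (continuous) part of the distribution is uniform on its
  # achievable range
  achievable <- mean(g$rho_neg < 1)
  sub <- g$p_neg[g$rho_neg < 1] / achievable
  expect_gt(suppressWarnings(stats::ks.test(sub, "punif"))$p.value, 0.01)
})

test_that("analyze_screen finds no hits when treatment equals control", {
  set.seed(31)
  scr <- sim_screen(80, seed = 31)
  mat <- scr$matrix
  # make treatment columns literal copies of control columns
  mat$treatment_1 <- mat$control_1
  mat$treatment_2 <- mat$control_2
  mat$treatment_3 <- mat$control_3
  res <- analyze_screen(mat, scr$design, n_perm = 300, seed = 31)
  expect_equal(sum(res$gene_stats$fdr_neg < 0.05), 0L)
  expect_equal(sum(res$gene_stats$fdr_pos < 0.05), 0L)
})

test_that("analyze_screen drops QC-failing samples and aborts when all
           treatment samples fail", {
  set.seed(41)
  conc <- c(1, 0.3, 0.1, 0.03, 0.01)
  scr <- sim_screen(40, depth = 2e5,
                    controls = data.frame(genotype = "wt",
                                          concentration = conc),
                    seed = 41)
  mat <- scr$matrix
  ## wreck the dilution series in one treatment sample
  ctrl_rows <- mat$barcode %in% scr$controls$barcode
  mat$treatment_3[ctrl_rows] <- 1000L
  res <- analyze_screen(mat, scr$design, scr$controls, n_perm = 200,
                        seed = 41)
  expect_false(res$qc$retained[res$qc$sample_id == "treatment_3"])
  expect_true(all(res$qc$retained[res$qc$sample_id != "treatment_3"]))

  for (s in paste0("treatment_", 1:3)) mat[[s]][ctrl_rows] <- 1000L
  expect_error(analyze_screen(mat, scr$design, scr$controls, n_perm = 200,
                              seed = 41),
               "all treatment samples failed")
})

test_that("results CSV is byte-identical across runs with the same seed", {
  scr <- sim_screen(60, gene_lfc = c(gene_0001 = -2), seed = 13)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_results(analyze_screen(scr$matrix, scr$design, n_perm = 200,
                               seed = 99), f1)
  write_results(analyze_screen(scr$matrix, scr$design, n_perm = 200,
                               seed = 99), f2)
  expect_identical(readLines(f1), readLines(f2))
})
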