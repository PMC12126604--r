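test_that("pseudo-bulk medians follow the textbook median conventions", {
  vals <- rbind(PGa = c(1, 2, 10, 7), PGb = c(1, 2, 3, 10))
  colnames(vals) <- paste0("f", 1:4)
  ann <- data.frame(fibre_id = paste0("f", 1:4), participant = "P1",
                    condition = "control")
  pm <- protein_matrix(vals, ann, log2 = TRUE)
  g <- setNames(rep("A", 4), paste0("f", 1:4))
  pb <- pseudobulk_median(pm, g)
  expect_equal(unname(pb$values["PGa", 1]), median(c(1, 2, 10, 7)))
  expect_equal(unname(pb$values["PGb", 1]), 2.5)  # even-n midpoint

  # a single fibre in a cell is the identity
  pb1 <- pseudobulk_median(pm, setNames("A", "f1"))
  expect_equal(unname(pb1$values[, 1]), c(1, 1))
  expect_equal(pb1$cells$n_fibres, 1L)

  # invariant to fibre order; NA-group fibres are excluded
  g2 <- g[c(3, 1, 4, 2)]
  expect_equal(pseudobulk_median(pm, g2)$values, pb$values)
  g3 <- g; g3["f4"] <- NA
  expect_equal(unname(pseudobulk_median(pm, g3)$values["PGb", 1]), 2)
  expect_error(pseudobulk_median(pm, setNames(NA_character_, "f1")), "empty")
})

test_that("per-cell medians skip missing fibre values", {
  vals <- rbind(PGa = c(1, NA, 5))
  colnames(vals) <- paste0("f", 1:3)
  ann <- data.frame(fibre_id = paste0("f", 1:3), participant = "P1",
                    condition = "control")
  pm <- protein_matrix(vals, ann, log2 = TRUE)
  pb <- pseudobulk_median(pm, setNames(rep("A", 3), paste0("f", 1:3)))
  expect_equal(unname(pb$values[1, 1]), 3)
  expect_equal(unname(pb$counts[1, 1]), 2)
})

test_that("quantile normalisation matches the worked example and its defining property", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalise(x)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  y <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(quantile_normalise(y), y)

  # complete case: all columns share one multiset; ranks are preserved
  set.seed(3)
  z <- matrix(rnorm(60), 12, 5)
  qz <- quantile_normalise(z)
  for (j in 2:5) expect_equal(sort(qz[, j]), sort(qz[, 1]))
  for (j in 1:5) expect_equal(order(qz[, j]), order(z[, j]))

  expect_warning(one <- quantile_normalise(matrix(1:3, 3, 1)), "identity")
  expect_equal(unname(one), matrix(1:3, 3, 1))
})

test_that("ties and missing rows are normalised by interpolation", {
  x <- cbind(c(1, 1, 2), c(10, 20, 30))
  qn <- quantile_normalise(x)
  ref <- rowMeans(cbind(sort(x[, 1]), sort(x[, 2])))
  expect_equal(qn[1, 1], mean(ref[1:2]))  # tied block mean
  expect_equal(qn[2, 1], mean(ref[1:2]))
  expect_equal(qn[3, 1], ref[3])

  # a row with a missing value keeps its within-column rank position
  z <- cbind(a = c(1, 2, 3, 2.5), b = c(4, 5, 6, NA))
  qz <- quantile_normalise(z)
  expect_true(is.na(qz[4, "b"]))
  expect_true(qz[4, "a"] > qz[2, "a"] && qz[4, "a"] < qz[3, "a"])
})

test_that("quantile normalisation agrees with the limma reference on complete data", {
  skip_if_not_installed("limma")
  set.seed(8)
  z <- matrix(rnorm(200, 10, 2), 40, 5)
  expect_equal(unname(quantile_normalise(z)),
               unname(limma::normalizeQuantiles(z)), tolerance = 1e-10)
})

make_pb <- function(values, participants, groups) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("PG%04d", seq_len(nrow(values)))
  cells <- data.frame(participant = participants, group = groups,
                      n_fibres = 1L)
  rownames(cells) <- colnames(values) <- paste(participants, groups, sep = ".")
  structure(list(values = values, cells = cells,
                 counts = (!is.na(values)) * 1L),
            class = "pseudobulk")
}

test_that("the moderated fit handles flat proteins and the equal-variance limit", {
  set.seed(5)
  v <- matrix(rnorm(50 * 8), 50, 8)
  v[1, ] <- rep(c(1, 2, 3, 4), 2)  # identical values in both groups
  pb <- make_pb(v, rep(paste0("P", 1:4), 2), rep(c("A", "B"), each = 4))
  res <- fit_diffabund(pb, c("A", "B"))
  r1 <- res[res$protein == rownames(pb$values)[1], ]
  expect_equal(r1$log2fc, 0)
  expect_equal(r1$p_raw, 1)

  # all proteins with exactly equal variance: moderation reduces to the
  # ordinary t computed with the pooled common variance
  v2 <- matrix(rnorm(30 * 8), 30, 8)
  v2 <- t(apply(v2, 1, function(r) {  # force every protein variance to 1
    r2 <- r
    r2[1:4] <- (r[1:4] - mean(r[1:4])) / sd(r[1:4])
    r2[5:8] <- (r[5:8] - mean(r[5:8])) / sd(r[5:8]) + 0.3
    r2
  }))
  pb2 <- make_pb(v2, rep(paste0("P", 1:4), 2), rep(c("A", "B"), each = 4))
  res2 <- fit_diffabund(pb2, c("A", "B"))
  expect_equal(attr(res2, "d0"), Inf)
  s2pool <- 1  # construction
  t_ord <- res2$log2fc / sqrt(s2pool * (1 / 4 + 1 / 4))
  expect_equal(res2$t_mod, t_ord, tolerance = 1e-10)
})

test_that("the moderated fit reproduces the limma reference on complete data", {
  skip_if_not_installed("limma")
  set.seed(21)
  n <- 200
  v <- matrix(rnorm(n * 10, sd = rep(sqrt(1 / rgamma(n, 4, 4)), 10)), n, 10)
  v[1:20, 1:5] <- v[1:20, 1:5] + 1
  rownames(v) <- sprintf("PG%03d", seq_len(n))
  pb <- make_pb(v, rep(paste0("P", 1:5), 2), rep(c("A", "B"), each = 5))
  res <- fit_diffabund(pb, c("A", "B"))

  design <- cbind(Intercept = 1, A = rep(c(1, 0), each = 5))
  efit <- limma::eBayes(limma::lmFit(v, design))
  expect_equal(res$log2fc, unname(efit$coefficients[, "A"]), tolerance = 1e-10)
  expect_equal(attr(res, "d0"), efit$df.prior, tolerance = 1e-4)
  expect_equal(attr(res, "s0"), efit$s2.prior, tolerance = 1e-4)
  expect_equal(res$t_mod, unname(efit$t[, "A"]), tolerance = 1e-5)
  expect_equal(res$p_raw, unname(efit$p.value[, "A"]), tolerance = 1e-5)
})

test_that("paired and unpaired fits agree when participant effects vanish", {
  set.seed(9)
  n_part <- 40
  v <- matrix(rnorm(100 * 2 * n_part), 100, 2 * n_part)
  pb <- make_pb(v, rep(paste0("P", seq_len(n_part)), 2),
                rep(c("A", "B"), each = n_part))
  up <- fit_diffabund(pb, c("A", "B"), paired = FALSE)
  pa <- fit_diffabund(pb, c("A", "B"), paired = TRUE)
  expect_equal(up$log2fc, pa$log2fc)
  expect_lt(mean(abs(up$p_raw - pa$p_raw)), 0.02)
})

test_that("the composite pi-value matches its closed form", {
  expect_equal(xiao_pi(0.05, 1), 0.05)
  expect_equal(xiao_pi(0.05, -1), 0.05)
  expect_equal(xiao_pi(0.01, 2), 1e-4)
  expect_equal(xiao_pi(0.04, 0.5), 0.2)
  expect_equal(xiao_pi(0.3, 0), 1)
  expect_warning(clipped <- xiao_pi(0, 2), "clipped")
  expect_gte(clipped, 0)
  expect_lt(clipped, 1e-300)
  expect_error(xiao_pi(0.5, Inf), "finite")
  expect_error(xiao_pi(1.5, 1), "p_raw")
})

test_that("significance calls use a strict composite threshold", {
  res <- data.frame(protein = c("a", "b", "c"),
                    log2fc = c(1, -2, 0.5),
                    xiao_pi = c(0.049, 0.05, 0.2))
  hits <- significant_hits(res, 0.05)
  expect_identical(hits$protein, "a")
  expect_equal(attr(hits, "n_up"), 1L)
  empty <- significant_hits(res[0, ], 0.05)
  expect_equal(nrow(empty), 0)

  # for |log2fc| = 1 the composite and raw-p calls coincide
  p <- runif(50)
  expect_identical(xiao_pi(p, rep(1, 50)) < 0.05, p < 0.05)
})

test_that("SRX-cluster contrast restricts to participants with both clusters", {
  set.seed(33)
  nf <- 24
  fibres <- sprintf("f%02d", 1:nf)
  ann <- data.frame(fibre_id = fibres,
                    participant = rep(c("P1", "P2", "P3"), each = 8),
                    condition = "control")
  vals <- matrix(rnorm(30 * nf, 10), 30, nf,
                 dimnames = list(sprintf("PG%02d", 1:30), fibres))
  pm <- protein_matrix(vals, ann, log2 = TRUE)
  srx <- setNames(rep(c(20, 80), nf / 2), fibres)
  srx[ann$participant == "P3"] <- 80  # P3 has no low fibres
  expect_message(res <- srx_cluster_contrast(pm, srx), "P3")
  expect_setequal(attr(res, "participants_used"), c("P1", "P2"))

  srx2 <- setNames(rep(80, nf), fibres)
  srx2[1] <- 20
  expect_error(suppressMessages(srx_cluster_contrast(pm, srx2)),
               "insufficient")
})

test_that("overlap and direction concordance are plain set algebra", {
  mk <- function(protein, log2fc, pi) data.frame(protein = protein,
                                                 log2fc = log2fc,
                                                 xiao_pi = pi)
  a <- mk(c("X", "Y"), c(1, -1), c(0.01, 0.01))
  b <- mk(c("X", "Z"), c(2, 1), c(0.01, 0.01))
  ov <- overlap_direction(a, b)
  expect_identical(ov$common, "X")
  expect_equal(ov$concordant_count, 1)
  expect_length(ov$discordant, 0)

  b2 <- mk("X", -3, 0.01)
  ov2 <- overlap_direction(a, b2)
  expect_identical(ov2$discordant, "X")
  expect_equal(ov2$concordant_count, 0)
})

test_that("null cohorts produce calibrated raw p-values downstream", {
  truth <- synthetic_truth(n_proteins = 400, n_effect = 0,
                           n_disease_module = 0)
  co <- simulate_cohort(truth, seed = 27)
  g <- grouping_from_truth(co)
  res <- diffabund_contrast(co$pm, g, c("typeI", "typeIIa"), paired = TRUE)
  rate <- mean(res$p_raw < 0.05)
  half <- 1.96 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), half + 0.02)
  expect_lt(mean(res$significant), 0.05)
})
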