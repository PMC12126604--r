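dual_pm <- function(values, participants = NULL) {
  fibres <- colnames(values)
  ann <- data.frame(fibre_id = fibres,
                    participant = participants %||% rep("P1", length(fibres)),
                    condition = "control")
  protein_matrix(values, ann, log2 = TRUE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("dual filtering applies the presence floors and is idempotent", {
  set.seed(2)
  v <- matrix(rnorm(10 * 10, 10), 10, 10,
              dimnames = list(sprintf("PG%02d", 1:10), sprintf("f%02d", 1:10)))
  v["PG01", 1:6] <- NA  # present in 4 of 10
  pm <- dual_pm(v)
  srx <- setNames(runif(8, 20, 80), sprintf("f%02d", 1:8))  # f09, f10 non-dual

  fl <- filter_dual(pm, srx, min_n_all = 5)
  expect_false("PG01" %in% rownames(fl$values))       # below the floor
  expect_false("f09" %in% colnames(fl$values))        # non-dual
  expect_equal(ncol(fl$values), 8)
  # idempotent
  fl2 <- filter_dual(fl, srx, min_n_all = 5)
  expect_equal(fl2$values, fl$values)
  # outliers removed
  fl3 <- filter_dual(pm, srx, outliers = "f01", min_n_all = 1)
  expect_false("f01" %in% colnames(fl3$values))
  # fully observed proteins survive any floor up to n
  expect_true("PG02" %in% rownames(filter_dual(pm, srx, min_n_all = 8)$values))
  expect_error(filter_dual(pm, setNames(50, "nope")), "insufficient")
})

test_that("Spearman correlation matches hand-derived values", {
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(40, 30, 20, 10))$rho, -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 2
  out <- spearman_cor(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(out$rho, 0.8)
  expect_error(spearman_cor(c(1, 1, 1, 1), 1:4), "zero variance")
  expect_error(spearman_cor(1:3, 3:1), "n >= 4")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(4)
  x <- rnorm(12); y <- rnorm(12)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearman_cor(exp(x), y)$p, base$p)
})

test_that("the t-approximation path agrees with the stats reference", {
  set.seed(6)
  x <- rnorm(30); y <- x + rnorm(30, sd = 2)
  out <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(out$rho, unname(ref$estimate))
  # cor.test uses the AS89/exact machinery; the t-approximation agrees closely
  tstat <- out$rho * sqrt(28 / (1 - out$rho^2))
  expect_equal(out$p, 2 * pt(-abs(tstat), 28))
})

test_that("exact small-sample p-values match an independent enumeration oracle", {
  set.seed(10)
  for (n in c(4, 5, 6, 7)) {
    for (rep in 1:4) {
      x <- rnorm(n)
      y <- if (rep %% 2 == 0) rnorm(n) else x + rnorm(n)
      if (rep == 3) y[1:2] <- y[2:1] * 0 + 3  # inject ties
      out <- spearman_cor(x, y)
      orc <- spearman_oracle(x, y)
      expect_equal(out$rho, orc$rho, tolerance = 1e-12)
      expect_equal(out$p, orc$p, tolerance = 1e-12)
    }
  }
})

test_that("SRX correlations respect subtype scopes and presence floors", {
  set.seed(12)
  nf <- 30
  fibres <- sprintf("f%02d", 1:nf)
  srx <- setNames(seq(10, 90, length.out = nf), fibres)
  v <- matrix(rnorm(3 * nf, 12), 3, nf,
              dimnames = list(c("PGup", "PGnull", "PGrare"), fibres))
  v["PGup", ] <- 10 + 0.05 * srx + rnorm(nf, sd = 0.1)
  v["PGrare", 10:nf] <- NA  # present in 9 fibres only
  pm <- dual_pm(v)
  types <- data.frame(fibre_id = fibres,
                      label = rep(c("I", "IIa"), each = nf / 2))

  all_res <- correlate_srx(pm, srx, scope = "all")
  expect_true(all_res$significant[all_res$protein == "PGup"])
  expect_gt(all_res$rho[all_res$protein == "PGup"], 0.8)
  # DRX = 100 - SRX flips every correlation sign exactly
  expect_equal(all_res$rho_drx, -all_res$rho)

  t1 <- correlate_srx(pm, srx, types = types, scope = "typeI",
                      min_n_subtype = 10)
  expect_false("PGrare" %in% t1$protein)  # 9 type-I fibres < floor 10
  expect_true(all(t1$n >= 10))
  expect_error(correlate_srx(pm, srx, types = types[0, ], scope = "typeI"),
               "fewer than 4")
})

test_that("divergent subtype couplings are recovered with opposite signs", {
  truth <- synthetic_truth(n_proteins = 120, fibres_per_participant = 8,
                           composition = c(I = 0.5, IIa = 0.5),
                           dropout_midpoint = -50, fibre_quality_sd = 0)
  co <- simulate_cohort(truth, seed = 41)
  target <- co$protein_truth$protein[!co$protein_truth$is_myh][1]
  coup <- rbind(data.frame(protein = target, scope = "typeI", beta = 0.8),
                data.frame(protein = target, scope = "typeIIa", beta = -0.8))
  sx <- simulate_srx(co, seed = 41, couplings = coup)
  types <- data.frame(fibre_id = co$fibre_truth$fibre_id,
                      label = co$fibre_truth$subtype)
  pm <- co$pm
  t1 <- correlate_srx(pm, sx$srx, types = types, scope = "typeI")
  t2 <- correlate_srx(pm, sx$srx, types = types, scope = "typeIIa")
  r1 <- t1[t1$protein == target, ]
  r2 <- t2[t2$protein == target, ]
  expect_gt(r1$rho, 0)
  expect_lt(r2$rho, 0)
  expect_true(r1$significant && r2$significant)
})

test_that("uncoupled proteins are significant at roughly the nominal rate", {
  truth <- synthetic_truth(n_proteins = 500, n_effect = 0,
                           n_disease_module = 0, dropout_midpoint = -50,
                           fibre_quality_sd = 0)
  co <- simulate_cohort(truth, seed = 43)
  coup <- data.frame(protein = co$protein_truth$protein[1], scope = "all",
                     beta = 0)
  sx <- simulate_srx(co, seed = 43, couplings = coup)
  res <- correlate_srx(co$pm, sx$srx, scope = "all")
  rate <- mean(res$significant)
  half <- 1.96 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), half + 0.02)
})

test_that("correlation profiles cluster deterministically with Newick output", {
  mk <- function(protein, rho, sig) data.frame(protein = protein, rho = rho,
                                               p_raw = 0.01, n = 20,
                                               significant = sig)
  t1 <- mk(c("a", "b", "c"), c(1, 1, -1), TRUE)
  t2 <- mk(c("a", "b", "c"), c(1, 1, -1), TRUE)
  cl <- cluster_srx_profiles(t1, t2, k = 2)
  expect_equal(cl$profiles$cluster[1], cl$profiles$cluster[2])
  expect_false(cl$profiles$cluster[1] == cl$profiles$cluster[3])
  expect_equal(length(unique(cluster_srx_profiles(t1, t2, k = 1)$profiles$cluster)), 1)
  expect_error(cluster_srx_profiles(t1, t2, k = 5), "exceeds")
  tree <- ape::read.tree(text = cl$newick)
  expect_equal(sort(tree$tip.label), c("a", "b", "c"))

  # planted two-group profiles recover the split
  set.seed(14)
  n <- 40
  rho1 <- c(runif(n / 2, 0.5, 0.9), runif(n / 2, 0.5, 0.9))
  rho2 <- c(runif(n / 2, 0.5, 0.9), runif(n / 2, -0.9, -0.5))
  tA <- mk(sprintf("p%02d", 1:n), rho1, TRUE)
  tB <- mk(sprintf("p%02d", 1:n), rho2, TRUE)
  cl2 <- cluster_srx_profiles(tA, tB, k = 2)
  truth_lab <- rep(1:2, each = n / 2)
  tab <- table(cl2$profiles$cluster, truth_lab)
  agreement <- max(sum(diag(tab)), sum(diag(tab[2:1, ]))) / n
  expect_gte(agreement, 0.95)
})
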