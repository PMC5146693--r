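# score construction: allele harmonization, LD r2, greedy thinning,
# weighted scores, standardization, threshold selection

test_that("harmonization is a no-op when alleles already agree", {
  dos <- cbind(s1 = c(0, 1, 2), s2 = c(2, 1, 0))
  g <- make_geno(dos, counted = c("A", "C"), other = c("G", "T"))
  st <- make_stats(c("s1", "s2"), weight = c(0.1, -0.2),
                   ea = c("A", "C"), oa = c("G", "T"))
  h <- harmonize_alleles(st, g)
  expect_equal(h$geno$dosage, g$dosage)
  expect_equal(unname(h$log["flipped"]), 0)
})

test_that("harmonization reflects dosages counted on the other allele", {
  dos <- cbind(s1 = c(2, 0, 1))
  g <- make_geno(dos, counted = c("G"), other = c("A"))
  st <- make_stats("s1", weight = 0.5, ea = "A", oa = "G")
  h <- harmonize_alleles(st, g)
  expect_equal(unname(h$geno$dosage[, 1]), c(0, 2, 1))
  expect_identical(h$geno$map$counted_allele, "A")
})

test_that("scores after harmonization equal scores on pre-flipped input", {
  set.seed(7)
  dos <- matrix(sample(0:2, 50, TRUE), 10, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
  flip <- c(FALSE, TRUE, FALSE, TRUE, TRUE)
  counted <- ifelse(flip, "G", "A"); other <- ifelse(flip, "A", "G")
  g <- make_geno(dos, counted = counted, other = other)
  st <- make_stats(paste0("v", 1:5), weight = c(0.2, -0.1, 0.4, 0.05, -0.3),
                   ea = rep("A", 5), oa = rep("G", 5))
  h <- harmonize_alleles(st, g)
  auto <- compute_grs(h$stats, h$geno)

  manual_dos <- dos
  manual_dos[, flip] <- 2 - manual_dos[, flip]
  g2 <- make_geno(manual_dos, counted = rep("A", 5), other = rep("G", 5))
  manual <- compute_grs(st, g2)
  expect_equal(auto$raw, manual$raw)
})

test_that("ambiguous SNPs are dropped unless frequencies are decisive", {
  dos <- cbind(amb1 = c(0, 1, 1, 2), amb2 = c(0, 0, 1, 0))  # freq .5, .125
  g <- make_geno(dos, counted = c("A", "C"), other = c("T", "G"))
  st <- make_stats(c("amb1", "amb2"), weight = c(0.1, 0.1),
                   eaf = c(0.5, 0.10), ea = c("A", "C"), oa = c("T", "G"))
  h <- harmonize_alleles(st, g)
  expect_false("amb1" %in% h$stats$snp_id)   # indecisive, dropped
  expect_true("amb2" %in% h$stats$snp_id)    # both freqs < 0.42, concordant
  # discordant decisive frequencies flip the ambiguous SNP
  st2 <- make_stats("amb2", weight = 0.1, eaf = 0.9, ea = "C", oa = "G")
  h2 <- harmonize_alleles(st2, subset_snps(g, "amb2"))
  expect_equal(unname(h2$geno$dosage[, 1]), 2 - c(0, 0, 1, 0))
})

test_that("zero SNP overlap is a hard error", {
  g <- make_geno(cbind(x = c(0, 1)))
  st <- make_stats("y", weight = 0.1)
  expect_error(harmonize_alleles(st, g), "no overlapping")
})

test_that("ld_r2 reproduces hand-computed values", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1.0)
  expect_equal(ld_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0.0)
  # x=[0,1,2,0], y=[1,1,2,0]: sum(dx dy)^2 / (sum dx^2 sum dy^2) = 4/5.5
  expect_equal(ld_r2(c(0, 1, 2, 0), c(1, 1, 2, 0)), 4 / 5.5)
  expect_warning(r <- ld_r2(c(1, 1, 1), c(0, 1, 2)), "variance")
  expect_true(is.na(r))
  expect_warning(ld_r2(c(NA, NA, 1), c(0, 1, 2)), "pairwise")
})

test_that("thinning keeps all SNPs when no pair exceeds the threshold", {
  set.seed(12)
  dos <- matrix(sample(0:2, 2000, TRUE), 200, 10,
                dimnames = list(NULL, paste0("t", 1:10)))
  g <- make_geno(dos, pos = seq_len(10) * 100L)
  st <- make_stats(paste0("t", 1:10), weight = runif(10),
                   pvalue = runif(10), pos = seq_len(10) * 100L)
  # independent columns at n = 200: all pairwise r2 far below 0.5
  kept <- ld_thin(st, g, r2_threshold = 0.5, window_bp = 1e6)
  expect_setequal(kept, st$snp_id)
  # kept-set pairwise r2 never exceeds the threshold, checked exhaustively
  kept2 <- ld_thin(st, g, r2_threshold = 0.01, window_bp = 1e6)
  idx <- match(kept2, colnames(dos))
  for (i in idx) for (j in idx) if (i < j)
    expect_lte(ld_r2(dos[, i], dos[, j]), 0.01)
})

test_that("duplicate SNPs resolve to the smaller p-value", {
  dos <- cbind(d1 = c(0, 1, 2, 1, 0), d2 = c(0, 1, 2, 1, 0))
  g <- make_geno(dos, pos = c(100L, 200L))
  st <- make_stats(c("d1", "d2"), weight = c(0.1, 0.1),
                   pvalue = c(0.5, 0.001), pos = c(100L, 200L))
  kept <- ld_thin(st, g, 0.7)
  expect_identical(kept, "d2")
})

test_that("thinning equals the exhaustive greedy oracle on small fixtures", {
  set.seed(33)
  for (rep in 1:8) {
    n <- 40
    base <- sample(0:2, n, TRUE)
    dos <- sapply(1:6, function(j) {
      mix <- rbinom(n, 1, 0.5 + j * 0.07)
      ifelse(mix == 1, base, sample(0:2, n, TRUE))
    })
    colnames(dos) <- paste0("c", 1:6)
    pos <- as.integer(sort(sample(1:5e5, 6)))
    st <- make_stats(paste0("c", 1:6), weight = runif(6),
                     pvalue = runif(6), pos = pos)
    g <- make_geno(dos, pos = pos)
    for (thr in c(0.2, 0.5, 0.8))
      expect_identical(ld_thin(st, g, thr), thin_oracle(st, dos, thr))
  }
})

test_that("lowering the threshold never increases the kept count", {
  cfg <- sim_config(n_samples = 300, n_snps = 60, block_size = 10,
                    rho = 0.85, seed = 61)
  g <- simulate_genotypes(cfg)
  tr <- true_model(g, cfg)
  st <- simulate_summary_stats(g, tr, cfg)
  h <- harmonize_alleles(st, g)
  counts <- vapply(c(1, 0.8, 0.5, 0.2, 0.05),
                   function(t) length(ld_thin(h$stats, h$geno, t)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("raw scores follow the weighted-sum definition", {
  # 2 SNPs, w = (ln 2, -ln 2), g = (2, 1) -> raw = ln 2
  g <- make_geno(cbind(a = 2, b = 1))
  st <- make_stats(c("a", "b"), weight = c(log(2), -log(2)))
  sc <- compute_grs(st, g)
  expect_equal(sc$raw, log(2), ignore_attr = TRUE)
  # all weights zero -> score zero
  st0 <- make_stats(c("a", "b"), weight = c(0, 0))
  expect_equal(unname(compute_grs(st0, g)$raw), 0)
  expect_error(compute_grs(st, g, character(0)), "empty")
})

test_that("missing dosages are mean-imputed with 2*eaf", {
  g <- make_geno(cbind(a = c(2, NA, 0)))
  st <- make_stats("a", weight = 0.5, eaf = 0.25)
  sc <- compute_grs(st, g)
  expect_equal(unname(sc$raw), c(1, 0.5 * 0.5, 0))
})

test_that("raw scores are additive over disjoint SNP subsets", {
  set.seed(4)
  dos <- matrix(sample(0:2, 60, TRUE), 10, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  g <- make_geno(dos)
  st <- make_stats(paste0("s", 1:6), weight = rnorm(6))
  a <- compute_grs(st, g, paste0("s", 1:3))$raw
  b <- compute_grs(st, g, paste0("s", 4:6))$raw
  expect_equal(a + b, compute_grs(st, g)$raw)
})

test_that("allele-label flips leave the standardized score unchanged", {
  set.seed(5)
  dos <- matrix(sample(0:2, 40, TRUE), 10, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
  g <- make_geno(dos)
  st <- make_stats(paste0("f", 1:4), weight = c(0.3, -0.2, 0.1, 0.4))
  s1 <- standardize_score(compute_grs(st, g))
  # flip SNP 2: w -> -w, g -> 2 - g
  dos2 <- dos; dos2[, 2] <- 2 - dos2[, 2]
  st2 <- st; st2$weight[2] <- -st2$weight[2]
  s2 <- standardize_score(compute_grs(st2, make_geno(dos2)))
  expect_equal(s1$standardized, s2$standardized)
  expect_equal(unname(s2$raw - s1$raw), rep(0.4, 10))  # constant shift 2w
})

test_that("standardization gives mean 0, SD 1 and is idempotent", {
  g <- make_geno(cbind(a = c(0, 1, 2)))
  st <- make_stats("a", weight = 1)
  sc <- standardize_score(compute_grs(st, g))
  expect_equal(unname(sc$standardized), c(-1, 0, 1))
  expect_lt(abs(mean(sc$standardized)), 1e-10)
  expect_lt(abs(sd(sc$standardized) - 1), 1e-10)
  expect_equal(standardize_score(sc)$standardized, sc$standardized)
  g0 <- make_geno(cbind(a = c(1, 1, 1)))
  expect_error(standardize_score(compute_grs(st, g0)), "constant")
})

test_that("threshold selection maximizes AUC with ties toward larger r2", {
  cfg <- sim_config(n_samples = 500, n_snps = 40, block_size = 8,
                    rho = 0.9, prop_causal = 0.5, gwas_n = 2000, seed = 71)
  g <- simulate_genotypes(cfg)
  tr <- true_model(g, cfg)
  st <- simulate_summary_stats(g, tr, cfg)
  h <- harmonize_alleles(st, g)
  outcome <- as.integer(scale(tr$true_score) + rnorm(500) > 1)

  single <- select_r2_threshold(h$stats, h$geno, outcome, grid = 0.7)
  expect_equal(single$r2_threshold, 0.7)

  res <- select_r2_threshold(h$stats, h$geno, outcome,
                             grid = c(1, 0.9, 0.5, 0.2))
  expect_true(res$r2_threshold %in% c(1, 0.9, 0.5, 0.2))
  expect_equal(max(res$table$auc), res$table$auc[res$table$r2_threshold ==
                                                   res$r2_threshold])
  # per-threshold AUC equals an independently coded score + AUC oracle
  for (i in seq_len(nrow(res$table))) {
    kept <- ld_thin(h$stats, h$geno, res$table$r2_threshold[i])
    w <- h$stats$weight[match(kept, h$stats$snp_id)]
    raw <- as.vector(h$geno$dosage[, match(kept, h$geno$map$snp_id),
                                   drop = FALSE] %*% w)
    pos <- raw[outcome == 1]; neg <- raw[outcome == 0]
    auc_naive <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(res$table$auc[i], auc_naive, tolerance = 1e-12)
  }
  # identical kept sets -> identical AUC -> larger threshold wins
  res2 <- select_r2_threshold(h$stats, h$geno, outcome, grid = c(1, 0.999))
  if (identical(ld_thin(h$stats, h$geno, 1),
                ld_thin(h$stats, h$geno, 0.999)))
    expect_equal(res2$r2_threshold, 1)
  expect_error(select_r2_threshold(h$stats, h$geno, rep(1, 500), grid = 0.7),
               "degenerate")
})
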