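test_that("Wald test matches the chi-square tail and is sign-invariant", {
  expect_equal(wald_test(0, 1)$p, 1)
  w <- wald_test(2, 1)
  expect_equal(w$W, 4)
  expect_equal(w$p, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(w$p, 0.0455, tolerance = 1e-3)
  expect_equal(wald_test(-2, 1)$p, wald_test(2, 1)$p)
  expect_warning(res <- wald_test(1, 0), "non-positive")
  expect_true(is.na(res$p))
})

test_that("genomic inflation factor follows its median definition", {
  expect_equal(genomic_inflation(c(0.2, 0.5, 0.9)), 1)
  expect_equal(genomic_inflation(0.05), log10(0.05) / log10(0.5),
               tolerance = 1e-12)
  expect_equal(genomic_inflation(0.05), 4.3219, tolerance = 1e-4)
  set.seed(61)
  expect_equal(genomic_inflation(runif(10000)), 1, tolerance = 0.05)
  expect_error(genomic_inflation(NA_real_), "finite")
})

test_that("q-values control the FDR calls and stay monotone in p", {
  expect_false(any(fdr_threshold(rep(1, 200), 0.05)$significant))

  set.seed(62)
  p <- c(1e-10, runif(9999))
  fd <- fdr_threshold(p, 0.05)
  expect_equal(fd$method, "storey")
  expect_true(fd$significant[1])
  # BH oracle agrees that the spiked marker is significant
  expect_lt(p.adjust(p, "BH")[1], 0.05)
  o <- order(p)
  expect_true(all(diff(fd$qvalues[o]) >= -1e-12))

  # small inputs fall back to Benjamini-Hochberg
  expect_message(fd2 <- fdr_threshold(runif(50), 0.05), "Benjamini")
  expect_equal(fd2$method, "bh")
  expect_equal(fdr_threshold(runif(50), 0.05, method = "bh")$method, "bh")
})

test_that("deviance-to-p conversion matches the chi-square oracle", {
  nl <- qxescan:::.neglog10_chisq(6.63, 1)
  expect_equal(nl, -log10(pchisq(6.63, 1, lower.tail = FALSE)),
               tolerance = 1e-10)
  expect_equal(nl, 2.0, tolerance = 0.01)
  expect_equal(qxescan:::.neglog10_chisq(1e4, 1), 300)  # capped
})

# A shared scan on a small deterministic replicate exercises the
# df ledger, the AMMI/GGE deviance identity, and the Wald columns.
rr <- small_replicate(seed = 63, m = 40, I = 120)
scan <- suppressMessages(run_scan(rr$geno, rr$pheno, fdr_method = "bh"))

test_that("the five tests carry df (1, L+1, L, L, L-1) for L = 2", {
  d <- attr(scan, "design")
  X <- base_fixed_design(d, compute_structure_covariates(rr$geno, 2,
                                                         d)$S)
  ks <- attr(scan, "kernel_set")
  y <- d$y
  ll_base <- fit_ml(y, X, ks$K_eigen)$loglik_ML
  for (i in c(4, 17, 60)) {
    x <- drop(d$Z_G %*% rr$geno$dosages[i, ])
    lls <- sapply(c("additive_main", "ammi", "gge"), function(kind)
      fit_ml(y, cbind(X, build_qtl_design(x, kind, d)$columns),
             ks$K_eigen)$loglik_ML)
    dev <- c(add = -2 * (ll_base - lls[["additive_main"]]),
             ammi_all = -2 * (ll_base - lls[["ammi"]]),
             gge_all = -2 * (ll_base - lls[["gge"]]),
             ammi_int = -2 * (lls[["additive_main"]] - lls[["ammi"]]),
             gge_int = -2 * (lls[["additive_main"]] - lls[["gge"]]))
    dev <- pmax(dev, 0)
    df <- c(add = 1, ammi_all = 3, gge_all = 2, ammi_int = 2, gge_int = 1)
    for (tn in names(df))
      expect_equal(scan[[paste0("neglog10p_", tn)]][i],
                   -pchisq(dev[[tn]], df[[tn]], lower.tail = FALSE,
                           log.p = TRUE) / log(10),
                   tolerance = 1e-6)
  }
})

test_that("AMMI and GGE all-terms deviances coincide while p differs", {
  dev_gge <- qchisq(-scan$neglog10p_gge_all * log(10), 2,
                    lower.tail = FALSE, log.p = TRUE)
  dev_ammi <- qchisq(-scan$neglog10p_ammi_all * log(10), 3,
                     lower.tail = FALSE, log.p = TRUE)
  expect_lt(max(abs(dev_gge - dev_ammi)), 1e-6)
  # one extra df systematically deflates the AMMI-type p-values
  expect_true(all(scan$neglog10p_ammi_all <= scan$neglog10p_gge_all + 1e-9))
})

test_that("per-environment effects and Wald columns are populated", {
  expect_true(all(c("theta_A", "theta_B", "wald_neglog10p_A",
                    "wald_neglog10p_B") %in% names(scan)))
  expect_true(all(is.finite(scan$theta_A)))
  expect_true(all(scan$wald_neglog10p_A >= 0))
  expect_true(all(scan$neglog10p_add >= 0))
  expect_true(all(10^(-scan$neglog10p_gge_all) <= 1))
})

test_that("markers without dosage variance are untestable", {
  g <- rr$geno
  g$dosages[5, ] <- 1                         # constant heterozygote
  g$allele_freq[5] <- 0.5
  s <- suppressMessages(run_scan(g, rr$pheno, tests = "add",
                                 fdr_method = "bh", wald = FALSE))
  expect_true(is.na(s$neglog10p_add[5]))
  expect_false(anyNA(s$neglog10p_add[-5]))
})

test_that("gge_int is refused with a single environment", {
  ph <- make_pheno(colnames(rr$geno$dosages), c(t1 = "A", t2 = "A"))
  expect_error(suppressMessages(run_scan(rr$geno, ph, tests = "gge_int")),
               "2 environments")
})

test_that("scan p-values are invariant to the GRM scale", {
  d <- attr(scan, "design")
  c1 <- build_components(compute_grm(rr$geno), d, "G+GE+GT")
  c2 <- build_components(7 * compute_grm(rr$geno), d, "G+GE+GT")
  w <- c(G = 2, GE = 1, GT = 1)
  ks1 <- integrate_kernel(w, c1)
  ks2 <- integrate_kernel(w, c2)
  s1 <- suppressMessages(run_scan(rr$geno, rr$pheno, kernel_set = ks1,
                                  tests = "gge_all", fdr_method = "bh",
                                  wald = FALSE))
  s2 <- suppressMessages(run_scan(rr$geno, rr$pheno, kernel_set = ks2,
                                  tests = "gge_all", fdr_method = "bh",
                                  wald = FALSE))
  expect_equal(s1$neglog10p_gge_all, s2$neglog10p_gge_all,
               tolerance = 1e-6)
})

test_that("additive-main p-values are calibrated on null data", {
  set.seed(64)
  lams <- replicate(8, {
    g <- generate_genotypes(40, 200, Fst = 0.1)
    d <- complete_design(g, c(A = 2, B = 2))
    # background + noise only: no major QTL anywhere
    G <- compute_grm(g)
    eg <- eigen(G, symmetric = TRUE)
    dr <- function() drop(d$Z_G %*% (eg$vectors %*%
                                       (sqrt(pmax(eg$values, 0)) * rnorm(40))))
    y <- dr() + rnorm(d$n)
    ph <- make_pheno(colnames(g$dosages), c(A_t1 = "A", A_t2 = "A",
                                            B_t1 = "B", B_t2 = "B"),
                     values = y)
    s <- suppressMessages(run_scan(g, ph, tests = "add", fdr_method = "bh",
                                   wald = FALSE))
    attr(s, "lambda_gc")[["add"]]
  })
  expect_gt(mean(lams), 0.9)
  expect_lt(mean(lams), 1.1)
})

test_that("the scan table round-trips through the TSV writer", {
  path <- tempfile(fileext = ".tsv")
  write_scan_tsv(scan, path, trait = "sim")
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(scan))
  expect_equal(back$neglog10p_add, scan$neglog10p_add, tolerance = 1e-6)
  expect_equal(back$trait[1], "sim")
})
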