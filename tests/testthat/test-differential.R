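two_group <- function(vals) {
  n <- ncol(vals)
  expression_dataset(vals, rep(c("a", "b"), each = n / 2))
}

test_that("a gene identical across conditions has t = 0, p = 1", {
  set.seed(1)
  base <- rnorm(20)
  vals <- rbind(g1 = c(base[1:10], base[1:10]), g2 = rnorm(20))
  colnames(vals) <- paste0("s", 1:20)
  de <- differential_expression(two_group(vals))
  expect_equal(de$de_t[de$gene == "g1"], 0, tolerance = 1e-10)
  expect_equal(de$de_p[de$gene == "g1"], 1, tolerance = 1e-10)
})

test_that("moderated t matches limma and approaches pooled z with heavy prior", {
  d <- noise_dataset(n_genes = 50, n1 = 8, n2 = 8, seed = 5)
  de <- differential_expression(d)
  design <- model.matrix(~factor(rep(c("a", "b"), each = 8)))
  fit0 <- limma::lmFit(d$values, design)
  # the d0 -> Inf limit: residual variances fully shrunk to a common value
  s2_pooled <- mean(fit0$sigma^2 * fit0$df.residual) /
    mean(fit0$df.residual)
  z_like <- fit0$coefficients[, 2] / (fit0$stdev.unscaled[, 2] *
                                        sqrt(s2_pooled))
  # limma with its estimated prior lies between per-gene t and pooled z
  expect_gt(cor(de$de_t, z_like), 0.98)
})

test_that("variance F test matches var.test gene by gene", {
  d <- noise_dataset(n_genes = 30, n1 = 9, n2 = 11, seed = 6)
  dv <- differential_variability(d)
  s1 <- condition_samples(d, "a")
  s2 <- condition_samples(d, "b")
  for (g in rownames(d$values)[c(1, 7, 30)]) {
    vt <- stats::var.test(d$values[g, s1], d$values[g, s2])
    expect_equal(dv$dv_f[dv$gene == g], unname(vt$estimate),
                 tolerance = 1e-12)
    expect_equal(dv$dv_p[dv$gene == g], vt$p.value, tolerance = 1e-12)
  }
})

test_that("F tail has the known closed form at n1 = n2 = 2", {
  vals <- rbind(g1 = c(0, 4, 1, 3))  # variances 8 and 2 -> F = 4
  colnames(vals) <- paste0("s", 1:4)
  d <- two_group(vals)
  dv <- differential_variability(d)
  expect_equal(dv$dv_f[1], 4)
  # P(F(1,1) <= x) = (2/pi) atan(sqrt(x))
  p_closed <- 2 * (1 - 2 / pi * atan(2))
  expect_equal(dv$dv_p[1], p_closed, tolerance = 1e-12)
})

test_that("equal variances give F = 1 and two-sided p = 1", {
  vals <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  colnames(vals) <- paste0("s", 1:6)
  dv <- differential_variability(two_group(vals))
  expect_equal(dv$dv_f[1], 1)
  expect_equal(dv$dv_p[1], 1)
})

test_that("planted DV genes are recovered at dv_scale 4", {
  sim <- generate_dataset(synthetic_config(seed = 21))
  d <- preprocess(sim$data)$data
  dv <- differential_variability(d)
  hits <- dv$gene[dv$dv_flag]
  expect_gte(mean(sim$truth$dv_genes %in% hits), 0.8)
})

test_that("planted DE genes are recovered at shift 1", {
  sim <- generate_dataset(synthetic_config(seed = 22))
  d <- preprocess(sim$data)$data
  de <- differential_expression(d)
  expect_gte(mean(sim$truth$de_genes %in% de$gene[de$de_flag]), 0.8)
})

test_that("identical conditions yield zero changed edges and rate 0", {
  set.seed(3)
  half <- matrix(rnorm(10 * 8), 10, 8)
  vals <- cbind(half, half)
  dimnames(vals) <- list(paste0("g", 1:10), paste0("s", 1:16))
  ce <- changed_edges(two_group(vals))
  expect_true(all(ce$counts == 0))
  expect_equal(ce$rate, 0)
  expect_true(all(abs(ce$z[upper.tri(ce$z)]) < 1e-8))
})

test_that("Fisher r-to-z matches the hand formula", {
  # r1 = 0.9, r2 = 0, n1 = n2 = 103: z = atanh(0.9)/sqrt(2/100)
  z_expect <- atanh(0.9) / sqrt(1 / 100 + 1 / 100)
  expect_equal(z_expect, 10.4096, tolerance = 1e-4)
  # construct data realizing those sample correlations exactly is fragile;
  # instead check the implementation against an independent per-pair loop
  d <- noise_dataset(n_genes = 10, n1 = 12, n2 = 12, seed = 9)
  d$values <- log2(d$values + 1)
  ce <- changed_edges(d, edge_alpha = 0.05)
  s1 <- condition_samples(d, "a")
  s2 <- condition_samples(d, "b")
  counts_brute <- stats::setNames(integer(10), rownames(d$values))
  for (i in 1:9) for (j in (i + 1):10) {
    r1 <- cor(d$values[i, s1], d$values[j, s1])
    r2 <- cor(d$values[i, s2], d$values[j, s2])
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / 9 + 1 / 9)
    if (2 * pnorm(-abs(z)) < 0.05) {
      counts_brute[i] <- counts_brute[i] + 1L
      counts_brute[j] <- counts_brute[j] + 1L
    }
    expect_equal(ce$z[i, j], z, tolerance = 1e-10)
  }
  expect_equal(ce$counts, counts_brute)
  expect_equal(ce$rate, sum(counts_brute) / (10 * 9))
})

test_that("binomial DW tail matches exhaustive enumeration at T = 10", {
  counts <- stats::setNames(0:10, paste0("g", 0:10))
  dw <- dw_test(counts, rate = 0.1, n_genes = 11)
  for (ni in 0:10) {
    exact <- sum(choose(10, ni:10) * 0.1^(ni:10) * 0.9^(10 - (ni:10)))
    expect_equal(dw$dw_p[ni + 1], exact, tolerance = 1e-12)
  }
  expect_equal(dw$dw_p[1], 1)  # P(X >= 0) = 1
  expect_true(all(diff(dw$dw_p) < 0))  # monotone in n_i
})

test_that("rate 0 with a positive count is flagged with p = 0", {
  dw <- dw_test(c(g1 = 1, g2 = 0), rate = 0, n_genes = 3)
  expect_equal(dw$dw_p, c(0, 1))
  expect_equal(dw$dw_flag, c(TRUE, FALSE))
  expect_error(dw_test(c(g1 = 5), rate = 0.1, n_genes = 3), "N - 1")
})

test_that("swapping condition labels negates t, inverts F, keeps DW fixed", {
  sim <- small_sim()
  d <- preprocess(sim$data)$data
  # exchange the DATA between the two groups (labels and their order stay):
  # the progressor-labelled columns now carry the nonprogressor values
  s1 <- condition_samples(d, "progressor")
  s2 <- condition_samples(d, "nonprogressor")
  swapped <- d
  swapped$values[, s1] <- d$values[, s2]
  swapped$values[, s2] <- d$values[, s1]
  genes <- rownames(d$values)[1:60]
  a <- differential_network(d, genes)
  b <- differential_network(swapped, genes)
  expect_equal(b$table$de_t, -a$table$de_t, tolerance = 1e-8)
  expect_equal(b$table$dv_f, 1 / a$table$dv_f, tolerance = 1e-10)
  expect_equal(b$table$dv_p, a$table$dv_p, tolerance = 1e-10)
  expect_equal(b$table$changed_edges, a$table$changed_edges)
  expect_equal(b$table$dw_p, a$table$dw_p, tolerance = 1e-12)
})

test_that("an extreme Fisher table matches the hypergeometric closed form", {
  universe <- paste0("g", 1:100)
  lab <- stats::setNames(rep("unassigned", 100), universe)
  lab[1:10] <- "M1"
  lab[11:50] <- "M2"
  part <- module_partition(lab)
  flags <- list(DE = universe[1:10])  # all affected genes inside M1
  enr <- module_enrichment(part, flags)
  p_closed <- 1 / choose(100, 10)
  expect_equal(enr$fisher_p[enr$module == "M1"], p_closed,
               tolerance = 1e-12)
  expect_equal(enr$bonferroni_p[enr$module == "M1"], 2 * p_closed,
               tolerance = 1e-12)
  expect_true(enr$enriched[enr$module == "M1"])
})

test_that("a module with no affected genes has one-sided p = 1", {
  universe <- paste0("g", 1:60)
  lab <- stats::setNames(rep(c("M1", "M2"), each = 30), universe)
  part <- module_partition(lab)
  enr <- module_enrichment(part, list(DW = universe[31:40]))
  expect_equal(enr$fisher_p[enr$module == "M2"],
               stats::fisher.test(matrix(c(10, 20, 0, 30), 2),
                                  alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(enr$fisher_p[enr$module == "M1"], 1)
  # empty class: all p 1
  enr0 <- module_enrichment(part, list(DE = character(0)))
  expect_true(all(enr0$fisher_p == 1))
})

test_that("uniformly scattered affected genes rarely enrich any module", {
  universe <- paste0("g", 1:1000)
  lab <- stats::setNames(
    rep(c(paste0("M", 1:5), "unassigned"), c(150, 150, 150, 150, 150, 250)),
    universe)
  part <- module_partition(lab)
  set.seed(31)
  any_hit <- logical(20)
  for (i in 1:20) {
    flags <- list(DE = sample(universe, 100), DV = sample(universe, 50),
                  DW = sample(universe, 10))
    enr <- module_enrichment(part, flags)
    any_hit[i] <- any(enr$enriched)
  }
  expect_gte(mean(!any_hit), 0.95)
})

test_that("DW hub calling respects the strict kME threshold", {
  tab <- data.frame(gene = c("g1", "g2", "g3"),
                    dw_p = c(1e-6, 1e-6, 0.5),
                    dw_flag = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  kme <- matrix(c(0.79, 0.92, 0.95, 0.1, 0.2, 0.1), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("M1", "M2")))
  stats_obj <- structure(list(kme = kme,
                              kim = c(g1 = 1, g2 = 1, g3 = 1),
                              condition = "a"),
                         class = "module_statistics")
  part <- module_partition(c(g1 = "M1", g2 = "M1", g3 = "M1"))
  hubs <- call_dw_hubs(tab, stats_obj, part)
  expect_equal(hubs$gene, "g2")  # g1 at 0.79 excluded, g3 not DW
  # no DW genes -> empty result
  tab$dw_flag <- FALSE
  expect_equal(nrow(call_dw_hubs(tab, stats_obj, part)), 0)
})

test_that("unassigned DW genes are judged by their best reference kME", {
  tab <- data.frame(gene = "g1", dw_p = 1e-9, dw_flag = TRUE,
                    stringsAsFactors = FALSE)
  kme <- matrix(c(0.3, 0.88), 1, 2,
                dimnames = list("g1", c("M1", "M2")))
  stats_obj <- structure(list(kme = kme, kim = c(g1 = 0), condition = "a"),
                         class = "module_statistics")
  part <- module_partition(c(g1 = "unassigned", g2 = "M1", g3 = "M1"))
  hubs <- call_dw_hubs(tab, stats_obj, part)
  expect_equal(hubs$module, "M2")
  expect_equal(hubs$kme, 0.88)
})
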