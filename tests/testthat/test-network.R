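test_that("bicor is 1 for exact affine relations and -1 for negation", {
  set.seed(4)
  x <- rnorm(30)
  vals <- rbind(g1 = x, g2 = 2 * x + 3, g3 = -x)
  colnames(vals) <- paste0("s", 1:30)
  d <- expression_dataset(vals, rep(c("a", "b"), 15))
  cc <- bicor_matrix(d)
  expect_equal(cc["g1", "g2"], 1, tolerance = 1e-12)
  expect_equal(cc["g1", "g3"], -1, tolerance = 1e-12)
  expect_symmetric(cc)
  expect_true(all(cc >= -1 & cc <= 1))
})

test_that("bicor resists a gross outlier better than Pearson", {
  set.seed(11)
  x <- rnorm(200)
  y <- x
  y[which.max(x)] <- -50  # one corrupted observation in an exact linear pair
  vals <- rbind(g1 = x, g2 = y)
  colnames(vals) <- paste0("s", 1:200)
  d <- expression_dataset(vals, rep(c("a", "b"), 100))
  b <- bicor_matrix(d)["g1", "g2"]
  p <- cor(x, y)
  expect_gt(abs(b), abs(p))
  expect_gt(b, 0.95)
})

test_that("zero-MAD genes fall back to Pearson with a warning", {
  set.seed(2)
  x <- rnorm(20)
  spiky <- c(rep(0, 18), 3, 9)  # MAD 0, variance > 0
  vals <- rbind(g1 = x, g2 = spiky, g3 = 2 * spiky + 1)
  colnames(vals) <- paste0("s", 1:20)
  d <- expression_dataset(vals, rep(c("a", "b"), 10))
  expect_warning(cc <- bicor_matrix(d), "MAD")
  expect_equal(cc["g2", "g3"], 1, tolerance = 1e-12)
})

test_that("bicor requires at least 4 samples", {
  d <- noise_dataset(n_genes = 5, n1 = 2, n2 = 1)
  expect_error(bicor_matrix(d), "4 samples")
})

test_that("adjacency follows |cor|^beta with unit diagonal", {
  cc <- matrix(c(1, -0.5, -0.5, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  net <- adjacency_from_cor(cc, beta = 2)
  expect_equal(net$adjacency["a", "b"], 0.25)
  net1 <- adjacency_from_cor(cc, beta = 1)
  expect_equal(net1$adjacency, abs(cc))
  cc0 <- matrix(c(1, 0, 0, 1), 2, dimnames = dimnames(cc))
  expect_equal(adjacency_from_cor(cc0, 6)$adjacency["a", "b"], 0)
  expect_error(adjacency_from_cor(cc, beta = 0))
})

test_that("a perfect power-law degree sequence fits with R^2 = 1", {
  # counts proportional to 1/k at k = 1..10, each in its own equal-width bin
  k <- rep(1:10, times = 2520 / (1:10))
  fit <- suppressWarnings(scale_free_fit(k))  # lm warns on an exact fit
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$slope, 0)
  # ascending degree frequencies give a NEGATIVE (signed) fit index
  k_up <- rep(1:10, times = 1:10 * 4)
  expect_lt(suppressWarnings(scale_free_fit(k_up))$r_squared, 0)
})

test_that("soft threshold selection returns the smallest qualifying beta", {
  sim <- small_sim()
  d <- preprocess(sim$data)$data
  cc <- bicor_matrix(d, condition_samples(d, "progressor"))
  # a target at the signed fit's floor qualifies every candidate
  expect_equal(pick_soft_threshold(cc, r2_target = -1)$beta, 1)
  st <- pick_soft_threshold(cc)
  expect_true(st$beta %in% 3:8)
  expect_equal(nrow(st$fit_table), 20)
  first_ok <- which(st$fit_table$r_squared >= 0.8)[1]
  expect_equal(st$beta, st$fit_table$beta[first_ok])
})

test_that("connectivity filter keeps the top fraction with lexicographic ties", {
  a <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  a["a", "b"] <- a["b", "a"] <- 1
  a["a", "c"] <- a["c", "a"] <- 1
  a["a", "d"] <- a["d", "a"] <- 1
  a["b", "c"] <- a["c", "b"] <- 1
  diag(a) <- 1
  net <- structure(list(gene_ids = letters[1:4], adjacency = a, beta = 1,
                        tom = NULL, condition_label = ""),
                   class = "weighted_network")
  # k = (3, 2, 2, 1): tie between b and c broken by gene id
  kept <- filter_top_connectivity(net, 0.5, min_genes = 2)
  expect_equal(kept$gene_ids, c("a", "b"))
  expect_equal(dim(kept$adjacency), c(2, 2))
  full <- filter_top_connectivity(net, 1, min_genes = 2)
  expect_equal(full$adjacency, a)
  expect_error(filter_top_connectivity(net, 0.5, min_genes = 10), "min_genes")
})

test_that("TOM matches a triple-loop brute force on random networks", {
  tom_brute <- function(a) {
    n <- nrow(a)
    ad <- a; diag(ad) <- 0
    k <- rowSums(ad)
    out <- diag(n)
    for (i in 1:n) for (j in 1:n) if (i != j) {
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + ad[i, u] * ad[u, j]
      out[i, j] <- (l + ad[i, j]) / (min(k[i], k[j]) + 1 - ad[i, j])
    }
    dimnames(out) <- dimnames(a)
    out
  }
  for (s in 1:3) {
    n <- c(6, 8, 10)[s]
    a <- random_adjacency(n, seed = s)
    net <- structure(list(gene_ids = rownames(a), adjacency = a, beta = 1,
                          tom = NULL, condition_label = ""),
                     class = "weighted_network")
    tom <- tom_similarity(net)$tom
    expect_lt(max(abs(tom - tom_brute(a))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_symmetric(tom)
  }
})

test_that("TOM limiting cases: identical rows give 1, isolation gives 0", {
  # genes 1 and 2: identical binary adjacency rows with a_ij = 1 — the
  # discrete maximal-overlap case
  a <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  a[1, 2] <- a[2, 1] <- 1
  a[1, 3] <- a[3, 1] <- 1
  a[2, 3] <- a[3, 2] <- 1
  diag(a) <- 1
  net <- structure(list(gene_ids = letters[1:4], adjacency = a, beta = 1,
                        tom = NULL, condition_label = ""),
                   class = "weighted_network")
  tom <- tom_similarity(net)$tom
  expect_equal(tom[1, 2], 1, tolerance = 1e-12)
  # disconnected pair with no shared neighbours
  b <- diag(4)
  dimnames(b) <- dimnames(a)
  b[1, 2] <- b[2, 1] <- 0.9
  b[3, 4] <- b[4, 3] <- 0.9
  netb <- structure(list(gene_ids = letters[1:4], adjacency = b, beta = 1,
                         tom = NULL, condition_label = ""),
                    class = "weighted_network")
  tomb <- tom_similarity(netb)$tom
  expect_equal(tomb[1, 3], 0)
})

test_that("adjacency and TOM are permutation-equivariant", {
  a <- random_adjacency(8, seed = 5)
  net <- structure(list(gene_ids = rownames(a), adjacency = a, beta = 1,
                        tom = NULL, condition_label = ""),
                   class = "weighted_network")
  tom <- tom_similarity(net)$tom
  set.seed(1)
  p <- sample(8)
  ap <- a[p, p]
  netp <- structure(list(gene_ids = rownames(ap), adjacency = ap, beta = 1,
                         tom = NULL, condition_label = ""),
                    class = "weighted_network")
  tomp <- tom_similarity(netp)$tom
  expect_equal(tomp, tom[p, p])
})
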