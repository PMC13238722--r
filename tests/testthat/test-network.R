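test_that("biweight midcorrelation handles perfect, inverted and outlying data", {
  set.seed(1)
  x <- rnorm(20)
  expect_equal(bicorRobust(x, x), 1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(bicorRobust(x, -x), -1, tolerance = 1e-12, ignore_attr = TRUE)
  # one gross outlier: bicor stays close to the outlier-free Pearson
  set.seed(2)
  xo <- rnorm(20); yo <- xo + rnorm(20, 0, 0.3)
  clean_p <- cor(xo, yo)
  yo_out <- yo; yo_out[1] <- 40
  contaminated_p <- cor(xo, yo_out)
  b <- bicorRobust(xo, yo_out)
  expect_lt(abs(b - clean_p), abs(contaminated_p - clean_p))
  # both sides constant -> 0 with flag
  z <- bicorRobust(rep(1, 10), rep(2, 10))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "undefined"))
  # MAD-zero side falls back to Pearson
  xm <- c(rep(0, 8), 1, 3); ym <- seq_len(10)
  expect_equal(as.numeric(bicorRobust(xm, ym)), cor(xm, ym), tolerance = 0.35)
})

test_that("signed adjacency maps correlations into [0,1] as ((1+r)/2)^beta", {
  expect_equal(signedAdjacency(1, 14), 1)
  expect_equal(signedAdjacency(-1, 14), 0)
  expect_equal(signedAdjacency(0, 14), 0.5^14, tolerance = 1e-15)
  expect_equal(signedAdjacency(0.5, 2), 0.75^2)
  expect_error(signedAdjacency(1.5, 6), "\\[-1, 1\\]")
})

test_that("soft-threshold pick returns the grid and shrinking connectivity", {
  X <- two_block_matrix(3, n_samples = 40, block_size = 60, bg = 30)
  res <- pickSoftThreshold(X, powers = c(2, 6, 10, 14))
  expect_true(res$power %in% c(2, 6, 10, 14))
  # mean connectivity non-increasing in beta (a <= 1 raised to growing power)
  expect_true(all(diff(res$fit_table$mean_k) <= 1e-9))
  expect_equal(pickSoftThreshold(X, powers = 9)$power, 9)
  expect_error(pickSoftThreshold(matrix(1, 25, 10), powers = 2), "constant")
})

test_that("TOM credits shared neighbors and stays in [0,1]", {
  # 3-clique with unit adjacency: (l + a)/(min(k) + 1 - a) = (1+1)/(2+1-1) = 1
  A <- matrix(1, 3, 3); diag(A) <- 0
  tom <- tomSimilarity(A)
  expect_equal(unname(tom[upper.tri(tom)]), rep(1, 3))
  # zero adjacency -> zero off-diagonal overlap
  tz <- tomSimilarity(matrix(0, 4, 4))
  expect_equal(unname(tz[upper.tri(tz)]), rep(0, 6))
  expect_equal(unname(diag(tz)), rep(1, 4))
  # property over random adjacencies: symmetric, bounded
  set.seed(9)
  for (i in 1:25) {
    n <- 30
    A <- matrix(runif(n * n), n, n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    tom <- tomSimilarity(A)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
  expect_error(tomSimilarity(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("module eigengene equals the first principal component (SVD oracle)", {
  set.seed(12)
  # one-gene module: its z-scored profile
  g <- matrix(rnorm(15), 1, 15, dimnames = list("g1", paste0("s", 1:15)))
  e1 <- moduleEigengene(g)
  expect_equal(unname(e1), unname(scale(g[1, ])[, 1]), tolerance = 1e-12)
  # two perfectly correlated genes: eigengene correlates 1 with both
  prof <- rnorm(20)
  m2 <- rbind(a = prof, b = 2 * prof + 3)
  colnames(m2) <- paste0("s", 1:20)
  e2 <- moduleEigengene(m2)
  expect_equal(abs(cor(e2, prof)), 1, tolerance = 1e-10)
  # brute-force oracle on random modules: matches first right singular
  # vector of the z-scored matrix up to sign, to 1e-8
  for (i in 1:10) {
    X <- matrix(rnorm(12 * 25), 12, 25,
                dimnames = list(paste0("g", 1:12), paste0("s", 1:25)))
    e <- moduleEigengene(X)
    zs <- t(scale(t(X)))
    v1 <- svd(zs)$v[, 1]
    v1 <- (v1 - mean(v1)) / sd(v1)
    expect_equal(abs(cor(e, v1)), 1, tolerance = 1e-8)
    expect_equal(sd(e), 1, tolerance = 1e-10)
    # sign alignment: mean correlation with members is positive
    expect_gte(mean(apply(X, 1, cor, y = e)), 0)
  }
})

test_that("module detection recovers planted blocks and merges near-identical ones", {
  X <- two_block_matrix(5, n_samples = 60, block_size = 100)
  ms <- buildNetwork(X, profile = "human", power = 14)
  lab <- moduleLabels(ms)
  mods <- setdiff(unique(lab), "grey")
  expect_equal(length(mods), 2)
  for (tr in list(rownames(X)[1:100], rownames(X)[101:200])) {
    best <- max(vapply(mods, function(m)
      mean(names(lab)[lab == m] %in% tr) *
        (length(intersect(names(lab)[lab == m], tr)) > 0), numeric(1)))
    purity <- max(vapply(mods, function(m) {
      mg <- names(lab)[lab == m]
      length(intersect(mg, tr)) / length(mg)
    }, numeric(1)))
    expect_gte(purity, 0.95)
  }
  # independent genes: no surviving module structure
  set.seed(6)
  Xi <- matrix(rnorm(80 * 50), 80, 50,
               dimnames = list(paste0("g", 1:80), paste0("s", 1:50)))
  msi <- buildNetwork(Xi, profile = "human", power = 14, min_module_size = 30)
  ni <- setdiff(unique(moduleLabels(msi)), "grey")
  expect_lte(length(ni), 1)
  # two blocks driven by near-identical factors merge at merge height 0.1
  set.seed(7)
  f <- rnorm(50)
  f2 <- 0.99 * f + sqrt(1 - 0.99^2) * rnorm(50)  # eigengene r ~ 0.99
  a <- sqrt(0.9 / 0.1)
  Xm <- rbind(
    t(vapply(1:60, function(i) a * f + rnorm(50), numeric(50))),
    t(vapply(1:60, function(i) a * f2 + rnorm(50), numeric(50))))
  dimnames(Xm) <- list(paste0("g", 1:120), paste0("s", 1:50))
  msm <- buildNetwork(Xm, profile = "human", power = 14)
  expect_equal(length(setdiff(unique(moduleLabels(msm)), "grey")), 1)
})

test_that("module assignment is invariant under sample permutation", {
  X <- two_block_matrix(8, n_samples = 50, block_size = 60, bg = 0)
  ms1 <- buildNetwork(X, profile = "human", power = 14)
  set.seed(3)
  perm <- sample(ncol(X))
  ms2 <- buildNetwork(X[, perm], profile = "human", power = 14)
  expect_equal(moduleLabels(ms1), moduleLabels(ms2))
})

test_that("module-trait association matches direct Pearson computation", {
  set.seed(15)
  me <- rbind(turquoise = rnorm(30), blue = rnorm(30))
  colnames(me) <- paste0("s", 1:30)
  traits <- data.frame(t1 = me["turquoise", ] , t2 = rnorm(30),
                       flat = rep(1, 30))
  res <- moduleTraitAssoc(me, traits)
  r_tt <- res$r[res$module == "turquoise" & res$trait == "t1"]
  expect_equal(r_tt, 1, tolerance = 1e-12)
  # hand-sized 5-sample check against the direct formula
  e5 <- rbind(m = c(1, 2, 4, 3, 7)); colnames(e5) <- paste0("s", 1:5)
  tr5 <- data.frame(y = c(2, 1, 5, 4, 9))
  out5 <- moduleTraitAssoc(e5, tr5)
  expect_equal(out5$r, cor(c(1, 2, 4, 3, 7), c(2, 1, 5, 4, 9)),
               tolerance = 1e-12)
  expect_equal(out5$p_value, cor.test(c(1, 2, 4, 3, 7),
                                      c(2, 1, 5, 4, 9))$p.value,
               tolerance = 1e-10)
  # constant trait -> NA with no significance
  expect_true(all(is.na(res$r[res$trait == "flat"])))
  expect_false(any(res$significant[res$trait == "flat"]))
})

test_that("connectivity statistics decompose into within and outside module sums", {
  # 3-clique in one module: kTotal = kWithin = 2, kOut = 0, kDiff = 2
  A <- matrix(1, 3, 3); diag(A) <- 0
  dimnames(A) <- list(paste0("g", 1:3), paste0("g", 1:3))
  lab <- setNames(rep("turquoise", 3), rownames(A))
  cs <- connectivityStats(A, lab)
  expect_equal(cs$kTotal, rep(2, 3))
  expect_equal(cs$kWithin, rep(2, 3))
  expect_equal(cs$kOut, rep(0, 3))
  expect_equal(cs$kDiff, rep(2, 3))
  # singleton module has zero within-connectivity
  lab2 <- setNames(c("a", "a", "b"), rownames(A))
  cs2 <- connectivityStats(A, lab2)
  expect_equal(cs2$kWithin[3], 0)
  expect_equal(cs2$kDiff, cs2$kWithin - cs2$kOut)
  # members score higher own-module kME than outsiders on planted blocks
  X <- two_block_matrix(21, n_samples = 40, block_size = 50)
  ms <- buildNetwork(X, profile = "human", power = 14)
  kme <- moduleKME(ms)
  lab3 <- moduleLabels(ms)
  for (m in setdiff(unique(lab3), "grey")) {
    inside <- mean(kme[names(lab3)[lab3 == m], m])
    outside <- mean(kme[names(lab3)[lab3 != m], m])
    expect_gt(inside, outside)
  }
})
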