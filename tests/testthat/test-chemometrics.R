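toy_chem <- function() {
  m <- rbind(s1 = c(60, 30, 9.95, 0.05, 0),
             s2 = c(55, 35, 9.86, 0.04, 0.1),
             s3 = c(70, 20, 9.97, 0.03, 0))
  colnames(m) <- paste0("c", 1:5)
  chem_profile(m)
}

test_that("trace-compound filtering uses an inclusive 0.1% column-max rule", {
  chem <- toy_chem()
  filt <- filter_compounds(chem)
  # c4 never reaches 0.1% -> removed; c5 hits exactly 0.1% once -> kept
  expect_setequal(colnames(filt), c("c1", "c2", "c3", "c5"))
  keep_oracle <- apply(unclass(chem), 2, max) >= 0.1
  expect_setequal(colnames(filt), names(which(keep_oracle)))
  expect_error(filter_compounds(chem, threshold = 1000), "all compounds")
})

test_that("log10(x+1) transform then z-scaling matches a hand computation", {
  m <- rbind(a = c(10, 0), b = c(1, 0), c = c(0.1, 0))
  colnames(m) <- c("x", "zero")
  expect_warning(out <- transform_standardize(m), "zero-variance")
  expect_equal(out[, "zero"], c(a = 0, b = 0, c = 0))
  y <- log10(m[, "x"] + 1)
  expect_equal(unname(out[, "x"]), unname((y - mean(y)) / stats::sd(y)),
               tolerance = 1e-12)
  expect_equal(mean(out[, "x"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(out[, "x"]), 1, tolerance = 1e-12)
  expect_error(transform_standardize(rbind(c(-1, 2))), "negative")
})

test_that("Bray-Curtis distances follow the direct formula", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(0, 0, 6))
  d <- bray_curtis(m, shift = FALSE)
  expect_equal(unname(d["a", "b"]), 0)
  bc_direct <- function(x, y) sum(abs(x - y)) / sum(x + y)
  expect_equal(unname(d["a", "c"]), bc_direct(m["a", ], m["c", ]), tolerance = 1e-12)
  disj <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 2, 3))
  expect_equal(unname(bray_curtis(disj, shift = FALSE)["a", "b"]), 1)
  zz <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_warning(dz <- bray_curtis(zz, shift = FALSE), "zero total")
  expect_equal(unname(dz["a", "b"]), 0)
})

test_that("transform + Bray-Curtis is invariant to compound and sample order", {
  set.seed(3)
  m <- matrix(stats::runif(8 * 6, 0, 30), 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("c", 1:6)))
  d1 <- bray_curtis(transform_standardize(m))
  cp <- sample(ncol(m)); sp <- sample(nrow(m))
  d2 <- bray_curtis(transform_standardize(m[sp, cp]))
  expect_equal(unclass(d2[rownames(d1), rownames(d1)]), unclass(d1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("nMDS embeds embeddable configurations and reports stress-1", {
  set.seed(10)
  pts <- matrix(stats::rnorm(20), 10, 2)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("p", 1:10), paste0("p", 1:10))
  fit <- chem_nmds(dist_matrix(d), k = 3, n_runs = 10, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_equal(dim(fit$points), c(10, 3))
  # stress is rotation/reflection-invariant (configuration distances only)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, -1))
  expect_equal(stress1_oracle(d, fit$points %*% R), stress1_oracle(d, fit$points),
               tolerance = 1e-12)
  expect_error(chem_nmds(dist_matrix(d), k = 9), "k must be")
})

test_that("best nMDS stress is non-increasing in the number of restarts", {
  set.seed(21)
  m <- matrix(stats::runif(12 * 5), 12, 5,
              dimnames = list(paste0("s", 1:12), paste0("c", 1:5)))
  d <- bray_curtis(m, shift = FALSE)
  stresses <- vapply(c(1, 3, 8), function(nr)
    chem_nmds(d, k = 2, n_runs = nr, seed = 7)$stress, numeric(1))
  expect_true(all(diff(stresses) <= 1e-12))
})

test_that("perMANOVA pseudo-F equals classical ANOVA F on univariate data", {
  x <- c(0, 1, 4, 5)
  g <- c("A", "A", "B", "B")
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- permanova(dist_matrix(d), g, n_perm = 99, seed = 1)
  expect_equal(res$f, 32, tolerance = 1e-10)
  expect_equal(res$df_between, 1)
  # random univariate fixtures: oracle equivalence to aov
  for (s in 1:5) {
    set.seed(400 + s)
    x <- stats::rnorm(12)
    g <- rep(c("A", "B", "C"), each = 4)
    d <- as.matrix(stats::dist(x)); dimnames(d) <- list(paste0("i", 1:12), paste0("i", 1:12))
    res <- permanova(dist_matrix(d), g, n_perm = 19, seed = s)
    f_classic <- summary(stats::aov(x ~ g))[[1]]$`F value`[1]
    expect_equal(res$f, f_classic, tolerance = 1e-10)
    expect_false(is.null(res$pairwise))
    expect_true(all(res$pairwise$p_adj >= res$pairwise$p))
  }
  expect_error(permanova(dist_matrix(d), rep("A", 12)), ">= 2 groups")
  expect_error(permanova(dist_matrix(d), c("A", rep("B", 11))), "n >= 2")
})

test_that("dispersion distances and variability behave geometrically", {
  # two samples at distance d in one group: each d/2 from the centroid
  d <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_message(res <- dispersion_test(dist_matrix(d), c("G", "G"), n_perm = 19),
                 "single group")
  expect_equal(unname(res$distances), c(0.2, 0.2), tolerance = 1e-10)
  expect_equal(unname(res$variability[["G"]]), 0.2, tolerance = 1e-10)
  # identical profiles: zero variability, test skipped
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_message(rz <- dispersion_test(dist_matrix(z), c("G", "G", "H")),
                 "skipped")
  expect_true(is.na(rz$f))
  # observed distances and F match vegan's betadisper route exactly,
  # including the negative-eigenvalue (Bray-Curtis) case
  set.seed(77)
  m <- matrix(stats::runif(14 * 6, 0, 20), 14, 6,
              dimnames = list(paste0("s", 1:14), paste0("c", 1:6)))
  bc <- bray_curtis(m, shift = FALSE)
  gg <- rep(c("A", "B"), 7)
  mine <- suppressWarnings(dispersion_test(bc, gg, n_perm = 19, seed = 1))
  ref <- vegan::betadisper(stats::as.dist(unclass(bc)), gg, type = "centroid")
  expect_equal(unname(mine$distances), unname(ref$distances), tolerance = 1e-8)
  expect_equal(mine$f, stats::anova(ref)$`F value`[1], tolerance = 1e-8)
  # engineered unequal spread is detected by the permutation test
  hits <- 0L
  for (s in 1:10) {
    set.seed(600 + s)
    tight <- matrix(stats::rnorm(16, sd = 0.05), 8, 2)
    loose <- matrix(stats::rnorm(16, sd = 1), 8, 2)
    pts <- rbind(tight, loose)
    rownames(pts) <- paste0("s", 1:16)
    dd <- as.matrix(stats::dist(pts))
    res <- dispersion_test(dist_matrix(dd), rep(c("T", "L"), each = 8),
                           n_perm = 199, seed = s)
    if (res$p_perm < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("IndVal reproduces hand-computed specificity x fidelity values", {
  # compound exclusive to and ubiquitous in one group -> 100
  m <- rbind(a1 = c(5, 2), a2 = c(3, 4), b1 = c(0, 2), b2 = c(0, 0))
  colnames(m) <- c("excl", "shared")
  g <- c("A", "A", "B", "B")
  res <- indval(m, g, n_perm = 99, seed = 1)
  expect_equal(unname(res$indval["A", "excl"]), 100)
  # hand application of A*B*100: group means {3,1}, presence {1, 1/2}
  m2 <- rbind(a1 = 2, a2 = 4, b1 = 2, b2 = 0)
  colnames(m2) <- "c"
  r2 <- indval(m2, g, n_perm = 99, seed = 1)
  expect_equal(unname(r2$indval["A", "c"]), 75)
  expect_equal(unname(r2$indval["B", "c"]), 12.5)
  # scale invariance per compound
  m3 <- m; m3[, "excl"] <- m3[, "excl"] * 37
  r3 <- indval(m3, g, n_perm = 99, seed = 1)
  expect_equal(r3$indval, indval(m, g, n_perm = 99, seed = 1)$indval,
               tolerance = 1e-12)
  # absent compound: IndVal 0 everywhere
  m4 <- cbind(m, none = 0)
  r4 <- indval(m4, g, n_perm = 19, seed = 1)
  expect_equal(unname(r4$indval[, "none"]), c(0, 0))
  expect_false(r4$significant[["none"]])
})
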