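test_that("median-joining network handles simple chains without medians", {
  # two haplotypes 3 sites apart: one edge, 3 mutations, no medians
  a2 <- seq_alignment(c("AAA", "TTT"), c("x", "y"), "l")
  n2 <- median_joining_network(collapse_haplotypes(a2))
  expect_equal(nrow(n2$edges), 1)
  expect_equal(n2$edges$mutations, 3)
  expect_false(any(n2$nodes$is_median))
  # AAA - AAT - ATT: a path with unit links
  a3 <- seq_alignment(c("AAA", "AAT", "ATT"), c("x", "y", "z"), "l")
  n3 <- median_joining_network(collapse_haplotypes(a3))
  expect_equal(nrow(n3$edges), 2)
  expect_equal(sort(n3$edges$mutations), c(1, 1))
  expect_false(any(n3$nodes$is_median))
  deg <- table(c(n3$edges$from, n3$edges$to))
  expect_equal(unname(deg["H2"]), 2)   # the intermediate haplotype is the hub
})

test_that("network contains every link of every weighted MST (4-haplotype fixture)", {
  haps <- c("AAA", "AAG", "AAC", "AAT")
  aln <- seq_alignment(haps, paste0("s", 1:4), "l")
  net <- median_joining_network(collapse_haplotypes(aln))
  d <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    a <- strsplit(haps[i], "")[[1]]; b <- strsplit(haps[j], "")[[1]]
    w <- 0
    for (s in which(a != b)) {
      ts <- (a[s] %in% c("A", "G") && b[s] %in% c("A", "G")) ||
        (a[s] %in% c("C", "T") && b[s] %in% c("C", "T"))
      w <- w + if (ts) 1 else 2
    }
    d[i, j] <- d[j, i] <- w
  }
  msts <- all_msts(d)
  expect_gt(length(msts), 1)   # the fixture is genuinely tie-rich
  got <- paste(pmin(match(net$edges$from, paste0("H", 1:4)),
                    match(net$edges$to, paste0("H", 1:4))),
               pmax(match(net$edges$from, paste0("H", 1:4)),
                    match(net$edges$to, paste0("H", 1:4))))
  for (mst in msts) {
    want <- paste(mst[, 1], mst[, 2])
    expect_true(all(want %in% got))
  }
})

test_that("with unit weights MJN equals a unique median-free MST", {
  # star-like set whose MST is unique: centre plus three satellites at
  # distinct distances
  haps <- c("AAAAAA", "TAAAAA", "TTCAAA", "TTTTGA")
  aln <- seq_alignment(haps, paste0("s", seq_along(haps)), "l")
  net <- median_joining_network(collapse_haplotypes(aln),
                                transversion_weight = 1)
  # unit-weight distances are plain Hamming distances
  hm <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    hm[i, j] <- sum(strsplit(haps[i], "")[[1]] != strsplit(haps[j], "")[[1]])
  msts <- all_msts(hm)
  expect_length(msts, 1)
  expect_false(any(net$nodes$is_median))
  expect_equal(nrow(net$edges), nrow(msts[[1]]))
  got <- sort(paste(pmin(match(net$edges$from, paste0("H", 1:4)),
                         match(net$edges$to, paste0("H", 1:4))),
                    pmax(match(net$edges$from, paste0("H", 1:4)),
                         match(net$edges$to, paste0("H", 1:4)))))
  expect_equal(got, sort(paste(msts[[1]][, 1], msts[[1]][, 2])))
})

test_that("median vectors are inserted when they shorten the network", {
  # three haplotypes pairwise 2 apart whose consensus is a fourth state:
  # connecting through the median costs 3 < any spanning pair cost 4
  haps <- c("AAT", "ATA", "TAA")
  aln <- seq_alignment(haps, c("x", "y", "z"), "l")
  net <- median_joining_network(collapse_haplotypes(aln),
                                transversion_weight = 1)
  expect_true(any(net$nodes$is_median))
  mv <- net$nodes$sequence[net$nodes$is_median]
  expect_equal(mv, "AAA")
  expect_equal(net$nodes$freq[net$nodes$is_median], 0L)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$mutations == 1))
})

test_that("neighbour joining solves the 3-taxon case in closed form", {
  dm <- dist_matrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
                           dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tr <- neighbor_joining(dm)
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[c("A", "B", "C")]), c(1, 2, 3))
  expect_error(neighbor_joining(dm[1:2, 1:2]), ">= 3")
  dm2 <- dm; dm2[1, 2] <- dm2[2, 1] <- NA
  expect_error(neighbor_joining(dm2))
})

test_that("NJ recovers random additive trees exactly", {
  for (s in 1:6) {
    n <- sample(4:8, 1)
    gen <- random_additive_tree(n, seed = 100 + s)
    rec <- neighbor_joining(gen$d[gen$tree$tip.label, gen$tree$tip.label])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen$tree), rec)), 0)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(gen$d), colnames(gen$d)],
                 gen$d, tolerance = 1e-8)
    expect_true(all(rec$edge.length >= 0))
  }
})

test_that("NJ is deterministic and length-invariant under relabelling", {
  gen <- random_additive_tree(6, seed = 77)
  d <- gen$d
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  perm <- sample(rownames(d))
  t3 <- neighbor_joining(d[perm, perm])
  expect_equal(sum(t3$edge.length), sum(t1$edge.length), tolerance = 1e-10)
})

test_that("bootstrap support saturates on a clean split and stays in range", {
  blockA <- paste(rep("A", 30), collapse = "")
  blockT <- paste(rep("T", 30), collapse = "")
  # perturb within pairs so distances are informative but the split clean
  sub <- function(s, i, ch) { x <- strsplit(s, "")[[1]]; x[i] <- ch; paste(x, collapse = "") }
  aln <- seq_alignment(c(blockA, sub(blockA, 1, "G"), blockT, sub(blockT, 1, "C")),
                       c("a1", "a2", "b1", "b2"), "l")
  tr <- bootstrap_support(list(aln, aln), n_reps = 100, seed = 5)
  sup <- as.numeric(tr$node.label)
  sup <- sup[!is.na(sup) & sup > 0]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(100 %in% sup)   # the 2+2 bipartition appears in every replicate
})

test_that("bootstrap replicates match a scripted replicate-by-replicate oracle", {
  alns <- lapply(1:2, function(k) random_alignment(4, 25, paste0("L", k), seed = 30 + k))
  tr <- bootstrap_support(alns, n_reps = 10, seed = 9)
  # independent reconstruction of the same resampling protocol
  mats <- lapply(alns, function(a) do.call(rbind, strsplit(a$sequences, "")))
  set.seed(9)
  reps <- list()
  for (r in 1:10) {
    boot <- lapply(seq_along(alns), function(k) {
      idx <- sample.int(ncol(mats[[k]]), ncol(mats[[k]]), replace = TRUE)
      seq_alignment(apply(mats[[k]][, idx, drop = FALSE], 1, paste, collapse = ""),
                    alns[[k]]$sample_ids, alns[[k]]$locus_id)
    })
    reps[[r]] <- neighbor_joining(pdist_oracle(boot))
  }
  ref <- neighbor_joining(pdist_oracle(alns))
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  expect_equal(as.numeric(tr$node.label), round(100 * counts / 10, 1))
  expect_error(bootstrap_support(alns, n_reps = 0), "n_reps")
})
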