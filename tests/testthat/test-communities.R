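twoCliques <- function() {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  diag(W) <- 0
  W[4, 5] <- W[5, 4] <- 1
  W
}

test_that("two joined cliques split into the two cliques", {
  part <- cnmCommunities(twoCliques())
  expect_identical(part@nCommunities, 2L)
  lab <- communityLabels(part)
  expect_equal(length(unique(lab[1:4])), 1)
  expect_equal(length(unique(lab[5:8])), 1)
  expect_equal(modularityScore(part), bruteForceModularity(twoCliques()),
               tolerance = 1e-12)
})

test_that("complete graphs stay one community; forceK controls the count", {
  K <- matrix(1, 6, 6); diag(K) <- 0
  expect_identical(cnmCommunities(K)@nCommunities, 1L)
  expect_identical(cnmCommunities(K, forceK = 6)@nCommunities, 6L)
  expect_identical(cnmCommunities(twoCliques(), forceK = 1)@nCommunities, 1L)
  expect_identical(cnmCommunities(twoCliques(), forceK = 3)@nCommunities, 3L)
  expect_error(cnmCommunities(K, forceK = 0), "1..N")
  expect_error(cnmCommunities(K, forceK = 7), "1..N")
})

test_that("modularity matches igraph on random weighted graphs", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      n <- sample(5:12, 1)
      W <- matrix(0, n, n)
      up <- upper.tri(W)
      W[up] <- rbinom(sum(up), 1, 0.4) * runif(sum(up))
      W <- W + t(W)
      if (sum(W) == 0) next
      part <- cnmCommunities(W)
      g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
      expect_equal(part@modularity,
                   igraph::modularity(g, communityLabels(part),
                                      weights = igraph::E(g)$weight),
                   tolerance = 1e-12)
    }
  })
})

test_that("greedy merge sequence is deterministic and label-stable", {
  W <- twoCliques()
  p1 <- cnmCommunities(W)
  p2 <- cnmCommunities(W)
  expect_identical(communityLabels(p1), communityLabels(p2))
})

test_that("fdr is zero on perfect recovery and label-permutation invariant", {
  truth <- setNames(rep(1:3, each = 4), paste0("m", 1:12))
  pred <- new("CommunityPartition", labels = truth, nCommunities = 3L,
              modularity = 0.5)
  expect_equal(fdr(pred, truth), 0)
  permuted <- setNames(c(3L, 1L, 2L)[truth], names(truth))
  predP <- new("CommunityPartition", labels = permuted, nCommunities = 3L,
               modularity = 0.5)
  expect_equal(fdr(predP, truth), 0)
})

test_that("fdr matches the best one-to-one assignment", {
  truth <- setNames(rep(1:2, each = 5), paste0("m", 1:10))
  single <- new("CommunityPartition",
                labels = setNames(rep(1L, 10), names(truth)),
                nCommunities = 1L, modularity = 0)
  expect_equal(fdr(single, truth), 0.5)
  # surplus communities: splitting one group in two still misassigns the
  # smaller shard only
  lab <- setNames(c(rep(1L, 3), rep(3L, 2), rep(2L, 5)), names(truth))
  split2 <- new("CommunityPartition", labels = lab, nCommunities = 3L,
                modularity = 0)
  expect_equal(fdr(split2, truth), 0.2)
  big <- setNames(rep(1:11, each = 2), paste0("m", 1:22))
  expect_error(fdr(new("CommunityPartition",
                       labels = setNames(rep(1L, 22), names(big)),
                       nCommunities = 1L, modularity = 0), big),
               "10 truth groups")
  expect_error(fdr(single, truth[1:9]), "same member set")
})

test_that("threshold sweep tracks links, density and a community plateau", {
  # planted 2-block intensity matrix: within 0.9, between 0.1
  N <- 10
  H <- matrix(0.1, N, N)
  H[1:5, 1:5] <- 0.9; H[6:10, 6:10] <- 0.9
  diag(H) <- 0
  net <- new("ReconstructedNetwork", intensity = H, rawIntensity = H,
             adjacency = matrix(FALSE, N, N), tm = NA_real_,
             memberIds = paste0("m", 1:N), meta = list())
  sw <- thresholdSweep(net, grid = seq(0, 1, by = 0.1))
  expect_true(all(diff(sw$link_count) <= 0))
  expect_true(all(sw$density >= 0 & sw$density <= 1))
  mid <- sw$n_communities[sw$t_m >= 0.2 & sw$t_m <= 0.8]
  expect_true(all(mid == 2))
  expect_true(all(sw$link_count[sw$t_m >= 0.9] == 0))
  expect_error(thresholdSweep(net, numeric(0)), "non-empty")
  expect_error(thresholdSweep(net, c(0, 2)), "\\[0, 1\\]")
})

test_that("zero-weight graphs degenerate to singletons", {
  part <- cnmCommunities(matrix(0, 4, 4))
  expect_identical(part@nCommunities, 4L)
  expect_equal(modularityScore(part), 0)
})
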