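test_that("BH adjustment matches the step-up rule and handles NA", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # NA propagates and is excluded from the effective number of tests
  mixed <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(mixed[2]))
  expect_equal(mixed[c(1, 3)], p.adjust(c(0.01, 0.02), "BH"))
  # monotone in the p-value ranks
  set.seed(1)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("GSEA enrichment scores equal exhaustive running-sum enumeration", {
  set.seed(4)
  for (rep in 1:8) {
    N <- sample(8:20, 1)
    scores <- setNames(round(rnorm(N), 2), sprintf("f%02d", 1:N))
    if (rep %% 2 == 0) scores[2] <- scores[1]   # exercise tie handling
    sets <- list(top = names(sort(scores, decreasing = TRUE))[1:3],
                 rand = sample(names(scores), 5),
                 bottom = names(sort(scores))[1:4])
    res <- gsea_preranked(scores, sets, n_perm = 50, seed = 1, min_size = 3)
    for (i in seq_len(nrow(res))) {
      expect_equal(res$ES[i], unname(oracle_es(scores, sets[[res$set[i]]])),
                   tolerance = 1e-12)
    }
    expect_true(all(abs(res$ES) <= 1 + 1e-12))
  }
})

test_that("GSEA sign antisymmetry, skips, and leading edges behave", {
  set.seed(6)
  scores <- setNames(rnorm(50), paste0("f", 1:50))
  sets <- list(s1 = names(sort(scores, decreasing = TRUE))[1:8],
               tiny = paste0("f", 1:2),
               all = names(scores))
  res <- gsea_preranked(scores, sets, n_perm = 200, seed = 2)
  expect_identical(res$set, "s1")
  expect_match(attr(res, "skipped")[["tiny"]], "intersection")
  expect_match(attr(res, "skipped")[["all"]], "universe")
  # reversing the score signs negates ES (exactly) and NES (in sign)
  neg <- gsea_preranked(-scores, sets["s1"], n_perm = 200, seed = 2)
  expect_equal(neg$ES, -res$ES, tolerance = 1e-12)
  expect_equal(sign(neg$NES), -sign(res$NES))
  # a set at the top of the ranking has positive ES and its leading edge
  # contains only set members
  expect_gt(res$ES[1], 0)
  le <- strsplit(res$leading_edge[1], ",")[[1]]
  expect_true(all(le %in% sets$s1))
})

test_that("GSEA p-values are calibrated for random scores and sets", {
  set.seed(11)
  scores <- setNames(rnorm(150), paste0("f", 1:150))
  sets <- lapply(1:200, function(i) sample(names(scores), 15))
  names(sets) <- paste0("s", 1:200)
  res <- gsea_preranked(scores, sets, n_perm = 400, seed = 3)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("hypergeometric overlap matches exact combinatorics", {
  universe <- paste0("g", 1:20)
  # complete overlap of a 5-set with a 5-query: p = 1/choose(20, 5)
  res <- hypergeom_overlap(paste0("g", 1:5), list(hit = paste0("g", 1:5)), universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5)
  # random small cases against the explicit combinatorial sum
  set.seed(2)
  for (rep in 1:10) {
    N <- sample(10:30, 1)
    uni <- paste0("u", 1:N)
    K <- sample(3:(N - 2), 1)
    m <- sample(3:(N - 2), 1)
    s <- sample(uni, K)
    q <- sample(uni, m)
    k <- length(intersect(s, q))
    ref <- sum(vapply(k:min(K, m), function(i)
      choose(K, i) * choose(N - K, m - i) / choose(N, m), numeric(1)))
    out <- hypergeom_overlap(q, list(s = s), uni)
    expect_equal(out$p, ref, tolerance = 1e-10)
  }
  # zero overlap: upper-tail p = 1
  res0 <- hypergeom_overlap(paste0("g", 1:5), list(miss = paste0("g", 6:10)),
                            paste0("g", 1:10))
  expect_equal(res0$p, 1)
  expect_true(is.finite(res0$odds_ratio))  # Haldane correction applied
  # overlap at independence expectation is unremarkable
  uni2 <- paste0("g", 1:100)
  ri <- hypergeom_overlap(paste0("g", 1:20), list(s = paste0("g", 16:35)), uni2)
  expect_equal(ri$overlap, 5)
  expect_gt(ri$p, 0.3)
  expect_error(hypergeom_overlap("x", list(s = "g1"), uni2), "subset")
})

test_that("decile trajectories bin by rank and summarize stages", {
  ids <- sprintf("g%02d", 1:20)
  scores <- setNames(seq(1, -1, length.out = 20), ids)
  # outer(score, stage): curves must be ordered by decile at every stage
  stage <- outer(scores, 1:4)
  rownames(stage) <- ids
  colnames(stage) <- paste0("st", 1:4)
  tr <- decile_trajectories(scores, stage)
  expect_equal(nrow(tr), 40)
  expect_true(all(tr$n == 2))           # 20 features -> deciles of size 2
  for (st in paste0("st", 1:4)) {
    sub <- tr[tr$stage == st, ]
    expect_true(all(diff(sub$median[order(sub$decile)]) <= 0))
  }
  # decile 1 holds the most positive scores
  top <- tr[tr$decile == 1 & tr$stage == "st4", ]
  expect_equal(top$median, median(stage[1:2, "st4"]))
  # constant stage matrix: all curves flat and identical
  flat <- matrix(5, 20, 3, dimnames = list(ids, NULL))
  tf <- decile_trajectories(scores, flat)
  expect_true(all(tf$median == 5) && all(tf$mean == 5))
  # unshared features are dropped and counted
  tr2 <- decile_trajectories(scores, stage[1:15, , drop = FALSE])
  expect_equal(attr(tr2, "n_dropped"), 5)
})

test_that("implementation agrees with fgsea on a moderate instance", {
  set.seed(13)
  scores <- setNames(rnorm(300), paste0("f", 1:300))
  sets <- list(a = sample(names(scores), 25), b = sample(names(scores), 40))
  mine <- gsea_preranked(scores, sets, n_perm = 2000, seed = 1)
  ref <- suppressWarnings(fgsea::fgsea(sets, scores, nPermSimple = 2000,
                                       scoreType = "std"))
  ref <- ref[match(mine$set, ref$pathway), ]
  expect_equal(mine$ES, ref$ES, tolerance = 1e-8)
  # NES conventions differ slightly in normalization but must agree in sign
  # and roughly in magnitude
  expect_equal(sign(mine$NES), sign(ref$NES))
})
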