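uniform_channel <- function(lab, value) {
  d <- array(0, dim(lab$data))
  d[lab$data == 1] <- value
  signal_volume(d, lab$spacing, valid_mask = lab$data == 1)
}

full_cube <- function(nvox = 18, spacing = 2) {
  label_volume(array(1, rep(nvox, 3)), rep(spacing, 3), "cube")
}

test_that("sample_for_clustering lays an isotropic grid over the consensus", {
  expect_identical(sampling_params()$edge, 18)
  # full 36x36x36 um cube, edge 18, coverage 0.5: a 2x2x2 grid, 8 rows
  cons <- full_cube(18, 2)   # 18 voxels at 2 um = 36 um
  ch <- uniform_channel(cons, 1)
  tab <- sample_for_clustering(list(sig = ch), cons)
  expect_identical(nrow(tab), 8L)
  expect_equal(tab$sig, rep(1, 8))
  expect_identical(sort(unique(tab$gi)), 1:2)
  # empty consensus errors
  e <- suppressWarnings(label_volume(array(0, c(8, 8, 8)), 2))
  expect_error(sample_for_clustering(list(sig = ch), e), "shapes|empty")
})

test_that("hierarchical clustering is complete-linkage Euclidean", {
  cons <- full_cube(18, 2)
  ch <- uniform_channel(cons, 1)
  tab <- sample_for_clustering(list(a = ch), cons)
  # two rows at distance d merge at height d
  t2 <- tab[1:2, ]
  attr(t2, "grid") <- attr(tab, "grid")
  class(t2) <- class(tab)
  t2$a <- c(1, 4)
  dend <- hierarchical_cluster(t2)
  expect_identical(nrow(dend$merge), 1L)
  expect_equal(dend$height, 3)
  # n rows: n - 1 merges
  dn <- hierarchical_cluster(tab)
  expect_identical(nrow(dn$merge), 7L)
  # two tight groups split by 100x their spread separate at the final merge
  t8 <- tab
  set.seed(99)
  t8$a <- c(rnorm(4, 0, 0.01), rnorm(4, 100, 0.01))
  d8 <- hierarchical_cluster(t8)
  z <- cut_zones(d8, 2)
  expect_identical(z$zone[1:4], rep(z$zone[1], 4))
  expect_identical(z$zone[5:8], rep(z$zone[5], 4))
  expect_false(z$zone[1] == z$zone[5])
  expect_error(hierarchical_cluster(t2[1, ]), "two")
})

test_that("cut_zones assigns dense ids by decreasing size", {
  cons <- full_cube(18, 2)
  ch <- uniform_channel(cons, 1)
  tab <- sample_for_clustering(list(a = ch), cons)
  tab$a <- c(1, 1, 1, 1, 1, 50, 50, 99)  # sizes 5, 2, 1
  dend <- hierarchical_cluster(tab)
  # k = 1: all rows zone 1
  expect_identical(cut_zones(dend, 1)$zone, rep(1L, 8))
  # k = leaf count: every row its own zone
  expect_identical(sort(cut_zones(dend, 8)$zone), 1:8)
  # ids ordered by decreasing cluster size
  z3 <- cut_zones(dend, 3)
  expect_identical(z3$zone, c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L))
  expect_error(cut_zones(dend, 0), "k must")
  expect_error(cut_zones(dend, 9), "k must")
})

test_that("zone recovery on planted zones meets the separation contract", {
  cons <- full_cube(48, 2)  # 96 um cube; zone slabs align with the grid
  means <- matrix(c(1, 5, 9,
                    9, 1, 5,
                    5, 9, 1), 3, 3, byrow = TRUE)
  zs <- make_zoned_signal(cons, 3, means, noise_sd = 0.1, seed = 41)
  tab <- sample_for_clustering(zs$channels, cons,
                               sampling_params(edge = 8, min_coverage = 0.5))
  dend <- hierarchical_cluster(tab)
  z <- cut_zones(dend, 3)
  # true zone per row: majority of the truth map inside the supervoxel
  g <- attr(tab, "grid")
  true_zone <- vapply(z$rows, function(r) {
    lo <- g$origin + (c(tab$gi[r], tab$gj[r], tab$gk[r]) - 1L) * g$cell
    hi <- pmin(lo + g$cell - 1L, g$shape)
    tv <- zs$truth[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    as.integer(names(which.max(table(tv[tv > 0]))))
  }, integer(1))
  # best label matching over the 6 permutations of 3 labels
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  acc <- max(vapply(perms, function(p) mean(p[z$zone] == true_zone),
                    numeric(1)))
  expect_gte(acc, 0.95)
  # profiles recover the planted means within noise sd / sqrt(n)
  prof <- zone_profiles(tab, z)
  sizes <- attr(prof, "zone_size")
  best <- perms[[which.max(vapply(perms, function(p)
    mean(p[z$zone] == true_zone), numeric(1)))]]
  for (zid in 1:3) {
    planted <- means[best[zid], ]
    nvox_per_row <- prod(g$cell)
    tol <- 5 * 0.1 / sqrt(sizes[zid] * nvox_per_row)
    expect_lt(max(abs(prof[zid, ] - planted)), max(tol, 0.05))
  }
})

test_that("zone_profiles aligns held-out channels and conserves the grand mean", {
  cons <- full_cube(18, 2)
  ch <- uniform_channel(cons, 1)
  tab <- sample_for_clustering(list(a = ch), cons)
  tab$a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  dend <- hierarchical_cluster(tab)
  z <- cut_zones(dend, 3)
  # single zone: profile = column means
  z1 <- cut_zones(dend, 1)
  expect_equal(as.numeric(zone_profiles(tab, z1)), mean(tab$a))
  # held-out channel equal to an in-table channel gives an identical column
  extra <- tab
  names(extra)[names(extra) == "a"] <- "b"
  attr(extra, "grid")$channels <- "b"
  prof <- zone_profiles(tab, z, extra = extra)
  expect_identical(prof[, "a"], prof[, "b"])
  # size-weighted mean of zone profiles equals the column mean
  sizes <- attr(prof, "zone_size")
  expect_equal(sum(prof[, "a"] * sizes) / sum(sizes), mean(tab$a),
               tolerance = 1e-12)
})

test_that("reconstruct_zone_volume round-trips zone ids", {
  ph <- make_phantom(small_phantom_spec())
  means <- matrix(c(1, 9, 5, 2, 8, 3), 2, 3)
  zs <- make_zoned_signal(ph$label, 2, means, noise_sd = 0, seed = 43)
  tab <- sample_for_clustering(zs$channels, ph$label,
                               sampling_params(edge = 8))
  dend <- hierarchical_cluster(tab)
  z <- cut_zones(dend, 2)
  zm <- reconstruct_zone_volume(z, tab, ph$label)
  # one zone: zone map equals the covered consensus support
  z1 <- cut_zones(dend, 1)
  zm1 <- reconstruct_zone_volume(z1, tab, ph$label)
  expect_true(all(zm1 %in% c(0L, 1L)))
  expect_true(all(zm1[ph$label$data == 0] == 0))
  # voxels of dropped rows stay 0: compare coverage
  covered <- zm1 == 1
  expect_true(all(ph$label$data[covered] == 1))
  # re-sampling the zone map recovers per-row zone ids exactly
  zch <- signal_volume(zm + 0, ph$label$spacing, valid_mask = zm > 0)
  tab2 <- sample_for_clustering(list(z = zch), ph$label,
                                sampling_params(edge = 8))
  key <- function(t) paste(t$gi, t$gj, t$gk)
  idx <- match(key(tab)[z$rows], key(tab2))
  expect_equal(tab2$z[idx], as.numeric(z$zone))
})

test_that("clustering is invariant to row order up to relabelling", {
  ph <- make_phantom(small_phantom_spec())
  means <- matrix(c(1, 8, 4, 7, 2, 6), 2, 3)
  zs <- make_zoned_signal(ph$label, 2, means, noise_sd = 0.05, seed = 47)
  tab <- sample_for_clustering(zs$channels, ph$label,
                               sampling_params(edge = 8))
  dend <- hierarchical_cluster(tab)
  z <- cut_zones(dend, 2)
  perm <- morphatlas:::with_seed(48, sample(nrow(tab)))
  tabp <- tab[perm, ]
  attr(tabp, "grid") <- attr(tab, "grid")
  class(tabp) <- class(tab)
  zp <- cut_zones(hierarchical_cluster(tabp), 2)
  # compare assignments through the permutation, allowing label swap
  a <- z$zone
  b <- zp$zone[order(perm)]
  agree <- max(mean(a == b), mean(a == (3L - b)))
  expect_gte(agree, 0.95)
})

test_that("cluster table TSV and Cluster 3.0 export round-trip", {
  tmp <- withr::local_tempdir()
  cons <- full_cube(18, 2)
  ch <- uniform_channel(cons, 2)
  tab <- sample_for_clustering(list(sig = ch), cons)
  p <- file.path(tmp, "tab.tsv")
  write_cluster_tsv(tab, p)
  back <- read_cluster_table(p)
  expect_equal(back$sig, tab$sig)
  expect_identical(attr(back, "grid")$cell, attr(tab, "grid")$cell)
  p3 <- file.path(tmp, "c3.txt")
  write_cluster_table(tab, p3)
  c3 <- read.delim(p3)
  expect_identical(names(c3), c("UNIQID", "sig"))
  expect_identical(nrow(c3), 8L)
})
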