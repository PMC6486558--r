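test_that("contingency tables tally presence against type membership", {
  x <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1), ncol = 2,
              dimnames = list(c("c1", "c2", "c3", "c4"), c("GA", "GB")))
  labels <- c("T", "T", "Other", "Other")
  expect_equal(contingency_table(x, labels, "T", "GA"),
               c(n11 = 2L, n10 = 0L, n01 = 0L, n00 = 2L))
  # gene absent everywhere
  x0 <- cbind(x, GZ = 0)
  t0 <- contingency_table(x0, labels, "T", "GZ")
  expect_equal(unname(t0[c("n11", "n01")]), c(0L, 0L))
  expect_error(contingency_table(x, labels, "T", "NOPE"), "gene space")
  expect_error(contingency_table(x, labels, "Missing", "GA"), "not present")
})

test_that("contingency marginals match label and presence counts", {
  ds <- generate_labeled_dataset(small_synth(6, n_types = 3L,
                                             cells_per_type = 40L))
  for (g in c("M1_1", "BG5", "M3_7")) {
    t <- contingency_table(ds$x, ds$labels$label, "Type2", g)
    expect_equal(unname(t["n11"] + t["n10"]), sum(ds$labels$label == "Type2"))
    expect_equal(unname(t["n11"] + t["n01"]),
                 sum(ds$x[, g]))
    expect_equal(sum(t), nrow(ds$x))
  }
})

test_that("information gain hits its closed-form anchors", {
  # perfect split of a balanced membership variable: exactly H(T) = 1 bit
  expect_identical(information_gain(c(50, 0, 0, 50)), 1)
  # constant gene carries no information
  expect_equal(information_gain(c(30, 0, 70, 0)), 0)
  expect_equal(information_gain(c(0, 30, 0, 70)), 0)
  expect_error(information_gain(c(0, 0, 0, 0)), "empty")
  # perfect split of an unbalanced variable equals its entropy, < 1 bit
  h <- -(0.3 * log2(0.3) + 0.7 * log2(0.7))
  expect_equal(information_gain(c(30, 0, 0, 70)), h, tolerance = 1e-12)
})

test_that("information gain equals brute-force mutual information", {
  expect_lt(abs(information_gain(c(30, 10, 20, 40)) -
                oracle_mutual_information(30, 10, 20, 40)), 1e-12)
  withr::with_seed(101, {
    for (i in 1:200) {
      t <- rmultinom(1, sample(10:500, 1), runif(4, 0.01, 1))[, 1]
      expect_lt(abs(information_gain(t) -
                    oracle_mutual_information(t[1], t[2], t[3], t[4])),
                1e-12)
    }
  })
})

test_that("gain is symmetric in present/absent relabeling and bounded", {
  withr::with_seed(55, {
    for (i in 1:50) {
      t <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
      g <- information_gain(t)
      swapped <- information_gain(t[c(2, 1, 4, 3)])
      expect_equal(g, swapped, tolerance = 1e-12)
      h_t <- -sum({
        p <- c(t[1] + t[2], t[3] + t[4]) / sum(t)
        p <- p[p > 0]
        p * log2(p)
      })
      expect_gte(g, 0)
      expect_lte(g, min(h_t, 1) + 1e-12)
    }
  })
})

test_that("planted markers outrank background genes and defaults return 50", {
  ds <- generate_labeled_dataset(
    synthetic_config(n_types = 3L, markers_per_type = 15L,
                     n_background_genes = 200L, cells_per_type = 150L,
                     seed = 13))
  rk <- top_signature_genes(ds$x, ds$labels$label, "Type1", n = 50L)
  expect_equal(nrow(rk), 50L)
  expect_equal(rk$rank, 1:50)
  expect_true(all(diff(rk$gain_bits) <= 1e-12))
  own_markers <- ds$marker_map$gene[ds$marker_map$type == "Type1"]
  # every planted Type1 marker ranks above every background gene
  bg_ranked <- rk$rank[grepl("^BG", rk$gene)]
  marker_ranked <- rk$rank[rk$gene %in% own_markers]
  expect_equal(length(marker_ranked), 15L)
  if (length(bg_ranked)) expect_lt(max(marker_ranked), min(bg_ranked))
})

test_that("rankings agree with per-gene contingency recomputation", {
  ds <- generate_labeled_dataset(small_synth(29, n_types = 3L,
                                             cells_per_type = 30L))
  rk <- top_signature_genes(ds$x, ds$labels$label, "Type2", n = 10L)
  for (i in 1:5) {
    t <- contingency_table(ds$x, ds$labels$label, "Type2", rk$gene[i])
    expect_equal(rk$gain_bits[i], information_gain(t), tolerance = 1e-12)
    expect_equal(unname(t), c(rk$n11[i], rk$n10[i], rk$n01[i], rk$n00[i]))
  }
})

test_that("oversized requests return the whole gene space with a warning", {
  ds <- generate_labeled_dataset(small_synth(2, n_types = 2L,
                                             cells_per_type = 20L))
  expect_warning(rk <- top_signature_genes(ds$x, ds$labels$label, "Type1",
                                           n = ncol(ds$x) + 10L),
                 "only")
  expect_equal(nrow(rk), ncol(ds$x))
})
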