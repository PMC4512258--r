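test_that("representative isoform selection follows PP, then |beta|, then id", {
  tab <- tibble::tibble(
    transcript_id = c("tA", "tB"), pp = c(0.99, 0.70), beta_mean = c(1, 2)
  )
  expect_equal(select_representative(tab), "tA")
  expect_equal(select_representative(tab[1, ]), "tA")
  tied <- tibble::tibble(
    transcript_id = c("tA", "tB"), pp = c(1, 1), beta_mean = c(2, 0.5)
  )
  expect_equal(select_representative(tied), "tA")
  tied2 <- tibble::tibble(
    transcript_id = c("tB", "tA"), pp = c(1, 1), beta_mean = c(1, 1)
  )
  expect_equal(select_representative(tied2), "tA")
})

simple_genes <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chromosome = "chr1",
    start = c(0, 5e5, 2e6),
    end = c(1e5, 6e5, 2.1e6),
    strand = "+",
    bias = c(0.95, 0.60, 0.55)
  )
}

test_that("the 1 MB chain rule and center threshold partition genes", {
  cl <- assign_clusters(simple_genes())
  # g1-g2 chain (gap 0.4 MB); g3 is 1.4 MB beyond g2's end -> own cluster
  expect_equal(dplyr::n_distinct(cl$cluster_id[cl$gene_id %in% c("g1", "g2")]), 1L)
  expect_false(cl$cluster_id[cl$gene_id == "g3"] %in%
                 cl$cluster_id[cl$gene_id == "g1"])
  expect_true(cl$is_center[cl$gene_id == "g1"])
  expect_false(cl$is_center[cl$gene_id == "g2"])
  expect_equal(cl$distance_bp[cl$gene_id == "g1"], 0)
  expect_equal(cl$distance_bp[cl$gene_id == "g2"], 4e5)  # start 5e5 - center end 1e5
  # g3's cluster has no center: NA distance, kept
  expect_true(is.na(cl$distance_bp[cl$gene_id == "g3"]))
  # every retained gene appears exactly once
  expect_equal(sort(cl$gene_id), c("g1", "g2", "g3"))
})

test_that("consecutive strong genes form one grouped center", {
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c"), chromosome = "chr2",
    start = c(0, 2e5, 5e5), end = c(1e5, 3e5, 6e5), strand = "+",
    bias = c(0.9, 0.9, 0.6)
  )
  cl <- assign_clusters(genes)
  expect_true(all(cl$is_center[cl$gene_id %in% c("a", "b")]))
  expect_equal(unique(cl$center_start), 0)
  expect_equal(unique(cl$center_end), 3e5)
  expect_equal(cl$distance_bp[cl$gene_id == "c"], 2e5)
})

test_that("multi-center clusters split at midpoints and distant genes drop", {
  genes <- tibble::tibble(
    gene_id = c("c1", "m1", "c2", "m2", "far"), chromosome = "chr3",
    start = c(0, 4e5, 1e6, 1.9e6, 2.9e6),
    end = c(1e5, 4.5e5, 1.1e6, 1.95e6, 2.95e6), strand = "+",
    bias = c(0.95, 0.6, 0.92, 0.6, 0.55)
  )
  cl <- assign_clusters(genes)
  # one chain (all end-to-start gaps < 1 MB) but two sub-clusters
  expect_equal(dplyr::n_distinct(cl$cluster_id), 2L)
  # boundary between centers: (1e5 + 1e6)/2 = 5.5e5 -> m1 (start 4e5) joins c1
  expect_equal(cl$cluster_id[cl$gene_id == "m1"], cl$cluster_id[cl$gene_id == "c1"])
  # m2 is 0.8 MB from c2's center edge -> kept in c2's sub-cluster
  expect_equal(cl$cluster_id[cl$gene_id == "m2"], cl$cluster_id[cl$gene_id == "c2"])
  # far is chained (0.95 MB from m2) but 1.8 MB from the center -> removed
  expect_false("far" %in% cl$gene_id)
  # partition: each retained gene has exactly one assignment within 1 MB
  expect_true(all(cl$distance_bp <= 1e6, na.rm = TRUE))
  expect_true(all(cl$bias[cl$is_center] >= 0.85))
})

test_that("assignment is invariant to input order and to dropping a member", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6), chromosome = "chr4",
    start = c(0, 3e5, 7e5, 1.2e6, 4e6, 4.3e6),
    end = c(1e5, 3.5e5, 7.5e5, 1.3e6, 4.1e6, 4.4e6), strand = "+",
    bias = c(0.9, 0.6, 0.55, 0.7, 0.95, 0.6)
  )
  a <- assign_clusters(genes)
  b <- assign_clusters(genes[sample(6), ])
  expect_equal(as.data.frame(a), as.data.frame(b))
  # removing a non-center member leaves the others untouched
  c <- assign_clusters(genes[genes$gene_id != "g3", ])
  expect_equal(
    as.data.frame(dplyr::filter(a, gene_id != "g3")),
    as.data.frame(c)
  )
})

test_that("strand normalisation restores sense orientation", {
  g <- tibble::tibble(start = c(10, 50), end = c(20, 30), strand = c("+", "-"))
  out <- normalize_strand(g)
  expect_equal(out$start, c(10, 30))
  expect_equal(out$end, c(20, 50))
})

test_that("decay regression recovers a noiseless linear decay exactly", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5), chromosome = "chr5",
    start = c(0, 2e5, 4e5, 6e5, 8e5),
    end = c(1e5, 2.5e5, 4.5e5, 6.5e5, 8.5e5), strand = "+",
    bias = c(0.95, 0.6, 0.6, 0.6, 0.6)
  )
  cl <- assign_clusters(genes)
  cl$bias <- ifelse(cl$is_center, cl$bias, 0.9 - 1e-7 * cl$distance_bp)
  # a zero-residual line makes summary.lm warn about a perfect fit
  fit <- suppressWarnings(decay_regression(cl))
  expect_equal(fit$slope, -1e-7, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.9, tolerance = 1e-9)
  expect_lt(fit$slope_p_value, 1e-10)

  expect_error(decay_regression(cl[cl$gene_id %in% c("g1", "g2"), ]),
               "at least 3")
  # flat biases give a zero slope
  cl$bias[!cl$is_center] <- 0.7
  expect_equal(suppressWarnings(decay_regression(cl))$slope, 0, tolerance = 1e-12)
})

test_that("simulated decaying cohorts yield negative pooled slopes", {
  set.seed(71)
  for (k in 1:3) {
    n <- 12
    starts <- sort(sample.int(9e5, n))
    genes <- tibble::tibble(
      gene_id = sprintf("g%d", seq_len(n)), chromosome = "chrX",
      start = starts, end = starts + 2e4, strand = "+",
      bias = NA_real_
    )
    genes$bias[1] <- 0.95
    cl0 <- assign_clusters(dplyr::mutate(genes, bias = dplyr::coalesce(bias, 0.6)))
    decayed <- cl0 |>
      dplyr::mutate(bias = ifelse(is_center, bias,
                                  pmax(0.5, 0.9 - 3e-7 * distance_bp +
                                         rnorm(dplyr::n(), 0, 0.02))))
    expect_lt(decay_regression(decayed)$slope, 0)
  }
})
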