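test_that("sites match pathway entries by any alias, case-insensitively", {
  g <- parse_kgml(fixture_kgml())
  m <- fixture_meth_matrix(
    c("erbb2_cg1", "her-2_cg2", "NOTAGENE_cg3", "casp3_cg4"),
    matrix(rep(0.5, 8), nrow = 4), c("s1", "s2"))
  hits <- match_sites(g, m)
  erbb2 <- hits[["11"]]
  expect_identical(erbb2$label, "ERBB2")
  # both the primary symbol and the alias row attach to the entry
  expect_identical(sort(m$features$gene[erbb2$rows]), c("erbb2", "her-2"))
  expect_identical(hits[["10"]]$rows, 4L)   # casp3
  expect_length(hits[["12"]]$rows, 0L)      # FAS: no rows
  # NOTAGENE matched nowhere
  all_rows <- unlist(lapply(hits, `[[`, "rows"))
  expect_false(3L %in% all_rows)
})

test_that("SD filter uses the sample estimator and strict threshold", {
  m <- fixture_meth_matrix(
    c("A_cg1", "B_cg2", "C_cg3"),
    matrix(c(0.1, 0.1, 0.9, 0.9,
             0.5, 0.5, 0.5, 0.5,
             0.5, NA, NA, NA), nrow = 3, byrow = TRUE),
    paste0("s", 1:4))
  part <- apply_filters(m, filter_spec(sd_threshold = 0.2))
  # sd([.1,.1,.9,.9]) = sqrt(4*0.16/3), well above 0.2
  expect_identical(part$passing, 1L)
  # constant site has sd 0; single-observation site fails any sd criterion
  expect_identical(part$excluded, c(2L, 3L))
  # the computed sd matches the closed form to near machine precision
  expect_equal(methpath:::site_sd(c(0.1, 0.1, 0.9, 0.9)),
               sqrt(4 * 0.16 / 3), tolerance = 1e-12)
})

test_that("beta-range, location and site-list criteria compose as AND", {
  m <- fixture_meth_matrix(
    c("A_cg1_exonic", "B_cg2_UTR5", "C_cg3_intronic", "D_cg4"),
    matrix(c(0.1, 0.2, 0.15, 0.25,
             0.1, 0.9, 0.2, 0.2,
             0.05, 0.1, 0.12, 0.2,
             0.1, 0.1, 0.2, 0.2), nrow = 4, byrow = TRUE),
    paste0("s", 1:4))
  # all betas must fall inside the range in "all" mode
  part <- apply_filters(m, filter_spec(beta_range = c(0, 0.3)))
  expect_setequal(part$passing, c(1L, 3L, 4L))
  # "any" mode needs only one in-range sample
  part <- apply_filters(m, filter_spec(beta_range = c(0.85, 1),
                                       range_mode = "any"))
  expect_identical(part$passing, 2L)
  # location filter: row without a location never passes
  part <- apply_filters(m, filter_spec(locations = c("exonic", "utr5")))
  expect_setequal(part$passing, c(1L, 2L))
  # explicit site list
  part <- apply_filters(m, filter_spec(site_list = c("cg3", "cg4")))
  expect_setequal(part$passing, c(3L, 4L))
  # combined criteria are conjunctive
  part <- apply_filters(m, filter_spec(beta_range = c(0, 0.3),
                                       locations = "exonic"))
  expect_identical(part$passing, 1L)
  # invalid range is a spec error
  expect_error(filter_spec(beta_range = c(0.8, 0.2)), "low <= high")
})

test_that("empty spec passes everything; filters partition and are idempotent", {
  set.seed(11)
  n <- 30
  vals <- matrix(runif(n * 6), nrow = n)
  vals[sample(length(vals), 25)] <- NA
  m <- fixture_meth_matrix(paste0("G", 1:n, "_cg", 1:n), vals,
                           paste0("s", 1:6))
  expect_length(apply_filters(m, filter_spec())$passing, n)

  spec <- filter_spec(sd_threshold = 0.15, beta_range = c(0.05, 0.95))
  part <- apply_filters(m, spec)
  expect_length(intersect(part$passing, part$excluded), 0L)
  expect_setequal(c(part$passing, part$excluded), seq_len(n))
  # idempotent on the passing set
  again <- apply_filters(m, spec, rows = part$passing)
  expect_identical(sort(again$passing), sort(part$passing))
  expect_length(again$excluded, 0L)
})

test_that("gene methylation display values average sites then groups", {
  m <- fixture_meth_matrix(
    c("A_cg1", "A_cg2"),
    matrix(c(0.2, 0.1, 0.9, 0.37,
             0.8, 0.3, 0.9, NA), nrow = 2, byrow = TRUE),
    paste0("s", 1:4))
  v <- gene_methylation_value(m, 1:2)
  # mean over sites per sample; missing site skipped
  expect_equal(unname(v$per_sample),
               c(0.5, 0.2, 0.9, 0.37))
  # single site, single sample: identity
  expect_equal(unname(gene_methylation_value(m, 1)$per_sample[4]), 0.37)

  path <- withr::local_tempfile()
  writeLines(c("s1\tg1", "s2\tg1", "s3\tg1", "s4\tg2"), path)
  grp <- read_grouping(path, m)
  v <- gene_methylation_value(m, 1, grouping = grp)
  # group of samples 0.2, 0.1, 0.9 -> mean 0.4
  expect_equal(unname(v$per_group["g1"]), 0.4)
  vmed <- gene_methylation_value(m, 1, grouping = grp,
                                 aggregator = "median")
  expect_equal(unname(vmed$per_group["g1"]), 0.2)
})

test_that("expression fold is log2 vs median, clipped at the scale", {
  all_vals <- c(10, 20, 40, 80, 20)   # median 20
  expect_identical(expression_fold(20, all_vals), 0)
  expect_equal(expression_fold(80, all_vals), 2, tolerance = 1e-3)
  # exact within-1e-6 check with median >> pseudocount
  big <- c(5e4, 1e5, 2e5, 4e5, 1e5)
  expect_equal(expression_fold(4e5, big), 2, tolerance = 1e-6)
  # 100x the median clips at the default scale of 4
  expect_identical(expression_fold(100 * 20, all_vals), 4)
  expect_identical(expression_fold(0.000001, big, scale = 4), -4)
  # odd around the median in log space (up to pseudocount effects)
  f_up <- expression_fold(2e5, big)
  f_dn <- expression_fold(5e4, big)
  expect_equal(f_up, -f_dn, tolerance = 1e-3)
})

test_that("similar-pattern search matches the hand-computed distance", {
  m <- fixture_meth_matrix(
    c("T_cg1", "X_cg2", "Y_cg3"),
    matrix(c(0.1, 0.2, 0.3,
             0.4, 0.6, 0.3,
             0.1, 0.2, 0.3), nrow = 3, byrow = TRUE),
    paste0("s", 1:3))
  hits <- find_similar(m, "T", top_k = 2)
  # identical vector: distance 0, rank 1
  expect_identical(hits$gene[1], "Y")
  expect_identical(hits$distance[1], 0)
  # sqrt((0.09 + 0.16 + 0)/3) = 0.2886751
  expect_equal(hits$distance[2], sqrt((0.09 + 0.16 + 0) / 3),
               tolerance = 1e-7)
  # target's own gene excluded
  expect_false("T" %in% hits$gene)
  # dissimilar direction reverses the ranking
  dis <- find_similar(m, "T", top_k = 2, direction = "dissimilar")
  expect_identical(dis$gene[1], "X")
})

test_that("similarity ranking equals the brute-force oracle with ties and missing data", {
  set.seed(42)
  for (rep in 1:3) {
    n_sites <- 20; n_samp <- 15
    vals <- matrix(runif(n_sites * n_samp), nrow = n_sites)
    vals[sample(length(vals), round(0.1 * length(vals)))] <- NA
    genes <- paste0("G", rep(1:10, each = 2))
    m <- fixture_meth_matrix(paste0(genes, "_cg", 1:n_sites), vals,
                             paste0("s", 1:n_samp))
    vals <- unname(m$values)   # as stored, so both routes see one dataset
    tvec <- colMeans(vals[1:2, ], na.rm = TRUE)

    # oracle: exhaustive per-gene minimum of pairwise RMS distances
    oracle <- data.frame(gene = character(), site = character(),
                         d = numeric(), stringsAsFactors = FALSE)
    for (g in unique(genes[-(1:2)])) {
      rows <- which(genes == g)
      ds <- vapply(rows, function(i) oracle_distance(tvec, vals[i, ]),
                   numeric(1))
      sites <- paste0("cg", rows)
      ok <- !is.na(ds)
      ds <- ds[ok]; sites <- sites[ok]
      ord <- order(ds, sites)
      oracle[nrow(oracle) + 1, ] <- list(g, sites[ord[1]], ds[ord[1]])
    }
    oracle <- oracle[order(oracle$d, oracle$gene), ]

    hits <- find_similar(m, "G1", top_k = nrow(oracle))
    expect_identical(hits$gene, oracle$gene)
    expect_identical(hits$site_id, oracle$site)
    expect_equal(hits$distance, oracle$d, tolerance = 1e-12)
    expect_identical(hits$rank, seq_len(nrow(hits)))
    expect_true(all(diff(hits$distance) >= 0))
  }
})

test_that("pattern distance is symmetric, zero iff equal on shared samples", {
  set.seed(5)
  for (i in 1:20) {
    a <- runif(8); b <- runif(8)
    a[sample(8, 2)] <- NA; b[sample(8, 2)] <- NA
    expect_identical(methpath:::pattern_distance(a, b),
                     methpath:::pattern_distance(b, a))
    expect_identical(methpath:::pattern_distance(a, a), 0)
  }
  # fewer than two shared samples: undefined
  expect_true(is.na(methpath:::pattern_distance(c(1, NA, NA), c(NA, 1, 1))))
})

test_that("spearman correlation matches hand computation and flags constants", {
  # perfect anti-monotone
  cc <- methylation_expression_correlation(c(1, 2, 3), c(6, 4, 2))
  expect_identical(cc$rho, -1)
  # ranks (1,3,2,4) vs (4,3,2,1): 1 - 6*18/(4*15) = -0.8
  cc <- methylation_expression_correlation(c(10, 30, 20, 40),
                                           c(9, 7, 5, 3))
  expect_equal(cc$rho, -0.8, tolerance = 1e-12)
  # p-value agrees with the t-approximation used by cor.test(exact = FALSE)
  x <- c(0.1, 0.5, 0.3, 0.9, 0.7, 0.2, 0.8)
  y <- c(9, 4, 6, 1, 3, 8, 2)
  cc <- methylation_expression_correlation(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(cc$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(cc$p_value, ref$p.value, tolerance = 1e-9)
  # constant vector: undefined, not an error
  cc <- methylation_expression_correlation(c(1, 2, 3), c(5, 5, 5))
  expect_true(cc$undefined)
  expect_true(is.na(cc$rho))
  # too few pairs is a precondition error
  expect_error(methylation_expression_correlation(c(1, 2), c(2, 1)),
               "at least 3")
})

test_that("monotone-coupled pairs reach rho -1, independent pairs stay weak", {
  set.seed(9)
  n <- 40
  beta <- runif(n)
  expr <- 100 * 2^(-3 * beta)   # strictly decreasing, no noise
  expect_equal(methylation_expression_correlation(beta, expr)$rho, -1,
               tolerance = 1e-12)
  indep <- runif(n)
  expect_lt(abs(methylation_expression_correlation(beta, indep)$rho), 0.5)
})

test_that("sample ordering is ascending, stable, undefined last", {
  m <- fixture_meth_matrix(
    c("A_cg1", "B_cg2"),
    matrix(c(0.9, 0.1, 0.5, 0.5, NA,
             0.1, 0.1, 0.1, 0.1, 0.1), nrow = 2, byrow = TRUE),
    paste0("s", 1:5))
  ord <- order_samples(m, "a")
  # ties s3/s4 keep original order; all-missing s5 last
  expect_identical(ord, c("s2", "s3", "s4", "s1", "s5"))
  expect_error(order_samples(m, "NOPE"), "not present")
  expect_error(order_samples(m, "A", filter_spec(sd_threshold = 0.9)),
               "no site passing")
})

test_that("overlays carry status flags and group values end to end", {
  g <- parse_kgml(fixture_kgml())
  # CASP3 has sites (one flat -> filtered), ERBB2 two variable sites,
  # FAS has no rows at all
  m <- fixture_meth_matrix(
    c("CASP3_cg1", "ERBB2_cg2", "ERBB2_cg3"),
    matrix(c(0.5, 0.5, 0.5, 0.5,
             0.1, 0.1, 0.9, 0.9,
             0.2, 0.2, 0.8, 0.8), nrow = 3, byrow = TRUE),
    paste0("s", 1:4))
  path <- withr::local_tempfile()
  writeLines(c("s1\tlow", "s2\tlow", "s3\thigh", "s4\thigh"), path)
  grp <- read_grouping(path, m)
  ov <- build_overlays(g, m, filter_spec(sd_threshold = 0.2), grp)
  by_gene <- stats::setNames(ov, vapply(ov, `[[`, character(1), "gene"))
  expect_identical(by_gene$CASP3$status, "no_passing_sites")
  expect_identical(by_gene$FAS$status, "no_data")
  expect_identical(by_gene$ERBB2$status, "ok")
  expect_true(by_gene$ERBB2$multi_site)
  expect_false(by_gene$CASP3$multi_site)
  expect_equal(unname(by_gene$ERBB2$per_group_value),
               c(0.15, 0.85))
  # expression overlays use fold values with group medians
  e <- fixture_expr_matrix("ERBB2", matrix(c(10, 20, 40, 80), 1),
                           paste0("s", 1:4))
  ove <- build_overlays(g, e, grouping = grp)
  erbb2 <- ove[[which(vapply(ove, `[[`, character(1), "gene") == "ERBB2")]]
  med <- stats::median(c(10, 20, 40, 80))
  expect_equal(unname(erbb2$per_group_value["low"]),
               log2((15 + 0.01) / (med + 0.01)), tolerance = 1e-9)
})
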