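test_that("beta gradient hits its endpoints exactly and interpolates linearly", {
  spec <- color_spec()
  expect_identical(beta_to_color(0, spec), "#00008B")
  expect_identical(beta_to_color(0.5, spec), "#FFFFFF")
  expect_identical(beta_to_color(1, spec), "#8B0000")
  # midpoint of the mid->high segment: linear-interpolation oracle
  mid <- round((col2rgb("#FFFFFF")[, 1] + col2rgb("#8B0000")[, 1]) / 2)
  expect_identical(beta_to_color(0.75, spec),
                   sprintf("#%02X%02X%02X", mid[1], mid[2], mid[3]))
  expect_error(beta_to_color(1.2), "out of range")
  expect_error(beta_to_color(-0.1), "out of range")
})

test_that("fold gradient: over-expression is blue, under-expression red", {
  spec <- color_spec()
  expect_identical(fold_to_color(0, 4, spec), "#FFFFFF")
  expect_identical(fold_to_color(4, 4, spec), spec$expr_over)   # blue pole
  expect_identical(fold_to_color(-4, 4, spec), spec$expr_under) # red pole
  expect_error(fold_to_color(5, 4, spec), "out of range")
})

test_that("gradients are monotone per channel along each segment", {
  spec <- color_spec()
  channel <- function(hex) col2rgb(hex)
  for (seg in list(seq(0, 0.5, length.out = 250),
                   seq(0.5, 1, length.out = 250))) {
    ch <- channel(beta_to_color(seg, spec))
    for (k in 1:3) {
      d <- diff(ch[k, ])
      expect_true(all(d >= 0) || all(d <= 0))
    }
  }
  for (seg in list(seq(-4, 0, length.out = 250),
                   seq(0, 4, length.out = 250))) {
    ch <- channel(fold_to_color(seg, 4, spec))
    for (k in 1:3) {
      d <- diff(ch[k, ])
      expect_true(all(d >= 0) || all(d <= 0))
    }
  }
})

render_fixture <- function() {
  g <- parse_kgml(fixture_kgml())
  m <- fixture_meth_matrix(
    c("CASP3_cg1", "ERBB2_cg2", "ERBB2_cg3"),
    matrix(c(0.5, 0.5, 0.5, 0.5,
             0.1, 0.1, 0.9, 0.9,
             0.2, 0.2, 0.8, 0.8), nrow = 3, byrow = TRUE),
    paste0("s", 1:4))
  path <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(c("s1\tlow", "s2\tlow", "s3\thigh", "s4\thigh"), path)
  grp <- read_grouping(path, m)
  ov <- build_overlays(g, m, filter_spec(sd_threshold = 0.2), grp)
  list(g = g, m = m, grp = grp, ov = ov)
}

test_that("group-wise pathway SVG has one sub-box per group per ok gene", {
  f <- render_fixture()
  svg <- render_pathway(f$g, f$ov, "group_wise", grouping = f$grp)
  doc <- xml2::read_xml(svg)
  rects <- xml2::xml_find_all(doc, ".//*[local-name()='rect']")
  fills <- xml2::xml_attr(rects, "fill")
  # ERBB2 (ok, 2 groups): group means 0.15 and 0.85 -> its two sub-box
  # fills are the exact gradient colors of those displayed values
  erbb2 <- f$ov[[which(vapply(f$ov, `[[`, character(1), "gene") == "ERBB2")]]
  expect_equal(unname(erbb2$per_group_value), c(0.15, 0.85))
  expect_true(all(beta_to_color(erbb2$per_group_value) %in% fills))
  # status fills appear exactly: CASP3 filtered out -> gray, FAS no data
  # -> light green
  expect_identical(sum(fills == color_spec()$no_passing_sites), 1L)
  expect_identical(sum(fills == color_spec()$no_data), 1L)
  # edge per relation
  lines <- xml2::xml_find_all(doc, ".//*[local-name()='line']")
  expect_length(lines, length(f$g$relations))
  # multi-site ERBB2 gets the green border
  strokes <- xml2::xml_attr(rects, "stroke")
  expect_true(color_spec()$multi_site_border %in% strokes)
  # group sizes annotated in the legend
  expect_match(svg, "low \\(2\\), high \\(2\\)")
})

test_that("rendering is byte-deterministic and view modes validate input", {
  f <- render_fixture()
  a <- render_pathway(f$g, f$ov, "group_wise", grouping = f$grp)
  b <- render_pathway(f$g, f$ov, "group_wise", grouping = f$grp)
  expect_identical(charToRaw(a), charToRaw(b))
  expect_error(render_pathway(f$g, f$ov, "group_wise"), "grouping")
  expect_error(render_pathway(f$g, f$ov, "single_sample"), "sample")
  # single-sample fill equals that sample's value color
  svg <- render_pathway(f$g, f$ov, "single_sample", sample = "s3")
  expect_match(svg, beta_to_color(0.85), fixed = TRUE)
})

test_that("gene grid lays overlays out row-major with the shared color rules", {
  f <- render_fixture()
  # 7 overlays by recycling
  ovs <- structure(rep(f$ov, length.out = 7), class = "gene_overlays",
                   kind = "methylation", fold_scale = 4)
  svg <- render_grid(ovs, "group_wise", grouping = f$grp, ncols = 3)
  doc <- xml2::read_xml(svg)
  texts <- xml2::xml_find_all(doc, ".//*[local-name()='text']")
  labels <- xml2::xml_text(texts)[-1]  # drop title
  expect_length(labels, 7L)
  # reading order preserves overlay order (rank order for similarity hits)
  expect_identical(labels,
                   vapply(ovs, `[[`, character(1), "gene"))
  # 3 columns x 3 rows, last row one cell: y coordinates form 3 levels
  ys <- as.numeric(xml2::xml_attr(texts[-1], "y"))
  expect_identical(length(unique(ys)), 3L)
  expect_identical(sum(ys == max(ys)), 1L)
  # 1 gene -> 1x1 grid renders fine
  one <- structure(f$ov[3], class = "gene_overlays", kind = "methylation",
                   fold_scale = 4)
  expect_no_error(render_grid(one, "group_wise", grouping = f$grp))
})

test_that("bar plot groups samples contiguously; histogram bins betas", {
  f <- render_fixture()
  ov <- f$ov[[which(vapply(f$ov, `[[`, character(1), "gene") == "ERBB2")]]
  res <- plot_gene(ov$per_sample_value, "ERBB2", grouping = f$grp,
                   kind = "barplot")
  expect_identical(nrow(res$data), 4L)
  expect_identical(res$data$group, c("low", "low", "high", "high"))
  expect_equal(res$data$value, unname(ov$per_sample_value[res$data$sample]))
  expect_match(res$svg, "<svg")

  hist_res <- plot_gene(stats::setNames(rep(0.5, 6), paste0("s", 1:6)),
                        "X", kind = "histogram", bins = 20)
  expect_identical(sum(hist_res$data$count > 0), 1L)
  expect_identical(sum(hist_res$data$count), 6L)
})

test_that("playback emits numbered deterministic frames in the given order", {
  f <- render_fixture()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ord <- order_samples(f$m, "ERBB2", filter_spec(sd_threshold = 0.2))
  p1 <- render_playback(f$g, f$ov, ord[1:3], d1)
  expect_identical(basename(p1),
                   c("frame_000.svg", "frame_001.svg", "frame_002.svg"))
  p2 <- render_playback(f$g, f$ov, ord[1:3], d2)
  for (i in 1:3) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
  # frames follow ascending displayed beta of the ordering gene
  vals <- f$ov[[which(vapply(f$ov, `[[`, character(1),
                             "gene") == "ERBB2")]]$per_sample_value
  expect_true(all(diff(vals[ord]) >= 0))
})

test_that("summary report blocks list sorted deduplicated matches", {
  rep <- summary_report(list(
    list(file = "a.tsv", pathway = "hsa04668",
         genes = c("FAS", "ERBB2", "erbb2")),
    list(file = "b.tsv", pathway = "hsa04668", genes = character(0))))
  blocks <- strsplit(rep, "\n\n")[[1]]
  expect_length(blocks, 2L)
  expect_match(blocks[1], "matched genes \\(2\\): ERBB2, FAS")
  expect_match(blocks[2], "matched genes \\(0\\)")
})

test_that("lookup URLs are built for the three annotation services", {
  urls <- gene_lookup_urls("ERBB2")
  expect_named(urls, c("genecards", "pubmed", "ensembl"))
  expect_match(urls["genecards"], "gene=ERBB2")
  expect_match(urls["pubmed"], "term=ERBB2")
})
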